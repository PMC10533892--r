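#' Idealized plateau-then-decay response trace
#'
#' Noiseless kinetic template of the biosensor response to a single
#' photostimulation pulse: the trace sits at `baseline` before `stim_time`,
#' jumps immediately to `baseline * (1 + A)`, holds that plateau for
#' `plateau_duration` seconds, then relaxes back toward `baseline` as a
#' single-phase exponential with rate constant `K` expressed per minute
#' (the convention for these recordings, although `t` is in seconds).
#'
#' @param t numeric vector of sample times (s), ascending.
#' @param baseline pre-stimulation level (arbitrary or F/F0 units).
#' @param A fractional rise (dimensionless), e.g. 0.65 for a 65% increase.
#' @param plateau_duration plateau length (s), >= 0.
#' @param K decay rate constant (per minute), >= 0.
#' @param stim_time stimulation onset (s).
#' @return numeric vector, the trace evaluated at `t`.
#' @export
#' @examples
#' t <- seq(0, 600, by = 5)
#' y <- simulate_trace(t, baseline = 1, A = 0.65, plateau_duration = 60,
#'                     K = 0.54, stim_time = 120)
simulate_trace <- function(t, baseline = 1, A = 0.65, plateau_duration = 60,
                           K = 0.54, stim_time = 0) {
  if (is.unsorted(t)) mp_stop("t must be ascending")
  if (plateau_duration < 0) mp_stop("plateau_duration must be >= 0")
  if (K < 0) mp_stop("K must be >= 0")
  y <- rep(baseline, length(t))
  on <- t >= stim_time
  tp <- stim_time + plateau_duration
  y[on & t < tp] <- baseline * (1 + A)
  post <- t >= tp
  y[post] <- baseline + baseline * A * exp(-K * (t[post] - tp) / 60)
  y
}

#' Multi-pulse response trace
#'
#' Extends [simulate_trace()] to repeated stimulation: at each pulse the
#' response resets to `baseline * (1 + A)` (re-oxidation to the same level),
#' holds the plateau, then decays with that pulse's own rate constant until
#' the next pulse.
#'
#' @param t sample times (s), ascending.
#' @param baseline pre-stimulation level.
#' @param A fractional rise per pulse (scalar or one per pulse).
#' @param plateau_duration plateau length (s).
#' @param K decay rate constants (per minute), recycled to one per pulse.
#' @param stim_times pulse onset times (s), ascending.
#' @return numeric vector.
#' @export
simulate_trace_multi <- function(t, baseline = 1, A = 0.65,
                                 plateau_duration = 60, K = c(0.54, 0.085),
                                 stim_times = numeric()) {
  if (length(stim_times) == 0L) return(rep(baseline, length(t)))
  if (is.unsorted(stim_times)) mp_stop("stim_times must be ascending")
  A <- rep_len(A, length(stim_times))
  K <- rep_len(K, length(stim_times))
  y <- rep(baseline, length(t))
  for (j in seq_along(stim_times)) {
    upper <- if (j < length(stim_times)) stim_times[j + 1] else Inf
    seg <- t >= stim_times[j] & t < upper
    y[seg] <- simulate_trace(t[seg], baseline, A[j], plateau_duration,
                             K[j], stim_times[j])
  }
  y
}

#' Simulate noisy dose-response samples from a standard curve
#'
#' Draws per-cell ratiometric responses at the given H2O2 concentrations from
#' a fitted (or constructed) sigmoid standard curve, with multiplicative
#' lognormal noise of a stated coefficient of variation. The lognormal is
#' mean-one, so `cv = 0` returns the curve values exactly.
#'
#' @param curve a [standard_curve()] object.
#' @param concentrations numeric vector of H2O2 concentrations (uM), >= 0.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param n_cells number of cells per concentration.
#' @param seed integer RNG seed.
#' @return data.frame with columns `microdomain`, `concentration_uM`,
#'   `response`, `cell_id`.
#' @export
simulate_dose_response <- function(curve, concentrations, cv = 0.05,
                                   n_cells = 10L, seed = 1L) {
  stopifnot(inherits(curve, "standard_curve"))
  if (cv < 0) mp_stop("cv must be >= 0")
  if (any(concentrations < 0)) mp_stop("concentrations must be >= 0")
  n_cells <- as.integer(n_cells)
  set.seed(as.integer(seed))
  conc <- rep(concentrations, each = n_cells)
  mu <- eval_standard_curve(curve, conc)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- rlnorm(length(conc), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise <- rep(1, length(conc))
  }
  data.frame(
    microdomain = curve$microdomain,
    concentration_uM = conc,
    response = mu * noise,
    cell_id = paste0("cell", rep(seq_len(n_cells), times = length(concentrations))),
    stringsAsFactors = FALSE
  )
}
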