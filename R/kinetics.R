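# Response kinetics: plateau-then-single-phase decay fits, half-rise times,
# AUC, and nested-model comparison by the extra sum-of-squares F test.

#' Plateau-then-single-phase-decay model
#'
#' `f(t) = plateau` for `t <= t0`;
#' `f(t) = baseline + (plateau - baseline) * exp(-K (t - t0) / 60)` after.
#' `K` is in F/F0 per minute (time in seconds, hence the /60).
#'
#' @param t times (s). @param plateau elevated level. @param t0 decay onset
#'   (s). @param K decay rate (per min). @param baseline asymptote.
#' @return model values.
#' @export
plateau_decay_model <- function(t, plateau, t0, K, baseline) {
  ifelse(t <= t0, plateau,
         baseline + (plateau - baseline) * exp(-K * (t - t0) / 60))
}

# For fixed (t0, K) the model is linear in (plateau, baseline):
# f = plateau * u + baseline * v with u = 1, v = 0 on the plateau and
# u = e, v = 1 - e on the decay. Solve the 2x2 normal equations, enforcing
# baseline >= 0 by clamping.
rss_linear <- function(t, y, t0, K, fixed_baseline = NA_real_) {
  e <- ifelse(t <= t0, 1, exp(-K * (t - t0) / 60))
  u <- e
  v <- 1 - e
  suu <- sum(u * u); svv <- sum(v * v); suv <- sum(u * v)
  suy <- sum(u * y); svy <- sum(v * y)
  if (is.finite(fixed_baseline)) {
    baseline <- fixed_baseline
    plateau <- (suy - baseline * suv) / suu
  } else {
    det <- suu * svv - suv * suv
    if (det > 1e-12 * suu * max(svv, 1e-300)) {
      plateau <- (suy * svv - svy * suv) / det
      baseline <- (svy * suu - suy * suv) / det
    } else {
      plateau <- suy / suu
      baseline <- 0
    }
    if (baseline < 0) {
      baseline <- 0
      plateau <- suy / suu
    }
  }
  fit <- plateau * u + baseline * v
  list(plateau = plateau, baseline = baseline, rss = sum((y - fit)^2))
}

rss_given_t0 <- function(t, y, t0, K_max, fixed_baseline = NA_real_) {
  f <- function(K) plateau_rss_cpp(t, y, t0, K, fixed_baseline)
  opt <- optimize(f, c(0, K_max), tol = 1e-9)
  # the optimum can sit at K = 0 (no decay); check the endpoint
  if (f(0) <= opt$objective) list(K = 0, rss = f(0))
  else list(K = opt$minimum, rss = opt$objective)
}

#' Fit the plateau-then-decay model to one trace
#'
#' Least squares over the post-stimulation points. The decay-onset
#' changepoint `t0` is handled by a grid search over the sample times
#' followed by local continuous refinement; for each candidate `t0` the rate
#' `K` is optimized one-dimensionally with `plateau` and `baseline` solved
#' in closed form (the model is conditionally linear).
#'
#' By default the asymptote is a free parameter bounded below by zero. For
#' slow decays observed over few time constants, `K` and a free asymptote
#' lie on a nearly flat ridge of the RSS surface and neither is precisely
#' estimable; when the asymptote is known — e.g. baseline-normalized traces
#' expected to relax back to F/F0 = 1 — `asymptote = "fixed"` conditions on
#' it and restores precision.
#'
#' @param time,value the trace (s, dimensionless).
#' @param stim_time stimulation onset (s); only `time >= stim_time` is fit.
#' @param K_max upper bound of the rate search (per min).
#' @param asymptote `"free"` (default) or `"fixed"`.
#' @param baseline_value asymptote used when `asymptote = "fixed"`.
#' @return object of class `decay_fit`: plateau, t0, K, baseline, RSS, n,
#'   converged. A flat trace yields `converged = FALSE` with `K = 0`
#'   (rate unidentifiable), not an error.
#' @export
fit_plateau_decay <- function(time, value, stim_time = 0, K_max = 60,
                              asymptote = c("free", "fixed"),
                              baseline_value = 1) {
  asymptote <- match.arg(asymptote)
  fb <- if (asymptote == "fixed") baseline_value else NA_real_
  sel <- time >= stim_time
  t <- time[sel]; y <- value[sel]
  n <- length(t)
  if (n < 8L) mp_stop("need at least 8 post-stimulation points")

  const_rss <- sum((y - mean(y))^2)
  scale2 <- max(const_rss, sum(y^2) * 1e-12)
  if (const_rss <= sum(y^2) * 1e-18) {
    return(structure(list(plateau = mean(y), t0 = t[1], K = 0,
                          baseline = mean(y), RSS = const_rss, n = n,
                          converged = FALSE,
                          note = "flat trace: rate unidentifiable"),
                     class = "decay_fit"))
  }

  # grid over t0 at the distinct sample times (t0 beyond the last point
  # would make the decay empty); duplicates arise from pooled datasets
  ut <- sort(unique(t))
  cand <- ut[-length(ut)]
  best <- NULL
  for (t0 in cand) {
    r <- rss_given_t0(t, y, t0, K_max, fb)
    if (is.null(best) || r$rss < best$rss) best <- c(r, list(t0 = t0))
  }
  # continuous refinement of t0 between the neighbouring sample points
  k <- which(cand == best$t0)[1]
  lo <- if (k > 1L) cand[k - 1L] else ut[1]
  hi <- if (k < length(cand)) cand[k + 1L] else ut[length(ut)]
  if (hi > lo) {
    ref <- optimize(function(t0) rss_given_t0(t, y, t0, K_max, fb)$rss,
                    c(lo, hi), tol = 1e-8)
    if (ref$objective < best$rss) {
      r <- rss_given_t0(t, y, ref$minimum, K_max, fb)
      best <- c(r, list(t0 = ref$minimum))
    }
  }
  # final polish of K at the chosen t0
  fin <- rss_given_t0(t, y, best$t0, K_max, fb)
  lin <- rss_linear(t, y, best$t0, fin$K, fb)
  structure(list(plateau = lin$plateau, t0 = best$t0, K = fin$K,
                 baseline = lin$baseline, RSS = lin$rss, n = n,
                 converged = lin$rss < const_rss + 1e-12 * scale2),
            class = "decay_fit")
}

#' Half-maximal rise time
#'
#' Peak response is the post-stimulation maximum; the half-rise time is the
#' first time the trace crosses `baseline + (peak - baseline)/2`, linearly
#' interpolated between samples, reported relative to `stim_time`.
#'
#' @param time,value the trace. @param stim_time stimulation onset (s).
#' @param baseline pre-stimulation level; defaults to the mean of the
#'   pre-stimulation samples (or the first sample if none).
#' @return list: T_half (s), peak_value, peak_time (s),
#'   method = "first-crossing, linear interpolation".
#' @export
t_half_rise <- function(time, value, stim_time = 0, baseline = NULL) {
  pre <- value[time < stim_time]
  if (is.null(baseline)) baseline <- if (length(pre)) mean(pre) else value[1]
  post <- time >= stim_time
  if (!any(post)) mp_stop("trace does not span the stimulation")
  tp <- time[post]; yp <- value[post]
  peak_i <- which.max(yp)
  peak <- yp[peak_i]
  if (peak <= baseline) mp_stop("no response above baseline")
  half <- baseline + (peak - baseline) / 2
  above <- which(yp >= half)
  i <- above[1]
  if (i == 1L) {
    # crossing within the first post-stimulation interval (or a step at the
    # stimulation frame); interpolate from the last pre-stimulation sample
    prev_t <- if (any(!post)) max(time[!post]) else stim_time
    prev_y <- if (any(!post)) value[which(time == prev_t)[1]] else baseline
  } else {
    prev_t <- tp[i - 1L]; prev_y <- yp[i - 1L]
  }
  t_cross <- if (yp[i] == prev_y) tp[i] else
    prev_t + (half - prev_y) / (yp[i] - prev_y) * (tp[i] - prev_t)
  t_cross <- max(t_cross, stim_time)
  list(T_half = t_cross - stim_time, peak_value = peak, peak_time = tp[peak_i],
       method = "first-crossing, linear interpolation")
}

#' Area under the curve (trapezoidal)
#'
#' Trapezoidal integral of `value - baseline_ref` over a time window; the
#' window endpoints are included by linear interpolation when they fall
#' between samples.
#'
#' @param time,value the trace. @param window length-2 numeric (s).
#' @param baseline_ref reference level subtracted before integration.
#' @return scalar area (dimensionless * s).
#' @export
auc_trace <- function(time, value, window = range(time), baseline_ref = 0) {
  if (length(window) != 2L || window[2] <= window[1])
    mp_stop("window must be an increasing length-2 range")
  if (window[1] < min(time) || window[2] > max(time))
    mp_stop("window outside the trace span")
  inside <- time > window[1] & time < window[2]
  tt <- c(window[1], time[inside], window[2])
  yy <- c(stats::approx(time, value, xout = window[1])$y, value[inside],
          stats::approx(time, value, xout = window[2])$y) - baseline_ref
  sum(diff(tt) * (head(yy, -1) + yy[-1]) / 2)
}

#' Extra sum-of-squares F test between two sets of decay traces
#'
#' Compares a shared plateau-decay fit (one parameter set for the pooled
#' data of both conditions) against separate fits, with
#' `F = ((RSS_shared - RSS_separate) / (df_shared - df_separate)) /
#' (RSS_separate / df_separate)` and a one-sided upper-tail p value.
#'
#' @param time_A,value_A,time_B,value_B the two datasets (pooled traces of
#'   each condition).
#' @param stim_time stimulation onset common to both.
#' @param n_par number of free model parameters (4: plateau, t0, K,
#'   baseline).
#' @return list: F, df_num, df_den, p, RSS_shared, RSS_separate, and the
#'   three fits.
#' @export
extra_ss_f_test <- function(time_A, value_A, time_B, value_B, stim_time = 0,
                            n_par = 4L) {
  fit_A <- fit_plateau_decay(time_A, value_A, stim_time)
  fit_B <- fit_plateau_decay(time_B, value_B, stim_time)
  fit_sh <- fit_plateau_decay(c(time_A, time_B), c(value_A, value_B),
                              stim_time)
  n_A <- fit_A$n; n_B <- fit_B$n
  rss_sep <- fit_A$RSS + fit_B$RSS
  rss_sh <- fit_sh$RSS
  df_sep <- n_A + n_B - 2L * n_par
  df_sh <- n_A + n_B - n_par
  if (df_sep <= 0L) mp_stop("not enough points for separate fits")
  # numerical safety: the shared model is nested, so RSS_shared >= RSS_separate
  Fstat <- max(0, ((rss_sh - rss_sep) / (df_sh - df_sep)) / (rss_sep / df_sep))
  list(F = Fstat, df_num = df_sh - df_sep, df_den = df_sep,
       p = pf(Fstat, df_sh - df_sep, df_sep, lower.tail = FALSE),
       RSS_shared = rss_sh, RSS_separate = rss_sep,
       fit_A = fit_A, fit_B = fit_B, fit_shared = fit_sh)
}
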