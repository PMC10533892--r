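# Microdomain-specific sigmoid standard curves for H2O2 dose-response data
# and their inversion into exogenous-H2O2-equivalent concentrations.

#' Sigmoid standard curve object
#'
#' Four-parameter logistic in concentration,
#' `S(c) = bottom + (top - bottom) / (1 + (EC50/c)^h)`, with the 0 uM anchor
#' handled as the limit `S(0) = bottom` (no log-dose dialect needed).
#'
#' @param microdomain compartment label (`"matrix"`, `"IMS"`, `"IBM"`,
#'   `"OMM"`, `"cytosol"`, ...).
#' @param bottom,top response units (R/R0), `bottom < top`.
#' @param EC50 midpoint concentration (uM), > 0.
#' @param hill Hill slope, > 0.
#' @param R2 goodness of fit in `[0, 1]` (NA for constructed curves).
#' @param normalization `"raw"` or `"baseline_saturation"`.
#' @return a `standard_curve` object.
#' @export
standard_curve <- function(microdomain, bottom, top, EC50, hill, R2 = NA_real_,
                           normalization = c("raw", "baseline_saturation")) {
  normalization <- match.arg(normalization)
  if (!(bottom < top)) mp_stop("need bottom < top")
  if (EC50 <= 0) mp_stop("EC50 must be positive")
  if (hill <= 0) mp_stop("Hill slope must be positive")
  if (!is.na(R2) && (R2 < 0 || R2 > 1)) mp_stop("R2 must lie in [0, 1]")
  structure(list(microdomain = microdomain, bottom = bottom, top = top,
                 EC50 = EC50, hill = hill, R2 = R2,
                 normalization = normalization), class = "standard_curve")
}

#' Evaluate a standard curve at given concentrations
#'
#' @param curve a [standard_curve()]. @param conc concentrations (uM), >= 0.
#' @return response values; `S(0) = bottom`.
#' @export
eval_standard_curve <- function(curve, conc) {
  if (any(conc < 0)) mp_stop("concentrations must be >= 0")
  out <- rep(curve$bottom, length(conc))
  pos <- conc > 0
  out[pos] <- curve$bottom + (curve$top - curve$bottom) /
    (1 + (curve$EC50 / conc[pos])^curve$hill)
  out
}

#' Fit a sigmoid standard curve to dose-response samples
#'
#' Per-cell responses are averaged per concentration before fitting (the
#' calibration convention for these curves), then the four-parameter
#' logistic is fit by least squares with multistart Nelder-Mead over
#' (bottom, top, log EC50, log hill). A warning is raised when the fit
#' quality misses the R^2 > 0.99 gate; downstream interpolation then marks
#' results as provisional.
#'
#' @param samples data.frame with columns `concentration_uM`, `response` and
#'   optionally `microdomain`.
#' @param microdomain label stored on the curve (defaults to the samples'
#'   single microdomain, or "unknown").
#' @param r2_gate required goodness of fit (default 0.99).
#' @return a `standard_curve` with `R2` filled in.
#' @export
fit_standard_curve <- function(samples, microdomain = NULL, r2_gate = 0.99) {
  if (is.null(microdomain))
    microdomain <- if ("microdomain" %in% names(samples) &&
                       length(unique(samples$microdomain)) == 1L)
      samples$microdomain[1] else "unknown"
  conc <- samples$concentration_uM
  resp <- samples$response
  if (any(conc < 0)) mp_stop("concentrations must be >= 0")
  mconc <- sort(unique(conc))
  if (length(mconc) < 4L) mp_stop("need >= 4 distinct concentrations")
  mresp <- vapply(mconc, function(cc) mean(resp[conc == cc]), 0.0)
  if (max(mresp) - min(mresp) <= 1e-12 * max(abs(mresp), 1))
    mp_stop("degenerate dose-response data: no spread in responses")

  obj <- function(par) {
    bottom <- par[1]; top <- par[2]
    ec50 <- exp(par[3]); h <- exp(par[4])
    if (!(bottom < top)) return(1e12)
    mu <- bottom + (top - bottom) / (1 + (ec50 / pmax(mconc, 1e-300))^h)
    mu[mconc == 0] <- bottom
    sum((mresp - mu)^2)
  }
  span <- max(mresp) - min(mresp)
  half <- min(mresp) + span / 2
  ec50_guess <- stats::approx(mresp, mconc, xout = half, ties = mean)$y
  if (is.na(ec50_guess) || ec50_guess <= 0)
    ec50_guess <- stats::median(mconc[mconc > 0])
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) {
    start <- c(min(mresp), max(mresp), log(ec50_guess), log(h0))
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- best$par
  tss <- sum((mresp - mean(mresp))^2)
  r2 <- 1 - best$value / tss
  curve <- standard_curve(microdomain, bottom = par[1], top = par[2],
                          EC50 = exp(par[3]), hill = exp(par[4]),
                          R2 = max(0, min(1, r2)))
  if (r2 <= r2_gate)
    mp_warn("standard curve for ", microdomain, " fails the R2 gate (R2 = ",
            signif(r2, 4), " <= ", r2_gate, "); equivalents are provisional")
  curve
}

#' Baseline/saturation normalization of responses
#'
#' Linear rescale `r' = (r - baseline) / (saturation - baseline)`, mapping
#' the baseline response to 0 and the saturating response to 1. Values may
#' fall slightly outside `[0, 1]` under noise; they are not clipped.
#'
#' @param responses numeric.
#' @param baseline_resp,saturation_resp scalars, `saturation > baseline`.
#' @return normalized responses.
#' @export
normalize_baseline_saturation <- function(responses, baseline_resp,
                                          saturation_resp) {
  if (saturation_resp <= baseline_resp)
    mp_stop("saturation response must exceed baseline response")
  (responses - baseline_resp) / (saturation_resp - baseline_resp)
}

#' Interpolate an exogenous-H2O2-equivalent concentration
#'
#' Inverts the standard curve: `c = EC50 * ((r - bottom)/(top - r))^(1/h)`.
#' The result is the bath concentration that would elicit the same response
#' in that microdomain -- explicitly not an in-situ concentration. Responses
#' at or below the fitted bottom are flagged `below_baseline` (the exclusion
#' rule for cells that decreased below baseline); responses at or above the
#' saturation cutoff (fitted top minus 1% of span) are flagged
#' `above_saturation`.
#'
#' @param response measured response (same units as the curve).
#' @param curve a fitted [standard_curve()].
#' @return list: equivalent_conc (uM or NA), valid flag, reason in
#'   `ok`, `below_baseline`, `above_saturation`, and `provisional` (TRUE when
#'   the curve missed the R2 gate).
#' @export
interpolate_equivalents <- function(response, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  span <- curve$top - curve$bottom
  cutoff <- curve$top - 0.01 * span
  provisional <- !is.na(curve$R2) && curve$R2 <= 0.99
  if (response <= curve$bottom) {
    return(list(equivalent_conc = NA_real_, valid = FALSE,
                reason = "below_baseline", provisional = provisional))
  }
  if (response >= cutoff) {
    return(list(equivalent_conc = NA_real_, valid = FALSE,
                reason = "above_saturation", provisional = provisional))
  }
  conc <- curve$EC50 *
    ((response - curve$bottom) / (curve$top - response))^(1 / curve$hill)
  list(equivalent_conc = conc, valid = TRUE, reason = "ok",
       provisional = provisional)
}

#' Per-cell equivalents table across microdomains
#'
#' Applies [interpolate_equivalents()] to every cell response using the
#' standard curve of its microdomain; invalid cells are carried through with
#' their reason codes and excluded from the summary.
#'
#' @param per_cell_responses data.frame with columns `cell_id`,
#'   `microdomain`, `response` (and optionally `condition`).
#' @param curves named list of `standard_curve` objects, one per microdomain.
#' @return list with `cells` (per-cell table: equivalent_uM, valid, reason)
#'   and `summary` (per microdomain x condition: n, mean_uM, sd_uM).
#' @export
equivalents_table <- function(per_cell_responses, curves) {
  req <- unique(per_cell_responses$microdomain)
  missing <- setdiff(req, names(curves))
  if (length(missing))
    mp_stop("no standard curve for microdomain(s): ",
            paste(missing, collapse = ", "))
  cells <- per_cell_responses
  res <- lapply(seq_len(nrow(cells)), function(i)
    interpolate_equivalents(cells$response[i],
                            curves[[cells$microdomain[i]]]))
  cells$equivalent_uM <- vapply(res, function(r)
    if (r$valid) r$equivalent_conc else NA_real_, 0.0)
  cells$valid <- vapply(res, function(r) r$valid, TRUE)
  cells$reason <- vapply(res, function(r) r$reason, "")
  ok <- cells[cells$valid, , drop = FALSE]
  if (!nrow(ok)) {
    mp_warn("no valid cells to summarize")
    summary <- data.frame(microdomain = character(), n = integer(),
                          mean_uM = numeric(), sd_uM = numeric())
  } else {
    grp <- if ("condition" %in% names(ok))
      interaction(ok$microdomain, ok$condition, drop = TRUE) else
        factor(ok$microdomain)
    summary <- do.call(rbind, lapply(levels(grp), function(g) {
      sub <- ok[grp == g, , drop = FALSE]
      data.frame(microdomain = sub$microdomain[1],
                 condition = if ("condition" %in% names(sub))
                   sub$condition[1] else NA_character_,
                 n = nrow(sub), mean_uM = mean(sub$equivalent_uM),
                 sd_uM = if (nrow(sub) > 1) sd(sub$equivalent_uM) else 0,
                 stringsAsFactors = FALSE)
    }))
  }
  list(cells = cells, summary = summary)
}
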