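# Sigmoid standard curves: fitting, normalization, inverse interpolation
# and gating.

test_that("noiseless 4PL parameters are recovered essentially exactly", {
  cu <- standard_curve("matrix", bottom = 1, top = 6.5, EC50 = 1.4, hill = 1.8)
  dr <- simulate_dose_response(cu, c(0, 0.25, 0.5, 1, 2.5, 5, 10, 25),
                               cv = 0, n_cells = 2, seed = 1)
  fit <- fit_standard_curve(dr)
  expect_equal(fit$bottom, 1, tolerance = 1e-6)
  expect_equal(fit$top, 6.5, tolerance = 1e-6)
  expect_equal(fit$EC50, 1.4, tolerance = 1e-6)
  expect_equal(fit$hill, 1.8, tolerance = 1e-6)
  expect_gt(fit$R2, 0.9999)
})

test_that("degenerate or insufficient dose-response data error out", {
  flat <- data.frame(concentration_uM = c(0, 1, 5, 25), response = 2)
  expect_error(fit_standard_curve(flat), "degenerate")
  few <- data.frame(concentration_uM = c(0, 1, 5), response = c(1, 2, 3))
  expect_error(fit_standard_curve(few), "4 distinct")
})

test_that("poor fits trigger the R2 gate warning and provisional flag", {
  set.seed(3)
  noisy <- data.frame(concentration_uM = rep(c(0, 0.5, 2, 8, 25), each = 4),
                      response = runif(20, 1, 6))
  expect_warning(fit <- fit_standard_curve(noisy), "R2 gate")
  res <- interpolate_equivalents(mean(c(fit$bottom, fit$top)), fit)
  expect_true(res$provisional)
})

test_that("baseline/saturation normalization is linear and idempotent", {
  expect_equal(normalize_baseline_saturation(2, 2, 6), 0)
  expect_equal(normalize_baseline_saturation(6, 2, 6), 1)
  expect_equal(normalize_baseline_saturation(4, 2, 6), 0.5)
  v <- c(0, 0.3, 1, 1.02)
  expect_equal(normalize_baseline_saturation(v, 0, 1), v)
  expect_error(normalize_baseline_saturation(1, 5, 5), "exceed")
})

test_that("interpolation inverts the curve and applies exclusion rules", {
  # hill = 1.5: S(25) stays below the saturation gate, so (0, 25] inverts
  cu <- standard_curve("IMS", bottom = 1.1, top = 5.2, EC50 = 1.9, hill = 1.5)
  # roundtrip over the working range
  for (c0 in c(0.01, 0.25, 1, 1.9, 2.5, 10, 25)) {
    r <- eval_standard_curve(cu, c0)
    res <- interpolate_equivalents(r, cu)
    expect_true(res$valid)
    expect_equal(res$equivalent_conc, c0, tolerance = 1e-9)
  }
  # midpoint response maps to EC50 exactly
  expect_equal(interpolate_equivalents((1.1 + 5.2) / 2, cu)$equivalent_conc,
               1.9, tolerance = 1e-12)
  # exclusion rules
  low <- interpolate_equivalents(1.0, cu)
  expect_false(low$valid); expect_equal(low$reason, "below_baseline")
  high <- interpolate_equivalents(5.19, cu)
  expect_false(high$valid); expect_equal(high$reason, "above_saturation")
})

test_that("curve and inverse are strictly monotone", {
  cu <- standard_curve("OMM", bottom = 1, top = 4, EC50 = 1.2, hill = 1.5)
  cc <- seq(0.05, 25, length.out = 200)
  ss <- eval_standard_curve(cu, cc)
  expect_true(all(diff(ss) > 0))
  rr <- seq(1.01, 3.9, length.out = 100)
  inv <- vapply(rr, function(r) interpolate_equivalents(r, cu)$equivalent_conc, 0.0)
  expect_true(all(diff(inv) > 0))
})

test_that("equivalents tables recover cohort means and carry reason codes", {
  curves <- list(
    matrix = standard_curve("matrix", 1, 6.5, 1.4, 1.8),
    IMS = standard_curve("IMS", 1.05, 5.0, 1.7, 2.0),
    OMM = standard_curve("OMM", 0.95, 4.2, 1.2, 1.6))
  true_conc <- c(matrix = 1.0, IMS = 0.8, OMM = 1.0)
  set.seed(11)
  cells <- do.call(rbind, lapply(names(true_conc), function(md) {
    n <- 25
    resp <- eval_standard_curve(curves[[md]], true_conc[[md]]) *
      exp(rnorm(n, 0, sqrt(log(1 + 0.05^2))))
    data.frame(cell_id = paste0(md, seq_len(n)), microdomain = md,
               response = resp)
  }))
  tab <- equivalents_table(cells, curves)
  for (md in names(true_conc)) {
    got <- tab$summary$mean_uM[tab$summary$microdomain == md]
    expect_equal(got, true_conc[[md]], tolerance = 0.05)
  }
  # single noiseless cell is exact
  one <- data.frame(cell_id = "c1", microdomain = "matrix",
                    response = eval_standard_curve(curves$matrix, 1.3))
  expect_equal(equivalents_table(one, curves)$cells$equivalent_uM, 1.3,
               tolerance = 1e-9)
  # all-saturated cohort: flagged, empty summary with a warning
  sat <- data.frame(cell_id = c("a", "b"), microdomain = "matrix",
                    response = c(6.5, 7))
  expect_warning(tab2 <- equivalents_table(sat, curves), "no valid")
  expect_true(all(tab2$cells$reason == "above_saturation"))
  expect_equal(nrow(tab2$summary), 0L)
  expect_error(equivalents_table(
    data.frame(cell_id = "x", microdomain = "IBM", response = 2), curves),
    "no standard curve")
})
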