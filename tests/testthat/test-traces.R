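# Normalized traces, distances, population classification, morphology
# metrics and population summaries.

test_that("area normalization is a pure density and scale-invariant", {
  tr <- data.frame(area_um2 = c(1, 2, 4), sum_biosensor = c(100, 200, 400))
  expect_equal(area_normalize(tr), c(100, 100, 100))
  tr2 <- tr; tr2$sum_biosensor <- tr2$sum_biosensor * 2
  tr2$area_um2 <- tr2$area_um2 * 2
  expect_equal(area_normalize(tr2), area_normalize(tr))
  tr$area_um2[2] <- 0
  expect_error(area_normalize(tr), "area")
})

test_that("baseline normalization is exact and scale invariant", {
  expect_equal(baseline_normalize(rep(3, 5), 1:2), rep(1, 5))
  v <- c(1, 1, 1, 1.65, 1.65)
  expect_equal(baseline_normalize(v * 7, 1:3), baseline_normalize(v, 1:3),
               tolerance = 1e-12)
  expect_equal(baseline_normalize(v, 1:3, dff = TRUE)[4], 0.65)
  expect_error(baseline_normalize(c(-1, -1, 2), 1:2), "positive")
  expect_error(baseline_normalize(v, integer()), "empty")
})

test_that("ratiometric traces cancel common losses", {
  b <- 1:3
  expect_equal(ratiometric_trace(c(5, 5, 5, 5), c(5, 5, 5, 5), b), rep(1, 4))
  r <- ratiometric_trace(c(4, 4, 4, 8), c(2, 2, 2, 2), b)
  expect_equal(r[4], 2)
  bleach <- exp(-0.1 * (0:3))
  r2 <- ratiometric_trace(c(4, 4, 4, 8) * bleach, c(2, 2, 2, 2) * bleach, b)
  expect_equal(r2, r, tolerance = 1e-12)
  expect_error(ratiometric_trace(1:3, c(1, 0, 1), 1), "positive")
})

test_that("quench ratio preserves compartment ordering of quench rates", {
  t <- seq(0, 1000, by = 10)
  b <- which(t < 100)
  ref <- exp(-t / 300)                      # cytosolic reference quenches
  expect_equal(quench_ratio_trace(ref, ref, b), rep(1, length(t)))
  r <- quench_ratio_trace(rep(1, length(t)), ref, b)
  expect_true(all(diff(r) >= 0))
  # sensor quench rates ordered OMM fastest, matrix slowest
  rates <- c(matrix = 1 / 2000, IMS = 1 / 800, OMM = 1 / 300)
  endpoint <- vapply(rates, function(k)
    quench_ratio_trace(exp(-k * t), ref, b)[t == 1000], 0.0)
  expect_true(endpoint[["matrix"]] > endpoint[["IMS"]])
  expect_true(endpoint[["IMS"]] > endpoint[["OMM"]])
})

test_that("distances and population thresholds follow the stated rules", {
  tr <- data.frame(x_um = 3, y_um = 4)
  expect_equal(distance_to_stim(tr, c(0, 0)), 5)
  expect_equal(distance_to_stim(data.frame(x_um = 2, y_um = 9), c(2, 9)), 0)
  expect_error(distance_to_stim(tr, NULL), "stim_point")

  cfg <- population_config("HEK")
  # M = 20 um: d = 5 -> proximal, 15 -> distal, 10 -> other, 1 -> spot
  d <- c(5, 15, 10, 1, 20)
  expect_identical(mitopulse:::classify_distances(d, cfg),
                   c("proximal", "distal", "other", "spot", "distal"))
  mef <- population_config("MEF")
  # MEF thresholds 20%/50% of M = 20: d = 3 proximal, 8 in the gap, 15 distal
  expect_identical(mitopulse:::classify_distances(c(3, 15, 8, 20), mef),
                   c("proximal", "distal", "other", "distal"))
  expect_error(mitopulse:::classify_distances(c(0, 0), cfg), "M is zero")
  expect_error(population_config(proximal_frac = 0.8, distal_frac = 0.7),
               "proximal_frac")
})

test_that("classify_population freezes labels from the reference window", {
  tracks <- data.frame(
    track_id = rep(1:3, each = 2), frame = rep(c(0, 1), 3),
    x_um = c(1, 10, 6, 6, 20, 20), y_um = 0)
  labs <- classify_population(tracks, c(0, 0), population_config("HEK"),
                              reference_frames = 0)
  expect_identical(labs$population, c("spot", "other", "distal"))
  # reference at frame 1 changes track 1's label (it moved away)
  labs2 <- classify_population(tracks, c(0, 0), population_config("HEK"),
                               reference_frames = 1)
  expect_identical(labs2$population[1], "other")
})

test_that("form factor has the circle/square closed forms and rescales", {
  expect_equal(form_factor(2 * pi, pi), 1)
  expect_equal(form_factor(4, 1), 16 / (4 * pi) / 4 * 4)  # unit square 4/pi
  expect_equal(form_factor(4, 1), 4 / pi)
  expect_equal(form_factor(2 * pi * 3, pi * 9), 1)  # scale invariance
  expect_error(form_factor(0, 1), "positive")
})

test_that("population summaries partition and keep smoothing display-only", {
  df <- data.frame(frame = rep(0:4, 2),
                   value = c(rep(1, 5), rep(3, 5)),
                   population = rep(c("proximal", "distal"), each = 5))
  s <- population_summary(df, smooth_window = 3L)
  expect_true(all(s$sem == 0))
  expect_equal(s$mean[s$population == "proximal"], rep(1, 5))
  # proportions per frame sum to 1 over all populations
  tot <- tapply(s$proportion, s$frame, sum)
  expect_equal(unname(as.numeric(tot)), rep(1, 5))
  # smoothing touches only the display column
  expect_true("mean_smoothed" %in% names(s))
  expect_equal(s$mean[s$population == "distal"], rep(3, 5))
  # exclusions drop a population from both rows and denominators
  s2 <- population_summary(df, exclude = "distal")
  expect_false("distal" %in% s2$population)
  expect_equal(unique(s2$proportion), 1)
})

test_that("whole-channel scaling leaves all normalized outputs unchanged", {
  sim <- simulate_movie(noiseless_params(n_mitos = 3L, seed = 23L))
  seg <- segment_movie(sim$movie, segmentation_config())
  tr <- link_tracks(seg, frame_interval = 5)
  traces <- extract_traces(tr, sim$movie$meta)
  for (k in c(0.5, 3)) {
    tr2 <- tr
    tr2$sum_biosensor <- tr2$sum_biosensor * k
    traces2 <- extract_traces(tr2, sim$movie$meta)
    expect_equal(traces2$value, traces$value, tolerance = 1e-12)
  }
})

test_that("photosensitizer-expression normalization divides by the baseline", {
  expect_equal(normalize_kr_expression(c(2, 3), c(4, 10)), c(0.5, 0.3))
  expect_error(normalize_kr_expression(1, 0), "positive")
})
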