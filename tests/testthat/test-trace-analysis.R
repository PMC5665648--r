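test_that("molecule traces are extracted with interpolated gap frames flagged", {
  cal <- structure(list(unit_intensity = 35, unit_intensity_sd = 1,
                        exposure_reference = 21),
                   class = "calibration_curve")
  g <- acq_geometry(n_volumes = 20, volume_shape = c(24, 80, 80))
  s <- make_spots(frame = setdiff(3:9, 6), z = 3000, y = 4000, x = 4000,
                  amplitude = 35 * 12)
  track <- list(track_id = 7L, spots = s, gap_frames = 6L,
                flags = character(0), class_label = "I")
  tr <- extract_trace(track, cal, g)
  expect_s3_class(tr, "molecule_trace")
  expect_equal(nrow(tr), 7)
  expect_equal(tr$N, rep(12, 7), tolerance = 1e-9)
  expect_true(tr$interpolated[tr$frame == 6])
  expect_false(any(tr$interpolated[tr$frame != 6]))
  expect_equal(diff(tr$time), rep(0.85, 6), tolerance = 1e-12)
  expect_error(extract_trace(track, NULL, g), "calibration")
})

test_that("lifetime is occupied frames times the frame interval; censored traces are excluded", {
  tr <- fake_trace(rep(30, 12))
  expect_equal(lifetime(tr), 10.2)
  cen <- fake_trace(rep(30, 12), censored = TRUE)
  expect_true(is.na(lifetime(cen)))
  expect_true(attr(lifetime(cen), "censored"))
})

test_that("bi-exponential lifetime fit recovers generating parameters within 15%", {
  set.seed(801)
  n <- 2000
  comp <- runif(n) < 0.7
  x <- ifelse(comp, rexp(n, 1 / 4), rexp(n, 1 / 20))
  fit <- fit_biexponential(x)
  expect_equal(fit$w, 0.7, tolerance = 0.15)
  expect_equal(fit$tau1, 4, tolerance = 0.15)
  expect_equal(fit$tau2, 20, tolerance = 0.15)
  expect_equal(fit$K, 2L)
})

test_that("a single-exponential sample collapses to K = 1 with the rate recovered", {
  set.seed(802)
  x <- rexp(1500, 1 / 8)
  fit <- fit_biexponential(x)
  expect_equal(fit$K, 1L)
  expect_equal(fit$tau1, 8, tolerance = 0.1)
})

test_that("left truncation is handled: ignoring it biases tau1, modeling it does not", {
  set.seed(803)
  n <- 4000
  comp <- runif(n) < 0.7
  x <- ifelse(comp, rexp(n, 1 / 4), rexp(n, 1 / 20))
  xt <- x[x >= 2.5]
  naive <- fit_biexponential(xt, min_observable = 0)
  proper <- fit_biexponential(xt, min_observable = 2.5)
  expect_equal(proper$tau1, 4, tolerance = 0.2)
  # the untruncated fit misses the fast component badly
  expect_gt(abs(naive$tau1 - 4) / 4, abs(proper$tau1 - 4) / 4)
})

test_that("accumulation statistics match closed forms", {
  flat <- fake_trace(rep(24, 8))
  a <- accumulation_stats(flat)
  expect_equal(a$max_accumulation, 24)
  expect_equal(a$mean_accumulation, 24)
  tri <- accumulation_stats(c(0, 10, 20, 30, 20, 10, 0))
  expect_equal(tri$max_accumulation, 30)
  expect_equal(tri$mean_accumulation, mean(c(0, 10, 20, 30, 20, 10, 0)))
})

test_that("max-accumulation mixture reports the wild-type first mode and resolves bimodality", {
  set.seed(804)
  uni <- rnorm(3000, 24, 6)
  m1 <- fit_max_mixture(uni, K = 2)
  expect_equal(m1$mode, 24, tolerance = 0.03)
  expect_equal(m1$mode_sd, 6, tolerance = 0.15)
  # two hexamer populations (12 and 24 molecules = 2 and 4 hexamers)
  bi <- c(rnorm(1500, 12, 2.5), rnorm(1500, 24, 4))
  m2 <- fit_max_mixture(bi, K = 2)
  expect_equal(m2$means, c(12, 24), tolerance = 0.05)
  # degenerate: identical values
  m3 <- fit_max_mixture(rep(18, 50))
  expect_equal(m3$K, 1L)
  expect_equal(m3$mode, 18)
  expect_equal(m3$mode_sd, 0)
})

test_that("the multi-start EM matches an independent mixture fit at the global optimum", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(805)
  x <- c(rnorm(2000, 24, 6), rnorm(1000, 48, 9))
  mine <- fit_max_mixture(x, K = 2)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # same or better likelihood, and agreeing means when both converge well
  expect_gte(mine$loglik + 1e-6, ref$loglik)
  expect_equal(mine$mode, min(ref$parameters$mean), tolerance = 0.02)
})

test_that("cohort averaging reproduces identical traces and drops thin cohorts", {
  tmpl <- c(0, 30, 32, 31, 30, 29, 0)
  traces <- c(replicate(15, fake_trace(tmpl[tmpl > 0]), simplify = FALSE),
              list(fake_trace(rep(20, 14))))   # lone long-lived trace
  cc <- cohort_curves(traces, bin_edges = c(3, 5, 10, 51), min_count = 10,
                      n_boot = 50)
  expect_length(cc, 1)
  expect_equal(cc[[1]]$n, 15)
  expect_equal(cc[[1]]$mean, tmpl[tmpl > 0], tolerance = 1e-9)
  expect_true("[10,51)" %in% attr(cc, "dropped"))
})

test_that("cross-correlation peaks at lag 0 for a trace against itself and at the imposed shift", {
  set.seed(806)
  base <- cumsum(rnorm(40)) + 30
  self <- cross_correlate(list(fake_trace(base)), list(fake_trace(base)),
                          max_lag = 5)
  i0 <- which(self$lags == 0)
  expect_equal(self$cc_intensity[i0], 1)
  expect_true(all(self$cc_intensity[-i0] < 1))
  shifted <- c(base[-(1:3)], base[1:3] * 0 + mean(base))
  cc <- cross_correlate(list(fake_trace(base)), list(fake_trace(shifted)),
                        max_lag = 5)
  expect_equal(cc$lags[which.max(cc$cc_derivative)], -3)
  # independent noise decorrelates
  noise <- cross_correlate(
    lapply(1:20, function(i) fake_trace(rnorm(40, 30, 5))),
    lapply(1:20, function(i) fake_trace(rnorm(40, 30, 5))),
    max_lag = 5)
  expect_lt(max(abs(noise$cc_intensity)), 2 / sqrt(40) + 0.1)
  expect_error(cross_correlate(list(fake_trace(rep(30, 5))),
                               list(fake_trace(rep(30, 5)))),
               "minimum lifetime")
})

test_that("fluctuation peaks honor topographic prominence", {
  bump <- c(0, 0, 10, 20, 10, 0, 0)
  p <- fluctuation_peaks(bump, min_prominence = 6)
  expect_equal(nrow(p), 1)
  expect_equal(p$height, 20)
  expect_equal(p$prominence, 20)
  two <- c(0, 18, 6, 10, 6, 30, 0)
  p6 <- fluctuation_peaks(two, min_prominence = 6)
  expect_equal(nrow(p6), 2)
  p14 <- fluctuation_peaks(two, min_prominence = 14)
  expect_equal(nrow(p14), 1)
  expect_equal(sort(p6$height), c(18, 30))
})

test_that("productive classification thresholds at four hexamers and matches ground truth", {
  expect_true(classify_productive(c(0, 12, 24, 12, 0)))
  expect_false(classify_productive(c(0, 12, 18, 12, 0)))
  expect_false(classify_productive(rep(0, 10)))
  set.seed(807)
  p <- protein_params("vps4")
  agree <- replicate(200, {
    counts <- simulate_trace(p, 850)$counts
    classify_productive(counts) ==
      (max(molecules_to_hexamers(counts)) >= 4)
  })
  expect_true(all(agree))
})

test_that("FRAP fitting recovers rates and flags non-recovering traces", {
  tr <- generate_frap_trace(k = 0.5, bleach_depth = 0.8,
                            mobile_fraction = 0.9, noise_sd = 0,
                            n_frames = 120, dt = 0.1)
  fit <- fit_frap(tr$time, tr$intensity)
  expect_equal(fit$k, 0.5, tolerance = 0.01)
  expect_equal(fit$mobile_fraction, 0.9, tolerance = 0.02)
  expect_false(fit$no_recovery)
  flat <- generate_frap_trace(mobile_fraction = 0, noise_sd = 0.002,
                              n_frames = 120, dt = 0.1)
  expect_true(fit_frap(flat$time, flat$intensity)$no_recovery)
  set.seed(808)
  ks <- replicate(40, {
    nz <- generate_frap_trace(k = 0.5, bleach_depth = 0.8,
                              mobile_fraction = 0.9, noise_sd = 0.05,
                              n_frames = 120, dt = 0.1)
    fit_frap(nz$time, nz$intensity)$k
  })
  expect_equal(mean(ks), 0.5, tolerance = 0.15)
})
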