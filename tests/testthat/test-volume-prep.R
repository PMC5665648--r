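make_series <- function(frames, geom, deskewed = TRUE) {
  llsmtrace:::new_volume_series(frames, geom, deskewed = deskewed)
}

test_that("flat-field correction is identity for uniform light and fixes a gradient", {
  g <- tiny_geom(shape = c(4, 20, 20))
  a <- array(runif(4 * 20 * 20, 90, 110), dim = c(4, 20, 20))
  vol <- make_series(list(a), g)
  unif <- matrix(1, 20, 20)
  expect_equal(flatfield_correct(vol, unif)$frames[[1]], a)
  # linear 2x illumination gradient along x, applied then corrected
  prof <- matrix(rep(seq(1, 2, length.out = 20), each = 20), 20, 20)
  flat <- array(100, dim = c(4, 20, 20))
  shaded <- flat
  for (k in 1:4) shaded[k, , ] <- flat[k, , ] * prof / mean(prof)
  fixed <- flatfield_correct(make_series(list(shaded), g), prof)$frames[[1]]
  col_means <- apply(fixed, 3, mean)
  expect_lt(max(abs(col_means - mean(col_means))) / mean(col_means), 0.01)
  bad <- prof; bad[1, 1] <- 0
  expect_error(flatfield_correct(vol, bad), "strictly positive")
})

test_that("deskew geometry: 500 nm step at 31.5 degrees gives a 261 nm z-step and 90 degrees is a pure restack", {
  g <- tiny_geom(shape = c(6, 10, 10))
  expect_equal(round(g$z_step), 261)
  g90 <- acq_geometry(sheet_angle = 89.999, volume_shape = c(6, 10, 10),
                      n_volumes = 1)
  a <- array(runif(600), dim = c(6, 10, 10))
  out <- deskew(make_series(list(a), g90, deskewed = FALSE))
  expect_equal(dim(out$frames[[1]]), c(6, 10, 10))
  expect_equal(out$frames[[1]], a, tolerance = 1e-6)
})

test_that("deskew refuses already-deskewed input and conserves intensity", {
  set.seed(401)
  m <- tiny_models()
  pos <- matrix(c(8 * m$geom$z_step, 12 * m$geom$pixel_size_xy,
                  50 * m$geom$pixel_size_xy), 1, 3)
  sc <- build_scene(0, 0, m$geom, background_photon_rate = 0)
  sc$emitters <- list(list(emitter_id = 1L, class_label = "I",
                           positions = pos, counts = 40L,
                           onset_frame = 1L, release_frame = 1L))
  cam0 <- camera_model(offset = 0, read_noise = 0)
  r <- render_volume_series(sc, m$geom, cam0, m$fluor, m$psf,
                            shape = c(17, 25, 25), skewed = TRUE)
  skewed <- r$channels[[1]]
  out <- deskew(skewed, fill = 0)
  expect_error(deskew(out), "already deskewed")
  expect_equal(sum(out$frames[[1]]), sum(skewed$frames[[1]]),
               tolerance = 0.005)
})

test_that("a skewed-rendered point source deskews back to its true position", {
  set.seed(402)
  m <- tiny_models()
  g <- m$geom
  pos <- matrix(c(8 * g$z_step, 12 * g$pixel_size_xy,
                  50 * g$pixel_size_xy), 1, 3)
  sc <- build_scene(0, 0, g)
  sc$emitters <- list(list(emitter_id = 1L, class_label = "I",
                           positions = pos, counts = 30L,
                           onset_frame = 1L, release_frame = 1L))
  r <- render_volume_series(sc, g, m$cam, m$fluor, m$psf,
                            shape = c(17, 25, 25), skewed = TRUE)
  dsk <- deskew(r$channels[[1]])
  sp <- detect_frame(dsk$frames[[1]], m$psf, g)
  i <- which.max(sp$amplitude)
  expect_lt(abs(sp$z[i] - pos[1]) / g$z_step, 0.5)
  expect_lt(abs(sp$y[i] - pos[2]) / g$pixel_size_xy, 0.5)
  expect_lt(abs(sp$x[i] - pos[3]) / g$pixel_size_xy, 0.5)
})

test_that("Richardson-Lucy sharpens a blurred point and conserves flux", {
  g <- tiny_geom(shape = c(13, 15, 15))
  psf <- psf_model(geom = g)
  # noise-free blurred point: the PSF kernel itself, embedded mid-volume
  a <- array(0, dim = c(13, 15, 15))
  k <- psf$kernel
  off <- (c(13, 15, 15) - dim(k)) %/% 2
  a[off[1] + seq_len(dim(k)[1]), off[2] + seq_len(dim(k)[2]),
    off[3] + seq_len(dim(k)[3])] <- k * 1000
  vol <- make_series(list(a), g)
  prev_peak <- max(a)
  for (it in c(5, 15)) {
    out <- richardson_lucy(vol, psf, iterations = it)$frames[[1]]
    expect_gt(max(out), prev_peak)
    prev_peak <- max(out)
    expect_true(all(out >= 0))
    expect_equal(sum(out), sum(a), tolerance = 0.01)
  }
})

test_that("Richardson-Lucy handles identity, zero input and unnormalized kernels", {
  g <- tiny_geom(shape = c(5, 9, 9))
  a <- array(runif(5 * 9 * 9, 0, 50), dim = c(5, 9, 9))
  delta <- psf_model(geom = g)
  delta$kernel <- array(0, dim = c(3, 3, 3)); delta$kernel[2, 2, 2] <- 1
  out <- richardson_lucy(make_series(list(a), g), delta,
                         iterations = 5)$frames[[1]]
  expect_equal(out, a, tolerance = 1e-6)
  zero <- richardson_lucy(make_series(list(array(0, dim(a))), g), delta)
  expect_true(all(zero$frames[[1]] == 0))
  unnorm <- delta; unnorm$kernel <- delta$kernel * 2
  logged <- richardson_lucy(make_series(list(a), g), unnorm, iterations = 2)
  expect_true(any(grepl("renormalized", logged$provenance)))
})

test_that("RL output stays non-negative for arbitrary non-negative inputs", {
  set.seed(403)
  g <- tiny_geom(shape = c(7, 11, 11))
  psf <- psf_model(geom = g, half_width_sigmas = 2)
  for (i in 1:5) {
    a <- array(rexp(7 * 11 * 11, 1 / 20), dim = c(7, 11, 11))
    out <- richardson_lucy(make_series(list(a), g), psf, iterations = 5,
                           background = 2)$frames[[1]]
    expect_true(all(out >= 0))
  }
})
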