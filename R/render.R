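#' @keywords internal
new_volume_series <- function(frames, geom, channel = "eGFP",
                              deskewed = TRUE, provenance = character()) {
  structure(list(frames = frames, geometry = geom, channel = channel,
                 deskewed = deskewed, provenance = provenance),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("volume_series [%s]: %d frames of %d x %d x %d (z,y,x), %s\n",
              x$channel, length(x$frames), d[1], d[2], d[3],
              if (x$deskewed) "deskewed" else "skewed"))
  invisible(x)
}

# EMCCD forward model: scaled-Poisson shot noise with excess noise factor F
# (variance F^2 x shot), Gaussian read noise, constant offset.
emccd_counts <- function(expected_pe, cam) {
  f2 <- cam$excess_noise_factor^2
  n <- length(expected_pe)
  counts <- cam$offset +
    cam$gain * f2 * stats::rpois(n, as.vector(expected_pe) / f2) +
    stats::rnorm(n, 0, cam$read_noise)
  array(counts, dim = dim(expected_pe))
}

# Expected photoelectron field for one frame of a scene (z, y, x array).
# Molecule counts may carry a per-channel bleach survival factor already.
expected_pe_frame <- function(positions_nm, molecules, geom, cam, fluor,
                              psf, shape, skewed = FALSE) {
  exposure <- geom$exposure_per_plane
  shift <- if (skewed) geom$stage_step_s * cos(geom$sheet_angle * pi / 180)
           else 0
  pe <- array(0, dim = shape)
  if (length(molecules) == 0 || all(molecules == 0)) return(pe)
  sx <- psf$sigma_xy; sz <- psf$sigma_z
  hx <- ceiling(4.5 * sx / geom$pixel_size_xy)
  hz <- ceiling(4.5 * sz / geom$z_step)
  for (e in seq_along(molecules)) {
    if (molecules[e] <= 0) next
    total_pe <- molecules[e] * fluor$photon_rate * exposure *
      cam$quantum_efficiency
    zc <- positions_nm[e, 1]; yc <- positions_nm[e, 2]
    xc <- positions_nm[e, 3]
    iz <- round(zc / geom$z_step) + 1
    zlo <- max(1, iz - hz); zhi <- min(shape[1], iz + hz)
    if (zlo > zhi) next
    zr <- zlo:zhi
    gz <- exp(-0.5 * (((zr - 1) * geom$z_step - zc) / sz)^2)
    iy <- round(yc / geom$pixel_size_xy) + 1
    ylo <- max(1, iy - hx); yhi <- min(shape[2], iy + hx)
    if (ylo > yhi) next
    yr <- ylo:yhi
    gy <- exp(-0.5 * (((yr - 1) * geom$pixel_size_xy - yc) / sx)^2)
    # in skewed (raw stage-scan) frames each plane is laterally displaced
    for (zi in seq_along(zr)) {
      x0 <- xc - (zr[zi] - 1) * shift
      ix <- round(x0 / geom$pixel_size_xy) + 1
      xlo <- max(1, ix - hx); xhi <- min(shape[3], ix + hx)
      if (xlo > xhi) next
      xr <- xlo:xhi
      gx <- exp(-0.5 * (((xr - 1) * geom$pixel_size_xy - x0) / sx)^2)
      w <- gz[zi] * outer(gy, gx)
      pe[zr[zi], yr, xr] <- pe[zr[zi], yr, xr] + total_pe * w /
        psf_grid_norm(psf, geom)
    }
  }
  pe
}

# Normalization of a Gaussian sampled on the voxel grid: sum over an
# unclipped footprint, independent of sub-voxel offset to high accuracy.
psf_grid_norm <- function(psf, geom) {
  sxp <- psf$sigma_xy / geom$pixel_size_xy
  szp <- psf$sigma_z / geom$z_step
  (sxp * sqrt(2 * pi))^2 * (szp * sqrt(2 * pi))
}

# Peak weight of the sampled PSF: fraction of total expected photons that
# lands in the amplitude of the fitted (sampled) Gaussian.
psf_peak_weight <- function(psf, geom) 1 / psf_grid_norm(psf, geom)

#' Predicted single-fluorophore fit amplitude
#'
#' The amplitude (in camera counts) that the 3D Gaussian fit reports for
#' one fluorophore imaged for one plane exposure: photon budget times
#' quantum efficiency, gain, and the voxel-sampled PSF peak weight.
#'
#' @param geom,cam,fluor,psf Acquisition geometry, camera, fluorophore and
#'   PSF models.
#' @return Expected amplitude in counts per molecule.
#' @export
unit_amplitude <- function(geom = acq_geometry(), cam = camera_model(),
                           fluor = fluorophore_model(),
                           psf = psf_model(geom = geom)) {
  fluor$photon_rate * geom$exposure_per_plane * cam$quantum_efficiency *
    cam$gain * psf_peak_weight(psf, geom)
}

#' Render a scene into noisy EMCCD volume series
#'
#' Forward model of the acquisition: expected photons per emitter per plane
#' are `molecules x photon_rate x exposure x QE x bleach survival`,
#' distributed over voxels by the anisotropic Gaussian PSF; recorded counts
#' are `offset + gain x excess-noise-scaled Poisson(signal + background) +
#' Gaussian read noise`.  With `skewed = TRUE` each plane is laterally
#' displaced by `stage_step_s * cos(sheet_angle)` to emulate raw
#' stage-scan frames.
#'
#' @param scene A [build_scene()] scene.
#' @param geom,cam,psf Acquisition geometry, camera and PSF models.
#' @param fluor A `fluorophore_model` for the primary channel, or a list of
#'   models (one per channel; a second entry renders emitter `counts2`).
#' @param shape Volume shape `(z, y, x)`; defaults to `geom$volume_shape`.
#' @param skewed Render raw stage-scan (sheared) frames?
#' @return A list with `channels` (list of `volume_series`) and `truth`, a
#'   data.frame of per-frame true positions (nm) and molecule counts.
#' @export
render_volume_series <- function(scene, geom = scene$geom,
                                 cam = camera_model(),
                                 fluor = fluorophore_model(),
                                 psf = psf_model(geom = geom),
                                 shape = NULL, skewed = FALSE) {
  if (inherits(fluor, "fluorophore_model")) fluor <- list(fluor)
  if (is.null(shape)) shape <- geom$volume_shape
  if (any(dim(psf$kernel) > shape))
    stop("PSF kernel larger than the rendered volume")
  n_frames <- scene$n_frames
  channels <- vector("list", length(fluor))
  truth <- list()
  for (ch in seq_along(fluor)) {
    fl <- fluor[[ch]]
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      t_s <- (f - 1) * geom$frame_interval / 1000
      surv <- exp(-fl$bleach_rate * t_s)
      pos <- do.call(rbind, lapply(scene$emitters, function(e)
        e$positions[f, ]))
      mol <- vapply(scene$emitters, function(e) {
        cnt <- if (ch == 1) e$counts else
          if (!is.null(e$counts2)) e$counts2 else 0L
        if (length(cnt) >= f) cnt[f] else 0L
      }, numeric(1))
      bg_pe <- scene$background_photon_rate * geom$exposure_per_plane *
        cam$quantum_efficiency
      pe <- expected_pe_frame(pos, mol * surv, geom, cam, fl, psf,
                              shape, skewed) + bg_pe
      frames[[f]] <- emccd_counts(pe, cam)
      if (ch == 1 && length(mol)) {
        truth[[f]] <- data.frame(
          frame = f,
          emitter_id = vapply(scene$emitters, `[[`, integer(1),
                              "emitter_id"),
          class_label = vapply(scene$emitters, `[[`, character(1),
                               "class_label"),
          z = pos[, 1], y = pos[, 2], x = pos[, 3],
          molecules = mol)
      }
    }
    channels[[ch]] <- new_volume_series(
      frames, geom, channel = fl$channel_name, deskewed = !skewed,
      provenance = sprintf("rendered (%s)",
                           if (skewed) "skewed" else "orthogonal"))
  }
  list(channels = channels,
       truth = do.call(rbind, truth))
}

#' Render a single-fluorophore calibration field
#'
#' Emulates bacterially produced eGFP adsorbed to a coverslip: sparse,
#' immobile emitters of 1-3 fluorophores (given mixture fractions) on a
#' single focal plane, bleaching in single-molecule steps, over a low
#' in-vitro background.
#'
#' @param n_emitters Number of spots.
#' @param geom,cam,fluor,psf Imaging models.
#' @param exposure Calibration exposure (ms).  Single fluorophores are dim
#'   at the live-imaging exposure, so the calibration series is recorded
#'   at a longer exposure (the calibration curve is linear in exposure and
#'   is rescaled when converting in-cell amplitudes); the default is three
#'   times the live exposure in `geom`.
#' @param fractions Multiplicity fractions for 1-, 2-, 3-mers; must sum
#'   to 1.
#' @param bleach_prob Per-molecule per-frame bleaching probability.
#' @param n_frames Number of rendered frames.
#' @param background_photon_rate Coverslip background (photons/voxel/ms).
#' @param shape Volume shape `(z, y, x)`; chosen automatically to hold the
#'   emitters on a sparse grid when `NULL`.
#' @return A list with `volumes` (a `volume_series`), `truth` (data.frame
#'   of emitter positions and per-frame molecule counts) and
#'   `true_unit_amplitude` (counts per molecule, from [unit_amplitude()]).
#' @export
generate_calibration_field <- function(n_emitters = 200,
                                       geom = acq_geometry(),
                                       cam = camera_model(),
                                       fluor = fluorophore_model(),
                                       psf = psf_model(geom = geom),
                                       fractions = c(0.7, 0.2, 0.1),
                                       bleach_prob = 0.06,
                                       n_frames = 10,
                                       background_photon_rate = 0.02,
                                       shape = NULL,
                                       exposure = 3 * geom$exposure_per_plane) {
  stopifnot(n_emitters >= 1, abs(sum(fractions) - 1) < 1e-8)
  geom$exposure_per_plane <- exposure
  geom$frame_interval <- max(geom$frame_interval,
                             geom$planes_per_volume * exposure)
  spacing_px <- 12                      # grid pitch, > 10 sigma_xy
  n_side <- ceiling(sqrt(n_emitters))
  if (is.null(shape)) {
    side <- (n_side + 1) * spacing_px
    shape <- c(max(dim(psf$kernel)[1] + 4, 15), side, side)
  }
  mult <- sample(seq_along(fractions), n_emitters, replace = TRUE,
                 prob = fractions)
  iz <- floor(shape[1] / 2)
  pos <- cbind(z = rep(iz * geom$z_step, n_emitters),
               y = (spacing_px * (((seq_len(n_emitters) - 1) %/% n_side) + 1) +
                      stats::runif(n_emitters, -0.5, 0.5)) *
                 geom$pixel_size_xy,
               x = (spacing_px * (((seq_len(n_emitters) - 1) %% n_side) + 1) +
                      stats::runif(n_emitters, -0.5, 0.5)) *
                 geom$pixel_size_xy)
  counts <- matrix(0L, n_frames, n_emitters)
  counts[1, ] <- mult
  for (f in seq_len(n_frames)[-1]) {
    counts[f, ] <- counts[f - 1, ] -
      stats::rbinom(n_emitters, counts[f - 1, ], bleach_prob)
  }
  frames <- vector("list", n_frames)
  bg_pe <- background_photon_rate * geom$exposure_per_plane *
    cam$quantum_efficiency
  for (f in seq_len(n_frames)) {
    pe <- expected_pe_frame(pos, counts[f, ], geom, cam, fluor, psf,
                            shape, skewed = FALSE) + bg_pe
    frames[[f]] <- emccd_counts(pe, cam)
  }
  truth <- data.frame(emitter_id = seq_len(n_emitters),
                      z = pos[, 1], y = pos[, 2], x = pos[, 3],
                      multiplicity = mult)
  list(volumes = new_volume_series(frames, geom, deskewed = TRUE,
                                   provenance = "calibration field"),
       truth = truth, counts = counts, exposure = exposure,
       true_unit_amplitude = unit_amplitude(geom, cam, fluor, psf))
}

#' Generate a synthetic FRAP recovery trace
#'
#' Post-bleach intensity follows
#' `I(t) = I0 * (1 - bleach_depth * (mobile_fraction * exp(-k t) +
#' (1 - mobile_fraction)))` plus Gaussian noise; `mobile_fraction = 0`
#' yields the flat, barely recovering traces seen when the cytosolic pool
#' is depleted.
#'
#' @param k Recovery rate (per s).
#' @param bleach_depth Fraction of the pre-bleach intensity removed by the
#'   bleach pulse, in (0, 1].
#' @param mobile_fraction Fraction of the bleached signal that exchanges.
#' @param noise_sd Additive Gaussian noise SD (fraction of `I0`).
#' @param n_frames Number of post-bleach frames.
#' @param dt Frame spacing (s).
#' @param i0 Pre-bleach intensity.
#' @param n_prebleach Number of pre-bleach baseline frames included.
#' @return A data.frame with `time` (s, bleach at t = 0) and `intensity`.
#' @export
generate_frap_trace <- function(k = 0.5, bleach_depth = 0.8,
                                mobile_fraction = 0.9, noise_sd = 0,
                                n_frames = 100, dt = 0.1, i0 = 1,
                                n_prebleach = 10) {
  if (!(bleach_depth > 0 && bleach_depth <= 1))
    stop("bleach_depth must lie in (0, 1]")
  t_post <- seq(0, by = dt, length.out = n_frames)
  i_post <- i0 * (1 - bleach_depth *
                    (mobile_fraction * exp(-k * t_post) +
                       (1 - mobile_fraction)))
  t_pre <- seq(-n_prebleach * dt, -dt, by = dt)
  tr <- data.frame(time = c(t_pre, t_post),
                   intensity = c(rep(i0, n_prebleach), i_post))
  if (noise_sd > 0)
    tr$intensity <- tr$intensity + stats::rnorm(nrow(tr), 0, noise_sd * i0)
  tr
}
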