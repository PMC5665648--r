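#' Bead-style noise-floor control
#'
#' Renders one immobile emitter carrying a constant number of fluorophores
#' through the full forward model, quantifies it frame by frame with the
#' default detection + calibration pipeline, and reports the spread of the
#' per-frame molecule estimates.  An instrument whose molecule-number SD
#' on a constant ~50-fluorophore bead is ~3 cannot explain the much larger
#' fluctuations seen on endosomes, which must then be biological.
#'
#' @param n_molecules Constant fluorophore count on the bead.
#' @param n_frames Number of rendered frames.
#' @param geom,cam,fluor,psf Imaging models; the volume is cropped to a
#'   small field around the bead.
#' @param cal Optional pre-fitted calibration curve; fitted from a fresh
#'   default calibration field when `NULL`.
#' @return A list with `estimates` (per-frame molecule numbers), `sd`,
#'   `mean` and the calibration used.
#' @export
bead_control <- function(n_molecules = 50, n_frames = 60,
                         geom = acq_geometry(),
                         cam = camera_model(),
                         fluor = fluorophore_model(),
                         psf = psf_model(geom = geom),
                         cal = NULL) {
  shape <- c(17, 25, 25)
  if (is.null(cal)) cal <- default_calibration(geom, cam, fluor, psf)
  pos <- matrix(c(8 * geom$z_step, 12 * geom$pixel_size_xy,
                  12 * geom$pixel_size_xy), 1, 3)
  est <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    pe <- expected_pe_frame(pos, n_molecules, geom, cam, fluor, psf,
                            shape) +
      0.1 * geom$exposure_per_plane * cam$quantum_efficiency
    frame <- emccd_counts(pe, cam)
    sp <- detect_frame(frame, psf, geom)
    if (!nrow(sp)) next
    i <- which.max(sp$amplitude)
    est[f] <- amplitude_to_molecules(sp$amplitude[i], sp$amplitude_sd[i],
                                     cal,
                                     geom$exposure_per_plane)$n_molecules
  }
  est <- est[!is.na(est)]
  list(estimates = est, sd = stats::sd(est), mean = mean(est),
       calibration = cal)
}

#' Fit a calibration curve from a freshly rendered calibration field
#'
#' Convenience wrapper: renders the default single-fluorophore field,
#' detects spots in the first (pre-bleach) frame with PSF-pinned widths,
#' and fits the constrained mixture.
#'
#' @param geom,cam,fluor,psf Imaging models.
#' @param n_emitters Spots in the field.
#' @return A `calibration_curve`.
#' @export
default_calibration <- function(geom = acq_geometry(),
                                cam = camera_model(),
                                fluor = fluorophore_model(),
                                psf = psf_model(geom = geom),
                                n_emitters = 200) {
  field <- generate_calibration_field(n_emitters, geom, cam, fluor, psf,
                                      n_frames = 1)
  sp <- detect_frame(field$volumes$frames[[1]], psf, geom,
                     fix_sigma = TRUE)
  fit_single_molecule_mixture(sp$amplitude,
                              exposure_reference = field$exposure)
}

#' Signal-to-noise of dim rendered spots
#'
#' Renders isolated static emitters of `n_molecules` fluorophores each
#' under the default imaging settings (in-cell background), fits each with
#' the detection module, and returns per-spot SNR = fitted amplitude /
#' SD of the local background residuals.
#'
#' @param n_spots Number of emitters.
#' @param n_molecules Fluorophores per emitter.
#' @param geom,cam,fluor,psf Imaging models.
#' @param background_photon_rate In-cell background (photons/voxel/ms).
#' @return A list with `snr` (per detected spot), `median_snr`,
#'   `n_detected`.
#' @export
snr_experiment <- function(n_spots = 200, n_molecules = 3,
                           geom = acq_geometry(),
                           cam = camera_model(),
                           fluor = fluorophore_model(),
                           psf = psf_model(geom = geom),
                           background_photon_rate = 0.1) {
  spacing_px <- 12
  n_side <- ceiling(sqrt(n_spots))
  side <- (n_side + 1) * spacing_px
  shape <- c(17, side, side)
  pos <- cbind(z = rep(8 * geom$z_step, n_spots) +
                 stats::runif(n_spots, -0.5, 0.5) * geom$z_step,
               y = (spacing_px * (((seq_len(n_spots) - 1) %/% n_side) + 1) +
                      stats::runif(n_spots, -0.5, 0.5)) *
                 geom$pixel_size_xy,
               x = (spacing_px * (((seq_len(n_spots) - 1) %% n_side) + 1) +
                      stats::runif(n_spots, -0.5, 0.5)) *
                 geom$pixel_size_xy)
  pe <- expected_pe_frame(pos, rep(n_molecules, n_spots), geom, cam,
                          fluor, psf, shape) +
    background_photon_rate * geom$exposure_per_plane *
      cam$quantum_efficiency
  frame <- emccd_counts(pe, cam)
  sp <- detect_frame(frame, psf, geom)
  list(snr = sp$snr, median_snr = stats::median(sp$snr),
       n_detected = nrow(sp))
}
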