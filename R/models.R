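#' Acquisition geometry of a stage-scanned light-sheet time series
#'
#' Collects the sampling constants that connect voxel indices to world
#' coordinates for a lattice light-sheet acquisition in which the sample
#' stage is stepped along the s-axis at an angle to the detection axis.
#' The defaults describe a 51 s series of 60 volumes of 512 x 512 x 30
#' voxels recorded at 21 ms exposure per plane with a 500 nm stage step at
#' a 31.5 degree sheet angle, i.e. a ~261 nm z-step after deskewing.
#'
#' @param pixel_size_xy Camera pixel size in sample space (nm).
#' @param stage_step_s Stage step along the scan axis (nm).
#' @param sheet_angle Angle between light sheet and coverslip (degrees),
#'   strictly between 0 and 90.
#' @param planes_per_volume Number of planes per 3D stack.
#' @param n_volumes Number of time points.
#' @param frame_interval Time between consecutive volumes (ms).
#' @param exposure_per_plane Camera exposure per plane (ms).
#' @param volume_shape Integer vector `(z, y, x)` of voxel counts.
#'
#' @return An object of class `acq_geometry` with the fields above plus
#'   `z_step`, the deskewed axial spacing `stage_step_s * sin(sheet_angle)`
#'   in nm.
#' @export
acq_geometry <- function(pixel_size_xy = 97.7,
                         stage_step_s = 500,
                         sheet_angle = 31.5,
                         planes_per_volume = 30,
                         n_volumes = 60,
                         frame_interval = 850,
                         exposure_per_plane = 21,
                         volume_shape = c(30, 512, 512)) {
  stopifnot(pixel_size_xy > 0, stage_step_s > 0,
            planes_per_volume >= 1, n_volumes >= 1,
            frame_interval > 0, exposure_per_plane > 0,
            length(volume_shape) == 3, all(volume_shape >= 1))
  if (!(sheet_angle > 0 && sheet_angle < 90))
    stop("sheet_angle must lie strictly between 0 and 90 degrees")
  if (frame_interval < planes_per_volume * exposure_per_plane)
    stop("frame_interval shorter than planes_per_volume * exposure_per_plane")
  g <- list(pixel_size_xy = pixel_size_xy,
            stage_step_s = stage_step_s,
            sheet_angle = sheet_angle,
            planes_per_volume = as.integer(planes_per_volume),
            n_volumes = as.integer(n_volumes),
            frame_interval = frame_interval,
            exposure_per_plane = exposure_per_plane,
            volume_shape = as.integer(volume_shape),
            z_step = stage_step_s * sin(sheet_angle * pi / 180))
  class(g) <- "acq_geometry"
  g
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf(
    "acq_geometry: %d volumes every %g ms, %d planes, %g ms exposure\n",
    x$n_volumes, x$frame_interval, x$planes_per_volume,
    x$exposure_per_plane))
  cat(sprintf("  xy pixel %.1f nm; stage step %.0f nm at %.1f deg -> z-step %.1f nm\n",
              x$pixel_size_xy, x$stage_step_s, x$sheet_angle, x$z_step))
  cat(sprintf("  volume shape (z,y,x) = %s\n",
              paste(x$volume_shape, collapse = " x ")))
  invisible(x)
}

#' EMCCD camera noise model
#'
#' Electron-multiplying CCDs amplify photoelectrons through a gain register
#' that adds multiplicative "excess" noise: the variance of the amplified
#' signal is `excess_noise_factor^2` times the shot-noise variance.  The
#' rendering model draws `Poisson(lambda / F^2)` events scaled by
#' `gain * F^2`, which reproduces the EMCCD mean and variance, and adds
#' Gaussian read noise and a constant digitizer offset.
#'
#' @param offset Digitizer offset (counts).
#' @param gain Counts per photoelectron after EM amplification.
#' @param excess_noise_factor Multiplicative noise factor F, in [1, 2];
#'   sqrt(2) for a high-gain EM register.
#' @param read_noise Read noise SD (counts).
#' @param quantum_efficiency Photon-to-photoelectron conversion fraction.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(offset = 100, gain = 12,
                         excess_noise_factor = 1.41,
                         read_noise = 6, quantum_efficiency = 0.9) {
  stopifnot(gain > 0, read_noise >= 0, offset >= 0)
  if (!(excess_noise_factor >= 1 && excess_noise_factor <= 2))
    stop("excess_noise_factor must be in [1, 2]")
  if (!(quantum_efficiency > 0 && quantum_efficiency <= 1))
    stop("quantum_efficiency must be in (0, 1]")
  structure(list(offset = offset, gain = gain,
                 excess_noise_factor = excess_noise_factor,
                 read_noise = read_noise,
                 quantum_efficiency = quantum_efficiency),
            class = "camera_model")
}

#' Fluorophore photophysics
#'
#' Emission rate and photobleaching rate for one spectral channel.  The
#' default eGFP rate is set so that a diffraction-limited spot holding three
#' molecules is recorded with a signal-to-noise ratio of about 4 under the
#' default geometry and camera.  mCherry bleaches much faster; its default
#' rate leaves roughly a third of second-channel traces bright enough to
#' analyze over a typical event lifetime.
#'
#' @param photon_rate Detected-photon emission rate (photons per molecule
#'   per ms, before quantum-efficiency losses).
#' @param bleach_rate First-order photobleaching rate (per s).
#' @param channel_name Channel label, e.g. `"eGFP"` or `"mCherry"`.
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(photon_rate = 4.5, bleach_rate = 0,
                              channel_name = "eGFP") {
  stopifnot(photon_rate > 0, bleach_rate >= 0)
  structure(list(photon_rate = photon_rate, bleach_rate = bleach_rate,
                 channel_name = channel_name),
            class = "fluorophore_model")
}

#' Default mCherry channel model
#'
#' @return A `fluorophore_model` with a reduced photon budget and a bleach
#'   rate of 0.08/s.
#' @export
mcherry_model <- function() {
  fluorophore_model(photon_rate = 2.2, bleach_rate = 0.08,
                    channel_name = "mCherry")
}

#' Anisotropic Gaussian point spread function
#'
#' @param sigma_xy Lateral Gaussian width (nm).
#' @param sigma_z Axial Gaussian width (nm).
#' @param geom An [acq_geometry()]; sets the voxel sampling of the kernel.
#' @param half_width_sigmas Kernel support half-width in units of sigma.
#' @return An object of class `psf_model` with fields `sigma_xy`, `sigma_z`
#'   (nm) and `kernel`, a 3D array `(z, y, x)` of non-negative weights
#'   summing to 1, centered and unimodal.
#' @export
psf_model <- function(sigma_xy = 110, sigma_z = 380,
                      geom = acq_geometry(), half_width_sigmas = 4) {
  stopifnot(sigma_xy > 0, sigma_z > 0)
  sx <- sigma_xy / geom$pixel_size_xy
  sz <- sigma_z / geom$z_step
  hx <- max(1L, ceiling(half_width_sigmas * sx))
  hz <- max(1L, ceiling(half_width_sigmas * sz))
  gx <- exp(-0.5 * ((-hx:hx) / sx)^2)
  gz <- exp(-0.5 * ((-hz:hz) / sz)^2)
  k <- outer(gz, outer(gx, gx))          # (z, y, x)
  dim(k) <- c(2 * hz + 1, 2 * hx + 1, 2 * hx + 1)
  k <- k / sum(k)
  structure(list(sigma_xy = sigma_xy, sigma_z = sigma_z,
                 sigma_xy_px = sx, sigma_z_px = sz, kernel = k),
            class = "psf_model")
}
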