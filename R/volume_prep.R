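#' Subtract the camera offset from a volume series
#'
#' Multiplicative steps downstream (flat-fielding, Richardson-Lucy) assume
#' Poisson-scaled data, so the digitizer offset is removed first and the
#' result clamped at zero.
#'
#' @param vol A `volume_series`.
#' @param cam A [camera_model()]; its `offset` is subtracted.
#' @return The offset-subtracted `volume_series`.
#' @export
subtract_offset <- function(vol, cam = camera_model()) {
  vol$frames <- lapply(vol$frames, function(a) pmax(a - cam$offset, 0))
  vol$provenance <- c(vol$provenance,
                      sprintf("offset %g subtracted, clamped at 0",
                              cam$offset))
  vol
}

#' Flat-field correction
#'
#' Divides every plane by the illumination profile normalized to unit
#' mean, so the field-averaged intensity is preserved.
#'
#' @param vol A `volume_series`.
#' @param illumination_profile Strictly positive `(y, x)` matrix matching
#'   the plane shape.
#' @return The corrected `volume_series`.
#' @export
flatfield_correct <- function(vol, illumination_profile) {
  d <- dim(vol$frames[[1]])
  if (!is.matrix(illumination_profile) ||
      any(dim(illumination_profile) != d[2:3]))
    stop("illumination_profile must be a (y, x) matrix matching the planes")
  if (any(illumination_profile <= 0))
    stop("illumination_profile must be strictly positive")
  prof <- illumination_profile / mean(illumination_profile)
  vol$frames <- lapply(vol$frames, function(a) {
    for (k in seq_len(d[1])) a[k, , ] <- a[k, , ] / prof
    a
  })
  vol$provenance <- c(vol$provenance, "flat-field corrected")
  vol
}

#' Deskew stage-scanned volumes to orthogonal coordinates
#'
#' In stage-scan acquisition, plane `k` is laterally displaced by
#' `k * stage_step_s * cos(sheet_angle)`.  Deskewing shifts each plane back
#' by linear interpolation onto a common x grid (extended to hold the full
#' shear) and declares the axial spacing `stage_step_s * sin(sheet_angle)`.
#' Voxels outside the recorded field are filled with the plane's median
#' (a local-background estimate) unless `fill` is numeric.
#'
#' @param vol A skewed `volume_series`.
#' @param fill `"median"` or a numeric fill value for out-of-field voxels.
#' @return The deskewed `volume_series` (wider along x).
#' @export
deskew <- function(vol, fill = "median") {
  if (vol$deskewed) stop("volume series is already deskewed")
  g <- vol$geometry
  shift_px <- g$stage_step_s * cos(g$sheet_angle * pi / 180) /
    g$pixel_size_xy
  nz_planes <- dim(vol$frames[[1]])[1]
  if (shift_px * (nz_planes - 1) < 0.05) {
    # sheet normal to the stage axis: no shear, deskew is a pure restack
    vol$deskewed <- TRUE
    vol$provenance <- c(vol$provenance,
                        sprintf("deskewed: no shear, z-step %.1f nm",
                                g$z_step))
    return(vol)
  }
  d <- dim(vol$frames[[1]])
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  nx_out <- nx + ceiling((nz - 1) * shift_px)
  vol$frames <- lapply(vol$frames, function(a) {
    out <- array(0, dim = c(nz, ny, nx_out))
    for (k in seq_len(nz)) {
      fillval <- if (identical(fill, "median")) stats::median(a[k, , ])
                 else fill
      # orthogonal x index i maps back to skewed index i - (k-1)*shift
      xi <- seq_len(nx_out) - (k - 1) * shift_px
      lo <- floor(xi); frac <- xi - lo
      v_lo <- ifelse(lo >= 1 & lo <= nx, lo, NA)
      v_hi <- ifelse(lo + 1 >= 1 & lo + 1 <= nx, lo + 1, NA)
      plane <- a[k, , , drop = TRUE]
      dim(plane) <- c(ny, nx)
      left <- matrix(fillval, ny, nx_out)
      right <- matrix(fillval, ny, nx_out)
      left[, !is.na(v_lo)] <- plane[, v_lo[!is.na(v_lo)]]
      right[, !is.na(v_hi)] <- plane[, v_hi[!is.na(v_hi)]]
      wf <- matrix(frac, ny, nx_out, byrow = TRUE)
      out[k, , ] <- left * (1 - wf) + right * wf
    }
    out
  })
  vol$deskewed <- TRUE
  vol$provenance <- c(vol$provenance,
                      sprintf(
                        "deskewed: %.2f px/plane shear, z-step %.1f nm%s",
                        shift_px, g$z_step,
                        if (identical(fill, "median"))
                          ", out-of-field filled with plane median" else ""))
  vol
}

# 3D convolution via zero-padded FFT, "same" output size.
conv3d_fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  dp <- da + dk - 1
  pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(dp)
  off <- (dk - 1) %/% 2
  full[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]),
       off[3] + seq_len(da[3]), drop = FALSE]
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative RL updates with the measured background
#' subtracted (clamped at zero) beforehand.  Fifteen iterations is the
#' conventional stopping point for visualization of light-sheet data.
#'
#' @param vol A `volume_series` (deskewed).
#' @param psf A [psf_model()]; a non-normalized kernel is renormalized with
#'   a note in the provenance log.
#' @param iterations Number of RL iterations.
#' @param background Constant background (counts) subtracted first.
#' @return The deconvolved `volume_series`.
#' @export
richardson_lucy <- function(vol, psf, iterations = 15, background = 0) {
  stopifnot(background >= 0, iterations >= 1)
  k <- psf$kernel
  if (abs(sum(k) - 1) > 1e-6) {
    k <- k / sum(k)
    vol$provenance <- c(vol$provenance,
                        "warning: PSF kernel renormalized to unit sum")
  }
  if (any(dim(k) > dim(vol$frames[[1]])))
    stop("PSF kernel larger than the volume")
  km <- k[rev(seq_len(dim(k)[1])), rev(seq_len(dim(k)[2])),
          rev(seq_len(dim(k)[3])), drop = FALSE]
  eps <- 1e-12
  vol$frames <- lapply(vol$frames, function(a) {
    obs <- pmax(a - background, 0)
    if (all(obs == 0)) return(obs)
    est <- array(mean(obs), dim = dim(obs))
    for (i in seq_len(iterations)) {
      ratio <- obs / pmax(conv3d_fft(est, k), eps)
      est <- est * conv3d_fft(ratio, km)
      est <- pmax(est, 0)
    }
    est
  })
  vol$provenance <- c(vol$provenance,
                      sprintf("Richardson-Lucy deconvolved, %d iterations, background %g",
                              iterations, background))
  vol
}
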