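# Separable Gaussian smoothing along one axis with edge replication.
smooth_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-0.5 * ((-h:h) / sigma)^2)
  w <- w / sum(w)
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (o in -h:h) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + w[o + h + 1] * shifted
  }
  out
}

smooth3d <- function(arr, sigma_zyx) {
  for (axis in 1:3) arr <- smooth_axis(arr, sigma_zyx[axis], axis)
  arr
}

#' Detect candidate spots in one 3D frame
#'
#' Computes a difference-of-Gaussians band-pass response at the PSF scale
#' and returns its 26-connected local maxima above a low, permissive
#' threshold (a multiple of the robust noise SD of the response).  Final
#' acceptance is deferred to the per-spot significance test.
#'
#' @param frame 3D array `(z, y, x)` in counts, deskewed.
#' @param psf A [psf_model()].
#' @param geom An [acq_geometry()] (voxel sampling).
#' @param threshold_sigmas Response threshold in units of its robust SD.
#' @return Integer matrix with columns `z, y, x` (1-based voxel indices).
#' @export
detect_candidates <- function(frame, psf, geom = acq_geometry(),
                              threshold_sigmas = 6) {
  s <- c(psf$sigma_z / geom$z_step,
         psf$sigma_xy / geom$pixel_size_xy,
         psf$sigma_xy / geom$pixel_size_xy)
  dog <- smooth3d(frame, s) - smooth3d(frame, 1.6 * s)
  noise <- stats::mad(dog)
  thr <- stats::median(dog) + threshold_sigmas * max(noise, 1e-12)
  d <- dim(frame)
  is_max <- dog >= thr
  for (axis in 1:3) {
    n <- d[axis]
    for (o in c(-1L, 1L)) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      nb <- switch(axis,
                   dog[idx, , , drop = FALSE],
                   dog[, idx, , drop = FALSE],
                   dog[, , idx, drop = FALSE])
      is_max <- is_max & (dog >= nb)
    }
  }
  cand <- which(is_max, arr.ind = TRUE)
  colnames(cand) <- c("z", "y", "x")
  # strict 26-neighborhood check to break plateau duplicates
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    ord <- order(dog[cand])
    for (i in ord) {
      if (!keep[i]) next
      same <- which(keep &
                      abs(cand[, 1] - cand[i, 1]) <= 1 &
                      abs(cand[, 2] - cand[i, 2]) <= 1 &
                      abs(cand[, 3] - cand[i, 3]) <= 1)
      same <- setdiff(same, i)
      if (any(dog[cand[same, , drop = FALSE]] >= dog[cand[i, , drop = FALSE]]))
        keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand
}

gauss3d_model <- function(z, y, x, z0, y0, x0, sz, sxy, a, c0) {
  a * exp(-0.5 * (((z - z0) / sz)^2 + ((y - y0) / sxy)^2 +
                    ((x - x0) / sxy)^2)) + c0
}

#' Fit a 3D asymmetric Gaussian to one candidate spot
#'
#' Least-squares fit of `A * G(sigma_xy, sigma_z) + background` in a
#' window of `window_sigmas` PSF widths per axis around the candidate.
#' The lateral widths are tied (`sigma_x = sigma_y`), matching the axially
#' elongated PSF; parameter SDs come from the fit covariance.
#'
#' @param frame 3D array `(z, y, x)` in counts.
#' @param candidate Voxel index `c(z, y, x)` (1-based).
#' @param psf,geom PSF and geometry models.
#' @param window_sigmas Fit window half-width in PSF sigmas.
#' @return A one-row data.frame (class `spot_fit` rows): position and
#'   per-axis SD in nm, `amplitude`/`amplitude_sd`, `background`/
#'   `background_sd` in counts, fitted `sigma_xy`/`sigma_z` in nm,
#'   `residual_sd`, `snr`, `n_voxels`, `converged`.
#' @export
fit_spot <- function(frame, candidate, psf, geom = acq_geometry(),
                     window_sigmas = 4, fix_sigma = FALSE) {
  d <- dim(frame)
  sxp <- psf$sigma_xy / geom$pixel_size_xy
  szp <- psf$sigma_z / geom$z_step
  hx <- ceiling(window_sigmas * sxp)
  hz <- ceiling(window_sigmas * szp)
  zr <- max(1, candidate[1] - hz):min(d[1], candidate[1] + hz)
  yr <- max(1, candidate[2] - hx):min(d[2], candidate[2] + hx)
  xr <- max(1, candidate[3] - hx):min(d[3], candidate[3] + hx)
  win <- frame[zr, yr, xr, drop = FALSE]
  grid <- expand.grid(z = zr, y = yr, x = xr)
  v <- as.vector(win)
  bg0 <- stats::median(v)
  a0 <- max(v) - bg0
  fit <- if (fix_sigma) {
    # immobile point sources of known PSF (calibration fields): widths
    # pinned to the PSF removes the amplitude bias of free-width fits at
    # low signal-to-noise
    tryCatch(
      minpack.lm::nlsLM(
        v ~ gauss3d_model(z, y, x, z0, y0, x0, szp, sxp, a, c0),
        data = cbind(grid, v = v, szp = szp, sxp = sxp),
        start = list(z0 = candidate[1], y0 = candidate[2],
                     x0 = candidate[3], a = max(a0, 1e-6), c0 = bg0),
        lower = c(z0 = min(zr) - 1, y0 = min(yr) - 1, x0 = min(xr) - 1,
                  a = -Inf, c0 = -Inf),
        upper = c(z0 = max(zr) + 1, y0 = max(yr) + 1, x0 = max(xr) + 1,
                  a = Inf, c0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 120)),
      error = function(e) NULL)
  } else tryCatch(
    minpack.lm::nlsLM(
      v ~ gauss3d_model(z, y, x, z0, y0, x0, sz, sxy, a, c0),
      data = cbind(grid, v = v),
      start = list(z0 = candidate[1], y0 = candidate[2],
                   x0 = candidate[3], sz = szp, sxy = sxp,
                   a = max(a0, 1e-6), c0 = bg0),
      # nothing images narrower than the PSF; sub-PSF widths are noise
      # latching and bias the amplitude upward
      lower = c(z0 = min(zr) - 1, y0 = min(yr) - 1, x0 = min(xr) - 1,
                sz = 0.8 * szp, sxy = 0.8 * sxp, a = -Inf, c0 = -Inf),
      upper = c(z0 = max(zr) + 1, y0 = max(yr) + 1, x0 = max(xr) + 1,
                sz = 4 * szp, sxy = 4 * sxp, a = Inf, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 120)),
    error = function(e) NULL)
  empty <- data.frame(frame = NA_integer_,
                      z = NA_real_, y = NA_real_, x = NA_real_,
                      z_sd = NA_real_, y_sd = NA_real_, x_sd = NA_real_,
                      amplitude = NA_real_, amplitude_sd = NA_real_,
                      background = NA_real_, background_sd = NA_real_,
                      sigma_xy = NA_real_, sigma_z = NA_real_,
                      residual_sd = NA_real_, snr = NA_real_,
                      p_value = NA_real_, n_voxels = length(v),
                      n_free = if (fix_sigma) 5L else 7L,
                      converged = FALSE)
  if (is.null(fit)) return(empty)
  # coefficient order follows the start list:
  #   free widths:  z0 y0 x0 sz sxy a c0   fixed widths: z0 y0 x0 a c0
  cf <- as.numeric(stats::coef(fit))
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  if (is.null(se) || any(!is.finite(se))) return(empty)
  se <- as.numeric(se)
  res_sd <- stats::sd(stats::residuals(fit))
  ia <- if (fix_sigma) 4L else 6L
  ic <- ia + 1L
  # shot noise concentrates at the spot peak, so the homoscedastic fit
  # covariance understates the parameter errors; use the heteroscedastic
  # sandwich over the fit Jacobian and keep the larger SE per parameter
  sand <- tryCatch({
    J <- fit$m$gradient()
    bread <- solve(crossprod(J))
    h <- pmin(rowSums((J %*% bread) * J), 0.99)   # leverage (HC3)
    meat <- crossprod(J * stats::residuals(fit) / (1 - h))
    sqrt(diag(bread %*% meat %*% bread))
  }, error = function(e) NULL)
  if (!is.null(sand) && all(is.finite(sand))) se <- pmax(se, sand)
  data.frame(frame = NA_integer_,
             z = (cf[1] - 1) * geom$z_step,
             y = (cf[2] - 1) * geom$pixel_size_xy,
             x = (cf[3] - 1) * geom$pixel_size_xy,
             z_sd = se[1] * geom$z_step,
             y_sd = se[2] * geom$pixel_size_xy,
             x_sd = se[3] * geom$pixel_size_xy,
             amplitude = cf[ia],
             amplitude_sd = se[ia],
             background = cf[ic],
             background_sd = se[ic],
             sigma_xy = (if (fix_sigma) sxp else cf[5]) * geom$pixel_size_xy,
             sigma_z = (if (fix_sigma) szp else cf[4]) * geom$z_step,
             residual_sd = res_sd,
             snr = cf[ia] / max(res_sd, 1e-12),
             p_value = NA_real_, n_voxels = length(v),
             n_free = length(cf),
             converged = TRUE)
}

#' Significance test of a fitted spot against its local background
#'
#' One-sided t-test of amplitude > 0 against the local residual noise:
#' `t = A / SD(A)` with `n_voxels` minus the number of free fit
#' parameters as degrees of freedom.  Degenerate residuals (zero amplitude SD) accept the spot
#' only if the amplitude is positive.
#'
#' @param fit A one-row spot fit from [fit_spot()].
#' @param alpha Acceptance level.
#' @return The fit row with `p_value` filled and an `accepted` column.
#' @export
test_significance <- function(fit, alpha = 0.05) {
  if (!isTRUE(fit$converged)) {
    fit$p_value <- NA_real_; fit$accepted <- FALSE
    return(fit)
  }
  df <- max(fit$n_voxels - fit$n_free, 1)
  if (!is.finite(fit$amplitude_sd) || fit$amplitude_sd <= 0) {
    fit$p_value <- if (fit$amplitude > 0) 0 else 1
  } else {
    tstat <- fit$amplitude / fit$amplitude_sd
    fit$p_value <- stats::pt(tstat, df, lower.tail = FALSE)
  }
  fit$accepted <- fit$p_value < alpha
  fit
}

#' Detect and fit all significant spots in one 3D frame
#'
#' Candidate detection, Gaussian fitting and the amplitude significance
#' test composed; duplicate fits converging within one PSF sigma of each
#' other are merged keeping the higher amplitude.  Candidates closer than
#' `border_sigmas` PSF sigmas to the volume boundary are not fitted.
#'
#' @param frame 3D array `(z, y, x)` in counts, deskewed.
#' @param psf,geom PSF and geometry models.
#' @param alpha Significance level for spot acceptance.
#' @param border_sigmas Exclusion margin near the volume faces (PSF sigmas).
#' @param threshold_sigmas Passed to [detect_candidates()].
#' @return A data.frame of accepted spot fits (possibly 0 rows).
#' @export
detect_frame <- function(frame, psf, geom = acq_geometry(), alpha = 0.05,
                         border_sigmas = 1.5, threshold_sigmas = 6,
                         fix_sigma = FALSE) {
  cand <- detect_candidates(frame, psf, geom, threshold_sigmas)
  d <- dim(frame)
  if (nrow(cand)) {
    mz <- border_sigmas * psf$sigma_z / geom$z_step
    mx <- border_sigmas * psf$sigma_xy / geom$pixel_size_xy
    ok <- cand[, 1] > mz & cand[, 1] <= d[1] - mz &
      cand[, 2] > mx & cand[, 2] <= d[2] - mx &
      cand[, 3] > mx & cand[, 3] <= d[3] - mx
    cand <- cand[ok, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty_spot_table())
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    test_significance(fit_spot(frame, cand[i, ], psf, geom,
                               fix_sigma = fix_sigma), alpha)))
  fits <- fits[fits$converged & fits$accepted, , drop = FALSE]
  if (nrow(fits) <= 1) return(fits)
  # merge duplicates within 1 PSF sigma, keeping the higher amplitude
  ord <- order(-fits$amplitude)
  keep <- logical(nrow(fits))
  for (i in ord) {
    dup <- keep &
      abs(fits$x - fits$x[i]) < psf$sigma_xy &
      abs(fits$y - fits$y[i]) < psf$sigma_xy &
      abs(fits$z - fits$z[i]) < psf$sigma_z
    if (!any(dup)) keep[i] <- TRUE
  }
  fits[keep, , drop = FALSE]
}

empty_spot_table <- function() {
  out <- data.frame(frame = integer(0), z = numeric(0), y = numeric(0),
                    x = numeric(0), z_sd = numeric(0), y_sd = numeric(0),
                    x_sd = numeric(0), amplitude = numeric(0),
                    amplitude_sd = numeric(0), background = numeric(0),
                    background_sd = numeric(0), sigma_xy = numeric(0),
                    sigma_z = numeric(0), residual_sd = numeric(0),
                    snr = numeric(0), p_value = numeric(0),
                    n_voxels = integer(0), n_free = integer(0),
                    converged = logical(0))
  out$accepted <- logical(0)
  out
}

#' Detect spots in every frame of a volume series
#'
#' @param vol A deskewed `volume_series` (offset-subtracted or raw; the
#'   constant-background fit absorbs the offset).
#' @param psf A [psf_model()].
#' @param alpha Significance level.
#' @param ... Passed to [detect_frame()].
#' @return A data.frame of spot fits with the `frame` column set.
#' @export
detect_series <- function(vol, psf, alpha = 0.05, ...) {
  if (!vol$deskewed)
    stop("detect_series requires deskewed volumes; run deskew() first")
  out <- lapply(seq_along(vol$frames), function(f) {
    sp <- detect_frame(vol$frames[[f]], psf, vol$geometry, alpha, ...)
    if (nrow(sp)) sp$frame <- f
    sp
  })
  do.call(rbind, out)
}
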