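# Log-likelihood of the physics-constrained Gaussian mixture: component k
# (k fluorophores) has mean k*mu1 and variance k*sigma1^2.
constrained_mix_loglik <- function(x, w, mu1, sigma1) {
  K <- length(w)
  dens <- vapply(seq_len(K), function(k)
    w[k] * stats::dnorm(x, k * mu1, sqrt(k) * sigma1), numeric(length(x)))
  if (K == 1) dim(dens) <- c(length(x), 1)
  sum(log(pmax(rowSums(dens), 1e-300)))
}

constrained_mix_em <- function(x, K, mu1_init, sigma1_init,
                               max_iter = 500, tol = 1e-9) {
  n <- length(x)
  w <- rep(1 / K, K)
  mu1 <- mu1_init; sigma1 <- sigma1_init
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * stats::dnorm(x, k * mu1, sqrt(k) * sigma1), numeric(n))
    if (K == 1) dim(dens) <- c(n, 1)
    tot <- pmax(rowSums(dens), 1e-300)
    r <- dens / tot
    w <- colMeans(r)
    ks <- seq_len(K)
    # M-step of the constrained likelihood:
    #   mu1      = sum_ik r_ik x_i / sum_ik r_ik k
    #   sigma1^2 = (1/n) sum_ik r_ik (x_i - k mu1)^2 / k
    mu1 <- sum(r * x) / sum(sweep(r, 2, ks, `*`))
    resid2 <- vapply(ks, function(k) (x - k * mu1)^2 / k, numeric(n))
    if (K == 1) dim(resid2) <- c(n, 1)
    sigma1 <- sqrt(sum(r * resid2) / n)
    ll <- constrained_mix_loglik(x, w, mu1, sigma1)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  list(w = w, mu1 = mu1, sigma1 = sigma1, loglik = ll_old,
       converged = converged)
}

# Finite-difference observed information for (mu1, sigma1); returns SE(mu1).
constrained_mix_se <- function(x, w, mu1, sigma1) {
  f <- function(p) constrained_mix_loglik(x, w, p[1], p[2])
  p0 <- c(mu1, sigma1)
  h <- pmax(abs(p0) * 1e-4, 1e-8)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (f(p0 + ei + ej) - f(p0 + ei - ej) -
                  f(p0 - ei + ej) + f(p0 - ei - ej)) / (4 * h[i] * h[j])
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || V[1, 1] <= 0) return(sigma1 / sqrt(length(x)))
  sqrt(V[1, 1])
}

#' Fit the single-fluorophore intensity unit from spot amplitudes
#'
#' Fits physics-constrained Gaussian mixtures to the amplitude histogram
#' of a sparse single-fluorophore field: component `k` (a `k`-mer) is
#' forced to mean `k * mu1` and variance `k * sigma1^2`, encoding `k`
#' independent emitters.  Models with `K = 1..K_max` components are fitted
#' by EM and the component count chosen by BIC; the first component is the
#' single-molecule unit intensity.
#'
#' @param intensities Accepted spot amplitudes (counts); at least 200.
#' @param K_max Largest multiplicity considered.
#' @param exposure_reference Exposure (ms) the amplitudes were recorded
#'   at; stored for linear rescaling to other exposures.
#' @return An object of class `calibration_curve`: `unit_intensity` (mu1,
#'   counts), `unit_intensity_sd` (observed-information SE), `exposure_reference`,
#'   `n_samples` and `mixture` (weights, mu1, sigma1, loglik, BIC, K).
#' @export
fit_single_molecule_mixture <- function(intensities, K_max = 4,
                                        exposure_reference = 21) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 200)
    stop("need at least 200 accepted amplitudes for calibration")
  fits <- list()
  for (K in seq_len(K_max)) {
    # initialize mu1 from lower-quantile spacing; monomers dominate
    inits <- unique(c(stats::median(x), stats::quantile(x, 0.35),
                      mean(x) / ((1 + K) / 2)))
    best <- NULL
    for (m0 in inits) {
      fit <- constrained_mix_em(x, K, m0, stats::mad(x) / sqrt(1))
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best$K <- K
    best$n_free <- (K - 1) + 2
    best$BIC <- -2 * best$loglik + best$n_free * log(length(x))
    fits[[K]] <- best
  }
  ok <- vapply(fits, function(f) f$converged && is.finite(f$BIC),
               logical(1))
  if (!any(ok)) stop("constrained mixture EM failed for every K")
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "BIC"))]]
  se <- constrained_mix_se(x, best$w, best$mu1, best$sigma1)
  structure(list(unit_intensity = best$mu1,
                 unit_intensity_sd = se,
                 exposure_reference = exposure_reference,
                 n_samples = length(x),
                 mixture = list(K = best$K, weights = best$w,
                                means = seq_len(best$K) * best$mu1,
                                sds = sqrt(seq_len(best$K)) * best$sigma1,
                                log_likelihood = best$loglik,
                                BIC = best$BIC,
                                converged = best$converged,
                                n_points = length(x))),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve: unit intensity %.2f +/- %.2f counts (%d spots, K = %d, %g ms)\n",
    x$unit_intensity, x$unit_intensity_sd, x$n_samples, x$mixture$K,
    x$exposure_reference))
  invisible(x)
}

#' Convert spot amplitudes to molecule numbers with propagated error
#'
#' `N = A / mu1` with the unit intensity rescaled linearly to the trace's
#' exposure; the propagated uncertainty is the square root of the squared
#' sums of the fit and calibration uncertainties:
#' `sigma_N = sqrt((sigma_A / mu1)^2 + (A * sigma_mu1 / mu1^2)^2)`.
#' Negative amplitudes (baseline noise) keep their sign.
#'
#' @param amplitude,amplitude_sd Fitted amplitude and SD (counts).
#' @param cal A [fit_single_molecule_mixture()] calibration curve.
#' @param exposure Exposure (ms) of the measurement.
#' @return A data.frame with `n_molecules` and `n_molecules_sd`.
#' @export
amplitude_to_molecules <- function(amplitude, amplitude_sd, cal,
                                   exposure = cal$exposure_reference) {
  if (!inherits(cal, "calibration_curve") || cal$unit_intensity <= 0)
    stop("invalid calibration: unit intensity must be positive")
  scale <- exposure / cal$exposure_reference
  mu1 <- cal$unit_intensity * scale
  smu1 <- cal$unit_intensity_sd * scale
  n <- amplitude / mu1
  sn <- sqrt((amplitude_sd / mu1)^2 + (amplitude * smu1 / mu1^2)^2)
  data.frame(n_molecules = n, n_molecules_sd = sn)
}

#' Scale tagged-Snf7 counts to total Snf7
#'
#' Only a third of Snf7 is eGFP-tagged in the imaging strain, so the
#' molecule count read from fluorescence is multiplied by 3 to estimate
#' total Snf7.  The factor is exposed, never folded silently into the
#' tagged counts.
#'
#' @param n_tagged Tagged-molecule count(s), non-negative.
#' @param factor Labeling dilution factor.
#' @return `factor * n_tagged`.
#' @export
scale_snf7 <- function(n_tagged, factor = 3) {
  stopifnot(all(n_tagged >= 0))
  factor * n_tagged
}

#' Convert a molecule count to Vps4 hexamers
#'
#' Nearest-integer quantization (half rounds up): 20 molecules is ~3
#' hexamers, 11 is ~2.
#'
#' @param n Molecule count(s), non-negative.
#' @return Integer hexamer count(s).
#' @export
molecules_to_hexamers <- function(n) {
  if (any(n < 0)) stop("molecule count must be non-negative")
  as.integer(floor(n / 6 + 0.5))
}

#' Mean stoichiometric ratio between two channels
#'
#' Per-event ratio of mean accumulations between paired trace sets,
#' averaged across events; `scale_a` applies a labeling correction to
#' channel A (for example x3 for Snf7-eGFP).  Events with a zero
#' denominator are excluded and counted.
#'
#' @param traces_a,traces_b Paired lists of molecule traces (each with an
#'   `N` column) or numeric vectors of per-event mean accumulations.
#' @param scale_a Multiplier applied to channel A.
#' @return A list with `ratio`, `se`, `n_events`, `n_excluded`.
#' @export
stoichiometry_ratio <- function(traces_a, traces_b, scale_a = 1) {
  mean_acc <- function(tr) {
    if (is.numeric(tr)) return(mean(tr))
    mean(tr$N)
  }
  if (!length(traces_a) || !length(traces_b))
    stop("both trace sets must be non-empty")
  stopifnot(length(traces_a) == length(traces_b))
  a <- vapply(traces_a, mean_acc, numeric(1))
  b <- vapply(traces_b, mean_acc, numeric(1))
  ok <- is.finite(a) & is.finite(b) & b != 0
  r <- scale_a * a[ok] / b[ok]
  list(ratio = mean(r), se = stats::sd(r) / sqrt(length(r)),
       n_events = sum(ok), n_excluded = sum(!ok))
}
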