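#' Parameters of a synthetic recruitment event
#'
#' An event starts with an abrupt burst from baseline to about `burst_mean`
#' molecules, fluctuates with no net drift through a balanced birth-death
#' exchange, and releases all molecules in a single frame.  Lifetimes are
#' drawn from a truncated bi-exponential mixture.  ESCRT-III subunits
#' exchange one molecule at a time (`quantum_step = 1`); Vps4 joins and
#' leaves as hexamers (`quantum_step = 6`).
#'
#' @param burst_mean Mean number of molecules recruited at onset.
#' @param burst_sd SD of the onset burst.
#' @param exchange_rate Exchange events per second after onset.
#' @param quantum_step Molecules per exchange event, 1 or 6.
#' @param lifetime_mix_weight Weight `w` of the fast lifetime component.
#' @param lifetime_tau1,lifetime_tau2 Time constants (s), `tau1 <= tau2`.
#' @param min_lifetime,max_lifetime Truncation bounds (s) for lifetimes.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(burst_mean = 60, burst_sd = 15,
                         exchange_rate = 1.5, quantum_step = 1,
                         lifetime_mix_weight = 0.7,
                         lifetime_tau1 = 4, lifetime_tau2 = 20,
                         min_lifetime = 3, max_lifetime = 45) {
  stopifnot(burst_mean > 0, burst_sd >= 0, exchange_rate >= 0)
  if (!quantum_step %in% c(1, 6))
    stop("quantum_step must be 1 (ESCRT-III) or 6 (Vps4 hexamers)")
  if (!(lifetime_mix_weight >= 0 && lifetime_mix_weight <= 1))
    stop("lifetime_mix_weight must lie in [0, 1]")
  if (!(lifetime_tau1 > 0 && lifetime_tau2 > 0 &&
        lifetime_tau1 <= lifetime_tau2))
    stop("need 0 < lifetime_tau1 <= lifetime_tau2")
  if (!(min_lifetime < max_lifetime))
    stop("min_lifetime must be smaller than max_lifetime")
  structure(list(burst_mean = burst_mean, burst_sd = burst_sd,
                 exchange_rate = exchange_rate,
                 quantum_step = as.integer(quantum_step),
                 lifetime_mix_weight = lifetime_mix_weight,
                 lifetime_tau1 = lifetime_tau1,
                 lifetime_tau2 = lifetime_tau2,
                 min_lifetime = min_lifetime,
                 max_lifetime = max_lifetime),
            class = "trace_params")
}

#' Event parameter presets for the three tagged proteins
#'
#' Onset levels follow the measured accumulations: about 60 Snf7-eGFP,
#' 14 Vps24-eGFP and 20 Vps4-eGFP molecules; Vps4 exchanges in hexamer
#' steps.
#'
#' @param protein One of `"snf7"`, `"vps24"`, `"vps4"`.
#' @return A [trace_params()] object.
#' @export
protein_params <- function(protein = c("snf7", "vps24", "vps4")) {
  switch(match.arg(protein),
         snf7  = trace_params(burst_mean = 60, burst_sd = 15,
                              exchange_rate = 2, quantum_step = 1),
         vps24 = trace_params(burst_mean = 14, burst_sd = 4,
                              exchange_rate = 1, quantum_step = 1),
         vps4  = trace_params(burst_mean = 20, burst_sd = 6,
                              exchange_rate = 0.5, quantum_step = 6))
}

#' Draw event lifetimes from the truncated bi-exponential mixture
#'
#' Samples `w * Exp(tau1) + (1 - w) * Exp(tau2)` and rejection-resamples
#' every draw into `[min_lifetime, max_lifetime]`, so the returned values
#' follow the doubly truncated mixture exactly.
#'
#' @param params A [trace_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of lifetimes (s).
#' @export
sample_lifetime <- function(params, n = 1) {
  stopifnot(inherits(params, "trace_params"), n >= 1)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    comp <- stats::runif(m) < params$lifetime_mix_weight
    x <- ifelse(comp,
                stats::rexp(m, 1 / params$lifetime_tau1),
                stats::rexp(m, 1 / params$lifetime_tau2))
    out <- c(out, x[x >= params$min_lifetime & x <= params$max_lifetime])
  }
  out[seq_len(n)]
}

#' Density of the truncated bi-exponential lifetime mixture
#'
#' @param t Times (s).
#' @param w,tau1,tau2 Mixture weight and time constants.
#' @param lower,upper Truncation bounds (s); `upper = Inf` for
#'   left-truncation only.
#' @return Density values, zero outside `[lower, upper]`.
#' @export
dbiexp_trunc <- function(t, w, tau1, tau2, lower = 0, upper = Inf) {
  p_mix <- function(q) {
    w * stats::pexp(q, 1 / tau1) + (1 - w) * stats::pexp(q, 1 / tau2)
  }
  mass <- p_mix(upper) - p_mix(lower)
  d <- w * stats::dexp(t, 1 / tau1) + (1 - w) * stats::dexp(t, 1 / tau2)
  ifelse(t >= lower & t <= upper, d / mass, 0)
}

#' Simulate one molecule-count recruitment trace
#'
#' The count jumps from zero to a quantized `Normal(burst_mean, burst_sd)`
#' draw at onset.  Every following frame adds `Poisson(exchange_rate * dt)`
#' arrivals and removes binomial departures with matched expectation (zero
#' mean drift), both in units of `quantum_step`, then the event releases to
#' zero in a single frame at the end of its lifetime.
#'
#' @param params A [trace_params()] object.
#' @param frame_interval Frame spacing (ms).
#' @param lifetime Optional lifetime (s); drawn via [sample_lifetime()] if
#'   `NULL`.
#' @return A list with `counts` (integer molecule counts, one per occupied
#'   frame), `lifetime` (s) and `n_frames`.
#' @export
simulate_trace <- function(params, frame_interval = 850, lifetime = NULL) {
  stopifnot(inherits(params, "trace_params"), frame_interval > 0)
  if (is.null(lifetime)) lifetime <- sample_lifetime(params)
  dt <- frame_interval / 1000
  n_frames <- max(1L, round(lifetime / dt))
  q <- params$quantum_step
  units <- max(1L, round(stats::rnorm(1, params$burst_mean,
                                      params$burst_sd) / q))
  counts <- integer(n_frames)
  counts[1] <- units * q
  if (n_frames > 1) {
    lambda <- params$exchange_rate * dt
    for (f in 2:n_frames) {
      arr <- stats::rpois(1, lambda)
      dep <- if (units > 0) {
        stats::rbinom(1, units, min(1, lambda / units))
      } else 0L
      units <- max(0L, units + arr - dep)
      counts[f] <- units * q
    }
  }
  list(counts = counts, lifetime = n_frames * dt, n_frames = n_frames)
}
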