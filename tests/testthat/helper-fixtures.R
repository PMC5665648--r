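# Shared fixtures: a small imaging configuration and constructors for
# synthetic detections / traces, so every test builds its data in code.

tiny_geom <- function(n_volumes = 1, shape = c(17, 25, 25)) {
  acq_geometry(n_volumes = n_volumes, volume_shape = shape)
}

tiny_models <- function(n_volumes = 1, shape = c(17, 25, 25)) {
  geom <- tiny_geom(n_volumes, shape)
  list(geom = geom, cam = camera_model(), fluor = fluorophore_model(),
       psf = psf_model(geom = geom))
}

# Render one frame holding emitters at voxel positions (z, y, x in px,
# 1-based) with given molecule counts.
render_emitters_frame <- function(pos_px, molecules, m = tiny_models(),
                                  background = 0.1) {
  pos_nm <- cbind((pos_px[, 1] - 1) * m$geom$z_step,
                  (pos_px[, 2] - 1) * m$geom$pixel_size_xy,
                  (pos_px[, 3] - 1) * m$geom$pixel_size_xy)
  pe <- llsmtrace:::expected_pe_frame(pos_nm, molecules, m$geom, m$cam,
                                      m$fluor, m$psf,
                                      m$geom$volume_shape) +
    background * m$geom$exposure_per_plane * m$cam$quantum_efficiency
  llsmtrace:::emccd_counts(pe, m$cam)
}

# Minimal spot table row(s) for the tracking module.
make_spots <- function(frame, z, y, x, amplitude = 500,
                       sigma_xy = 110, accepted = TRUE) {
  data.frame(frame = frame, z = z, y = y, x = x,
             z_sd = 30, y_sd = 15, x_sd = 15,
             amplitude = amplitude, amplitude_sd = amplitude / 10,
             background = 100, background_sd = 3,
             sigma_xy = sigma_xy, sigma_z = 380,
             residual_sd = 20, snr = 5, p_value = 1e-6,
             n_voxels = 1000L, n_free = 7L, converged = TRUE,
             accepted = accepted)
}

# A molecule_trace built directly from a molecule-count vector.
fake_trace <- function(N, dt_ms = 850, censored = FALSE, track_id = 1L,
                       class_label = "I", N_sd = NULL) {
  tr <- data.frame(time = (seq_along(N) - 1) * dt_ms / 1000,
                   frame = seq_along(N), N = N,
                   N_sd = if (is.null(N_sd)) pmax(sqrt(abs(N)), 1)
                          else N_sd,
                   background_N = 0.5, interpolated = FALSE)
  attr(tr, "track_id") <- track_id
  attr(tr, "channel") <- "eGFP"
  attr(tr, "class_label") <- class_label
  attr(tr, "censored") <- censored
  attr(tr, "frame_interval") <- dt_ms
  class(tr) <- c("molecule_trace", "data.frame")
  tr
}

# CDF of the doubly truncated bi-exponential mixture (oracle for the
# lifetime sampler).
biexp_trunc_cdf <- function(q, w, tau1, tau2, lower, upper) {
  p <- function(t) w * pexp(t, 1 / tau1) + (1 - w) * pexp(t, 1 / tau2)
  pmin(pmax((p(q) - p(lower)) / (p(upper) - p(lower)), 0), 1)
}
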