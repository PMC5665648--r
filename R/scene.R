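#' Ground-truth scene of recruitment events in a cell volume
#'
#' Builds the emitter population the movies are rendered from.  Class I
#' emitters are mobile, diffraction-limited endosomes carrying a single
#' recruitment event per channel; a typical cell holds 5-10 of them.  Class
#' II emitters are bright, nearly static perivacuolar clusters whose count
#' series is the sum of 3-5 asynchronous events, so their totals run 4-5x a
#' single event and their fluctuations stay of single-event magnitude.
#' When `coupled_channel` is `TRUE` every class I emitter carries a second
#' (Vps4-like) channel whose counts follow the first channel plus
#' independent noise, so the true cross-channel correlation peaks at lag 0.
#'
#' @param n_class1,n_class2 Numbers of class I and class II emitters.
#' @param geom An [acq_geometry()]; sets the frame grid and, with
#'   `cell_bounds`, the world volume.
#' @param params A [trace_params()] for the primary channel.
#' @param cell_bounds 3D box `c(z, y, x)` in nm containing all emitters;
#'   defaults to the field of view implied by `geom`.
#' @param diffusion_coefficient Class I diffusion coefficient (nm^2/ms).
#'   The default 5 nm^2/ms (0.005 um^2/s, typical for yeast endosomes)
#'   gives RMS frame-to-frame steps of ~90 nm per axis at 850 ms spacing.
#' @param coupled_channel Add a proportional second channel to class I
#'   emitters?
#' @param coupling_gain Second-channel counts per first-channel molecule.
#' @param coupling_noise_sd SD of the independent noise added to the
#'   coupled channel (molecules).
#' @return An object of class `scene`: a list with `cell_bounds`,
#'   `background_photon_rate`, `cytosol_haze_fraction`, `n_frames` and
#'   `emitters`, a list of emitter records with fields `emitter_id`,
#'   `class_label`, `positions` (`n_frames x 3` matrix, z/y/x nm),
#'   `counts` (primary channel), optional `counts2`, `onset_frame`,
#'   `release_frame`.
#' @export
build_scene <- function(n_class1 = 7, n_class2 = 2,
                        geom = acq_geometry(),
                        params = protein_params("snf7"),
                        cell_bounds = NULL,
                        diffusion_coefficient = 5,
                        coupled_channel = FALSE,
                        coupling_gain = 1 / 3,
                        coupling_noise_sd = 0.5,
                        background_photon_rate = 0.1,
                        cytosol_haze_fraction = 0.1) {
  if (is.null(cell_bounds)) {
    cell_bounds <- c(geom$volume_shape[1] * geom$z_step,
                     geom$volume_shape[2] * geom$pixel_size_xy,
                     geom$volume_shape[3] * geom$pixel_size_xy)
  }
  if (any(cell_bounds <= 0)) stop("cell_bounds must enclose a positive volume")
  n_frames <- geom$n_volumes
  dt <- geom$frame_interval                    # ms
  step_sd <- sqrt(2 * diffusion_coefficient * dt)
  emitters <- list()
  id <- 0L
  place_event <- function(counts) {
    # onset uniform over frames that keep the event inside the series
    len <- length(counts)
    onset <- if (len >= n_frames - 2) 2L else
      sample(seq(2L, n_frames - len), 1)
    full <- integer(n_frames)
    keep <- seq(onset, min(n_frames, onset + len - 1L))
    full[keep] <- counts[seq_along(keep)]
    list(full = full, onset = onset,
         release = onset + length(keep) - 1L)
  }
  random_walk <- function(start, sd_step) {
    pos <- matrix(0, n_frames, 3)
    pos[1, ] <- start
    if (n_frames > 1) {
      for (f in 2:n_frames) {
        p <- pos[f - 1, ] + stats::rnorm(3, 0, sd_step)
        # reflect at the cell boundary
        p <- abs(p)
        p <- ifelse(p > cell_bounds, 2 * cell_bounds - p, p)
        pos[f, ] <- pmin(pmax(p, 0), cell_bounds)
      }
    }
    colnames(pos) <- c("z", "y", "x")
    pos
  }
  for (i in seq_len(n_class1)) {
    id <- id + 1L
    ev <- place_event(simulate_trace(params, dt)$counts)
    start <- stats::runif(3, 0.3, 0.7) * cell_bounds
    em <- list(emitter_id = id, class_label = "I",
               positions = random_walk(start, step_sd),
               counts = ev$full, onset_frame = ev$onset,
               release_frame = ev$release)
    if (coupled_channel) {
      c2 <- round(coupling_gain * ev$full +
                    ifelse(ev$full > 0,
                           stats::rnorm(n_frames, 0, coupling_noise_sd), 0))
      em$counts2 <- pmax(0L, as.integer(c2)) *
        as.integer(ev$full > 0)
    }
    emitters[[id]] <- em
  }
  for (i in seq_len(n_class2)) {
    id <- id + 1L
    multiplicity <- sample(3:5, 1)
    total <- integer(n_frames)
    onset <- n_frames; release <- 1L
    for (k in seq_len(multiplicity)) {
      # perivacuolar clusters hold several concurrently active events:
      # asynchronous (staggered) onsets but long, mostly overlapping
      # lifetimes, so the summed plateau runs at ~multiplicity x one event
      # while the fluctuations stay of single-event magnitude
      lt <- stats::runif(1, 0.6, 0.95) * params$max_lifetime
      ev_counts <- simulate_trace(params, dt, lifetime = lt)$counts
      ev_onset <- sample(2:max(2, min(10, n_frames - 2)), 1)
      full <- integer(n_frames)
      keep <- seq(ev_onset, min(n_frames, ev_onset + length(ev_counts) - 1L))
      full[keep] <- ev_counts[seq_along(keep)]
      total <- total + full
      onset <- min(onset, ev_onset)
      release <- max(release, keep[length(keep)])
    }
    # perivacuolar: near the cell center, frame-to-frame SD < 0.25 px
    start <- stats::runif(3, 0.4, 0.6) * cell_bounds
    em <- list(emitter_id = id, class_label = "II",
               positions = random_walk(start, 0.2 * geom$pixel_size_xy),
               counts = total, onset_frame = onset,
               release_frame = release)
    emitters[[id]] <- em
  }
  structure(list(cell_bounds = cell_bounds,
                 background_photon_rate = background_photon_rate,
                 cytosol_haze_fraction = cytosol_haze_fraction,
                 n_frames = n_frames, geom = geom,
                 emitters = emitters),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  n1 <- sum(vapply(x$emitters, function(e) e$class_label == "I", logical(1)))
  cat(sprintf("scene: %d class I + %d class II emitters, %d frames\n",
              n1, length(x$emitters) - n1, x$n_frames))
  cat(sprintf("  cell bounds (z,y,x) = %.1f x %.1f x %.1f um\n",
              x$cell_bounds[1] / 1e3, x$cell_bounds[2] / 1e3,
              x$cell_bounds[3] / 1e3))
  invisible(x)
}
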