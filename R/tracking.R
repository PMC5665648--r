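#' Link per-frame spot fits into 3D tracks
#'
#' Frame-to-frame optimal one-to-one assignment (exact linear assignment)
#' minimizing summed squared displacement under a hard distance gate.
#' Unassigned detections seed new tracks; track ends are carried across up
#' to `max_gap` missing frames.  When two track ends compete for one
#' detection the involved tracks are flagged `merged`; when one end has
#' several detections in its gate they are flagged `split`.
#'
#' @param spots Data.frame of accepted spot fits from [detect_series()]
#'   (columns `frame`, `x`, `y`, `z` in nm, plus fit columns).
#' @param max_displacement Gate (nm) on frame-to-frame displacement.
#' @param max_gap Maximum number of consecutive missing frames bridged.
#' @return A list of `track` objects: each a list with `track_id`, `spots`
#'   (data.frame rows ordered by frame), `gap_frames`, `flags` (character
#'   vector), `class_label`.
#' @export
link_tracks <- function(spots, max_displacement = 800, max_gap = 2) {
  stopifnot(is.data.frame(spots))
  tracks <- list()
  active <- integer(0)                 # indices into tracks
  if (!nrow(spots)) return(tracks)
  frames <- sort(unique(spots$frame))
  gate2 <- max_displacement^2
  big <- 1e12
  for (f in seq(min(frames), max(frames))) {
    det <- spots[spots$frame == f, , drop = FALSE]
    nd <- nrow(det)
    # retire tracks that cannot be extended any more
    if (length(active)) {
      last <- vapply(active, function(i) max(tracks[[i]]$spots$frame),
                     numeric(1))
      active <- active[f - last <= max_gap + 1]
    }
    na <- length(active)
    assigned_det <- rep(FALSE, nd)
    if (na && nd) {
      endpos <- t(vapply(active, function(i) {
        s <- tracks[[i]]$spots
        unlist(s[nrow(s), c("z", "y", "x")])
      }, numeric(3)))
      d2 <- outer(seq_len(na), seq_len(nd), function(i, j)
        (endpos[i, 1] - det$z[j])^2 + (endpos[i, 2] - det$y[j])^2 +
          (endpos[i, 3] - det$x[j])^2)
      # merge/split competition flags before resolving the assignment
      in_gate <- d2 <= gate2
      for (j in seq_len(nd)) {
        comp <- which(in_gate[, j])
        if (length(comp) >= 2)
          for (i in comp)
            tracks[[active[i]]]$flags <-
              union(tracks[[active[i]]]$flags, "merged")
      }
      for (i in seq_len(na)) {
        if (sum(in_gate[i, ]) >= 2)
          tracks[[active[i]]]$flags <-
            union(tracks[[active[i]]]$flags, "split")
      }
      n <- na + nd
      cost <- matrix(big, n, n)
      cost[seq_len(na), seq_len(nd)] <- ifelse(in_gate, d2, big)
      for (i in seq_len(na)) cost[i, nd + i] <- gate2        # end track
      for (j in seq_len(nd)) cost[na + j, j] <- gate2        # new track
      cost[na + seq_len(nd), nd + seq_len(na)] <- 0
      a <- solve_assignment(cost)
      for (i in seq_len(na)) {
        j <- a[i]
        if (j <= nd && d2[i, j] <= gate2) {
          tr <- tracks[[active[i]]]
          prev <- max(tr$spots$frame)
          if (f - prev > 1)
            tr$gap_frames <- c(tr$gap_frames, seq(prev + 1, f - 1))
          tr$spots <- rbind(tr$spots, det[j, , drop = FALSE])
          tracks[[active[i]]] <- tr
          assigned_det[j] <- TRUE
        }
      }
    }
    if (nd) {
      for (j in which(!assigned_det)) {
        tracks[[length(tracks) + 1]] <-
          list(track_id = length(tracks) + 1L,
               spots = det[j, , drop = FALSE],
               gap_frames = integer(0), flags = character(0),
               class_label = "unclassified")
        active <- c(active, length(tracks))
      }
    }
  }
  tracks
}

#' Apply the valid-track filters
#'
#' A valid track never merges or splits, starts after the first frame and
#' ends before the last (its lifetime is fully included in the series),
#' contains only significance-accepted spots, keeps every position at
#' least `border_margin` from every edge of the imaged volume, and spans
#' at least `min_frames` frames.  Tracks present in every frame are routed
#' to the `persistent` set (lifetime longer than the series); everything
#' else is rejected with machine-readable reasons.
#'
#' @param tracks List of tracks from [link_tracks()].
#' @param geom An [acq_geometry()]; sets the series length.
#' @param volume_shape Volume shape `(z, y, x)` in voxels (world bounds).
#' @param border_margin Edge margin (nm), default 1.5 um.
#' @param min_frames Minimum track span in frames.
#' @return A list with `valid`, `persistent` and `rejected` track lists;
#'   rejected tracks carry their reasons in `$rejection_reasons`.
#' @export
filter_valid <- function(tracks, geom = acq_geometry(),
                         volume_shape = geom$volume_shape,
                         border_margin = 1500, min_frames = 3) {
  n_frames <- geom$n_volumes
  bounds <- c((volume_shape[1] - 1) * geom$z_step,
              (volume_shape[2] - 1) * geom$pixel_size_xy,
              (volume_shape[3] - 1) * geom$pixel_size_xy)
  valid <- list(); persistent <- list(); rejected <- list()
  for (tr in tracks) {
    s <- tr$spots
    f0 <- min(s$frame); f1 <- max(s$frame)
    reasons <- character(0)
    span <- f1 - f0 + 1
    everywhere <- (f0 == 1 && f1 == n_frames)
    if ("merged" %in% tr$flags) reasons <- c(reasons, "merged")
    if ("split" %in% tr$flags) reasons <- c(reasons, "split")
    if (!everywhere && f0 == 1)
      reasons <- c(reasons, "touches_series_start")
    if (!everywhere && f1 == n_frames)
      reasons <- c(reasons, "touches_series_end")
    if (!is.null(s$accepted) && !all(s$accepted))
      reasons <- c(reasons, "below_significance")
    near <- s$z < border_margin | s$z > bounds[1] - border_margin |
      s$y < border_margin | s$y > bounds[2] - border_margin |
      s$x < border_margin | s$x > bounds[3] - border_margin
    if (any(near)) reasons <- c(reasons, "near_border")
    if (span < min_frames) reasons <- c(reasons, "too_short")
    if (everywhere && !length(reasons)) {
      tr$flags <- union(tr$flags, "persistent")
      persistent[[length(persistent) + 1]] <- tr
    } else if (!length(reasons)) {
      valid[[length(valid) + 1]] <- tr
    } else {
      if (everywhere) reasons <- union(reasons, "persistent_but_flagged")
      tr$rejection_reasons <- reasons
      rejected[[length(rejected) + 1]] <- tr
    }
  }
  list(valid = valid, persistent = persistent, rejected = rejected)
}

track_mobility <- function(track) {
  s <- track$spots
  if (nrow(s) < 2) return(0)
  d <- sqrt(diff(s$z)^2 + diff(s$y)^2 + diff(s$x)^2) /
    diff(s$frame)
  mean(d)
}

#' Classify tracks into class I / class II objects
#'
#' Class I: diffraction-limited (median fitted lateral width within
#' `size_tolerance` of the PSF) and mobile.  Class II: spatially extended,
#' or static with high intensity (at least `intensity_factor` times the
#' class I median amplitude) -- the bright, low-mobility perivacuolar
#' clusters.  Dim static diffraction-limited objects stay unclassified.
#'
#' @param tracks List of valid/persistent tracks.
#' @param psf A [psf_model()].
#' @param mobility_threshold Mean frame-to-frame displacement (nm)
#'   separating mobile from static.
#' @param size_tolerance Relative width excess tolerated for
#'   "diffraction-limited".
#' @param intensity_factor Amplitude multiple of the class I median that
#'   marks a static object as class II.
#' @return The track list with `class_label` set to "I", "II" or
#'   "unclassified".
#' @export
classify_tracks <- function(tracks, psf, mobility_threshold = 100,
                            size_tolerance = 0.3, intensity_factor = 3) {
  if (!length(tracks)) return(tracks)
  med_sigma <- vapply(tracks, function(tr)
    stats::median(tr$spots$sigma_xy), numeric(1))
  mobil <- vapply(tracks, track_mobility, numeric(1))
  amp <- vapply(tracks, function(tr)
    stats::median(tr$spots$amplitude), numeric(1))
  dl <- med_sigma <= (1 + size_tolerance) * psf$sigma_xy
  mobile <- mobil >= mobility_threshold
  ref <- stats::median(amp[dl & mobile])
  if (!is.finite(ref)) ref <- stats::median(amp)
  for (i in seq_along(tracks)) {
    tracks[[i]]$class_label <-
      if (dl[i] && mobile[i]) "I"
      else if (!dl[i] || (!mobile[i] && amp[i] >= intensity_factor * ref))
        "II"
      else "unclassified"
  }
  tracks
}
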