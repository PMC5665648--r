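#' Write a volume series as multi-page TIFF plus JSON geometry sidecar
#'
#' Planes are written t-major then z as 16-bit grayscale pages; the
#' acquisition geometry, channel and deskew state go into `<path>.json`.
#' Counts are clamped to the 16-bit range and rounded, so the round trip
#' is lossless for integer data in [0, 65535].
#'
#' @param vol A `volume_series`.
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(vol, path) {
  pages <- list()
  for (f in seq_along(vol$frames)) {
    a <- vol$frames[[f]]
    for (k in seq_len(dim(a)[1])) {
      m <- a[k, , , drop = TRUE]
      dim(m) <- dim(a)[2:3]
      pages[[length(pages) + 1]] <- pmin(pmax(round(m), 0), 65535) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  g <- vol$geometry
  sidecar <- list(
    pixel_size_xy = g$pixel_size_xy, stage_step_s = g$stage_step_s,
    sheet_angle = g$sheet_angle, planes_per_volume = dim(vol$frames[[1]])[1],
    n_volumes = length(vol$frames), frame_interval = g$frame_interval,
    exposure_per_plane = g$exposure_per_plane,
    volume_shape = dim(vol$frames[[1]]),
    channel = vol$channel, deskewed = vol$deskewed,
    provenance = vol$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume series written by [write_volume_series()]
#'
#' @param path TIFF path; `<path>.json` must exist and its plane count
#'   must match the TIFF.
#' @return A `volume_series`.
#' @export
read_volume_series <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing geometry sidecar: expected ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- as.integer(sc$volume_shape)
  n_expected <- sc$n_volumes * shape[1]
  if (length(pages) != n_expected)
    stop(sprintf("TIFF holds %d planes but the sidecar declares %d",
                 length(pages), n_expected))
  frames <- vector("list", sc$n_volumes)
  p <- 1L
  for (f in seq_len(sc$n_volumes)) {
    a <- array(0, dim = shape)
    for (k in seq_len(shape[1])) {
      a[k, , ] <- round(pages[[p]] * 65535)
      p <- p + 1L
    }
    frames[[f]] <- a
  }
  geom <- acq_geometry(pixel_size_xy = sc$pixel_size_xy,
                       stage_step_s = sc$stage_step_s,
                       sheet_angle = sc$sheet_angle,
                       planes_per_volume = shape[1],
                       n_volumes = sc$n_volumes,
                       frame_interval = sc$frame_interval,
                       exposure_per_plane = sc$exposure_per_plane,
                       volume_shape = shape)
  new_volume_series(frames, geom, channel = sc$channel,
                    deskewed = sc$deskewed,
                    provenance = as.character(sc$provenance))
}

spot_table_columns <- c("track_id", "frame", "x", "y", "z",
                        "amplitude", "amplitude_sd",
                        "n_molecules", "n_molecules_sd",
                        "flags", "rejection_reasons")

#' Write track/trace tables as CSV
#'
#' One row per (track, frame) with positions in nm, amplitudes in counts,
#' molecule numbers with propagated SD, and human-readable flag and
#' rejection-reason codes.  The header row is mandatory; the round trip is
#' lossless to full double precision.
#'
#' @param tracks A track list (from [link_tracks()]/[filter_valid()],
#'   flattened), or `NULL`.
#' @param traces Optional list of `molecule_trace` objects aligned with
#'   `tracks` by `track_id` (fills the molecule columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(tracks, traces = NULL, path) {
  rows <- list()
  trace_ids <- if (is.null(traces)) integer(0) else
    vapply(traces, function(tr) attr(tr, "track_id"), integer(1))
  for (tr in tracks) {
    s <- tr$spots
    nmol <- rep(NA_real_, nrow(s)); nsd <- rep(NA_real_, nrow(s))
    ti <- match(tr$track_id, trace_ids)
    if (!is.na(ti)) {
      mt <- traces[[ti]]
      m <- match(s$frame, mt$frame)
      nmol <- mt$N[m]; nsd <- mt$N_sd[m]
    }
    rows[[length(rows) + 1]] <- data.frame(
      track_id = tr$track_id, frame = s$frame,
      x = s$x, y = s$y, z = s$z,
      amplitude = s$amplitude, amplitude_sd = s$amplitude_sd,
      n_molecules = nmol, n_molecules_sd = nsd,
      flags = paste(tr$flags, collapse = ";"),
      rejection_reasons = paste(tr$rejection_reasons, collapse = ";"))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(spot_table_columns))),
      spot_table_columns)
  utils::write.csv(format(tab, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tables()]
#'
#' @param path CSV path.
#' @return A data.frame with the declared column dictionary.
#' @export
read_tables <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(spot_table_columns, names(tab))
  if (length(missing))
    stop("table schema mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  tab$flags <- as.character(tab$flags)
  tab$flags[is.na(tab$flags)] <- ""
  tab$rejection_reasons <- as.character(tab$rejection_reasons)
  tab$rejection_reasons[is.na(tab$rejection_reasons)] <- ""
  tab
}
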