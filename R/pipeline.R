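#' Default desk-scale run configuration
#'
#' A reduced field of view (80 x 80 x 24 voxels) that keeps a full
#' simulate-render-detect-track-analyze cycle interactive while retaining
#' the acquisition constants (pixel size, stage step, sheet angle, frame
#' interval, exposure) of the full 512 x 512 x 30 acquisition.
#'
#' @param seed Integer seed recorded into the provenance of every stage.
#' @param n_volumes Number of time points.
#' @param volume_shape Voxel counts `(z, y, x)`.
#' @param n_class1,n_class2 Scene population.
#' @param protein Trace-parameter preset, see [protein_params()].
#' @param alpha Detection significance level.
#' @param max_displacement,max_gap Tracking gates.
#' @param border_margin Valid-track edge margin (nm).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_volumes = 60,
                       volume_shape = c(24, 80, 80),
                       n_class1 = 7, n_class2 = 2,
                       protein = "snf7", alpha = 0.05,
                       max_displacement = 800, max_gap = 2,
                       border_margin = 1500) {
  structure(list(seed = as.integer(seed), n_volumes = n_volumes,
                 volume_shape = volume_shape, n_class1 = n_class1,
                 n_class2 = n_class2, protein = protein, alpha = alpha,
                 max_displacement = max_displacement, max_gap = max_gap,
                 border_margin = border_margin),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic scene
#'
#' Generates a ground-truth scene, renders it through the EMCCD forward
#' model, detects and fits spots in every frame, links and filters tracks,
#' fits a single-molecule calibration on a rendered calibration field,
#' converts tracks to molecule traces and summarizes the events
#' (lifetimes, accumulations, hexamers, productive flags).  Deterministic
#' under `config$seed`.
#'
#' @param config A [run_config()].
#' @return A list with `config`, `scene`, `truth`, `spots`, `tracks`
#'   (filtered), `calibration`, `traces`, `events` (per-event summary
#'   data.frame) and `summary` (population statistics).
#' @export
run_pipeline <- function(config = run_config()) {
  set.seed(config$seed)
  geom <- acq_geometry(n_volumes = config$n_volumes,
                       volume_shape = config$volume_shape)
  cam <- camera_model()
  fluor <- fluorophore_model()
  psf <- psf_model(geom = geom)
  params <- protein_params(config$protein)
  scene <- build_scene(config$n_class1, config$n_class2, geom, params)
  rendered <- render_volume_series(scene, geom, cam, fluor, psf)
  cal_field <- generate_calibration_field(200, geom, cam, fluor, psf)
  cal_spots <- detect_series(cal_field$volumes, psf, alpha = config$alpha,
                             fix_sigma = TRUE)
  cal <- fit_single_molecule_mixture(
    cal_spots$amplitude[cal_spots$frame == 1],
    exposure_reference = cal_field$exposure)
  spots <- detect_series(rendered$channels[[1]], psf, alpha = config$alpha)
  tracks <- link_tracks(spots, config$max_displacement, config$max_gap)
  filtered <- filter_valid(tracks, geom, config$volume_shape,
                           config$border_margin)
  filtered$valid <- classify_tracks(filtered$valid, psf)
  traces <- lapply(filtered$valid, extract_trace, cal = cal, geom = geom)
  events <- summarize_events(traces, params$quantum_step)
  lifetimes <- events$lifetime[!events$censored]
  summary <- list(
    n_tracks = length(tracks),
    n_valid = length(filtered$valid),
    n_persistent = length(filtered$persistent),
    n_rejected = length(filtered$rejected),
    unit_intensity = cal$unit_intensity,
    mean_lifetime = mean(lifetimes),
    mean_max_accumulation = mean(events$max_accumulation),
    productive_fraction = mean(events$productive))
  list(config = config, scene = scene, truth = rendered$truth,
       spots = spots, tracks = filtered, calibration = cal,
       traces = traces, events = events, summary = summary)
}

#' Summarize molecule traces into per-event statistics
#'
#' @param traces List of `molecule_trace` objects.
#' @param quantum_step 6 for a Vps4 channel (enables hexamer columns),
#'   1 otherwise.
#' @return A data.frame with one row per trace: `track_id`, `lifetime`,
#'   `censored`, `max_accumulation`, `mean_accumulation`,
#'   `max_hexamers`, `productive`, `n_fluctuation_peaks`, `class_label`.
#' @export
summarize_events <- function(traces, quantum_step = 1) {
  if (!length(traces))
    return(data.frame(track_id = integer(0), lifetime = numeric(0),
                      censored = logical(0), max_accumulation = numeric(0),
                      mean_accumulation = numeric(0),
                      max_hexamers = integer(0), productive = logical(0),
                      n_fluctuation_peaks = integer(0),
                      class_label = character(0)))
  do.call(rbind, lapply(traces, function(tr) {
    acc <- accumulation_stats(tr)
    lt <- lifetime(tr)
    censored <- isTRUE(attr(lt, "censored"))
    peaks <- if (nrow(tr) >= 3)
      fluctuation_peaks(tr, min_prominence = if (quantum_step == 6) 6 else 10)
    else data.frame()
    data.frame(track_id = attr(tr, "track_id"),
               lifetime = if (censored) NA_real_ else as.numeric(lt),
               censored = censored,
               max_accumulation = acc$max_accumulation,
               mean_accumulation = acc$mean_accumulation,
               max_hexamers = molecules_to_hexamers(
                 max(max(tr$N, 0))),
               productive = classify_productive(tr),
               n_fluctuation_peaks = nrow(peaks),
               class_label = attr(tr, "class_label"))
  }))
}
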