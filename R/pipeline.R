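#' Pipeline configuration
#'
#' Bundles all stage parameters with defaults embodying the study constants:
#' 10x10 occupancy grid, window durations 5-360 s in steps of 5 s, 7 um/s
#' fast/slow split, hue bands 20/24/27/43-45, 50 frames/s acquisition with
#' 0.02 s exposure and a 10x long-exposure ratio.
#'
#' @param arena_width_um,arena_height_um,rho,n_cells,duration_s,seed Swarm
#'   generator parameters (see [swarm_config()]).
#' @param frame_interval_s,exposure_s,pixel_size_um Acquisition parameters.
#' @param long_exposure_ratio Frame-averaging factor for the synthetic long
#'   exposure (default 10: 50 frames/s to 5 frames/s).
#' @param intensity_threshold,min_area_px Immobile-cell detection.
#' @param grid Occupancy grid (default `c(10, 10)`).
#' @param durations_s Occupancy window durations (s).
#' @param fast_threshold_ums Fast-subset speed split (um/s).
#' @param neighbor_cutoffs_um Cutoff radii for the speed-neighbour curve.
#' @param hue_on,hue_off Wetness-event hysteresis thresholds.
#' @param n_subsamples Renderer subsamples per exposure.
#' @param ... Further [swarm_config()] arguments.
#' @return A `pipeline_config` list with elements `swarm` (a
#'   [swarm_config()]) and the stage parameters.
#' @export
pipeline_config <- function(arena_width_um = 60, arena_height_um = 60,
                            rho = 0.3, n_cells = NULL, duration_s = 60,
                            frame_interval_s = 0.02, exposure_s = 0.02,
                            pixel_size_um = 0.2,
                            long_exposure_ratio = 10L,
                            intensity_threshold = 0.9, min_area_px = 140,
                            grid = c(10L, 10L),
                            durations_s = seq(5, 360, by = 5),
                            fast_threshold_ums = 7,
                            neighbor_cutoffs_um = c(3, 5, 7, 10),
                            hue_on = 0.5, hue_off = 0.2,
                            n_subsamples = 11L, seed = 1L, ...) {
  if (!is.null(n_cells) && n_cells < 1) {
    stop("invalid configuration: n_cells must be >= 1", call. = FALSE)
  }
  swarm <- swarm_config(arena_width_um = arena_width_um,
                        arena_height_um = arena_height_um,
                        rho = rho, n_cells = n_cells,
                        duration_s = duration_s,
                        frame_interval_s = frame_interval_s,
                        seed = seed, ...)
  width_px <- as.integer(round(arena_width_um / pixel_size_um))
  height_px <- as.integer(round(arena_height_um / pixel_size_um))
  structure(list(
    swarm = swarm,
    meta = stack_meta(width_px, height_px, pixel_size_um,
                      frame_interval_s, exposure_s),
    long_exposure_ratio = as.integer(long_exposure_ratio),
    intensity_threshold = intensity_threshold, min_area_px = min_area_px,
    grid = as.integer(grid), durations_s = durations_s,
    fast_threshold_ums = fast_threshold_ums,
    neighbor_cutoffs_um = neighbor_cutoffs_um,
    hue_on = hue_on, hue_off = hue_off,
    n_subsamples = as.integer(n_subsamples),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "render", "detect", "occupancy", "kinematics", "hue", "ctmc")
}

#' Run the full analysis pipeline
#'
#' Simulate a swarm, render intensity stacks, synthesise long exposures,
#' detect immobile cells, compute bin-occupancy statistics, kinematics, hue
#' events and flagellar-state inference, writing intermediate artifacts and
#' a single JSON summary of every headline statistic. Stage seeds fan out
#' deterministically from the master seed, so re-running with the same seed
#' is byte-reproducible and changing a downstream stage's seed leaves
#' upstream artifacts unchanged.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` keeps results
#'   in memory only.
#' @param seed Master seed overriding `config$seed`.
#' @param through Last stage to run: one of `"simulate"`, `"render"`,
#'   `"detect"`, `"occupancy"`, `"kinematics"`, `"hue"`, `"ctmc"` or
#'   `"all"`.
#' @return Invisible list of stage results, including `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         through = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  through <- match.arg(through, c(pipeline_stages(), "all"))
  last <- if (through == "all") length(pipeline_stages()) else
    match(through, pipeline_stages())
  if (is.null(seed)) seed <- config$seed
  stage_seed <- function(k) (seed * 131L + k * 7919L) %% .Machine$integer.max
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  wrap <- c(config$swarm$arena_width_um, config$swarm$arena_height_um)
  summary <- list(schema_version = 1L, seed = seed)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # simulate
  res$tracks <- run_stage("simulate",
    simulate_swarm(config$swarm, seed = stage_seed(1L)))
  if (!is.null(out_dir)) {
    write_tracks(res$tracks, file.path(out_dir, "tracks.csv"))
  }
  if (last >= 2L) {  # render
    res$stack <- run_stage("render",
      render_stack(res$tracks, config$meta,
                   n_subsamples = config$n_subsamples, wrap = wrap))
    res$long_stack <- run_stage("render",
      synthesize_long_exposure(res$stack, config$long_exposure_ratio))
    if (!is.null(out_dir)) {
      write_stack(res$stack, file.path(out_dir, "stack.tif"))
      write_stack(res$long_stack, file.path(out_dir, "long_stack.tif"))
    }
  }
  if (last >= 3L) {  # detect
    res$masks <- run_stage("detect",
      lapply(res$long_stack$frames, detect_immobile,
             intensity_threshold = config$intensity_threshold,
             min_area_px = config$min_area_px))
    fr <- vapply(res$masks, immobile_fraction,
                 numeric(1), n_cells_total = config$swarm$n_cells)
    summary$mean_immobile_fraction <- mean(fr)
  }
  if (last >= 4L) {  # occupancy
    res$occupancy <- run_stage("occupancy", {
      cell_area_px <- config$swarm$cell_length_um *
        config$swarm$cell_width_um / config$meta$pixel_size_um^2
      bin_occupancy(res$masks, res$long_stack$meta$frame_interval_s,
                    grid = config$grid, cell_area_px = cell_area_px)
    })
    res$occupancy_stats <- run_stage("occupancy",
      suppressWarnings(occupancy_stats(res$occupancy, config$durations_s)))
    summary$mean_occupancy_fraction <-
      res$occupancy_stats$mean_fraction[1]
    expo <- tryCatch(as.numeric(fit_std_exponent(res$occupancy_stats)),
                     error = function(e) NA_real_, warning = function(w) NA_real_)
    summary$std_exponent <- expo
    ac <- tryCatch(occupancy_autocorrelation(res$occupancy),
                   error = function(e) NULL)
    summary$occupancy_decay_time_s <- if (is.null(ac)) NA_real_ else
      ac$decay_time_s
    nb <- attr(res$occupancy_stats, "per_bin")[[1]]
    nc <- tryCatch(normality_check(nb), error = function(e) NULL)
    summary$occupancy_shapiro_p <- if (is.null(nc)) NA_real_ else nc$p_value
  }
  if (last >= 5L) {  # kinematics
    res$speeds <- run_stage("kinematics",
      do.call(rbind, lapply(res$tracks, instantaneous_speeds, wrap = wrap)))
    ss <- speed_summary(res$speeds$speed_ums, config$fast_threshold_ums)
    summary$fast_mean_speed_ums <- ss$fast_mean_ums
    res$speed_vs_k <- run_stage("kinematics",
      speed_vs_neighbors(res$tracks, config$neighbor_cutoffs_um, wrap = wrap))
    if (!is.null(out_dir)) {
      utils::write.csv(res$speed_vs_k,
                       file.path(out_dir, "speed_vs_neighbors.csv"),
                       row.names = FALSE)
    }
  }
  if (last >= 6L) {  # hue
    res$hue_events <- run_stage("hue", {
      tt <- res$tracks[[1]]$time_s
      hue_times <- tt[seq(1, length(tt), by = config$long_exposure_ratio)]
      evs <- lapply(seq_along(res$tracks), function(i) {
        maps <- lapply(seq_along(hue_times), function(k) {
          classify_hue(render_dic_hue(res$tracks[i], hue_times[k],
                                      config$meta, wrap = wrap,
                                      seed = stage_seed(6L) + i * 1000L + k))
        })
        dfr <- dry_fraction_timeseries(maps, hue_times, res$tracks[[i]],
                                       normalize = TRUE)
        detect_wetness_events(dfr, config$hue_on, config$hue_off,
                              cell_id = i)
      })
      do.call(rbind, evs)
    })
    summary$n_wetness_events <- nrow(res$hue_events)
    summary$mean_stall_duration_s <-
      if (length(stall_durations(res$hue_events)))
        mean(stall_durations(res$hue_events)) else NA_real_
    if (!is.null(out_dir)) {
      utils::write.csv(res$hue_events, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
    }
  }
  if (last >= 7L) {  # ctmc
    res$extraction <- run_stage("ctmc", extract_dwells(res$tracks))
    em <- embedded_matrix(res$extraction)
    res$embedded <- em
    summary$exit_rates_per_s <- unname(signif(em$exit_rates, 3))
    summary$embedded_matrix <- unname(em$embedded)
    Q <- two_step_matrix(res$extraction)
    summary$memorylessness_error <- tryCatch(
      memorylessness_error(em$embedded, Q), error = function(e) NA_real_)
    open_dwells <- with(res$extraction$dwells,
                        duration_s[state == "OPEN" & !censored])
    if (length(open_dwells) >= 10) {
      fs <- mle_exponential(open_dwells)
      fm <- fit_exponential_mixture(open_dwells, seed = stage_seed(7L))
      summary$delta_aic_open <- aic_compare(fs, fm)
    } else summary$delta_aic_open <- NA_real_
    sbs <- speed_by_state(res$tracks)
    summary$state_mean_speed_ums <- list(
      CLOSED = sbs$CLOSED$mean_ums, PARTIAL = sbs$PARTIAL$mean_ums,
      OPEN = sbs$OPEN$mean_ums)
  }
  res$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
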