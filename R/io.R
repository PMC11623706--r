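#' Write cell tracks to CSV
#'
#' One row per cell per frame, UTF-8, '.' decimal, with header:
#' `cell_id, frame, time_s, x_um, y_um, theta_rad, state, wetness` (plus any
#' extra ground-truth columns present, e.g. `speed_ums`, `n_neighbors`).
#'
#' @param tracks List of `cell_track` data.frames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- tracks_df(tracks)
  core <- c("cell_id", "frame", "time_s", "x_um", "y_um", "theta_rad",
            "state", "wetness")
  missing_core <- setdiff(core, names(df))
  if ("theta_rad" %in% missing_core) df$theta_rad <- NA_real_
  if ("wetness" %in% missing_core) df$wetness <- NA_real_
  if ("state" %in% missing_core) df$state <- NA_character_
  df <- df[, c(core, setdiff(names(df), core))]
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "cell_id" &
    names(df) != "frame"
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read cell tracks from CSV
#'
#' Inverse of [write_tracks()]: validates the schema, the state symbols and
#' the uniform timebase, and splits rows into per-cell `cell_track`
#' data.frames.
#'
#' @param path CSV path.
#' @param cell_length_um,cell_width_um Rod dimensions attached to each track.
#' @return List of `cell_track` data.frames (empty list for a header-only
#'   file).
#' @export
read_tracks <- function(path, cell_length_um = 7, cell_width_um = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  core <- c("cell_id", "frame", "time_s", "x_um", "y_um", "theta_rad",
            "state", "wetness")
  miss <- setdiff(core, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) return(list())
  known <- c(flagellar_states(), NA_character_)
  bad <- which(!(df$state %in% known))
  if (length(bad)) {
    stop("unknown state token '", df$state[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  }
  out <- lapply(split(df, df$cell_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    dt <- diff(tr$time_s)
    if (length(dt) && max(abs(dt - dt[1])) > 1e-6) {
      stop("non-uniform timebase for cell ", tr$cell_id[1], call. = FALSE)
    }
    rownames(tr) <- NULL
    structure(tr, class = c("cell_track", "data.frame"),
              cell_length_um = cell_length_um, cell_width_um = cell_width_um)
  })
  unname(out[order(as.numeric(names(out)))])
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages; pixel size, frame interval
#' and exposure go to `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 32, reduce = FALSE)
  meta <- stack$meta
  jsonlite::write_json(
    list(width_px = meta$width_px, height_px = meta$height_px,
         pixel_size_um = meta$pixel_size_um,
         frame_interval_s = meta$frame_interval_s,
         exposure_s = meta$exposure_s, n_frames = length(stack$frames)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.json` must exist and agree with the frame
#'   count.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar ", sidecar, call. = FALSE)
  }
  meta_js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) != meta_js$n_frames) {
    stop("sidecar reports ", meta_js$n_frames, " frames but TIFF has ",
         length(frames), call. = FALSE)
  }
  meta <- stack_meta(meta_js$width_px, meta_js$height_px,
                     meta_js$pixel_size_um, meta_js$frame_interval_s,
                     meta_js$exposure_s)
  image_stack(frames, meta)
}

#' Total duration of a stack
#'
#' @param stack An [image_stack()].
#' @return Duration in seconds (frames times frame interval).
#' @export
stack_duration <- function(stack) {
  length(stack$frames) * stack$meta$frame_interval_s
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the [pipeline_config()] argument names (any subset;
#' the rest take defaults).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml/.yml or .json", call. = FALSE))
  do.call(pipeline_config, raw)
}
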