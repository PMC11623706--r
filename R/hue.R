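#' Hue class labels and codes
#'
#' @return Named integer vector mapping class names to export codes.
#' @export
hue_classes <- function() {
  c(BLACK = 0L, BLUE = 1L, GREEN = 2L, UNCLASSIFIED = 3L, BACKGROUND = 4L)
}

#' Classify a hue map into wet/dry classes
#'
#' Applies the fixed integer thresholds: hue <= 20 is BLACK, 21-24 BLUE,
#' 25-27 GREEN, 28-42 UNCLASSIFIED, >= 43 BACKGROUND. Fractional hues are
#' floored first (the band edges are integers with no interpolation rule).
#' BLACK/BLUE/GREEN mark increasingly shallow exposed (dry) topography;
#' BACKGROUND covers the agar and moving (wet) cells.
#'
#' @param hue_map Numeric matrix of hues (finite, >= 0), e.g. from
#'   [render_dic_hue()].
#' @return A `hue_class_map`: integer matrix of class codes (see
#'   [hue_classes()]) with any `meta` attribute propagated.
#' @export
classify_hue <- function(hue_map) {
  h <- unclass(hue_map)
  if (any(!is.finite(h))) stop("hue values must be finite", call. = FALSE)
  if (any(h < 0)) stop("negative hue values", call. = FALSE)
  hf <- floor(h)
  cls <- matrix(hue_classes()[["UNCLASSIFIED"]], nrow(h), ncol(h))
  cls[hf <= 20] <- hue_classes()[["BLACK"]]
  cls[hf >= 21 & hf <= 24] <- hue_classes()[["BLUE"]]
  cls[hf >= 25 & hf <= 27] <- hue_classes()[["GREEN"]]
  cls[hf >= 43] <- hue_classes()[["BACKGROUND"]]
  structure(cls, meta = attr(hue_map, "meta"),
            class = c("hue_class_map", "matrix", "array"))
}

#' Per-frame dry fraction of a cell's neighbourhood
#'
#' For each classified frame, the fraction of non-background pixels inside a
#' padded axis-aligned bounding box around the cell's position. A fully wet
#' cell is indistinguishable from background (fraction 0); a fully dry
#' stationary cell contributes roughly its body area over the box area.
#'
#' @param class_maps List of `hue_class_map` matrices.
#' @param times_s Frame times (s), same length as `class_maps`.
#' @param track A `cell_track` data.frame overlapping `times_s`.
#' @param pad_um Padding added around the cell half-length (default 1 um).
#' @param pixel_size_um Pixel size; taken from the map metadata when present.
#' @param normalize If `TRUE`, report dry pixels relative to the cell-body
#'   area instead of the box area, so a fully dry cell reads close to 1
#'   regardless of how much empty box surrounds the rod (clipped to [0, 1]).
#' @return Data.frame with `time_s` and `dry_fraction`.
#' @export
dry_fraction_timeseries <- function(class_maps, times_s, track, pad_um = 1,
                                    pixel_size_um = NULL, normalize = FALSE) {
  stopifnot(length(class_maps) == length(times_s))
  meta <- attr(class_maps[[1]], "meta")
  ps <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(ps)) stop("pixel size unknown", call. = FALSE)
  half_um <- (attr(track, "cell_length_um") %||% 7) / 2 + pad_um
  bg <- hue_classes()[["BACKGROUND"]]
  frac <- vapply(seq_along(class_maps), function(f) {
    cm <- class_maps[[f]]
    i <- which.min(abs(track$time_s - times_s[f]))
    cx <- track$x_um[i] / ps
    cy <- track$y_um[i] / ps
    r <- half_um / ps
    ix <- max(0, floor(cx - r)):min(ncol(cm) - 1, ceiling(cx + r))
    iy <- max(0, floor(cy - r)):min(nrow(cm) - 1, ceiling(cy + r))
    if (!length(ix) || !length(iy) || ix[1] > ix[length(ix)]) {
      stop("empty cell region at frame ", f, call. = FALSE)
    }
    box <- cm[iy + 1, ix + 1, drop = FALSE]
    if (normalize) {
      cell_px <- (attr(track, "cell_length_um") %||% 7) *
        (attr(track, "cell_width_um") %||% 1) / ps^2
      min(sum(box != bg) / cell_px, 1)
    } else {
      mean(box != bg)
    }
  }, numeric(1))
  data.frame(time_s = times_s, dry_fraction = frac)
}

#' Detect stopping and wetting events by hysteresis
#'
#' A STOPPING event is recorded when the dry fraction rises through the `on`
#' threshold (a moving cell stops and dries: green to blue to black); a
#' WETTING event when it falls back through the `off` threshold (the cell
#' re-wets and eventually moves: black back to green). Hysteresis
#' (`off < on`) guarantees the two event types alternate. The `duration_s`
#' of a WETTING event is the dry (stall) interval, from the on-crossing to
#' the off-crossing — the quantity comparable to open-state dwell times.
#'
#' @param dry_fraction Data.frame from [dry_fraction_timeseries()] (or any
#'   with `time_s`, `dry_fraction`).
#' @param on,off Hysteresis thresholds, `0 < off < on < 1` (defaults 0.5,
#'   0.2).
#' @param cell_id Identifier attached to the events.
#' @return Data.frame of events: `cell_id`, `type`, `t_start`, `t_end`,
#'   `duration_s`. Empty (zero rows) when no threshold crossing occurs.
#' @export
detect_wetness_events <- function(dry_fraction, on = 0.5, off = 0.2,
                                  cell_id = NA_integer_) {
  if (!(off > 0 && on < 1 && off < on)) {
    stop("need 0 < off < on < 1", call. = FALSE)
  }
  tt <- dry_fraction$time_s
  f <- dry_fraction$dry_fraction
  ev <- list()
  dry <- FALSE
  t_low <- tt[1]
  t_dry_start <- NA_real_
  for (i in seq_along(f)) {
    if (!dry) {
      if (f[i] <= off) t_low <- tt[i]
      if (f[i] >= on) {
        dry <- TRUE
        t_dry_start <- tt[i]
        ev[[length(ev) + 1L]] <- data.frame(
          cell_id = cell_id, type = "STOPPING",
          t_start = t_low, t_end = tt[i],
          duration_s = tt[i] - t_low)
      }
    } else if (f[i] <= off) {
      dry <- FALSE
      t_low <- tt[i]
      ev[[length(ev) + 1L]] <- data.frame(
        cell_id = cell_id, type = "WETTING",
        t_start = t_dry_start, t_end = tt[i],
        duration_s = tt[i] - t_dry_start)
    }
  }
  if (!length(ev)) {
    return(data.frame(cell_id = integer(0), type = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0)))
  }
  do.call(rbind, ev)
}

#' Stall durations from wetness events
#'
#' @param events Event data.frame from [detect_wetness_events()].
#' @return Numeric vector of dry-interval durations (s), one per completed
#'   WETTING event.
#' @export
stall_durations <- function(events) {
  events$duration_s[events$type == "WETTING"]
}
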