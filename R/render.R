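#' Image-stack geometry and timing metadata
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Pixel size (um/px); default 0.2 um/px, the scale
#'   regime of a 63x objective on the camera geometry assumed here.
#' @param frame_interval_s Time between frame starts (s); default 0.02 s
#'   (50 frames/s).
#' @param exposure_s Exposure time (s); must not exceed the frame interval.
#' @return A `stack_meta` list.
#' @export
stack_meta <- function(width_px = 1000L, height_px = 1000L,
                       pixel_size_um = 0.2, frame_interval_s = 0.02,
                       exposure_s = 0.02) {
  if (exposure_s > frame_interval_s + 1e-12) {
    stop("exposure must not exceed the frame interval", call. = FALSE)
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 exposure_s = exposure_s),
            class = "stack_meta")
}

#' Construct an image stack
#'
#' An ordered set of equally shaped 2D intensity frames (values in [0, 1])
#' plus pixel-size, frame-interval and exposure metadata. Pixel coordinates
#' are 0-based with the origin at the top-left pixel centre, x rightward
#' (columns), y downward (rows); physical position (um) = pixel index times
#' `pixel_size_um`.
#'
#' @param frames List of numeric matrices (rows = y, cols = x).
#' @param meta A [stack_meta()].
#' @return An `image_stack`.
#' @export
image_stack <- function(frames, meta) {
  stopifnot(inherits(meta, "stack_meta"), length(frames) >= 1)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("all frames must have the same shape", call. = FALSE)
  }
  if (d[1] != meta$height_px || d[2] != meta$width_px) {
    stop("frame shape does not match metadata", call. = FALSE)
  }
  structure(list(frames = frames, meta = meta), class = "image_stack")
}

# Instantaneous binary rasterization of rod cells (filled rotated rectangles,
# intensity 1 on background 0). `wrap` gives the periodic arena size (um) so
# cells straddling the boundary draw their wrapped copies; NULL disables.
rasterize_cells <- function(x_um, y_um, theta, meta,
                            cell_length_um = 7, cell_width_um = 1,
                            wrap = NULL) {
  img <- matrix(0, meta$height_px, meta$width_px)
  ps <- meta$pixel_size_um
  half_diag <- sqrt(cell_length_um^2 + cell_width_um^2) / 2
  offs <- if (is.null(wrap)) list(c(0, 0)) else {
    expand <- expand.grid(dx = c(-wrap[1], 0, wrap[1]),
                          dy = c(-wrap[2], 0, wrap[2]))
    lapply(seq_len(nrow(expand)), function(i) as.numeric(expand[i, ]))
  }
  for (i in seq_along(x_um)) {
    ct <- cos(theta[i]); st <- sin(theta[i])
    for (o in offs) {
      cx <- x_um[i] + o[1]; cy <- y_um[i] + o[2]
      ix0 <- max(0L, floor((cx - half_diag) / ps))
      ix1 <- min(meta$width_px - 1L, ceiling((cx + half_diag) / ps))
      iy0 <- max(0L, floor((cy - half_diag) / ps))
      iy1 <- min(meta$height_px - 1L, ceiling((cy + half_diag) / ps))
      if (ix0 > ix1 || iy0 > iy1) next
      px <- (ix0:ix1) * ps - cx
      py <- (iy0:iy1) * ps - cy
      u <- outer(py * st, px * ct, "+")          # along-rod coordinate
      v <- outer(py * ct, -px * st, "+")         # across-rod coordinate
      inside <- abs(u) <= cell_length_um / 2 & abs(v) <= cell_width_um / 2
      sub <- img[iy0:iy1 + 1L, ix0:ix1 + 1L, drop = FALSE]
      sub[inside] <- 1
      img[iy0:iy1 + 1L, ix0:ix1 + 1L] <- sub
    }
  }
  img
}

# Positions/orientations of every track at time t, linearly interpolated
# between samples (minimum-image displacement so wrapped jumps interpolate
# correctly). Orientation is held from the earlier sample.
interp_tracks <- function(tracks, t, wrap = NULL) {
  out <- lapply(tracks, function(tr) {
    tt <- tr$time_s
    if (t < tt[1] - 1e-9 || t > tt[length(tt)] + 1e-9) {
      stop("time ", t, " outside track support", call. = FALSE)
    }
    i <- min(max(findInterval(t, tt), 1L), length(tt) - 1L)
    frac <- (t - tt[i]) / (tt[i + 1] - tt[i])
    frac <- min(max(frac, 0), 1)
    dx <- tr$x_um[i + 1] - tr$x_um[i]
    dy <- tr$y_um[i + 1] - tr$y_um[i]
    if (!is.null(wrap)) {
      dx <- dx - wrap[1] * round(dx / wrap[1])
      dy <- dy - wrap[2] * round(dy / wrap[2])
    }
    x <- tr$x_um[i] + frac * dx
    y <- tr$y_um[i] + frac * dy
    if (!is.null(wrap)) { x <- x %% wrap[1]; y <- y %% wrap[2] }
    c(x = x, y = y, theta = tr$theta_rad[i])
  })
  do.call(rbind, out)
}

#' Render one frame with exposure-time motion blur
#'
#' The frame is the arithmetic mean of `n_subsamples` instantaneous
#' rasterizations at times uniformly spanning `[t, t + exposure]` (endpoints
#' included). Each instantaneous image draws every cell as a filled rotated
#' rectangle at intensity 1 on background 0. Moving cells smear into faint
#' streaks while immobile cells stay sharp at intensity near 1 — the basis of
#' long-exposure immobile-cell detection.
#'
#' @param tracks List of `cell_track` data.frames (e.g. [simulate_swarm()]).
#' @param t Frame start time (s); `[t, t + exposure]` must lie inside the
#'   track support.
#' @param meta A [stack_meta()].
#' @param n_subsamples Number of instantaneous rasterizations averaged
#'   (default 11; odd, endpoints included, gap-free for 20 um/s at 0.2 s
#'   exposure and 0.2 um/px).
#' @param smooth_sigma Optional Gaussian blur sigma (px) applied to the
#'   averaged image; 0 disables.
#' @param noise_sd Additive Gaussian noise sd; 0 disables. Result is clipped
#'   to [0, 1].
#' @param wrap Optional periodic arena size `c(Lx, Ly)` in um.
#' @param seed Optional seed for the noise draw.
#' @return Numeric matrix (height x width) with values in [0, 1].
#' @export
render_frame <- function(tracks, t, meta, n_subsamples = 11L,
                         smooth_sigma = 0, noise_sd = 0, wrap = NULL,
                         seed = NULL) {
  stopifnot(n_subsamples >= 1)
  cl <- attr(tracks[[1]], "cell_length_um") %||% 7
  cw <- attr(tracks[[1]], "cell_width_um") %||% 1
  ts <- if (n_subsamples == 1L) t else
    seq(t, t + meta$exposure_s, length.out = n_subsamples)
  acc <- matrix(0, meta$height_px, meta$width_px)
  for (tk in ts) {
    p <- interp_tracks(tracks, tk, wrap = wrap)
    acc <- acc + rasterize_cells(p[, "x"], p[, "y"], p[, "theta"], meta,
                                 cell_length_um = cl, cell_width_um = cw,
                                 wrap = wrap)
  }
  img <- acc / length(ts)
  if (smooth_sigma > 0) {
    img <- EBImage::gblur(img, sigma = smooth_sigma)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  pmin(pmax(img, 0), 1)
}

#' Render an image stack over a track's frames
#'
#' Renders one frame per track sample time whose exposure window fits inside
#' the track support.
#'
#' @inheritParams render_frame
#' @param times Optional frame start times; defaults to all track sample
#'   times with a complete exposure window.
#' @return An [image_stack()].
#' @export
render_stack <- function(tracks, meta, times = NULL, n_subsamples = 11L,
                         smooth_sigma = 0, noise_sd = 0, wrap = NULL,
                         seed = NULL) {
  tt <- tracks[[1]]$time_s
  if (is.null(times)) times <- tt[tt + meta$exposure_s <= tt[length(tt)] + 1e-9]
  frames <- lapply(seq_along(times), function(k) {
    render_frame(tracks, times[k], meta, n_subsamples = n_subsamples,
                 smooth_sigma = smooth_sigma, noise_sd = noise_sd,
                 wrap = wrap,
                 seed = if (is.null(seed)) NULL else seed + k)
  })
  image_stack(frames, meta)
}

#' Synthesize longer exposures by frame averaging
#'
#' Each output frame is the arithmetic mean of `ratio` consecutive input
#' frames; the frame interval and exposure are multiplied by `ratio`. A
#' trailing remainder of fewer than `ratio` frames is dropped. Averaging a
#' 50 frames/s, 0.02 s-exposure stack with ratio 10 emulates acquisition at
#' 5 frames/s with 0.2 s exposure.
#'
#' @param stack An [image_stack()].
#' @param ratio Positive integer averaging factor.
#' @return An [image_stack()] with `floor(n / ratio)` frames.
#' @export
synthesize_long_exposure <- function(stack, ratio) {
  stopifnot(inherits(stack, "image_stack"))
  ratio <- as.integer(ratio)
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  n <- length(stack$frames)
  if (n == 0) stop("empty stack", call. = FALSE)
  n_out <- n %/% ratio
  if (n_out == 0) stop("fewer frames than `ratio`", call. = FALSE)
  frames <- lapply(seq_len(n_out), function(k) {
    idx <- ((k - 1L) * ratio + 1L):(k * ratio)
    Reduce(`+`, stack$frames[idx]) / ratio
  })
  meta <- stack$meta
  meta$frame_interval_s <- meta$frame_interval_s * ratio
  meta$exposure_s <- min(meta$exposure_s * ratio, meta$frame_interval_s)
  image_stack(frames, meta)
}

#' Render a DIC-like hue map
#'
#' Encodes local wetness as hue on the abstract axis on which the
#' classification thresholds live: the agar background and fully wet cells
#' draw hues uniform in [43, 45]; cells drier than `wet_threshold` draw hues
#' that decrease with dryness, spanning down from 27 toward and below 20 for
#' a fully dry cell, with variation across the rod so a dry cell shows a
#' mixture of the black/blue/green classes (its exposed topography has two
#' slopes). A small fraction of pixels carries noise hues in (28, 42).
#'
#' @param tracks List of `cell_track` data.frames carrying a `wetness`
#'   column (generator ground truth in [0, 1]).
#' @param t Time (s) at which to render.
#' @param meta A [stack_meta()].
#' @param wet_threshold Wetness above which a cell is indistinguishable from
#'   background (default 0.5).
#' @param noise_frac Fraction of pixels replaced by uniform (28, 42) noise
#'   hues (default 0.002).
#' @param wrap Optional periodic arena size `c(Lx, Ly)` in um.
#' @param seed Optional seed.
#' @return A `hue_map`: numeric matrix of hues with `meta` attached as an
#'   attribute.
#' @export
render_dic_hue <- function(tracks, t, meta, wet_threshold = 0.5,
                           noise_frac = 0.002, wrap = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- attr(tracks[[1]], "cell_length_um") %||% 7
  cw <- attr(tracks[[1]], "cell_width_um") %||% 1
  hue <- matrix(stats::runif(meta$height_px * meta$width_px, 43, 45),
                meta$height_px, meta$width_px)
  p <- interp_tracks(tracks, t, wrap = wrap)
  wet <- vapply(tracks, function(tr) {
    i <- min(max(findInterval(t, tr$time_s), 1L), nrow(tr))
    tr$wetness[i]
  }, numeric(1))
  if (any(wet < 0 | wet > 1)) stop("wetness must lie in [0, 1]", call. = FALSE)
  ps <- meta$pixel_size_um
  half_diag <- sqrt(cl^2 + cw^2) / 2
  for (i in seq_along(tracks)) {
    if (wet[i] >= wet_threshold) next  # wet cell: background hue
    dry <- 1 - wet[i] / wet_threshold  # 0 at threshold .. 1 fully dry
    cx <- p[i, "x"]; cy <- p[i, "y"]
    ct <- cos(p[i, "theta"]); st <- sin(p[i, "theta"])
    ix0 <- max(0L, floor((cx - half_diag) / ps))
    ix1 <- min(meta$width_px - 1L, ceiling((cx + half_diag) / ps))
    iy0 <- max(0L, floor((cy - half_diag) / ps))
    iy1 <- min(meta$height_px - 1L, ceiling((cy + half_diag) / ps))
    if (ix0 > ix1 || iy0 > iy1) next
    px <- (ix0:ix1) * ps - cx
    py <- (iy0:iy1) * ps - cy
    u <- outer(py * st, px * ct, "+")
    v <- outer(py * ct, -px * st, "+")
    inside <- abs(u) <= cl / 2 & abs(v) <= cw / 2
    # slope factor: 0 on the ridge line, growing toward the long edges and
    # the rounded poles, so a dry rod spans all three dry bands
    s <- pmin(abs(v) / (cw / 2) + abs(u) / cl, 1)
    cell_hue <- 27 - 19 * dry * s
    sub <- hue[iy0:iy1 + 1L, ix0:ix1 + 1L, drop = FALSE]
    sub[inside] <- pmax(cell_hue[inside], 0)
    hue[iy0:iy1 + 1L, ix0:ix1 + 1L] <- sub
  }
  if (noise_frac > 0) {
    npx <- length(hue)
    k <- stats::rbinom(1, npx, noise_frac)
    if (k > 0) {
      idx <- sample.int(npx, k)
      hue[idx] <- stats::runif(k, 28, 42)
    }
  }
  structure(hue, meta = meta, class = c("hue_map", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
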