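#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking: a detection is appended to an
#' active track when the two are each other's nearest partner and closer than
#' `max_displacement_um`; unmatched detections start new tracks, unmatched
#' tracks terminate.
#'
#' @param per_frame_centroids List (one element per frame) of numeric
#'   matrices with columns `x`, `y` in um.
#' @param max_displacement_um Maximum per-frame displacement for a link.
#' @param frame_interval_s Frame interval (s).
#' @return List of `cell_track` data.frames with columns `cell_id`, `frame`,
#'   `time_s`, `x_um`, `y_um`.
#' @export
link_tracks <- function(per_frame_centroids, max_displacement_um,
                        frame_interval_s = 0.02) {
  if (max_displacement_um <= 0) {
    stop("max_displacement_um must be positive", call. = FALSE)
  }
  tracks <- list()       # each: list(rows = data.frame, active = TRUE)
  active <- integer(0)   # indices into `tracks`
  for (f in seq_along(per_frame_centroids)) {
    det <- per_frame_centroids[[f]]
    det <- matrix(as.numeric(det), ncol = 2,
                  dimnames = list(NULL, c("x", "y")))
    nd <- nrow(det)
    matched_det <- rep(FALSE, nd)
    next_active <- integer(0)
    if (length(active) && nd > 0) {
      last <- t(vapply(active, function(i) {
        r <- tracks[[i]]; c(r$x_um[nrow(r)], r$y_um[nrow(r)])
      }, numeric(2)))
      d2 <- outer(last[, 1], det[, 1], "-")^2 +
            outer(last[, 2], det[, 2], "-")^2
      nn_det <- apply(d2, 1, which.min)  # track -> nearest detection
      nn_trk <- apply(d2, 2, which.min)  # detection -> nearest track
      for (a in seq_along(active)) {
        j <- nn_det[a]
        if (nn_trk[j] == a &&
            d2[a, j] <= max_displacement_um^2 && !matched_det[j]) {
          i <- active[a]
          tracks[[i]] <- rbind(tracks[[i]], data.frame(
            cell_id = tracks[[i]]$cell_id[1], frame = f - 1L,
            time_s = (f - 1L) * frame_interval_s,
            x_um = det[j, 1], y_um = det[j, 2]))
          matched_det[j] <- TRUE
          next_active <- c(next_active, i)
        }
      }
    }
    if (nd > 0) for (j in which(!matched_det)) {
      id <- length(tracks) + 1L
      tracks[[id]] <- data.frame(
        cell_id = id, frame = f - 1L, time_s = (f - 1L) * frame_interval_s,
        x_um = det[j, 1], y_um = det[j, 2])
      next_active <- c(next_active, id)
    }
    active <- next_active
  }
  lapply(tracks, function(tr) {
    rownames(tr) <- NULL
    structure(tr, class = c("cell_track", "data.frame"))
  })
}

#' Instantaneous speeds along a track
#'
#' Central-difference displacement magnitude over the sampling interval
#' (forward/backward difference at the track ends). Central differences are
#' less biased by localisation noise than one-sided ones.
#'
#' @param track A `cell_track` data.frame with uniform `time_s` spacing.
#' @param wrap Optional periodic arena size `c(Lx, Ly)` um; displacements use
#'   the minimum-image convention.
#' @return Data.frame of speed samples: `cell_id`, `time_s`, `speed_ums`.
#' @export
instantaneous_speeds <- function(track, wrap = NULL) {
  n <- nrow(track)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  dt <- diff(track$time_s)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1)) {
    stop("non-uniform sampling interval", call. = FALSE)
  }
  dt <- dt[1]
  mi <- function(d, L) if (is.null(wrap)) d else d - L * round(d / L)
  dx <- mi(diff(track$x_um), if (is.null(wrap)) NULL else wrap[1])
  dy <- mi(diff(track$y_um), if (is.null(wrap)) NULL else wrap[2])
  # cumulative unwrapped positions make central differences wrap-safe
  xu <- cumsum(c(track$x_um[1], dx))
  yu <- cumsum(c(track$y_um[1], dy))
  v <- numeric(n)
  v[1] <- sqrt((xu[2] - xu[1])^2 + (yu[2] - yu[1])^2) / dt
  v[n] <- sqrt((xu[n] - xu[n - 1])^2 + (yu[n] - yu[n - 1])^2) / dt
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- sqrt((xu[i + 1] - xu[i - 1])^2 + (yu[i + 1] - yu[i - 1])^2) /
      (2 * dt)
  }
  data.frame(cell_id = track$cell_id[1], time_s = track$time_s,
             speed_ums = v)
}

#' Speed histogram and fast-subset mean
#'
#' Summarises a set of speed samples: a histogram at fixed bin width and the
#' mean over the fast subset — samples faster than `fast_threshold_ums`
#' (default 7 um/s, the split below which drying affects the distribution).
#'
#' @param speeds_ums Numeric vector of speeds (um/s).
#' @param fast_threshold_ums Fast/slow split (um/s).
#' @param bin_width_ums Histogram bin width (um/s).
#' @return List with `histogram` (a [hist()] object), `fast_mean_ums` (NA
#'   with `fast_defined = FALSE` when no sample exceeds the threshold),
#'   `fast_defined`, `n`, `n_fast`.
#' @export
speed_summary <- function(speeds_ums, fast_threshold_ums = 7,
                          bin_width_ums = 1) {
  if (!length(speeds_ums)) stop("need >= 1 speed sample", call. = FALSE)
  breaks <- seq(0, max(speeds_ums, bin_width_ums) + bin_width_ums,
                by = bin_width_ums)
  h <- graphics::hist(speeds_ums, breaks = breaks, plot = FALSE)
  fast <- speeds_ums[speeds_ums > fast_threshold_ums]
  list(histogram = h,
       fast_mean_ums = if (length(fast)) mean(fast) else NA_real_,
       fast_defined = length(fast) > 0,
       n = length(speeds_ums), n_fast = length(fast))
}

#' Gaussian-tail check of a speed histogram
#'
#' Fits the log of the speed density above the mode, with the geometric speed
#' prefactor removed, to a quadratic in speed. For a Rayleigh distribution
#' with scale sigma the fit is exact with curvature -1/(2 sigma^2) and zero
#' linear term; heavier (e.g. exponential) tails give visibly lower R^2.
#'
#' @param histogram A [hist()] object (e.g. from [speed_summary()]).
#' @return List with `curvature` (coefficient of speed^2), `sigma_ums`
#'   (implied Rayleigh scale, NA if curvature >= 0), `r_squared`, `n_bins`.
#' @export
tail_gaussian_check <- function(histogram) {
  mids <- histogram$mids
  dens <- histogram$density
  mode_i <- which.max(dens)
  sel <- seq_along(mids) > mode_i & dens > 0 & mids > 0
  if (sum(sel) < 5) stop("fewer than 5 usable tail bins", call. = FALSE)
  v <- mids[sel]
  y <- log(dens[sel]) - log(v)
  # weight by bin counts when available: the variance of a log-count is
  # roughly 1/count, so sparse far-tail bins do not dominate the fit
  w <- if (!is.null(histogram$counts)) histogram$counts[sel] else
    rep(1, sum(sel))
  fit <- stats::lm(y ~ v + I(v^2), weights = w)
  curv <- unname(stats::coef(fit)[3])
  list(curvature = curv,
       sigma_ums = if (curv < 0) sqrt(-1 / (2 * curv)) else NA_real_,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_bins = sum(sel))
}

#' Mean speed conditioned on neighbour count
#'
#' For each cutoff radius, counts each cell's neighbours (centre-to-centre,
#' minimum-image if `wrap` is given) at every sample time, and reports the
#' mean central-difference speed per neighbour count. Tracks shorter than
#' `min_track_len` frames are excluded. Empty neighbour-count bins are
#' absent from the result, not reported as zero.
#'
#' @param tracks List of `cell_track` data.frames sharing sample times.
#' @param cutoffs_um Cutoff radii scanned (um).
#' @param wrap Optional periodic arena size `c(Lx, Ly)` um.
#' @param min_track_len Minimum track length in frames (default 5).
#' @return Data.frame with columns `cutoff_um`, `k`, `mean_speed_ums`, `n`.
#' @export
speed_vs_neighbors <- function(tracks, cutoffs_um = c(3, 5, 7, 10),
                               wrap = NULL, min_track_len = 5L) {
  tracks <- Filter(function(tr) nrow(tr) >= min_track_len, tracks)
  if (!length(tracks)) stop("no tracks of sufficient length", call. = FALSE)
  nt <- length(tracks)
  nf <- nrow(tracks[[1]])
  X <- vapply(tracks, `[[`, numeric(nf), "x_um")
  Y <- vapply(tracks, `[[`, numeric(nf), "y_um")
  V <- vapply(tracks, function(tr) {
    instantaneous_speeds(tr, wrap = wrap)$speed_ums
  }, numeric(nf))
  Lx <- if (is.null(wrap)) Inf else wrap[1]
  Ly <- if (is.null(wrap)) Inf else wrap[2]
  out <- list()
  for (r in cutoffs_um) {
    K <- t(vapply(seq_len(nf), function(f) {
      if (nt == 1L) return(0L)
      dx <- abs(outer(X[f, ], X[f, ], "-"))
      dy <- abs(outer(Y[f, ], Y[f, ], "-"))
      if (is.finite(Lx)) { dx <- pmin(dx, Lx - dx); dy <- pmin(dy, Ly - dy) }
      as.integer(colSums(dx * dx + dy * dy <= r * r)) - 1L
    }, integer(nt)))
    agg <- stats::aggregate(
      data.frame(speed = as.vector(V)),
      by = list(k = as.vector(K)), FUN = mean)
    cnt <- stats::aggregate(
      data.frame(n = rep(1L, length(K))),
      by = list(k = as.vector(K)), FUN = sum)
    out[[length(out) + 1L]] <- data.frame(
      cutoff_um = r, k = agg$k, mean_speed_ums = agg$speed, n = cnt$n)
  }
  do.call(rbind, out)
}
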