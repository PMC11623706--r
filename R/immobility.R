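#' Detect temporarily immobile cells in a long-exposure frame
#'
#' At long exposure, moving cells smear into faint streaks while immobile
#' cells stay sharp near intensity 1, so a plain intensity threshold followed
#' by connected-component filtering isolates the immobile cells.
#'
#' @param long_frame Numeric matrix with intensities in [0, 1].
#' @param intensity_threshold Threshold in (0, 1); pixels at or above it enter
#'   the mask (default 0.9).
#' @param min_area_px Components smaller than this are removed (default 140 px,
#'   about 80% of a 1x7 um cell body at 0.2 um/px).
#' @param max_area_px Components larger than this are removed (default `Inf`);
#'   set near the cell-body area to keep only single-cell components.
#' @return An `immobile_mask`: list with `mask` (logical matrix), `labels`
#'   (integer component labels), `areas` (px per component) and `centroids`
#'   (component centroids, columns `x`, `y`, in 0-based pixel coordinates).
#' @export
detect_immobile <- function(long_frame, intensity_threshold = 0.9,
                            min_area_px = 140, max_area_px = Inf) {
  if (intensity_threshold <= 0 || intensity_threshold >= 1) {
    stop("intensity_threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  mask <- long_frame >= intensity_threshold
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  n0 <- max(labels)
  if (n0 > 0) {
    areas <- tabulate(labels[labels > 0], nbins = n0)
    drop <- which(areas < min_area_px | areas > max_area_px)
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      # relabel compactly
      keep <- sort(unique(labels[labels > 0]))
      labels[] <- match(labels, keep, nomatch = 0L)
    }
  }
  mask <- labels > 0
  n <- max(labels)
  areas <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer(0)
  centroids <- if (n > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    cbind(x = tapply(idx[, 2] - 1, lab, mean),
          y = tapply(idx[, 1] - 1, lab, mean))
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  structure(list(mask = mask, labels = labels, areas = areas,
                 centroids = centroids),
            class = "immobile_mask")
}

#' Fraction of cells that are immobile
#'
#' @param mask An `immobile_mask` from [detect_immobile()].
#' @param n_cells_total Total number of cells in the field (>= 1).
#' @return Component count over total, clipped to [0, 1].
#' @export
immobile_fraction <- function(mask, n_cells_total) {
  stopifnot(inherits(mask, "immobile_mask"))
  if (n_cells_total < 1) stop("n_cells_total must be >= 1", call. = FALSE)
  min(length(mask$areas) / n_cells_total, 1)
}

#' Bin occupancy of immobile cells on a grid
#'
#' Divides the field into a grid of equally sized bins (10 x 10 by default)
#' and marks a bin occupied at a frame when the masked immobile-cell area
#' inside it reaches a minimum coverage — by default one third of the nominal
#' cell-body area, so a sliver of a cell does not count.
#'
#' @param masks List of `immobile_mask` objects (or logical matrices), one
#'   per long-exposure frame, all the same shape.
#' @param frame_interval_s Time between the long-exposure frames (s).
#' @param grid Integer vector `c(rows, cols)`; image dimensions must be
#'   divisible by it.
#' @param cell_area_px Nominal cell-body area in pixels (e.g. 7 um^2 at
#'   0.2 um/px = 175 px).
#' @param min_coverage_frac Minimum masked area inside a bin, as a fraction
#'   of `cell_area_px` (default 1/3).
#' @return An `occupancy_series`: binary matrix (frames x bins) with
#'   attributes `grid` and `frame_interval_s`.
#' @export
bin_occupancy <- function(masks, frame_interval_s, grid = c(10L, 10L),
                          cell_area_px = 175, min_coverage_frac = 1 / 3) {
  get_mask <- function(m) if (inherits(m, "immobile_mask")) m$mask else m
  m1 <- get_mask(masks[[1]])
  nr <- nrow(m1); nc <- ncol(m1)
  if (nr %% grid[1] != 0 || nc %% grid[2] != 0) {
    stop("image dimensions (", nr, "x", nc, ") must be divisible by the grid",
         call. = FALSE)
  }
  br <- nr / grid[1]; bc <- nc / grid[2]
  need <- min_coverage_frac * cell_area_px
  row_bin <- rep(seq_len(grid[1]), each = br)
  col_bin <- rep(seq_len(grid[2]), each = bc)
  bin_of <- outer(row_bin, (col_bin - 1) * grid[1], "+")  # column-major bins
  occ <- t(vapply(masks, function(m) {
    msk <- get_mask(m)
    counts <- tabulate(bin_of[msk], nbins = grid[1] * grid[2])
    as.integer(counts >= need)
  }, integer(grid[1] * grid[2])))
  structure(occ, grid = grid, frame_interval_s = frame_interval_s,
            class = c("occupancy_series", "matrix", "array"))
}

#' Occupation-fraction statistics over window durations
#'
#' For each window duration T, the series is cut into disjoint windows of T
#' and each bin's occupation fraction (occupied frames / frames per window)
#' is computed per window. The reported mean is over all bin-window samples;
#' the standard deviation is over the same samples, i.e. the spread of
#' occupation fractions measured over a single window of length T — the
#' quantity that decays as T^(-1/2) for memoryless stalling. (Averaging each
#' bin over all windows first would use the whole series for every T and
#' erase that scaling.) Disjoint windows keep the samples independent.
#'
#' @param series An `occupancy_series` from [bin_occupancy()].
#' @param durations_s Window durations (s), default 5 to 360 in steps of 5.
#'   Durations longer than the series are dropped with a warning.
#' @return An `occupancy_stats` data.frame with columns `duration_s`,
#'   `mean_fraction`, `sd_fraction`, plus the per-duration window-averaged
#'   per-bin fractions in attribute `per_bin` and the bin-window samples in
#'   attribute `samples`.
#' @export
occupancy_stats <- function(series, durations_s = seq(5, 360, by = 5)) {
  stopifnot(inherits(series, "occupancy_series"))
  if (nrow(series) == 0) stop("empty occupancy series", call. = FALSE)
  dt <- attr(series, "frame_interval_s")
  total_s <- nrow(series) * dt
  keep <- durations_s <= total_s + 1e-9
  if (!any(keep)) stop("no duration fits inside the series", call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " duration(s) longer than the series were dropped")
    durations_s <- durations_s[keep]
  }
  samples <- lapply(durations_s, function(T) {
    w <- max(1L, round(T / dt))
    n_win <- nrow(series) %/% w
    vapply(seq_len(n_win), function(k) {
      rows <- ((k - 1L) * w + 1L):(k * w)
      colMeans(series[rows, , drop = FALSE])
    }, numeric(ncol(series)))  # bins x windows
  })
  out <- data.frame(
    duration_s = durations_s,
    mean_fraction = vapply(samples, mean, numeric(1)),
    sd_fraction = vapply(samples, stats::sd, numeric(1))
  )
  attr(out, "per_bin") <- lapply(samples, function(s) {
    rowMeans(matrix(s, nrow = ncol(series)))
  })
  attr(out, "samples") <- samples
  class(out) <- c("occupancy_stats", "data.frame")
  out
}

#' Scaling exponent of the across-bin standard deviation
#'
#' Ordinary least-squares slope of log(sd) against log(duration). For
#' memoryless stalling the central limit theorem gives an exponent of -1/2.
#'
#' @param stats An `occupancy_stats` data.frame (or any data.frame with
#'   `duration_s` and `sd_fraction`).
#' @return The fitted exponent (slope); the full `lm` fit is attached as
#'   attribute `fit`.
#' @export
fit_std_exponent <- function(stats) {
  ok <- stats$sd_fraction > 0
  if (any(!ok)) {
    warning(sum(!ok), " duration(s) with zero sd excluded from the fit")
  }
  if (sum(ok) < 5) stop("need >= 5 durations with positive sd", call. = FALSE)
  fit <- stats::lm(log(sd_fraction) ~ log(duration_s), data = stats[ok, ])
  structure(unname(stats::coef(fit)[2]), fit = fit)
}

#' Gaussianity of per-bin occupation counts
#'
#' Shapiro-Wilk test on the per-bin occupation counts (or fractions) at a
#' fixed window duration.
#'
#' @param counts Numeric vector of per-bin counts, length >= 20.
#' @return List with `statistic`, `p_value`, `degenerate` (TRUE when the
#'   counts are constant and the test is undefined).
#' @export
normality_check <- function(counts) {
  if (length(counts) < 20) stop("need >= 20 bins", call. = FALSE)
  if (stats::sd(counts) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  sw <- stats::shapiro.test(counts)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       degenerate = FALSE)
}

#' Temporal autocorrelation of bin occupancy
#'
#' Per-bin mean-subtracted autocorrelation, averaged over bins with positive
#' variance and normalised to 1 at lag zero. The decay time is the first lag
#' at which the correlation falls to 1/e; the first zero crossing is reported
#' alongside (the "decays to zero" reading, which is noisier to estimate).
#'
#' @param series An `occupancy_series`.
#' @param max_lag_s Maximum lag (s); default a quarter of the series.
#' @return List with `lag_s`, `correlation`, `decay_time_s` (1/e crossing)
#'   and `zero_crossing_s` (NA if not reached).
#' @export
occupancy_autocorrelation <- function(series, max_lag_s = NULL) {
  stopifnot(inherits(series, "occupancy_series"))
  dt <- attr(series, "frame_interval_s")
  nfr <- nrow(series)
  vars <- apply(series, 2, stats::var)
  use <- which(vars > 0)
  if (!length(use)) stop("zero-variance occupancy series", call. = FALSE)
  if (is.null(max_lag_s)) max_lag_s <- nfr * dt / 4
  max_lag <- min(nfr - 2L, max(1L, round(max_lag_s / dt)))
  # average autocovariance over bins, then normalise by lag-0 value
  acv <- rowMeans(vapply(use, function(j) {
    stats::acf(series[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L)))
  corr <- acv / acv[1]
  lag_s <- (seq_along(corr) - 1L) * dt
  below_e <- which(corr <= exp(-1))
  decay <- if (length(below_e)) lag_s[below_e[1]] else NA_real_
  zero <- which(corr <= 0)
  zero_s <- if (length(zero)) lag_s[zero[1]] else NA_real_
  list(lag_s = lag_s, correlation = corr,
       decay_time_s = decay, zero_crossing_s = zero_s)
}

#' Ground-truth immobility labels for a long-exposure window
#'
#' A cell counts as temporarily immobile over `[t, t + exposure]` when it is
#' in the open (stall) state for at least `min_open_frac` of the window —
#' the labelling rule used to score detection against the generator.
#'
#' @param tracks List of `cell_track` data.frames.
#' @param t Window start (s).
#' @param exposure_s Window length (s).
#' @param min_open_frac Minimum open-state fraction (default 0.9).
#' @return Logical vector, one entry per track.
#' @export
immobile_ground_truth <- function(tracks, t, exposure_s,
                                  min_open_frac = 0.9) {
  vapply(tracks, function(tr) {
    sel <- tr$time_s >= t - 1e-9 & tr$time_s <= t + exposure_s + 1e-9
    mean(tr$state[sel] == "OPEN") >= min_open_frac
  }, logical(1))
}
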