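#' Swarm simulation configuration
#'
#' Parameters of the synthetic swarm generator. Defaults describe the study
#' conditions: rod cells 1x7 um at surface fraction 0.3, moving-cell mean
#' speed 19.5 um/s, imaging at 50 frames/s. If `n_cells` is `NULL` it is
#' derived from the target surface fraction `rho` as
#' `rho * arena_area / cell_area`.
#'
#' @param arena_width_um,arena_height_um Arena size (um); periodic boundaries.
#' @param rho Target surface fraction covered by cell bodies.
#' @param n_cells Number of cells; derived from `rho` when `NULL`.
#' @param cell_length_um,cell_width_um Rod dimensions (um).
#' @param run_speed_mean_ums Mean speed of running (closed-state) cells, um/s.
#'   Per-dwell speeds are Rayleigh with this mean unless `speed_noise = FALSE`.
#' @param tumble_speed_frac Tumble speed as a fraction of the run-dwell speed.
#' @param tumble_spread_rad Half-width of the uniform per-frame reorientation
#'   while tumbling (rad).
#' @param neighbor_cutoff_um Neighbour-count cutoff radius (um),
#'   centre-to-centre with minimum-image distances.
#' @param saturation_k Neighbour count at which the speed-coupling ramp
#'   saturates; `g(k) = min(k, saturation_k) / saturation_k`, so isolated
#'   cells (`k = 0`) do not move.
#' @param coupling Logical; disable to remove neighbour-speed coupling.
#' @param speed_noise Logical; `FALSE` makes every run dwell move at exactly
#'   `run_speed_mean_ums`.
#' @param dry_tau_s,wet_tau_s Time constants (s) of the first-order wetness
#'   relaxation: wetness decays toward 0 when a cell has no neighbours and
#'   recovers toward 1 otherwise.
#' @param duration_s Simulated duration (s).
#' @param frame_interval_s Sampling interval (s); 0.02 s = 50 frames/s.
#' @param seed Integer seed.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(arena_width_um = 60, arena_height_um = 60,
                         rho = 0.3, n_cells = NULL,
                         cell_length_um = 7, cell_width_um = 1,
                         run_speed_mean_ums = 19.5,
                         tumble_speed_frac = 0.4,
                         tumble_spread_rad = pi / 2,
                         neighbor_cutoff_um = 5,
                         saturation_k = 5,
                         coupling = TRUE,
                         speed_noise = TRUE,
                         dry_tau_s = 2, wet_tau_s = 1,
                         duration_s = 10, frame_interval_s = 0.02,
                         seed = 1L) {
  cell_area <- cell_length_um * cell_width_um
  arena_area <- arena_width_um * arena_height_um
  if (is.null(n_cells)) {
    n_cells <- max(1L, round(rho * arena_area / cell_area))
  } else {
    rho <- n_cells * cell_area / arena_area
  }
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (n_cells * cell_area > arena_area) {
    stop("arena too small for ", n_cells, " cells at surface fraction ",
         signif(rho, 3), call. = FALSE)
  }
  cfg <- list(
    arena_width_um = arena_width_um, arena_height_um = arena_height_um,
    rho = rho, n_cells = as.integer(n_cells),
    cell_length_um = cell_length_um, cell_width_um = cell_width_um,
    run_speed_mean_ums = run_speed_mean_ums,
    tumble_speed_frac = tumble_speed_frac,
    tumble_spread_rad = tumble_spread_rad,
    neighbor_cutoff_um = neighbor_cutoff_um,
    saturation_k = saturation_k,
    coupling = coupling, speed_noise = speed_noise,
    dry_tau_s = dry_tau_s, wet_tau_s = wet_tau_s,
    duration_s = duration_s, frame_interval_s = frame_interval_s,
    seed = as.integer(seed)
  )
  scales <- c("run_speed_mean_ums", "neighbor_cutoff_um", "duration_s",
              "frame_interval_s", "cell_length_um", "cell_width_um",
              "dry_tau_s", "wet_tau_s")
  if (any(unlist(cfg[scales]) <= 0)) {
    stop("all scales in the configuration must be positive", call. = FALSE)
  }
  structure(cfg, class = "swarm_config")
}

# Minimum-image neighbour counts within r for positions on a periodic arena.
neighbor_counts <- function(x, y, r, Lx, Ly) {
  n <- length(x)
  if (n == 1L) return(0L)
  dx <- abs(outer(x, x, "-")); dx <- pmin(dx, Lx - dx)
  dy <- abs(outer(y, y, "-")); dy <- pmin(dy, Ly - dy)
  within <- (dx * dx + dy * dy) <= r * r
  as.integer(colSums(within)) - 1L  # exclude self
}

#' Simulate a swarm of state-coupled motile cells
#'
#' Each cell carries an independent flagellar-state history from
#' [simulate_ctmc()]. Per frame, its speed is a state-dependent base speed
#' scaled by a saturating ramp in the number of neighbours within the cutoff
#' radius: isolated cells do not move, and the ramp saturates at
#' `saturation_k` neighbours. Closed-state (run) dwells keep a persistent
#' heading and a per-dwell Rayleigh speed; partial (tumble) dwells reorient
#' every frame and move at a fraction of the run speed; open (stall) dwells
#' have exactly zero displacement. A per-cell wetness scalar relaxes toward 0
#' while the cell is isolated and toward 1 otherwise, and is exported as
#' ground truth for the hue renderer.
#'
#' @param config A [swarm_config()].
#' @param model A [transition_model()]; defaults to [swarm_transition_model()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of per-cell `cell_track` data.frames (columns `cell_id`,
#'   `frame`, `time_s`, `x_um`, `y_um`, `theta_rad`, `state`, `wetness`,
#'   `speed_ums`, `n_neighbors`), with the config, model and per-cell
#'   [state_track()]s attached as attributes `config`, `model`,
#'   `state_tracks`.
#' @export
simulate_swarm <- function(config, model = swarm_transition_model(),
                           seed = NULL) {
  stopifnot(inherits(config, "swarm_config"), inherits(model, "transition_model"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)

  n <- config$n_cells
  dt <- config$frame_interval_s
  times <- seq(0, config$duration_s, by = dt)
  nf <- length(times)
  Lx <- config$arena_width_um
  Ly <- config$arena_height_um
  states <- flagellar_states()
  ray_scale <- config$run_speed_mean_ums / sqrt(pi / 2)

  # Per-cell state histories and per-dwell run speeds (constant within a run).
  init <- sample(states, n, replace = TRUE,
                 prob = time_stationary(model))
  stracks <- vector("list", n)
  dwell_speed <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- simulate_ctmc(model, t_total = config$duration_s + dt,
                        initial = init[i])
    base <- numeric(nrow(tr))
    run <- tr$state == "CLOSED"
    base[run] <- if (config$speed_noise) {
      ray_scale * sqrt(-2 * log(stats::runif(sum(run))))  # Rayleigh draw
    } else config$run_speed_mean_ums
    tum <- tr$state == "PARTIAL"
    base[tum] <- config$tumble_speed_frac *
      (if (config$speed_noise) {
        ray_scale * sqrt(-2 * log(stats::runif(sum(tum))))
      } else config$run_speed_mean_ums)
    stracks[[i]] <- tr
    dwell_speed[[i]] <- base
  }
  # per-frame state index and base speed
  st_frame <- matrix("", nf, n)
  v_base <- matrix(0, nf, n)
  for (i in seq_len(n)) {
    tr <- stracks[[i]]
    di <- pmax(findInterval(pmin(times, tr$t_end[nrow(tr)] - 1e-12),
                            tr$t_start), 1L)
    st_frame[, i] <- tr$state[di]
    v_base[, i] <- dwell_speed[[i]][di]
  }

  x <- matrix(0, nf, n); y <- matrix(0, nf, n); th <- matrix(0, nf, n)
  wet <- matrix(1, nf, n); v_out <- matrix(0, nf, n)
  k_out <- matrix(0L, nf, n)
  x[1, ] <- stats::runif(n, 0, Lx)
  y[1, ] <- stats::runif(n, 0, Ly)
  th[1, ] <- stats::runif(n, -pi, pi)

  for (f in seq_len(nf)) {
    k <- neighbor_counts(x[f, ], y[f, ], config$neighbor_cutoff_um, Lx, Ly)
    k_out[f, ] <- k
    g <- if (config$coupling) pmin(k, config$saturation_k) / config$saturation_k
         else rep(1, n)
    v <- v_base[f, ] * g
    v[st_frame[f, ] == "OPEN"] <- 0
    v_out[f, ] <- v
    if (f > 1) {
      iso <- k == 0L
      tau <- ifelse(iso, config$dry_tau_s, config$wet_tau_s)
      target <- ifelse(iso, 0, 1)
      wet[f, ] <- target + (wet[f - 1, ] - target) * exp(-dt / tau)
    }
    if (f < nf) {
      tumbling <- st_frame[f, ] == "PARTIAL"
      th_next <- th[f, ]
      if (any(tumbling)) {
        th_next[tumbling] <- th_next[tumbling] +
          stats::runif(sum(tumbling), -config$tumble_spread_rad,
                       config$tumble_spread_rad)
      }
      th[f + 1, ] <- th_next
      x[f + 1, ] <- (x[f, ] + v * dt * cos(th_next)) %% Lx
      y[f + 1, ] <- (y[f, ] + v * dt * sin(th_next)) %% Ly
    }
  }

  tracks <- lapply(seq_len(n), function(i) {
    structure(
      data.frame(cell_id = i, frame = seq_len(nf) - 1L, time_s = times,
                 x_um = x[, i], y_um = y[, i], theta_rad = th[, i],
                 state = st_frame[, i], wetness = wet[, i],
                 speed_ums = v_out[, i], n_neighbors = k_out[, i],
                 stringsAsFactors = FALSE),
      class = c("cell_track", "data.frame"),
      cell_length_um = config$cell_length_um,
      cell_width_um = config$cell_width_um
    )
  })
  attr(tracks, "config") <- config
  attr(tracks, "model") <- model
  attr(tracks, "state_tracks") <- stracks
  class(tracks) <- c("swarm_tracks", "list")
  tracks
}

#' Bind a list of cell tracks into one long data.frame
#'
#' @param tracks A list of `cell_track` data.frames.
#' @return One data.frame with all rows, ordered by cell then frame.
#' @export
tracks_df <- function(tracks) {
  do.call(rbind, lapply(tracks, as.data.frame))
}
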