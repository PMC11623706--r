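# Shared fixtures, built in code. Expensive simulations are memoised so
# several test files can reuse one realisation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Hand-built track: straight motion at constant speed. `theta` is the rod
# orientation; `heading` (default the same) is the motion direction.
make_track <- function(id, x0, y0, theta = 0, speed = 0, n_frames = 11,
                       dt = 0.02, state = "CLOSED", wetness = 1,
                       cell_length_um = 7, cell_width_um = 1,
                       heading = theta) {
  times <- (seq_len(n_frames) - 1) * dt
  structure(
    data.frame(cell_id = id, frame = seq_len(n_frames) - 1L, time_s = times,
               x_um = x0 + speed * times * cos(heading),
               y_um = y0 + speed * times * sin(heading),
               theta_rad = theta,
               state = rep(state, length.out = n_frames),
               wetness = rep(wetness, length.out = n_frames),
               speed_ums = speed, n_neighbors = 0L,
               stringsAsFactors = FALSE),
    class = c("cell_track", "data.frame"),
    cell_length_um = cell_length_um, cell_width_um = cell_width_um)
}

# A long jump-limited realisation of the fitted flagellar model, shared by
# the dwell/transition tests.
big_ctmc <- function() fixture("big_ctmc", {
  simulate_ctmc(swarm_transition_model(), n_jumps = 5e4, seed = 101)
})

big_extraction <- function() fixture("big_extraction", extract_dwells(big_ctmc()))

# Binary occupancy series driven by independent per-bin stall (open-state)
# renewal processes sampled from the flagellar chain - the ground-truth
# occupancy process the image pipeline estimates.
stall_occupancy <- function(n_bins = 100, total_s = 1440, dt = 0.2,
                            model = swarm_transition_model(), seed = 7) {
  set.seed(seed)
  times <- seq(0, total_s - dt, by = dt)
  occ <- vapply(seq_len(n_bins), function(b) {
    tr <- simulate_ctmc(model, t_total = total_s + dt)
    as.integer(state_at(tr, times) == "OPEN")
  }, integer(length(times)))
  structure(occ, grid = c(10L, n_bins %/% 10L), frame_interval_s = dt,
            class = c("occupancy_series", "matrix", "array"))
}

scene_meta <- function() stack_meta(200, 200, 0.2, 0.02, 0.02)

# Long-exposure frame of a constructed scene: stalled cells sit still,
# moving ones travel at run speed, on a 40x40 um field.
scene_long_frame <- function(n_stalled = 3, n_moving = 7, speed = 20) {
  set.seed(202)
  meta <- scene_meta()
  # non-overlapping layout on a coarse lattice
  slots <- expand.grid(x = seq(6, 34, by = 9), y = seq(5, 35, by = 10))
  slots <- slots[sample(nrow(slots), n_stalled + n_moving), ]
  tracks <- lapply(seq_len(n_stalled + n_moving), function(i) {
    stalled <- i <= n_stalled
    make_track(i, slots$x[i], slots$y[i], theta = pi / 2 * (i %% 4) / 2,
               speed = if (stalled) 0 else speed,
               n_frames = 11, dt = 0.02,
               state = if (stalled) "OPEN" else "CLOSED")
  })
  meta_long <- stack_meta(200, 200, 0.2, 0.2, 0.2)
  list(frame = render_frame(tracks, 0, meta_long, n_subsamples = 11),
       tracks = tracks, meta = meta_long,
       truth = immobile_ground_truth(tracks, 0, 0.2))
}

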