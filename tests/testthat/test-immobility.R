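test_that("noise-free detection recovers exactly the stalled cells", {
  sc <- scene_long_frame(3, 7)
  mk <- detect_immobile(sc$frame, 0.9, min_area_px = 140)
  expect_identical(length(mk$areas), 3L)      # precision & recall both 1
  expect_identical(sum(sc$truth), 3L)
  truth_xy <- t(vapply(sc$tracks[sc$truth], function(tr) {
    c(tr$x_um[1], tr$y_um[1]) / 0.2
  }, numeric(2)))
  for (k in seq_len(nrow(mk$centroids))) {
    d <- sqrt((truth_xy[, 1] - mk$centroids[k, "x"])^2 +
              (truth_xy[, 2] - mk$centroids[k, "y"])^2)
    expect_lt(min(d), 1)                      # centroid within 1 px
  }
})

test_that("a field of fast movers yields an empty mask", {
  sc <- scene_long_frame(0, 8)
  mk <- detect_immobile(sc$frame, 0.9, min_area_px = 140)
  expect_identical(length(mk$areas), 0L)
  expect_identical(immobile_fraction(mk, 8), 0)
})

test_that("a field of stalled cells is fully detected", {
  sc <- scene_long_frame(8, 0)
  mk <- detect_immobile(sc$frame, 0.9, min_area_px = 140)
  expect_identical(length(mk$areas), 8L)
  expect_error(detect_immobile(sc$frame, 1.2), "strictly inside")
})

test_that("immobile_fraction is component count over cell count", {
  sc <- scene_long_frame(3, 7)
  mk <- detect_immobile(sc$frame, 0.9, min_area_px = 140)
  expect_equal(immobile_fraction(mk, 10), 0.3)
  expect_error(immobile_fraction(mk, 0), ">= 1")
})

test_that("longer stalls raise the immobile fraction (dry vs wet contrast)", {
  wet_model <- swarm_transition_model()
  dry_model <- transition_model(c(4, 4.76, 1.05 / 2), wet_model$embedded)
  frac_for <- function(model, seed) {
    # coupling off so the only immobile cells are the stalled (open) ones
    cfg <- swarm_config(arena_width_um = 40, arena_height_um = 40, rho = 0.15,
                        duration_s = 4, seed = seed, coupling = FALSE)
    tr <- simulate_swarm(cfg, model = model)
    meta <- stack_meta(200, 200, 0.2, 0.02, 0.02)
    st <- render_stack(tr, meta, times = seq(0, 3.8, by = 0.02),
                       n_subsamples = 1, wrap = c(40, 40))
    long <- synthesize_long_exposure(st, 10)
    mean(vapply(long$frames, function(f) {
      immobile_fraction(detect_immobile(f, 0.9, min_area_px = 140),
                        cfg$n_cells)
    }, numeric(1)))
  }
  expect_gt(frac_for(dry_model, 31), frac_for(wet_model, 31))
})

test_that("bin occupancy counts a cell only above the coverage threshold", {
  # one 100-px rectangle split 60/40 between two 20x20 bins, by construction
  mask <- matrix(FALSE, 20, 40)
  mask[6:15, 15:24] <- TRUE   # columns 15..20 in bin 1 (60 px), 21..24 in bin 2
  occ13 <- bin_occupancy(list(mask), 0.2, grid = c(1L, 2L),
                         cell_area_px = 100, min_coverage_frac = 1 / 3)
  expect_identical(as.integer(occ13), c(1L, 1L))
  occ12 <- bin_occupancy(list(mask), 0.2, grid = c(1L, 2L),
                         cell_area_px = 100, min_coverage_frac = 1 / 2)
  expect_identical(as.integer(occ12), c(1L, 0L))
  # fully inside one bin: exactly one occupied
  m2 <- matrix(FALSE, 20, 40)
  m2[4:13, 3:12] <- TRUE
  occ <- bin_occupancy(list(m2), 0.2, grid = c(1L, 2L), cell_area_px = 100)
  expect_identical(sum(occ), 1L)
  expect_error(bin_occupancy(list(matrix(FALSE, 21, 40)), 0.2,
                             grid = c(10L, 10L)), "divisible")
})

test_that("occupation fractions behave for constant and Bernoulli occupancy", {
  dt <- 0.2
  always <- structure(matrix(1L, 500, 100), grid = c(10L, 10L),
                      frame_interval_s = dt,
                      class = c("occupancy_series", "matrix", "array"))
  st <- occupancy_stats(always, durations_s = c(5, 10, 20))
  expect_true(all(st$mean_fraction == 1))
  expect_true(all(st$sd_fraction == 0))

  set.seed(55)
  p <- 0.06
  n_frames <- 9000   # 1800 s at 0.2 s
  bern <- structure(matrix(rbinom(n_frames * 100, 1, p), n_frames, 100),
                    grid = c(10L, 10L), frame_interval_s = dt,
                    class = c("occupancy_series", "matrix", "array"))
  st <- occupancy_stats(bern, durations_s = seq(5, 360, by = 5))
  expect_equal(mean(st$mean_fraction), p, tolerance = 0.05)
  # closed-form binomial std of a single window's occupation fraction
  for (i in c(1, 10, 36)) {
    Tn <- st$duration_s[i] / dt
    oracle <- sqrt(p * (1 - p) / Tn)
    expect_equal(st$sd_fraction[i], oracle, tolerance = 0.15)
  }
  expo <- fit_std_exponent(st)
  expect_lt(abs(as.numeric(expo) - (-0.5)), 0.1)
  # mean is invariant to duration: regression slope CI contains 0
  fit <- lm(mean_fraction ~ duration_s, data = st)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("constructed std profiles recover their exponents", {
  mk <- function(sd) {
    structure(data.frame(duration_s = seq(5, 60, by = 5), sd_fraction = sd),
              class = c("occupancy_stats", "data.frame"))
  }
  d <- seq(5, 60, by = 5)
  expect_equal(as.numeric(fit_std_exponent(mk(rep(0.2, 12)))), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(fit_std_exponent(mk(1 / d))), -1, tolerance = 1e-12)
  expect_error(suppressWarnings(fit_std_exponent(mk(c(rep(0, 8), 1:4)))),
               ">= 5")
})

test_that("normality check separates Gaussian, bimodal and constant counts", {
  set.seed(77)
  p_gauss <- vapply(1:20, function(i) {
    normality_check(rnorm(100, 50, 5))$p_value
  }, numeric(1))
  expect_gte(mean(p_gauss > 0.05), 0.9)
  bimodal <- c(rnorm(50, 0, 0.5), rnorm(50, 20, 0.5))
  expect_lt(normality_check(bimodal)$p_value, 0.05)
  res <- normality_check(rep(3, 100))
  expect_true(res$degenerate)
  expect_error(normality_check(rnorm(10)), ">= 20")
})

test_that("autocorrelation is flat for white noise and 1 at lag zero", {
  set.seed(88)
  wn <- structure(matrix(rbinom(2000 * 100, 1, 0.1), 2000, 100),
                  grid = c(10L, 10L), frame_interval_s = 0.2,
                  class = c("occupancy_series", "matrix", "array"))
  ac <- occupancy_autocorrelation(wn, max_lag_s = 10)
  expect_identical(ac$correlation[1], 1)
  expect_true(all(abs(ac$correlation[-1]) < 3 / sqrt(2000 * 100 / 10)))
})

test_that("autocorrelation decay tracks the stall dwell scale", {
  # on/off renewal oracle: exponential dwell rates a (leave occupied) and b
  # give correlation exp(-(a+b) t); with mean stall tau and off-time 10 tau
  # the 1/e time is tau / 1.1
  set.seed(91)
  dt <- 0.05
  mk_series <- function(tau) {
    occ <- vapply(1:100, function(b) {
      t_tot <- 600 * tau
      n <- ceiling(1.5 * t_tot / (11 * tau)) * 2 + 20
      dw <- cbind(rexp(n, 1 / tau), rexp(n, 1 / (10 * tau)))
      edges <- cumsum(as.vector(t(dw)))
      tt <- seq(0, t_tot, by = dt * tau / 0.2)
      idx <- findInterval(tt, c(0, edges))
      as.integer(idx %% 2 == 1)   # odd intervals = stalled
    }, integer(length(seq(0, 600 * tau, by = dt * tau / 0.2))))
    structure(occ, grid = c(10L, 10L),
              frame_interval_s = dt * tau / 0.2,
              class = c("occupancy_series", "matrix", "array"))
  }
  decays <- vapply(c(0.2, 0.5, 1.0), function(tau) {
    occupancy_autocorrelation(mk_series(tau), max_lag_s = 5 * tau)$decay_time_s
  }, numeric(1))
  expect_lt(abs(decays[2] - 0.5 / 1.1), 0.2 * 0.5)
  # decay time grows monotonically with the stall dwell scale
  expect_true(all(diff(decays) > 0))
})
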