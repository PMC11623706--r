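test_that("dwell extraction handles a constructed frame-labelled sequence", {
  tr <- make_track(1, 0, 0, n_frames = 6, dt = 0.1,
                   state = c("CLOSED", "CLOSED", "PARTIAL", "PARTIAL",
                             "PARTIAL", "OPEN"))
  ex <- extract_dwells(list(tr))
  expect_equal(ex$dwells$duration_s, c(0.2, 0.3, 0.1))
  expect_identical(ex$dwells$state, c("CLOSED", "PARTIAL", "OPEN"))
  expect_identical(ex$dwells$censored, c(TRUE, FALSE, TRUE))
  expect_equal(unname(ex$one_step["CLOSED", "PARTIAL"]), 1)
  expect_equal(unname(ex$one_step["PARTIAL", "OPEN"]), 1)
  expect_equal(sum(ex$one_step), 2)
  expect_equal(unname(ex$two_step["CLOSED", "OPEN"]), 1)
  bad <- tr; bad$state[2] <- "WOBBLE"
  expect_error(extract_dwells(list(bad)), "WOBBLE")
})

test_that("interval state tracks extract without discretisation", {
  tr <- big_ctmc()
  ex <- big_extraction()
  expect_equal(nrow(ex$dwells), nrow(tr))
  expect_equal(sum(ex$one_step), nrow(tr) - 1)
  # no closed-open adjacency under the fitted model's structural zeros
  expect_equal(unname(ex$one_step["CLOSED", "OPEN"]), 0)
  expect_equal(unname(ex$one_step["OPEN", "CLOSED"]), 0)
})

test_that("the exponential MLE is the sample mean in closed form", {
  fit <- mle_exponential(c(1, 3))
  expect_equal(fit$means, 2)
  expect_equal(fit$rates, 0.5)
  expect_equal(fit$loglik, 2 * (-log(2) - 1))
  expect_error(mle_exponential(1), ">= 2")
  expect_error(mle_exponential(c(1, -1)), "positive")
  # printed dwell means give the printed rates at 3 significant figures
  expect_equal(signif(1 / c(0.25, 0.21, 0.95), 3), c(4, 4.76, 1.05))
})

test_that("closed-form MLE agrees with a numeric optimiser to 1e-10", {
  set.seed(5)
  d <- rexp(500, 1 / 0.95)
  fit <- mle_exponential(d)
  num <- stats::optimize(function(m) -sum(stats::dexp(d, 1 / m, log = TRUE)),
                         interval = c(1e-3, 100), tol = 1e-12)
  expect_lt(abs(fit$means - num$minimum), 1e-6)
  expect_lt(abs(fit$loglik - (-num$objective)), 1e-10)
})

test_that("large-sample exponential fits recover the mean within 1%", {
  set.seed(19)
  d <- rexp(1e5, 1 / 0.95)
  fit <- mle_exponential(d)
  expect_lt(abs(fit$means - 0.95) / 0.95, 0.01)
})

test_that("the mixture EM recovers well-separated components", {
  set.seed(23)
  d <- c(rexp(1000, 1 / 0.2), rexp(1000, 1 / 2))
  fit <- fit_exponential_mixture(d, seed = 23)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 0.2) / 0.2, 0.15)
  expect_lt(abs(fit$means[2] - 2) / 2, 0.15)
  expect_equal(sum(fit$weights), 1)
})

test_that("the mixture never fits worse than the single exponential", {
  set.seed(29)
  for (i in 1:5) {
    d <- rexp(300, 1 / runif(1, 0.2, 2))
    fs <- mle_exponential(d)
    fm <- fit_exponential_mixture(d, seed = i)
    expect_gte(fm$loglik, fs$loglik - 1e-9)
  }
})

test_that("AIC comparison follows the parameter-count convention", {
  fs <- mle_exponential(c(1, 2, 3))
  fm <- fit_exponential_mixture(rexp(20, 1), seed = 1)
  expect_error(aic_compare(fs, fm), "sample sizes")
  # identical log-likelihoods, 1 vs 3 free parameters -> difference -4
  mock_s <- list(aic = 2 * 1 - 2 * 10, n = 100)
  mock_m <- list(aic = 2 * 3 - 2 * 10, n = 100)
  expect_equal(aic_compare(mock_s, mock_m), -4)
})

test_that("AIC prefers the true generating family", {
  set.seed(37)
  d_single <- replicate(11, {
    d <- rexp(500, 1 / 0.95)
    aic_compare(mle_exponential(d),
                fit_exponential_mixture(d, seed = 1))
  })
  expect_gt(mean(d_single <= 0), 0.5)  # single-exponential truth
  d <- c(rexp(1000, 1 / 0.1), rexp(1000, 1 / 3))
  expect_gt(aic_compare(mle_exponential(d),
                        fit_exponential_mixture(d, seed = 2)), 0)
})

test_that("embedded matrix normalises counts and attaches rates", {
  ex <- list(one_step = matrix(c(0, 5, 0, 10, 0, 10, 0, 5, 0), 3,
                               dimnames = list(from = flagellar_states(),
                                               to = flagellar_states())),
             dwells = data.frame(
               cell_id = 1,
               state = rep(flagellar_states(), each = 4),
               duration_s = rep(c(0.25, 0.21, 0.95), each = 4),
               censored = FALSE))
  em <- embedded_matrix(ex)
  expect_equal(unname(em$embedded),
               matrix(c(0, 0.5, 0, 1, 0, 1, 0, 0.5, 0), 3))
  expect_equal(unname(signif(em$exit_rates, 3)), c(4, 4.76, 1.05))
  expect_length(em$undefined_states, 0)
})

test_that("generator parameters are recovered from 5e4 transitions", {
  em <- embedded_matrix(big_extraction())
  true_rates <- swarm_transition_model()$exit_rates
  expect_true(all(abs(em$exit_rates - true_rates) / true_rates < 0.02))
  expect_true(all(abs(em$embedded - swarm_transition_model()$embedded) < 0.01,
                  na.rm = TRUE))
})

test_that("memorylessness error is zero when Q equals P squared", {
  P <- swarm_transition_model()$embedded
  expect_equal(memorylessness_error(P, P %*% P), 0)
  Qbad <- P %*% P; Qbad[1, 1] <- Qbad[1, 1] + 0.1
  expect_error(memorylessness_error(P, Qbad), "sum to 1")
})

test_that("a deterministic cyclic switcher fails the memorylessness test", {
  # dwell order C,P,O,P,C,P,O,... : one-step frequencies match the fitted
  # model but the two-step matrix is deterministic, not P^2
  seq_states <- rep(c("CLOSED", "PARTIAL", "OPEN", "PARTIAL"), 500)
  tr <- state_track(seq_states, t_start = seq_along(seq_states) - 1,
                    t_end = seq_along(seq_states))
  ex <- extract_dwells(tr)
  P <- ex$one_step / rowSums(ex$one_step)
  Q <- two_step_matrix(ex)
  # analytic: from CLOSED, two steps always reach OPEN, but P^2 gives 1/2
  expect_equal(unname(Q["CLOSED", "OPEN"]), 1)
  expect_gt(memorylessness_error(P, Q), 0.5)
})

test_that("memorylessness error shrinks with sample size", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    med <- vapply(1:3, function(s) {
      ex <- extract_dwells(simulate_ctmc(swarm_transition_model(),
                                         n_jumps = n, seed = 1000 + s))
      memorylessness_error(ex$one_step / rowSums(ex$one_step),
                           two_step_matrix(ex))
    }, numeric(1))
    stats::median(med)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("keeping censored dwells biases the fitted mean low", {
  set.seed(41)
  means <- replicate(20, {
    tr <- simulate_ctmc(swarm_transition_model(), t_total = 30)
    d <- tr$t_end - tr$t_start
    open <- tr$state == "OPEN"
    c(with_cens = mean(d[open]),
      without = mean(d[open & !tr$censored]))
  })
  expect_lt(mean(means["with_cens", ] - means["without", ]), 0)
})

test_that("speeds conditioned on state separate the three modes", {
  cfg <- swarm_config(arena_width_um = 30, arena_height_um = 30, rho = 0.3,
                      duration_s = 5, seed = 44, coupling = FALSE)
  tr <- simulate_swarm(cfg)
  sbs <- speed_by_state(tr)
  expect_identical(sbs$OPEN$mean_ums, 0)
  expect_true(all(sbs$OPEN$speeds == 0))
  expect_gt(sbs$CLOSED$mean_ums, sbs$PARTIAL$mean_ums)
  # unlabelled samples are dropped with a count, empty states do not crash
  t2 <- tr[[1]]
  t2$state[1:5] <- NA
  sbs2 <- speed_by_state(list(t2))
  expect_identical(sbs2$n_dropped, 5L)
})
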