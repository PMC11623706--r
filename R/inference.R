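#' Extract dwell times and transition counts from labelled tracks
#'
#' Maximal constant-state runs become dwells; jumps between consecutive
#' distinct states are counted into the one-step matrix, and pairs of states
#' two jumps apart (overlapping, all n vs n+2) into the two-step matrix.
#' The first and last dwell of every track are flagged censored — they are
#' truncated by the observation window and bias dwell means low if kept.
#'
#' @param tracks List of `cell_track` data.frames (frame-sampled `state`
#'   column at uniform intervals) and/or [state_track()] interval objects.
#' @return List with `dwells` (data.frame `cell_id`, `state`, `duration_s`,
#'   `censored`), `one_step` and `two_step` (3x3 count matrices, canonical
#'   state order).
#' @export
extract_dwells <- function(tracks) {
  if (inherits(tracks, "data.frame") || inherits(tracks, "state_track")) {
    tracks <- list(tracks)
  }
  states <- flagellar_states()
  one <- matrix(0L, 3, 3, dimnames = list(from = states, to = states))
  two <- matrix(0L, 3, 3, dimnames = list(from = states, to = states))
  dw <- list()
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    if (inherits(tr, "state_track")) {
      st <- tr$state
      dur <- tr$t_end - tr$t_start
      cen <- tr$censored
      cid <- ti
    } else {
      st_raw <- tr$state
      if (!all(st_raw %in% states)) {
        bad <- setdiff(unique(st_raw), states)
        stop("unknown state symbol(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      dt <- diff(tr$time_s)
      if (length(dt) && max(abs(dt - dt[1])) > 1e-9) {
        stop("states must be sampled at uniform intervals", call. = FALSE)
      }
      r <- rle(st_raw)
      st <- r$values
      dur <- r$lengths * if (length(dt)) dt[1] else NA_real_
      cen <- rep(FALSE, length(st))
      cen[c(1L, length(st))] <- TRUE
      cid <- tr$cell_id[1]
    }
    dw[[length(dw) + 1L]] <- data.frame(
      cell_id = cid, state = st, duration_s = dur, censored = cen,
      stringsAsFactors = FALSE)
    si <- match(st, states)
    m <- length(si)
    if (m >= 2) {  # column-major cell index: from + 3 * (to - 1)
      one <- one + matrix(tabulate(si[-m] + 3L * (si[-1] - 1L), 9L), 3, 3)
    }
    if (m >= 3) {
      lead2 <- si[-(1:2)]
      two <- two + matrix(tabulate(si[1:(m - 2)] + 3L * (lead2 - 1L), 9L), 3, 3)
    }
  }
  list(dwells = do.call(rbind, dw), one_step = one, two_step = two)
}

fit_result <- function(family, means, weights, loglik, n, converged = TRUE) {
  k_free <- if (family == "exponential") 1L else 2L * length(means) - 1L
  structure(list(family = family, means = means, weights = weights,
                 rates = 1 / means, loglik = loglik,
                 aic = 2 * k_free - 2 * loglik, k_free = k_free, n = n,
                 converged = converged),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): means = %s s, weights = %s, loglik = %.3f, AIC = %.3f\n",
              x$family, x$n, paste(signif(x$means, 4), collapse = "/"),
              paste(signif(x$weights, 3), collapse = "/"), x$loglik, x$aic))
  invisible(x)
}

#' Exponential maximum-likelihood fit of dwell times
#'
#' The exponential MLE in closed form: the fitted mean is the sample mean,
#' the rate its reciprocal, and the maximised log-likelihood is
#' `n * (-log(mean) - 1)`.
#'
#' @param dwells Numeric vector of (uncensored) dwell durations, length >= 2.
#' @return A `dwell_fit` with the mean, rate, log-likelihood and AIC.
#' @export
mle_exponential <- function(dwells) {
  dwells <- as.numeric(dwells)
  if (length(dwells) < 2) stop("need >= 2 uncensored dwells", call. = FALSE)
  if (any(dwells <= 0)) stop("dwell durations must be positive", call. = FALSE)
  m <- mean(dwells)
  n <- length(dwells)
  fit_result("exponential", means = m, weights = 1,
             loglik = n * (-log(m) - 1), n = n)
}

#' Two-component exponential mixture fit by EM
#'
#' Expectation-maximisation with multiple restarts (quantile-based starts
#' plus random perturbations; one restart begins at the single-exponential
#' solution, so the mixture log-likelihood can never fall below it).
#'
#' @param dwells Numeric vector of dwell durations, length >= 10.
#' @param k Number of components (2 supported).
#' @param n_restarts Number of EM restarts (default 10).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Iteration cap per restart (default 500).
#' @param seed Optional seed for the random restarts.
#' @return A `dwell_fit`; `converged = FALSE` flags failure to converge in
#'   every restart.
#' @export
fit_exponential_mixture <- function(dwells, k = 2L, n_restarts = 10L,
                                    tol = 1e-8, max_iter = 500L,
                                    seed = NULL) {
  dwells <- as.numeric(dwells)
  if (length(dwells) < 10) stop("need >= 10 dwells", call. = FALSE)
  if (k != 2L) stop("only k = 2 supported", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dwells)
  m0 <- mean(dwells)
  qs <- stats::quantile(dwells, c(0.25, 0.75))
  starts <- list(
    list(means = c(m0 * 0.999, m0 * 1.001), w = 0.5),   # single-exp start
    list(means = as.numeric(qs) / log(2), w = 0.5)      # quantile start
  )
  while (length(starts) < n_restarts) {
    starts[[length(starts) + 1L]] <- list(
      means = m0 * stats::runif(2, 0.2, 3), w = stats::runif(1, 0.2, 0.8))
  }
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    mu <- pmax(s$means, 1e-12)
    w <- c(s$w, 1 - s$w)
    ll_old <- -Inf
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w[1] / mu[1] * exp(-dwells / mu[1])
      d2 <- w[2] / mu[2] * exp(-dwells / mu[2])
      tot <- d1 + d2
      ll <- sum(log(tot))
      g1 <- d1 / tot
      w <- c(mean(g1), 1 - mean(g1))
      if (w[1] > 1e-12) mu[1] <- sum(g1 * dwells) / sum(g1)
      if (w[2] > 1e-12) mu[2] <- sum((1 - g1) * dwells) / sum(1 - g1)
      if (is.finite(ll) && abs(ll - ll_old) < tol) { conv <- TRUE; break }
      ll_old <- ll
    }
    d1 <- w[1] / mu[1] * exp(-dwells / mu[1])
    d2 <- w[2] / mu[2] * exp(-dwells / mu[2])
    ll <- sum(log(d1 + d2))
    any_conv <- any_conv || conv
    if (is.null(best) || ll > best$ll) best <- list(mu = mu, w = w, ll = ll)
  }
  o <- order(best$mu)
  fit_result("exponential_mixture", means = best$mu[o], weights = best$w[o],
             loglik = max(best$ll, mle_exponential(dwells)$loglik),
             n = n, converged = any_conv)
}

#' AIC comparison of single-exponential and mixture fits
#'
#' Signed difference `AIC(single) - AIC(mixture)` on identical data. A
#' negative value favours the single exponential (the mixture's extra
#' parameters are not justified).
#'
#' @param fit_single,fit_mixture `dwell_fit` objects on the same dwells.
#' @return Numeric AIC difference.
#' @export
aic_compare <- function(fit_single, fit_mixture) {
  if (fit_single$n != fit_mixture$n) {
    stop("fits were made on different sample sizes", call. = FALSE)
  }
  fit_single$aic - fit_mixture$aic
}

#' Embedded transition matrix and exit rates from counts and dwells
#'
#' Row-normalises the one-step transition counts into the embedded jump
#' matrix and attaches exit rates from the per-state exponential dwell MLE
#' (1 / mean uncensored dwell). States with no outgoing transitions yield an
#' undefined (NA) row and are flagged.
#'
#' @param extraction Result of [extract_dwells()].
#' @param drop_censored Exclude censored dwells from the rate fit (default
#'   TRUE).
#' @return List with `embedded` (3x3, NA rows flagged), `exit_rates` (1/s),
#'   `mean_dwell_s`, `undefined_states`, `n_transitions`.
#' @export
embedded_matrix <- function(extraction, drop_censored = TRUE) {
  counts <- extraction$one_step
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  undef <- flagellar_states()[rs == 0]
  dw <- extraction$dwells
  if (drop_censored) dw <- dw[!dw$censored, , drop = FALSE]
  means <- vapply(flagellar_states(), function(s) {
    d <- dw$duration_s[dw$state == s]
    if (length(d) >= 2) mean(d) else NA_real_
  }, numeric(1))
  list(embedded = P, exit_rates = 1 / means, mean_dwell_s = means,
       undefined_states = undef, n_transitions = sum(counts))
}

#' Row-normalise two-step counts into a matrix
#'
#' @param extraction Result of [extract_dwells()].
#' @return 3x3 row-stochastic matrix of empirical two-step probabilities.
#' @export
two_step_matrix <- function(extraction) {
  counts <- extraction$two_step
  rs <- rowSums(counts)
  counts / ifelse(rs > 0, rs, NA_real_)
}

#' Memorylessness test: two-step matrix against the one-step square
#'
#' Under the Markov property the two-step transition matrix equals the
#' square of the one-step matrix; the discrepancy is summarised as the
#' maximum relative error over entries whose expected two-step probability
#' exceeds `eps` (structurally zero entries carry no information and are
#' excluded).
#'
#' @param P One-step row-stochastic 3x3 matrix.
#' @param Q Empirical two-step row-stochastic 3x3 matrix.
#' @param eps Entries of `P %*% P` at or below this are excluded (default
#'   0.01).
#' @return Maximum relative error (dimensionless; multiply by 100 for %).
#' @export
memorylessness_error <- function(P, Q, eps = 0.01) {
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("P rows must sum to 1", call. = FALSE)
  }
  if (any(abs(rowSums(Q) - 1) > 1e-9)) {
    stop("Q rows must sum to 1", call. = FALSE)
  }
  P2 <- P %*% P
  sel <- P2 > eps
  max(abs(Q[sel] - P2[sel]) / P2[sel])
}

#' Speed distributions conditioned on flagellar state
#'
#' @param tracks List of `cell_track` data.frames with `state` and either a
#'   ground-truth `speed_ums` column or positions to difference.
#' @param bin_width_ums Histogram bin width (default 1 um/s).
#' @param wrap Optional periodic arena size for position differencing.
#' @return List per state with `speeds`, `mean_ums`, `n`, `histogram` (NULL
#'   when the state is unobserved), plus `n_dropped` samples lacking labels.
#' @export
speed_by_state <- function(tracks, bin_width_ums = 1, wrap = NULL) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    sp <- if ("speed_ums" %in% names(tr)) tr$speed_ums else
      instantaneous_speeds(tr, wrap = wrap)$speed_ums
    data.frame(state = tr$state, speed_ums = sp, stringsAsFactors = FALSE)
  }))
  dropped <- sum(is.na(df$state) | !(df$state %in% flagellar_states()))
  df <- df[!is.na(df$state) & df$state %in% flagellar_states(), ]
  out <- lapply(flagellar_states(), function(s) {
    v <- df$speed_ums[df$state == s]
    h <- if (length(v)) {
      breaks <- seq(0, max(v, bin_width_ums) + bin_width_ums,
                    by = bin_width_ums)
      graphics::hist(v, breaks = breaks, plot = FALSE)
    } else NULL
    list(speeds = v, mean_ums = if (length(v)) mean(v) else NA_real_,
         n = length(v), histogram = h)
  })
  names(out) <- flagellar_states()
  out$n_dropped <- dropped
  out
}
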