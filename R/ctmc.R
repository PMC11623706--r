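#' Flagellar state labels
#'
#' The three flagellar arrangements of a swarmer cell, in fixed order used for
#' all matrix indexing: `CLOSED` (bundled flagella, "run"), `PARTIAL`
#' (partially unbundled, "tumble"), `OPEN` (fully unbundled, "stall").
#'
#' @return Character vector of the three state names, in canonical order.
#' @export
flagellar_states <- function() c("CLOSED", "PARTIAL", "OPEN")

#' Three-state flagellar transition model
#'
#' A continuous-time Markov chain on the flagellar states, parameterised by
#' per-state exit rates and the embedded (jump) transition matrix. The embedded
#' matrix is row-stochastic with zero diagonal: a jump always changes state.
#'
#' @param exit_rates Numeric length-3 vector of exit rates (1/s), one per
#'   state in the order CLOSED, PARTIAL, OPEN. All must be positive.
#' @param embedded 3x3 numeric matrix of jump probabilities; rows must sum to
#'   1 (tolerance 1e-12) and the diagonal must be exactly zero.
#' @return An object of class `transition_model` with elements `exit_rates`
#'   (named) and `embedded` (dimnamed matrix).
#' @seealso [swarm_transition_model()] for the fitted B. subtilis model.
#' @export
transition_model <- function(exit_rates, embedded) {
  states <- flagellar_states()
  exit_rates <- as.numeric(exit_rates)
  if (length(exit_rates) != 3L || any(!is.finite(exit_rates)) ||
      any(exit_rates <= 0)) {
    stop("`exit_rates` must be 3 finite positive rates (1/s)", call. = FALSE)
  }
  embedded <- as.matrix(embedded)
  if (!all(dim(embedded) == c(3L, 3L)) || any(!is.finite(embedded)) ||
      any(embedded < 0)) {
    stop("`embedded` must be a non-negative 3x3 matrix", call. = FALSE)
  }
  if (any(diag(embedded) != 0)) {
    stop("`embedded` diagonal must be exactly zero (jumps change state)",
         call. = FALSE)
  }
  if (any(abs(rowSums(embedded) - 1) > 1e-12)) {
    stop("`embedded` rows must sum to 1 (tolerance 1e-12)", call. = FALSE)
  }
  names(exit_rates) <- states
  dimnames(embedded) <- list(from = states, to = states)
  structure(list(exit_rates = exit_rates, embedded = embedded),
            class = "transition_model")
}

#' Fitted B. subtilis swarmer flagellar model
#'
#' The transition model inferred from manually labelled swarmer trajectories:
#' exit rates 4, 4.76 and 1.05 1/s out of the closed, partial and open states
#' (mean dwells 0.25, 0.21 and 0.95 s), with no direct closed-open jumps and
#' an even split out of the partial state.
#'
#' @return A [transition_model()].
#' @export
swarm_transition_model <- function() {
  transition_model(
    exit_rates = c(4, 4.76, 1.05),
    embedded = matrix(c(0,   1, 0,
                        0.5, 0, 0.5,
                        0,   1, 0), nrow = 3, byrow = TRUE)
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Three-state flagellar transition model\n")
  cat("Exit rates (1/s):",
      paste(sprintf("%s=%.3g", names(x$exit_rates), x$exit_rates),
            collapse = ", "), "\n")
  cat("Embedded jump matrix:\n")
  print(round(x$embedded, 4))
  invisible(x)
}

#' Stationary distribution of the embedded jump chain
#'
#' Solves pi = pi P for the discrete jump chain (left eigenvector of the
#' embedded matrix at eigenvalue 1, normalised to sum to 1).
#'
#' @param model A [transition_model()].
#' @return Named numeric vector over the three states.
#' @export
embedded_stationary <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  e <- eigen(t(model$embedded))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, flagellar_states())
}

#' Long-run fraction of time spent in each state
#'
#' Time-stationary occupation probabilities of the continuous-time chain:
#' the embedded stationary vector weighted by mean dwell times (1/exit rate)
#' and renormalised.
#'
#' @param model A [transition_model()].
#' @return Named numeric vector summing to 1.
#' @export
time_stationary <- function(model) {
  pi_e <- embedded_stationary(model)
  w <- pi_e / model$exit_rates
  w / sum(w)
}

#' Construct a state track from dwell intervals
#'
#' A state track is the piecewise-constant flagellar-state history of one
#' cell: contiguous, non-overlapping dwell intervals in which consecutive
#' intervals carry different states. First and last dwells are flagged
#' censored (truncated by the observation window) so inference can drop them.
#'
#' @param state Character vector of state names per interval.
#' @param t_start,t_end Numeric vectors of interval bounds (s).
#' @param censored Logical vector; defaults to flagging first and last dwell.
#' @return A `state_track` data.frame with columns `state`, `t_start`,
#'   `t_end`, `censored`.
#' @export
state_track <- function(state, t_start, t_end, censored = NULL) {
  n <- length(state)
  stopifnot(length(t_start) == n, length(t_end) == n, n >= 1)
  if (!all(state %in% flagellar_states())) {
    bad <- setdiff(unique(state), flagellar_states())
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(t_end <= t_start)) stop("dwell intervals must have t_end > t_start",
                                  call. = FALSE)
  if (n > 1) {
    if (any(abs(t_start[-1] - t_end[-n]) > 1e-9)) {
      stop("dwell intervals must be contiguous", call. = FALSE)
    }
    if (any(state[-1] == state[-n])) {
      stop("consecutive dwells must have different states", call. = FALSE)
    }
  }
  if (is.null(censored)) {
    censored <- rep(FALSE, n)
    censored[c(1L, n)] <- TRUE
  }
  structure(
    data.frame(state = state, t_start = t_start, t_end = t_end,
               censored = censored, stringsAsFactors = FALSE),
    class = c("state_track", "data.frame")
  )
}

#' Simulate the flagellar-state chain
#'
#' Gillespie-style sampling: the dwell in state i is Exponential with the
#' state's exit rate, and the next state is drawn from row i of the embedded
#' matrix. Simulation stops when the elapsed time reaches `t_total` (the final
#' dwell is truncated and flagged censored) or, if `n_jumps` is given, after
#' that many jumps.
#'
#' @param model A [transition_model()].
#' @param t_total Total simulated time (s); ignored if `n_jumps` is given.
#' @param initial Initial state name (default `"CLOSED"`).
#' @param seed Optional integer seed for reproducibility.
#' @param n_jumps Optional number of state-to-state jumps to simulate instead
#'   of a fixed duration (the track then has `n_jumps + 1` dwells).
#' @return A [state_track()].
#' @export
simulate_ctmc <- function(model, t_total = NULL, initial = "CLOSED",
                          seed = NULL, n_jumps = NULL) {
  stopifnot(inherits(model, "transition_model"))
  initial <- match.arg(initial, flagellar_states())
  if (is.null(n_jumps)) {
    if (is.null(t_total) || !is.finite(t_total) || t_total <= 0) {
      stop("`t_total` must be a positive duration (s)", call. = FALSE)
    }
  } else {
    stopifnot(n_jumps >= 0)
  }
  if (!is.null(seed)) set.seed(seed)

  states <- flagellar_states()
  s0 <- match(initial, states)
  seq_states <- simulate_embedded_sequence(
    model$embedded, s0,
    n_steps = if (is.null(n_jumps)) NA_integer_ else as.integer(n_jumps),
    t_total = t_total, exit_rates = model$exit_rates
  )
  idx <- seq_states$states
  dur <- seq_states$durations
  n <- length(idx)
  t_end <- cumsum(dur)
  t_start <- c(0, t_end[-n])
  censored <- rep(FALSE, n)
  censored[1L] <- TRUE
  censored[n] <- TRUE  # last dwell truncated (by t_total or by jump budget)
  state_track(states[idx], t_start, t_end, censored)
}

# Jump sequence + dwell durations for either a fixed number of jumps or a
# fixed total time. Dwells are drawn after the jump sequence is known (the
# durations depend only on the occupied state), which keeps the per-jump loop
# to a single categorical draw.
simulate_embedded_sequence <- function(P, s0, n_steps, t_total, exit_rates) {
  cum <- t(apply(P, 1, cumsum))
  if (!is.na(n_steps)) {
    n <- n_steps + 1L
    idx <- integer(n)
    idx[1L] <- s0
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      s <- s0
      for (k in seq_len(n - 1L)) {
        row <- cum[s, ]
        s <- if (u[k] <= row[1L]) 1L else if (u[k] <= row[2L]) 2L else 3L
        idx[k + 1L] <- s
      }
    }
    dur <- stats::rexp(n, rate = exit_rates[idx])
    return(list(states = idx, durations = dur))
  }
  # time-limited: grow in chunks until cumulative dwell time exceeds t_total
  idx <- integer(0)
  dur <- numeric(0)
  s <- s0
  elapsed <- 0
  mean_dwell <- sum(1 / exit_rates) / 3
  repeat {
    chunk <- max(64L, ceiling(1.3 * (t_total - elapsed) / mean_dwell))
    ci <- integer(chunk)
    u <- stats::runif(chunk)
    ci[1L] <- s
    for (k in seq_len(chunk - 1L)) {
      row <- cum[ci[k], ]
      ci[k + 1L] <- if (u[k] <= row[1L]) 1L else if (u[k] <= row[2L]) 2L else 3L
    }
    cd <- stats::rexp(chunk, rate = exit_rates[ci])
    idx <- c(idx, ci)
    dur <- c(dur, cd)
    elapsed <- elapsed + sum(cd)
    if (elapsed >= t_total) break
    row <- cum[ci[chunk], ]
    un <- stats::runif(1)
    s <- if (un <= row[1L]) 1L else if (un <= row[2L]) 2L else 3L
  }
  cum_t <- cumsum(dur)
  n <- which(cum_t >= t_total)[1L]
  idx <- idx[seq_len(n)]
  dur <- dur[seq_len(n)]
  dur[n] <- t_total - if (n > 1L) cum_t[n - 1L] else 0  # censor at t_total
  list(states = idx, durations = dur)
}

#' Look up the state of a track at given times
#'
#' @param track A [state_track()].
#' @param times Numeric vector of query times (s) within the track support.
#' @return Character vector of state names.
#' @export
state_at <- function(track, times) {
  if (any(times < track$t_start[1] - 1e-9) ||
      any(times > track$t_end[nrow(track)] + 1e-9)) {
    stop("query time outside track support", call. = FALSE)
  }
  i <- findInterval(pmin(times, track$t_end[nrow(track)] - 1e-12),
                    track$t_start)
  track$state[pmax(i, 1L)]
}
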