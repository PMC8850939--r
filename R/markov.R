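#' State space of a discrete-time cohort model
#'
#' @param states ordered character vector of unique state labels
#' @param absorbing subset of `states` that, once entered, are never left
#' @return object of class `state_space`
#' @export
state_space <- function(states, absorbing = character(0)) {
  if (anyDuplicated(states)) stop("state labels must be unique", call. = FALSE)
  if (!all(absorbing %in% states)) {
    stop("absorbing states must be a subset of the state labels", call. = FALSE)
  }
  structure(list(states = states, absorbing = absorbing), class = "state_space")
}

## Coerce a schedule (single matrix, or list of per-cycle matrices) to a
## list of length n_cycles and validate row-stochasticity to 1e-12,
## entries in [0,1], and self-absorption of absorbing states.
as_schedule <- function(schedule, space, n_cycles) {
  S <- length(space$states)
  if (is.matrix(schedule)) schedule <- rep(list(schedule), n_cycles)
  if (!is.list(schedule)) stop("schedule must be a matrix or list of matrices", call. = FALSE)
  if (length(schedule) == 1L && n_cycles > 1L) {
    schedule <- rep(schedule, n_cycles)
  }
  if (length(schedule) != n_cycles) {
    stop(sprintf("schedule defines %d cycle(s) but %d are required",
                 length(schedule), n_cycles), call. = FALSE)
  }
  abs_idx <- match(space$absorbing, space$states)
  for (t in seq_len(n_cycles)) {
    M <- schedule[[t]]
    if (!is.matrix(M) || nrow(M) != S || ncol(M) != S) {
      stop(sprintf("cycle %d transition matrix is not %dx%d", t, S, S), call. = FALSE)
    }
    if (any(M < 0) || any(M > 1)) {
      stop(sprintf("cycle %d transition matrix has entries outside [0,1]", t),
           call. = FALSE)
    }
    bad <- which(abs(rowSums(M) - 1) > 1e-12)
    if (length(bad)) {
      stop(sprintf("cycle %d transition matrix row '%s' sums to %.15f, not 1",
                   t, space$states[bad[1]], rowSums(M)[bad[1]]), call. = FALSE)
    }
    for (a in abs_idx) {
      if (abs(M[a, a] - 1) > 1e-12) {
        stop(sprintf("absorbing state '%s' must self-transition with probability 1",
                     space$states[a]), call. = FALSE)
      }
    }
    dimnames(schedule[[t]]) <- list(space$states, space$states)
  }
  schedule
}

#' Reward specification for a cohort model
#'
#' Per-state, per-cycle cost and utility accruals plus per-entry event
#' costs. `state_cost` and `state_utility` may be a single value, a vector
#' over states, or an `n_cycles x n_states` matrix for time-varying
#' rewards. Utilities are dimensionless weights applied over
#' `cycle_length` years; event costs are incurred once per entry into a
#' state (per patient, not per cycle of occupancy).
#'
#' @param state_cost cost per state per cycle (CNY)
#' @param state_utility utility weight per state, in `[0,1]`
#' @param event_cost cost per entry into each state (CNY)
#' @param cycle_length cycle length in years (> 0)
#' @return object of class `reward_spec`
#' @export
reward_spec <- function(state_cost = 0, state_utility = 0, event_cost = 0,
                        cycle_length = 1) {
  assert_number(cycle_length, "cycle_length", lower = .Machine$double.eps)
  if (any(state_utility < 0) || any(state_utility > 1)) {
    stop("state utilities must lie in [0,1]", call. = FALSE)
  }
  structure(list(state_cost = state_cost, state_utility = state_utility,
                 event_cost = event_cost, cycle_length = cycle_length),
            class = "reward_spec")
}

## expand a reward component to an n_cycles x S matrix
reward_matrix <- function(x, n_cycles, S) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == n_cycles, ncol(x) == S)
    return(x)
  }
  if (length(x) == 1L) x <- rep(x, S)
  stopifnot(length(x) == S)
  matrix(x, nrow = n_cycles, ncol = S, byrow = TRUE)
}

#' Discounted sum of a per-cycle value stream
#'
#' `sum_t v_t (1 + rate)^(-t * cycle_length)` with cycle 0 undiscounted.
#'
#' @param values per-cycle values, cycle 0 first
#' @param rate annual discount rate (>= 0)
#' @param cycle_length cycle length in years
#' @return scalar
#' @examples
#' discounted_sum(c(0, 100), rate = 0.05)  # 95.238...
#' @export
discounted_sum <- function(values, rate, cycle_length = 1) {
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  t <- seq_along(values) - 1
  sum(values * (1 + rate)^(-t * cycle_length))
}

#' Run a deterministic cohort trace
#'
#' Propagates a cohort distribution through per-cycle transition matrices:
#' `occupancy[t+1] = occupancy[t] %*% M[t]`. Cycle-`t` rewards are accrued
#' on the cycle-start occupancy (rows `0 .. n_cycles-1`) plus, for event
#' costs, on the entries generated by the cycle-`t` transition (an entry
#' into state `s` is flow into `s` from any other state). Both are
#' discounted by `(1 + rate)^(-t * cycle_length)`; with `half_cycle = TRUE`
#' state rewards use the average of the cycle-start and cycle-end
#' occupancy instead.
#'
#' @param space a [state_space()]
#' @param schedule transition matrix, or list of per-cycle matrices
#' @param initial initial distribution over states (sums to 1)
#' @param rewards a [reward_spec()]
#' @param n_cycles number of cycles to run
#' @param discount_rate annual discount rate
#' @param half_cycle logical; apply a half-cycle correction to state rewards
#' @return object of class `cohort_trace`: occupancy matrix
#'   (`n_cycles+1` rows), per-cycle undiscounted cost and QALY streams,
#'   per-cycle state-entry flows, cumulative entries per state, and
#'   discounted totals
#' @export
run_cohort <- function(space, schedule, initial, rewards, n_cycles,
                       discount_rate = 0, half_cycle = FALSE) {
  stopifnot(inherits(space, "state_space"), inherits(rewards, "reward_spec"))
  S <- length(space$states)
  if (length(initial) != S || abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    stop("initial distribution must be non-negative over all states and sum to 1",
         call. = FALSE)
  }
  if (discount_rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  schedule <- as_schedule(schedule, space, n_cycles)
  cl <- rewards$cycle_length
  cost_m <- reward_matrix(rewards$state_cost, n_cycles, S)
  util_m <- reward_matrix(rewards$state_utility, n_cycles, S)
  ev <- rewards$event_cost
  if (length(ev) == 1L) ev <- rep(ev, S)

  occ <- matrix(0, n_cycles + 1L, S, dimnames = list(0:n_cycles, space$states))
  occ[1L, ] <- initial
  entries <- matrix(0, n_cycles, S, dimnames = list(seq_len(n_cycles) - 1L, space$states))
  cost_cycle <- numeric(n_cycles)
  qaly_cycle <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    M <- schedule[[t]]
    cur <- occ[t, ]
    nxt <- as.numeric(cur %*% M)
    ## flow into s from states other than s
    inflow <- as.numeric(cur %*% M) - cur * diag(M)
    entries[t, ] <- inflow
    occ[t + 1L, ] <- nxt
    basis <- if (half_cycle) (cur + nxt) / 2 else cur
    cost_cycle[t] <- sum(basis * cost_m[t, ]) + sum(inflow * ev)
    qaly_cycle[t] <- sum(basis * util_m[t, ]) * cl
  }
  bad <- which(abs(rowSums(occ) - 1) > 1e-9)
  if (length(bad)) {
    stop(sprintf("occupancy row %d does not sum to 1", bad[1] - 1L), call. = FALSE)
  }
  df <- (1 + discount_rate)^(-(seq_len(n_cycles) - 1L) * cl)
  out <- list(
    space = space,
    occupancy = occ,
    entries = entries,
    cum_entries = colSums(entries),
    cost_per_cycle = cost_cycle,
    qaly_per_cycle = qaly_cycle,
    discount_rate = discount_rate,
    cycle_length = cl,
    total_cost = sum(cost_cycle * df),
    total_qalys = sum(qaly_cycle * df),
    ## undiscounted person-time in non-absorbing occupancy, in years
    life_years = sum(occ[seq_len(n_cycles),
                         setdiff(space$states, space$absorbing), drop = FALSE]) * cl,
    method = "cohort"
  )
  class(out) <- "cohort_trace"
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d states, %d cycles of %.4f yr, discount %.1f%%/yr\n",
              x$method, ncol(x$occupancy), nrow(x$occupancy) - 1L,
              x$cycle_length, 100 * x$discount_rate))
  cat(sprintf("discounted totals: cost %.2f, QALYs %.4f\n",
              x$total_cost, x$total_qalys))
  invisible(x)
}

#' Microsimulation estimate of a cohort trace
#'
#' Simulates `n_patients` individual trajectories through the same state
#' space, schedule and rewards as [run_cohort()], by categorical sampling
#' of each patient's next state every cycle. Serves as the engine's
#' independent validation oracle: its occupancy, cost and QALY estimates
#' converge to the deterministic trace, with binomial/empirical standard
#' errors reported.
#'
#' @inheritParams run_cohort
#' @param n_patients number of simulated patients (>= 1)
#' @param seed integer seed; output is deterministic given the seed
#' @return object of class `cohort_trace` with `method = "microsim"` and
#'   additional elements `se_total_cost`, `se_total_qalys`, `occupancy_se`
#' @export
run_microsim <- function(space, schedule, initial, rewards, n_cycles,
                         n_patients, seed, discount_rate = 0) {
  stopifnot(inherits(space, "state_space"), inherits(rewards, "reward_spec"))
  if (n_patients < 1L) stop("n_patients must be at least 1", call. = FALSE)
  S <- length(space$states)
  if (length(initial) != S || abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    stop("initial distribution must be non-negative over all states and sum to 1",
         call. = FALSE)
  }
  schedule <- as_schedule(schedule, space, n_cycles)
  cl <- rewards$cycle_length
  cost_m <- reward_matrix(rewards$state_cost, n_cycles, S)
  util_m <- reward_matrix(rewards$state_utility, n_cycles, S)
  ev <- rewards$event_cost
  if (length(ev) == 1L) ev <- rep(ev, S)
  df <- (1 + discount_rate)^(-(seq_len(n_cycles) - 1L) * cl)

  set.seed(as.integer(seed))
  n <- as.integer(n_patients)
  state <- findInterval(stats::runif(n), cumsum(initial)[-S]) + 1L
  occ <- matrix(0, n_cycles + 1L, S, dimnames = list(0:n_cycles, space$states))
  occ[1L, ] <- tabulate(state, S) / n
  entries <- matrix(0, n_cycles, S, dimnames = list(seq_len(n_cycles) - 1L, space$states))
  cost_i <- numeric(n)
  qaly_i <- numeric(n)
  for (t in seq_len(n_cycles)) {
    M <- schedule[[t]]
    cost_i <- cost_i + cost_m[t, state] * df[t]
    qaly_i <- qaly_i + util_m[t, state] * cl * df[t]
    u <- stats::runif(n)
    nxt <- integer(n)
    for (r in unique(state)) {
      idx <- which(state == r)
      nxt[idx] <- findInterval(u[idx], cumsum(M[r, ])[-S]) + 1L
    }
    moved <- nxt != state
    entries[t, ] <- tabulate(nxt[moved], S) / n
    cost_i <- cost_i + ifelse(moved, ev[nxt], 0) * df[t]
    state <- nxt
    occ[t + 1L, ] <- tabulate(state, S) / n
  }
  out <- list(
    space = space,
    occupancy = occ,
    occupancy_se = sqrt(occ * (1 - occ) / n),
    entries = entries,
    cum_entries = colSums(entries),
    cost_per_cycle = NULL,
    qaly_per_cycle = NULL,
    discount_rate = discount_rate,
    cycle_length = cl,
    total_cost = mean(cost_i),
    total_qalys = mean(qaly_i),
    se_total_cost = stats::sd(cost_i) / sqrt(n),
    se_total_qalys = stats::sd(qaly_i) / sqrt(n),
    n_patients = n,
    method = "microsim"
  )
  class(out) <- "cohort_trace"
  out
}

#' Export a cohort trace as a tidy table
#'
#' @param trace a [run_cohort()] or [run_microsim()] result
#' @param path optional CSV path; when given, the table is also written
#' @return data.frame with columns `cycle, state, occupancy, entries,
#'   cost, qaly, discount_rate` (per-cycle cost/qaly repeated across
#'   states of the same cycle; `NA` for microsimulation traces)
#' @export
trace_table <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- trace$occupancy
  n_cyc <- nrow(occ) - 1L
  states <- colnames(occ)
  out <- data.frame(
    cycle = rep(0:n_cyc, times = length(states)),
    state = rep(states, each = n_cyc + 1L),
    occupancy = as.vector(occ),
    entries = as.vector(rbind(NA, trace$entries)),
    cost = rep(c(trace$cost_per_cycle %||% rep(NA_real_, n_cyc), NA), length(states)),
    qaly = rep(c(trace$qaly_per_cycle %||% rep(NA_real_, n_cyc), NA), length(states)),
    discount_rate = trace$discount_rate,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
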