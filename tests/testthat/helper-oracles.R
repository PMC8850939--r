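# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Exhaustive enumeration of the chemotherapy event tree: per cycle an
# alive patient has five mutually exclusive outcomes (no FN; FN resolved;
# FN+infection resolved; fatal FN; fatal infection). Walks every path and
# returns expected cumulative FN episodes, infections and deaths per
# patient.
enum_chemo_events <- function(p_fn, p_inf, p_death_fn, p_death_inf, n_cycles) {
  recurse <- function(cycle) {
    if (cycle > n_cycles) return(c(fn = 0, inf = 0, deaths = 0))
    cont <- recurse(cycle + 1)
    p_none <- 1 - p_fn
    p_fn_ok <- p_fn * (1 - p_inf) * (1 - p_death_fn)
    p_inf_ok <- p_fn * p_inf * (1 - p_death_inf)
    p_fn_d <- p_fn * (1 - p_inf) * p_death_fn
    p_inf_d <- p_fn * p_inf * p_death_inf
    p_none * cont +
      p_fn_ok * (c(fn = 1, inf = 0, deaths = 0) + cont) +
      p_inf_ok * (c(fn = 1, inf = 1, deaths = 0) + cont) +
      p_fn_d * c(fn = 1, inf = 0, deaths = 1) +
      p_inf_d * c(fn = 1, inf = 1, deaths = 1)
  }
  recurse(1)
}

# Closed-form discounted annuity: constant reward r over cycles 0..n-1.
annuity <- function(r, rate, n, cycle_length = 1) {
  t <- 0:(n - 1)
  sum(r * (1 + rate)^(-t * cycle_length))
}

# Random valid model on S states (last state absorbing) for engine
# property tests.
random_model <- function(S = 4, n_cycles = 6) {
  M <- matrix(stats::rexp(S * S), S, S)
  M[S, ] <- 0
  M[S, S] <- 1
  M <- M / rowSums(M)
  states <- paste0("S", seq_len(S))
  dimnames(M) <- list(states, states)
  init <- stats::rexp(S)
  init[S] <- 0
  init <- init / sum(init)
  rw <- reward_spec(state_cost = stats::runif(S, 0, 100),
                    state_utility = stats::runif(S, 0, 1),
                    event_cost = stats::runif(S, 0, 50),
                    cycle_length = 1)
  list(space = state_space(states, absorbing = states[S]),
       M = M, init = init, rewards = rw, n_cycles = n_cycles)
}

default_profile_small <- function(n = 200) {
  cohort_profile(n_peg = n, n_rhg = n)
}
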