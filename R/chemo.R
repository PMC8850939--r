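## Per-arm view of the chemotherapy-model parameters, with the analysis
## switches applied (infection-risk equalization; per-course FN input
## converted to a per-cycle probability by an even hazard split).
chemo_arm_params <- function(params, arm = c("PEG", "RHG")) {
  arm <- match.arg(arm)
  sfx <- if (arm == "PEG") "peg" else "rhg"
  p_fn <- params[[paste0("p_fn_", sfx)]]
  if (params$fn_input_mode == "per_course") {
    p_fn <- 1 - (1 - p_fn)^(1 / params$n_chemo_cycles)
  }
  p_inf <- if (params$equalize_infection_risk) params$p_inf_fn_rhg else {
    params[[paste0("p_inf_fn_", sfx)]]
  }
  list(arm = arm, p_fn = p_fn, p_inf = p_inf,
       p_death_fn = params$p_death_fn, p_death_inf = params$p_death_inf,
       cost_gcsf = params[[paste0("cost_gcsf_", sfx)]])
}

#' Chemotherapy drug cost per cycle
#'
#' Docetaxel 75 mg/m2 plus cyclophosphamide 600 mg/m2, dosed by body
#' surface area and rounded up to whole vials (20 mg docetaxel, 0.2 g
#' cyclophosphamide per unit) at the listed unit prices.
#'
#' @param params a [cea_parameters()] object
#' @return cost in 2019 CNY per 3-week cycle
#' @export
chemo_drug_cost <- function(params) {
  vials_doce <- ceiling(params$dose_docetaxel_mg_m2 * params$bsa /
                          params$docetaxel_mg_per_unit)
  vials_cyclo <- ceiling(params$dose_cyclo_mg_m2 * params$bsa /
                           params$cyclo_mg_per_unit)
  vials_doce * params$cost_docetaxel_unit + vials_cyclo * params$cost_cyclo_unit
}

## The FN and infection health states are parity-duplicated (FNa/FNb,
## InfA/InfB): a patient whose consecutive cycles both bring an FN episode
## alternates between the two copies, so every episode is an observable
## state ENTRY. Entries carry the per-event hospitalization costs and the
## per-1000 event counts; occupancy carries the cycle utilities. Death
## within the cycle passes through one-cycle tunnel states (DeadFN,
## DeadInf) so that fatal episodes are also countable entries.
chemo_states <- function() {
  state_space(
    c("OnChemo", "FNa", "FNb", "InfA", "InfB", "DeadFN", "DeadInf",
      "Dead", "Completed"),
    absorbing = c("Dead", "Completed")
  )
}

fn_states <- c("FNa", "FNb", "InfA", "InfB", "DeadFN", "DeadInf")
inf_states <- c("InfA", "InfB", "DeadInf")
death_tunnels <- c("DeadFN", "DeadInf")

#' Build the 12-week chemotherapy Markov model for one arm
#'
#' Four 3-week chemotherapy cycles. Each cycle, a patient on treatment
#' develops febrile neutropenia (FN) with the arm's per-cycle probability;
#' given FN, an infection follows with the arm's conditional probability;
#' FN and infection episodes are fatal within the cycle with the
#' respective death probabilities (competing within-cycle outcomes);
#' survivors resume chemotherapy the next cycle. After the final cycle a
#' completion transition moves survivors to the absorbing `Completed`
#' state. Per-cycle state costs are chemotherapy drugs + G-CSF +
#' mean hospitalization; FN and infection episodes additionally incur
#' their per-patient event costs on state entry. Utilities: 0.70 on
#' chemotherapy, 0.33 during FN/infection, weighted by the cycle length
#' in years. No discounting in this model by default.
#'
#' @param params a [cea_parameters()] object
#' @param arm `"PEG"` or `"RHG"`
#' @return list with elements `space`, `schedule` (length
#'   `n_chemo_cycles + 1`), `rewards`, `initial`, `n_cycles`, and the
#'   resolved per-arm probabilities `arm_params`
#' @export
build_chemo_model <- function(params, arm = c("PEG", "RHG")) {
  validate_parameters(params)
  ap <- chemo_arm_params(params, arm)
  space <- chemo_states()
  st <- space$states
  S <- length(st)
  alive <- c("OnChemo", "FNa", "FNb", "InfA", "InfB")

  event_row <- function(from) {
    row <- stats::setNames(numeric(S), st)
    fn_tgt <- if (from == "FNa") "FNb" else "FNa"
    inf_tgt <- if (from == "InfA") "InfB" else "InfA"
    row["OnChemo"] <- 1 - ap$p_fn
    row[fn_tgt] <- ap$p_fn * (1 - ap$p_inf) * (1 - ap$p_death_fn)
    row[inf_tgt] <- ap$p_fn * ap$p_inf * (1 - ap$p_death_inf)
    row["DeadFN"] <- ap$p_fn * (1 - ap$p_inf) * ap$p_death_fn
    row["DeadInf"] <- ap$p_fn * ap$p_inf * ap$p_death_inf
    row
  }
  M_event <- diag(S); dimnames(M_event) <- list(st, st)
  for (s in alive) M_event[s, ] <- event_row(s)
  for (s in death_tunnels) {
    M_event[s, ] <- 0; M_event[s, "Dead"] <- 1
  }
  M_complete <- diag(S); dimnames(M_complete) <- list(st, st)
  for (s in alive) {
    M_complete[s, ] <- 0; M_complete[s, "Completed"] <- 1
  }
  for (s in death_tunnels) {
    M_complete[s, ] <- 0; M_complete[s, "Dead"] <- 1
  }
  n_chemo <- params$n_chemo_cycles
  schedule <- c(rep(list(M_event), n_chemo), list(M_complete))
  n_cycles <- n_chemo + 1L

  cycle_cost <- chemo_drug_cost(params) + ap$cost_gcsf + params$cost_hosp_cycle
  on_treatment <- st %in% alive
  cost_m <- matrix(0, n_cycles, S, dimnames = list(NULL, st))
  cost_m[seq_len(n_chemo), on_treatment] <- cycle_cost
  util_m <- matrix(0, n_cycles, S, dimnames = list(NULL, st))
  util_m[seq_len(n_chemo), "OnChemo"] <- params$u_chemo
  util_m[seq_len(n_chemo), c("FNa", "FNb")] <- params$u_fn
  util_m[seq_len(n_chemo), c("InfA", "InfB")] <- params$u_inf
  ev <- stats::setNames(numeric(S), st)
  ev[fn_states] <- params$cost_fn_inpatient
  ev[inf_states] <- ev[inf_states] + params$cost_inf_given_fn
  rewards <- reward_spec(state_cost = cost_m, state_utility = util_m,
                         event_cost = as.numeric(ev),
                         cycle_length = chemo_cycle_years(params))
  initial <- stats::setNames(numeric(S), st)
  initial["OnChemo"] <- 1
  list(space = space, schedule = schedule, rewards = rewards,
       initial = as.numeric(initial), n_cycles = n_cycles, arm_params = ap)
}

chemo_outcome_from_trace <- function(trace, arm) {
  ce <- trace$cum_entries
  out <- list(
    arm = arm,
    total_cost = trace$total_cost,
    total_qalys = trace$total_qalys,
    fn_per_1000 = 1000 * sum(ce[fn_states]),
    inf_per_1000 = 1000 * sum(ce[inf_states]),
    deaths_per_1000 = 1000 * sum(ce[death_tunnels]),
    p_fn_course = NA_real_,
    trace = trace
  )
  class(out) <- "chemo_outcome"
  out
}

#' Run the chemotherapy model for one arm
#'
#' Runs [build_chemo_model()] on the cohort engine (or, optionally, the
#' microsimulation oracle) and reduces the trace to the per-patient
#' totals and per-1000 event counts. `p_fn_course`, the probability of at
#' least one FN episode over the course, is also reported; it seeds the
#' post-chemotherapy survival model.
#'
#' @param params a [cea_parameters()] object
#' @param arm `"PEG"` or `"RHG"`
#' @param method `"cohort"` (deterministic trace) or `"microsim"`
#' @param n_patients,seed microsimulation size and seed (ignored for the
#'   cohort method)
#' @return object of class `chemo_outcome` with fields `total_cost` (CNY),
#'   `total_qalys`, `fn_per_1000`, `inf_per_1000`, `deaths_per_1000`,
#'   `p_fn_course`, and the underlying `trace`
#' @examples
#' run_chemo_arm(cea_parameters(), "PEG")
#' @export
run_chemo_arm <- function(params, arm = c("PEG", "RHG"),
                          method = c("cohort", "microsim"),
                          n_patients = 1e5, seed = 1) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  m <- build_chemo_model(params, arm)
  trace <- if (method == "cohort") {
    run_cohort(m$space, m$schedule, m$initial, m$rewards, m$n_cycles,
               discount_rate = params$discount_chemo,
               half_cycle = params$half_cycle)
  } else {
    run_microsim(m$space, m$schedule, m$initial, m$rewards, m$n_cycles,
                 n_patients = n_patients, seed = seed,
                 discount_rate = params$discount_chemo)
  }
  out <- chemo_outcome_from_trace(trace, arm)
  out$p_fn_course <- 1 - (1 - m$arm_params$p_fn)^params$n_chemo_cycles
  out
}

#' @export
print.chemo_outcome <- function(x, ...) {
  cat(sprintf("Chemotherapy-model outcome, %s arm\n", x$arm))
  cat(sprintf("  total cost:   %10.2f CNY/patient\n", x$total_cost))
  cat(sprintf("  total QALYs:  %10.4f /patient\n", x$total_qalys))
  cat(sprintf("  per 1000 treated: FN %.1f, infections %.1f, deaths %.1f\n",
              x$fn_per_1000, x$inf_per_1000, x$deaths_per_1000))
  invisible(x)
}

#' Compare two arms of the chemotherapy model
#'
#' @param outcome_peg,outcome_rhg [run_chemo_arm()] results (or any objects
#'   with `total_cost` and `total_qalys` fields)
#' @param wtp willingness-to-pay threshold, CNY/QALY
#' @return a [cea_compare()] result
#' @export
compare_arms <- function(outcome_peg, outcome_rhg, wtp = 72371) {
  cea_compare(cost1 = outcome_peg$total_cost, qaly1 = outcome_peg$total_qalys,
              cost0 = outcome_rhg$total_cost, qaly0 = outcome_rhg$total_qalys,
              wtp = wtp,
              labels = c(outcome_peg$arm %||% "intervention",
                         outcome_rhg$arm %||% "comparator"))
}
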