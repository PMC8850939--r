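test_that("no-event limit reproduces the pure drug/hospitalization cost", {
  params <- cea_parameters(p_fn_peg = 0, p_fn_rhg = 0)
  out <- run_chemo_arm(params, "PEG")
  cycle_cost <- chemo_drug_cost(params) + params$cost_gcsf_peg +
    params$cost_hosp_cycle
  expect_equal(out$total_cost, 4 * cycle_cost, tolerance = 1e-12)
  expect_equal(out$fn_per_1000, 0)
  expect_equal(out$inf_per_1000, 0)
  expect_equal(out$deaths_per_1000, 0)
  expect_equal(out$total_qalys, 4 * 0.70 * 3 / 52.18, tolerance = 1e-12)
})

test_that("certain fatal events kill the whole cohort in the first cycle", {
  params <- cea_parameters(p_fn_peg = 1, p_inf_fn_peg = 1, p_death_inf = 1)
  out <- run_chemo_arm(params, "PEG")
  occ <- out$trace$occupancy
  alive <- c("OnChemo", "FNa", "FNb", "InfA", "InfB")
  expect_equal(sum(occ[2, alive]), 0)
  expect_equal(out$deaths_per_1000, 1000)
  expect_equal(out$fn_per_1000, 1000)
})

test_that("event counts match exhaustive enumeration of the event tree", {
  ## two-cycle model with large probabilities, zero deaths: 1 expected FN
  params <- cea_parameters(p_fn_peg = 0.5, p_inf_fn_peg = 0.5,
                           p_death_fn = 0, p_death_inf = 0,
                           n_chemo_cycles = 2)
  out <- run_chemo_arm(params, "PEG")
  oracle <- enum_chemo_events(0.5, 0.5, 0, 0, 2)
  expect_equal(out$fn_per_1000 / 1000, 1.0, tolerance = 1e-12)
  expect_equal(out$fn_per_1000 / 1000, unname(oracle["fn"]), tolerance = 1e-12)
  expect_equal(out$inf_per_1000 / 1000, unname(oracle["inf"]), tolerance = 1e-12)

  ## with mortality, on both arms' base-case probabilities
  for (arm in c("PEG", "RHG")) {
    p2 <- cea_parameters(n_chemo_cycles = 2)
    out2 <- run_chemo_arm(p2, arm)
    ap <- if (arm == "PEG") c(0.0116, 0.0547) else c(0.0404, 0.547)
    oracle2 <- enum_chemo_events(ap[1], ap[2], 0.034, 0.034, 2)
    expect_equal(out2$fn_per_1000 / 1000, unname(oracle2["fn"]), tolerance = 1e-12)
    expect_equal(out2$inf_per_1000 / 1000, unname(oracle2["inf"]), tolerance = 1e-12)
    expect_equal(out2$deaths_per_1000 / 1000, unname(oracle2["deaths"]),
                 tolerance = 1e-12)
  }
})

test_that("PEG's lower FN risk gives fewer events than rhG in the base case", {
  params <- cea_parameters()
  peg <- run_chemo_arm(params, "PEG")
  rhg <- run_chemo_arm(params, "RHG")
  expect_lt(peg$fn_per_1000, rhg$fn_per_1000)
  expect_lt(peg$inf_per_1000, rhg$inf_per_1000)
  expect_lt(peg$deaths_per_1000, rhg$deaths_per_1000)
  ## structural coupling: infection only follows FN; deaths only follow events
  expect_lte(peg$inf_per_1000, peg$fn_per_1000)
  expect_lte(rhg$deaths_per_1000, rhg$fn_per_1000)
})

test_that("with no events the incremental cost is the pure G-CSF price gap", {
  params <- cea_parameters(p_fn_peg = 0, p_fn_rhg = 0)
  peg <- run_chemo_arm(params, "PEG")
  rhg <- run_chemo_arm(params, "RHG")
  cc <- compare_arms(peg, rhg)
  expect_equal(cc$inc_cost, 4 * (3315.74 - 734.34), tolerance = 1e-9)
  expect_equal(cc$inc_qaly, 0)
  expect_false(cc$icer_defined)
})

test_that("outcomes are monotone in the event probabilities", {
  grid <- seq(0, 0.8, by = 0.2)
  ## fn_per_1000 strictly increasing, QALYs strictly decreasing in p_fn
  res <- vapply(grid, function(p) {
    out <- run_chemo_arm(cea_parameters(p_fn_peg = p), "PEG")
    c(out$fn_per_1000, out$total_qalys, out$total_cost)
  }, numeric(3))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
  ## cost and QALYs monotone in the infection risk
  res_inf <- vapply(grid, function(p) {
    out <- run_chemo_arm(cea_parameters(p_inf_fn_peg = p, p_fn_peg = 0.2), "PEG")
    c(out$total_cost, out$total_qalys)
  }, numeric(2))
  expect_true(all(diff(res_inf[1, ]) >= 0))
  expect_true(all(diff(res_inf[2, ]) <= 0))
})

test_that("equal arm parameters give exactly zero increments", {
  params <- cea_parameters(p_fn_peg = 0.0404, p_inf_fn_peg = 0.547,
                           cost_gcsf_peg = 734.34)
  cc <- compare_arms(run_chemo_arm(params, "PEG"), run_chemo_arm(params, "RHG"))
  expect_identical(cc$inc_cost, 0)
  expect_identical(cc$inc_qaly, 0)
})

test_that("cohort and microsimulation agree on both base-case arms", {
  params <- cea_parameters()
  for (arm in c("PEG", "RHG")) {
    det <- run_chemo_arm(params, arm)
    sim <- run_chemo_arm(params, arm, method = "microsim",
                         n_patients = 5e4, seed = 31)
    expect_lt(abs(sim$total_cost - det$total_cost), 4 * sim$trace$se_total_cost)
    expect_lt(abs(sim$total_qalys - det$total_qalys),
              4 * sim$trace$se_total_qalys + 1e-12)
    n_fn_se <- sqrt(det$fn_per_1000 / 1000 / 5e4) * 1000  # Poisson-ish bound
    expect_lt(abs(sim$fn_per_1000 - det$fn_per_1000), 4 * n_fn_se + 1e-9)
  }
})

test_that("incremental arithmetic, dominance labels and NMB behave", {
  cc <- cea_compare(146091, 3.456, 146055, 3.352)
  expect_equal(cc$inc_cost, 36)
  expect_equal(cc$inc_qaly, 0.104)
  expect_equal(cc$icer, 36 / 0.104, tolerance = 1e-12)  # 346.15...

  dom <- cea_compare(100, 0.6, 110, 0.5)
  expect_equal(dom$status, "dominant")
  expect_equal(dom$nmb, 0.1 * 72371 + 10)

  zero_cost <- cea_compare(100, 0.6, 100, 0.5)
  expect_equal(zero_cost$icer, 0)
  expect_equal(zero_cost$status, "dominant")
})

test_that("analysis switches rescale the inputs coherently", {
  ## per-course FN reading converts through a 1/4 hazard split
  pc <- cea_parameters(fn_input_mode = "per_course")
  out <- run_chemo_arm(pc, "RHG")
  expect_equal(out$p_fn_course, 0.0404, tolerance = 1e-12)
  ## equalized infection risk uses the rhG value in both arms
  eq <- cea_parameters(equalize_infection_risk = TRUE)
  peg_eq <- run_chemo_arm(eq, "PEG")
  peg_v <- run_chemo_arm(cea_parameters(), "PEG")
  expect_gt(peg_eq$inf_per_1000, peg_v$inf_per_1000)
})

test_that("chemotherapy drug cost rounds doses up to whole vials", {
  params <- cea_parameters()  # BSA 1.6: 120 mg docetaxel -> 6 vials; 960 mg cyclo -> 5 vials
  expect_equal(chemo_drug_cost(params), 6 * 1792.74 + 5 * 120.75)
})
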