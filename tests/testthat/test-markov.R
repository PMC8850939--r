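two_state <- function(p_die) {
  space <- state_space(c("A", "Dead"), absorbing = "Dead")
  M <- matrix(c(1 - p_die, p_die, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("A", "Dead"), c("A", "Dead")))
  list(space = space, M = M)
}

test_that("identity chain accrues full utility and constant occupancy", {
  m <- two_state(0)
  rw <- reward_spec(state_utility = c(1, 0), cycle_length = 0.5)
  tr <- run_cohort(m$space, m$M, c(1, 0), rw, n_cycles = 6, discount_rate = 0)
  expect_equal(unname(tr$occupancy[, "A"]), rep(1, 7))
  expect_equal(tr$total_qalys, 6 * 1 * 0.5)
  expect_equal(tr$total_cost, 0)
})

test_that("hand-computed two-cycle survival and the annuity closed form hold", {
  m <- two_state(0.5)
  rw <- reward_spec(state_utility = c(1, 0), cycle_length = 1)
  tr <- run_cohort(m$space, m$M, c(1, 0), rw, n_cycles = 2)
  expect_equal(unname(tr$occupancy[3, "A"]), 0.25)

  ## constant reward r per cycle over 35 annual cycles at 5%/yr
  m0 <- two_state(0)
  rw_c <- reward_spec(state_cost = c(123.4, 0), state_utility = c(1, 0))
  tr35 <- run_cohort(m0$space, m0$M, c(1, 0), rw_c, 35, discount_rate = 0.05)
  expect_equal(tr35$total_cost, annuity(123.4, 0.05, 35), tolerance = 1e-12)
})

test_that("discounted_sum matches hand arithmetic and rejects negative rates", {
  expect_equal(discounted_sum(c(1, 2, 3), 0), 6)
  expect_equal(discounted_sum(c(0, 100), 0.05), 100 / 1.05)
  v <- rep(7, 35)
  expect_equal(discounted_sum(v, 0.05), annuity(7, 0.05, 35), tolerance = 1e-9)
  expect_error(discounted_sum(1:3, -0.01), "non-negative")
})

test_that("non-stochastic matrices and bad initial distributions are rejected", {
  space <- state_space(c("A", "B"), absorbing = "B")
  M_bad <- matrix(c(0.5, 0.4, 0, 1), 2, byrow = TRUE)
  rw <- reward_spec()
  expect_error(run_cohort(space, M_bad, c(1, 0), rw, 2), "sums to")
  M_abs <- matrix(c(0.5, 0.5, 0.1, 0.9), 2, byrow = TRUE)
  expect_error(run_cohort(space, M_abs, c(1, 0), rw, 2), "absorbing")
  M <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE)
  expect_error(run_cohort(space, M, c(0.7, 0.2), rw, 2), "sum to 1")
})

test_that("occupancy conservation and absorbing monotonicity hold for random models", {
  set.seed(101)
  for (rep in 1:10) {
    mod <- random_model(S = 4, n_cycles = 8)
    tr <- run_cohort(mod$space, mod$M, mod$init, mod$rewards, mod$n_cycles,
                     discount_rate = 0.03)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy[, 4]) >= -1e-12))
  }
})

test_that("microsimulation agrees with the deterministic trace", {
  ## deterministic chain: identical output
  space <- state_space(c("A", "B", "Dead"), absorbing = "Dead")
  M <- matrix(c(0, 1, 0,
                0, 0, 1,
                0, 0, 1), 3, byrow = TRUE)
  rw <- reward_spec(state_cost = c(10, 20, 0), state_utility = c(0.9, 0.5, 0))
  tr_c <- run_cohort(space, M, c(1, 0, 0), rw, 3)
  tr_m <- run_microsim(space, M, c(1, 0, 0), rw, 3, n_patients = 50, seed = 1)
  expect_equal(tr_m$occupancy, tr_c$occupancy)
  expect_equal(tr_m$total_cost, tr_c$total_cost)
  expect_equal(tr_m$total_qalys, tr_c$total_qalys)

  ## stochastic: binomial 4-SE agreement at large n
  m2 <- two_state(0.5)
  rw2 <- reward_spec(state_utility = c(1, 0))
  ms <- run_microsim(m2$space, m2$M, c(1, 0), rw2, 1, n_patients = 1e5, seed = 2)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(ms$occupancy[2, "Dead"] - 0.5), 4 * se)

  ## determinism given the seed
  ms2 <- run_microsim(m2$space, m2$M, c(1, 0), rw2, 1, n_patients = 1000, seed = 9)
  ms3 <- run_microsim(m2$space, m2$M, c(1, 0), rw2, 1, n_patients = 1000, seed = 9)
  expect_identical(ms2$occupancy, ms3$occupancy)
})

test_that("discounted QALYs are non-increasing in the discount rate", {
  m <- two_state(0.1)
  rw <- reward_spec(state_utility = c(0.9, 0))
  q <- vapply(c(0.03, 0.05, 0.07), function(r) {
    run_cohort(m$space, m$M, c(1, 0), rw, 35, discount_rate = r)$total_qalys
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("half-cycle correction averages start and end occupancy", {
  m <- two_state(0.5)
  rw <- reward_spec(state_utility = c(1, 0))
  tr <- run_cohort(m$space, m$M, c(1, 0), rw, 1, half_cycle = TRUE)
  expect_equal(tr$total_qalys, 0.75)  # (1 + 0.5)/2
})

test_that("trace export is tidy with one row per cycle-state pair", {
  m <- two_state(0.2)
  rw <- reward_spec(state_utility = c(1, 0))
  tr <- run_cohort(m$space, m$M, c(1, 0), rw, 4)
  tab <- trace_table(tr)
  expect_equal(nrow(tab), 5 * 2)
  expect_equal(sum(tab$occupancy[tab$cycle == 4]), 1)
})
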