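lt <- make_life_table()

test_that("RDI risk equations reproduce the published point estimates", {
  params <- cea_parameters()
  expect_identical(rdi_probability(45, FALSE, params), 0.247)
  expect_identical(rdi_probability(45, TRUE, params), 0.500)
  ## odds-ratio mode: odds 0.247/0.753 * 1.58
  p_or <- rdi_probability(45, TRUE, cea_parameters(rdi_mode = "odds"))
  odds <- 1.58 * 0.247 / 0.753
  expect_equal(p_or, odds / (1 + odds), tolerance = 1e-12)  # ~0.3413
  ## age adjustment multiplies the no-FN baseline
  expect_equal(rdi_probability(70, FALSE, params), 0.247 * 1.38, tolerance = 1e-12)
  expect_error(rdi_probability(10, FALSE, params), "18")
})

test_that("synthetic life table is calibrated and monotone", {
  lx <- cumprod(1 - lt$q_allcause)
  e0 <- sum(lx) + 0.5
  expect_equal(e0, 80, tolerance = 1e-6)
  expect_true(all(diff(lt$q_allcause[lt$age >= 30]) > 0))
  expect_true(all(lt$q_bc >= 0 & lt$q_bc <= 1))
  expect_equal(lt$q_bc[lt$age == 45], mean(c(0.008, 0.018, 0.034)))
  ## decay halves the cancer excess every 5 years beyond year 5
  q50 <- lt$q_bc[lt$age == 50]
  expect_equal(lt$q_bc[lt$age == 55], q50 / 2, tolerance = 1e-12)
})

test_that("life table CSV round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table_csv(lt, path)
  back <- read_life_table_csv(path)
  expect_equal(back$q_allcause, lt$q_allcause, tolerance = 1e-12)
  expect_equal(back$q_bc, lt$q_bc, tolerance = 1e-12)
  bad <- as.data.frame(lt)[, 1:3]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_life_table_csv(path), "missing column")
})

test_that("null hazard ratio makes survival independent of FN history", {
  params <- cea_parameters(hr_mort_rdi = 1)
  a <- run_postchemo_arm(params, lt, p_fn_course = 0)
  b <- run_postchemo_arm(params, lt, p_fn_course = 1)
  expect_equal(a$total_qalys, b$total_qalys, tolerance = 1e-12)
  expect_equal(a$life_years, b$life_years, tolerance = 1e-12)
})

test_that("zero mortality reproduces the discounted utility annuity", {
  zero_lt <- lt
  zero_lt$q_allcause <- 0
  zero_lt$q_bc <- 0
  out <- run_postchemo_arm(cea_parameters(), zero_lt, p_fn_course = 0.1)
  u <- ifelse(0:34 < 5, 0.86, 0.96)
  closed_form <- sum(u * 1.05^-(0:34))  # 16.0504...
  expect_equal(out$total_qalys, closed_form, tolerance = 1e-9)
  expect_equal(out$life_years, 35)
})

test_that("survival curves are monotone and ordered by RDI status", {
  m <- build_postchemo_model(cea_parameters(), lt, p_fn_course = 0.5)
  tr <- run_cohort(m$space, m$schedule, c(0.5, 0.5, 0), m$rewards, m$n_cycles,
                   discount_rate = 0.05)
  surv_low <- tr$occupancy[, "RDIlow"] / 0.5
  surv_ok <- tr$occupancy[, "RDIok"] / 0.5
  expect_true(all(diff(surv_low) <= 1e-12))
  expect_true(all(diff(surv_ok) <= 1e-12))
  expect_true(all(surv_low <= surv_ok + 1e-12))
})

test_that("lower FN-course risk yields more QALYs, bounded by the annuity", {
  params <- cea_parameters()
  q0 <- run_postchemo_arm(params, lt, p_fn_course = 0)$total_qalys
  q1 <- run_postchemo_arm(params, lt, p_fn_course = 1)$total_qalys
  expect_gt(q0, q1)
  u <- ifelse(0:34 < 5, 0.86, 0.96)
  expect_lt(q0, sum(u * 1.05^-(0:34)))
})

test_that("QALYs fall as the discount rate rises and vanish at horizon 0", {
  q <- vapply(c(0.03, 0.05, 0.07), function(r) {
    run_postchemo_arm(cea_parameters(discount_post = r), lt, 0.1)$total_qalys
  }, numeric(1))
  expect_true(all(diff(q) < 0))
  h0 <- run_postchemo_arm(cea_parameters(horizon_years = 0), lt, 0.1)
  expect_equal(h0$total_qalys, 0)
})

test_that("QALY gain grows with the hazard ratio and the FN-risk gap", {
  params <- cea_parameters()
  gap <- function(p, pfn_rhg) {
    peg <- run_postchemo_arm(p, lt, p_fn_course = 0.05)$total_qalys
    rhg <- run_postchemo_arm(p, lt, p_fn_course = pfn_rhg)$total_qalys
    peg - rhg
  }
  dq_hr <- vapply(c(1, 1.4, 1.73, 2.1), function(h) {
    gap(cea_parameters(hr_mort_rdi = h), 0.15)
  }, numeric(1))
  expect_true(all(diff(dq_hr) > 0))
  dq_gap <- vapply(c(0.06, 0.15, 0.3, 0.5), function(pf) gap(params, pf),
                   numeric(1))
  expect_true(all(diff(dq_gap) > 0))
})

test_that("missing life-table coverage is an error", {
  short <- lt[lt$age <= 60, ]
  class(short) <- class(lt)
  expect_error(build_postchemo_model(cea_parameters(), short, 0.1), "cover")
})
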