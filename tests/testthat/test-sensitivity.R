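test_that("explicit beta specs reproduce the published means", {
  expect_equal(fit_distribution(dist_spec("beta", alpha = 289, beta = 881))$mean,
               289 / 1170, tolerance = 1e-12)  # 0.24701...
  expect_equal(fit_distribution(dist_spec("beta", alpha = 40, beta = 6))$mean,
               40 / 46, tolerance = 1e-12)     # 0.8696
  set.seed(1)
  x <- fit_distribution(dist_spec("beta", alpha = 289, beta = 881))$sample(1e5)
  expect_lt(abs(mean(x) - 0.2470) / 0.2470, 0.01)
  set.seed(2)
  y <- fit_distribution(dist_spec("beta", alpha = 40, beta = 6))$sample(1e5)
  expect_lt(abs(mean(y) - 0.8696) / 0.8696, 0.01)
})

test_that("moment-matched samplers recover their moments", {
  set.seed(3)
  g <- fit_distribution(dist_spec("gamma", mean = 25000, se = 3750))
  x <- g$sample(1e5)
  expect_lt(abs(mean(x) - 25000) / 25000, 0.01)
  expect_lt(abs(sd(x) - 3750) / 3750, 0.02)
  set.seed(4)
  b <- fit_distribution(dist_spec("beta", mean = 0.33, se = 0.05))
  y <- b$sample(1e5)
  expect_lt(abs(mean(y) - 0.33) / 0.33, 0.01)
  expect_lt(abs(sd(y) - 0.05) / 0.05, 0.02)
})

test_that("degenerate and invalid distribution specs are handled", {
  f <- fit_distribution(dist_spec("fixed", value = 3.14))
  expect_equal(f$sample(5), rep(3.14, 5))
  expect_error(fit_distribution(dist_spec("beta", mean = 1.2, se = 0.1)), "mean in")
  expect_error(fit_distribution(dist_spec("beta", mean = 0.5, se = 0.9)), "se too large")
  expect_error(fit_distribution(dist_spec("gamma", mean = -5, se = 1)), "positive mean")
  expect_error(fit_distribution(dist_spec("beta", alpha = -1, beta = 2)), "positive")
})

test_that("fixed-spec PSA reproduces the base case bitwise", {
  params <- cea_parameters()
  lt <- make_life_table()
  specs <- default_psa_specs(params)
  fixed <- lapply(names(specs), function(nm) dist_spec("fixed", value = params[[nm]]))
  names(fixed) <- names(specs)
  cloud <- run_psa(params, specs = fixed, n_draws = 3, seed = 1, life_table = lt)
  base <- run_cea(params, life_table = lt)
  expect_identical(unique(cloud$dcost), base$comparison$chemo$inc_cost)
  expect_identical(unique(cloud$dqaly_total), base$comparison$total$inc_qaly)
})

test_that("PSA is reproducible and mean-centred sampling brackets the base case", {
  params <- cea_parameters()
  lt <- make_life_table()
  specs <- default_psa_specs(params, explicit = FALSE)  # all mean-centred
  c1 <- run_psa(params, specs = specs, n_draws = 60, seed = 7, life_table = lt)
  c2 <- run_psa(params, specs = specs, n_draws = 60, seed = 7, life_table = lt)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  base <- run_cea(params, life_table = lt)
  se <- sd(c1$dqaly_chemo) / sqrt(nrow(c1))
  expect_lt(abs(mean(c1$dqaly_chemo) - base$comparison$chemo$inc_qaly), 4 * se)
})

test_that("CEAC boundaries, monotonicity and single-draw logic hold", {
  cloud <- structure(
    data.frame(draw = 1L, dcost = 36, dqaly_chemo = 0.104,
               dqaly_post = 0, dqaly_total = 0.104),
    class = c("psa_cloud", "data.frame"))
  p <- ceac(cloud, wtp_grid = 72371)
  expect_equal(p$probability, 1)  # NMB = 72371*0.104 - 36 > 0
  expect_equal(ceac(cloud, wtp_grid = 0)$probability, 0)  # dcost > 0 at lambda=0

  set.seed(11)
  many <- structure(
    data.frame(draw = 1:200, dcost = rnorm(200, 50, 40),
               dqaly_chemo = 0, dqaly_post = 0,
               dqaly_total = abs(rnorm(200, 0.1, 0.05))),
    class = c("psa_cloud", "data.frame"))
  cv <- ceac(many, wtp_grid = seq(0, 5000, by = 100))
  expect_true(all(diff(cv$probability) >= 0))  # dQALY >= 0 everywhere
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  expect_error(ceac(many, wtp_grid = numeric(0)), "nonempty")
})

test_that("CE-plane export labels quadrants and keeps every draw", {
  cloud <- structure(
    data.frame(draw = 1:4, dcost = c(36, -10, 20, -5),
               dqaly_chemo = 0, dqaly_post = 0,
               dqaly_total = c(0.104, 0.1, -0.2, -0.3)),
    class = c("psa_cloud", "data.frame"))
  pl <- ce_plane_export(cloud)
  expect_equal(nrow(pl), 4)
  expect_equal(pl$quadrant, c("NE", "SE", "NW", "SW"))
})

test_that("irrelevant parameters have zero swing and linear ones are symmetric", {
  params <- cea_parameters()
  lt <- make_life_table()
  ranges <- data.frame(
    parameter = c("u_bc_gt5", "cost_gcsf_peg"),
    low = c(0.96 * 0.9, 3315.74 * 0.85),
    high = c(0.99, 3315.74 * 1.15))
  tor <- one_way_dsa(params, ranges, outcome = "incremental_cost",
                     life_table = lt)
  ## a survivor utility cannot move the chemotherapy-phase cost
  expect_equal(tor$swing[tor$parameter == "u_bc_gt5"], 0)
  ## the G-CSF price enters the incremental cost linearly: symmetric swing
  row <- tor[tor$parameter == "cost_gcsf_peg", ]
  base <- attr(tor, "base_outcome")
  expect_equal(row$outcome_high - base, base - row$outcome_low, tolerance = 1e-9)
})

test_that("tornado entries sort by swing with alphabetical ties, and the PEG price dominates cost", {
  params <- cea_parameters()
  lt <- make_life_table()
  tor <- one_way_dsa(params, outcome = "incremental_cost", life_table = lt)
  expect_true(all(diff(tor$swing) <= 1e-12))
  ties <- abs(diff(tor$swing)) < 1e-12
  if (any(ties)) {
    i <- which(ties)
    expect_true(all(tor$parameter[i] < tor$parameter[i + 1L]))
  }
  ## the PEG unit price has the largest swing among cost parameters
  cost_rows <- tor[startsWith(tor$parameter, "cost_"), ]
  expect_equal(cost_rows$parameter[1], "cost_gcsf_peg")

  expect_error(one_way_dsa(params, data.frame(parameter = "nope", low = 0, high = 1),
                           life_table = lt), "valid names")
})

test_that("discount-rate and horizon scenarios move QALYs the expected way", {
  params <- cea_parameters()
  lt <- make_life_table()
  ranges <- data.frame(parameter = c("discount_post", "horizon_years"),
                       low = c(0.03, 25), high = c(0.07, 45))
  tor <- one_way_dsa(params, ranges, outcome = "incremental_qaly",
                     horizon = "total", life_table = lt)
  dr <- tor[tor$parameter == "discount_post", ]
  expect_gt(dr$outcome_low, dr$outcome_high)  # lower discounting, more QALY gain
  hz <- tor[tor$parameter == "horizon_years", ]
  expect_lt(hz$outcome_low, hz$outcome_high)  # longer horizon, more QALY gain
})
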