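test_that("all-point-mass simulation equals the deterministic engine", {
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  det <- risk_summary(compute_risk(conc, reg))
  sim <- run_simulation(point_specs(conc, reg), reg, iterations = 5, seed = 1)
  for (pop in dust_populations) {
    d <- sim$draws[sim$draws$population == pop, ]
    expect_equal(d$hi, rep(det$hi[det$population == pop], 5),
                 tolerance = 1e-12)
    expect_equal(d$tcr, rep(det$tcr[det$population == pop], 5),
                 tolerance = 1e-12)
  }
  tt <- tidy(sim)
  expect_equal(tt$sd, rep(0, nrow(tt)))
})

test_that("simulations are reproducible and substreams are independent", {
  reg <- default_registry()
  s <- tiny_samples()
  specs <- mc_default_specs(s, reg)
  sim1 <- run_simulation(specs, reg, iterations = 200, seed = 42)
  sim2 <- run_simulation(specs, reg, iterations = 200, seed = 42)
  expect_identical(tidy(sim1), tidy(sim2))

  # dropping a variable leaves the other substreams untouched
  specs_drop <- specs[specs$variable != "conc_V", ]
  sim3 <- run_simulation(specs_drop, reg, iterations = 200, seed = 42)
  expect_identical(sim1$inputs$conc_Zn, sim3$inputs$conc_Zn)
  expect_identical(sim1$inputs$BW_children, sim3$inputs$BW_children)
})

test_that("simulated HI mean matches the deterministic value at the mean", {
  # HI is linear in concentration, so E[HI] is HI at E[c]
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  specs <- point_specs(conc, reg)
  i <- specs$variable == "conc_Zn"
  specs$family[i] <- "lognormal"
  specs$sd[i] <- specs$mean[i] * 0.5
  sim <- run_simulation(specs, reg, iterations = 10000, seed = 3)
  det <- risk_summary(compute_risk(conc, reg))
  d <- sim$draws[sim$draws$population == "children", ]
  se <- sd(d$hi) / sqrt(nrow(d))
  expect_lt(abs(mean(d$hi) - det$hi[det$population == "children"]), 3 * se)
})

test_that("exceedance probabilities hit their bounds and are monotone", {
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  sim <- run_simulation(point_specs(conc, reg), reg, iterations = 10, seed = 2)
  t0 <- sim$draws$tcr[sim$draws$population == "children"][1]
  expect_equal(exceedance(sim, t0 / 2, "tcr", "children")$probability, 1)
  expect_equal(exceedance(sim, t0 * 2, "tcr", "children")$probability, 0)

  specs <- mc_default_specs(tiny_samples(), reg)
  sim2 <- run_simulation(specs, reg, iterations = 500, seed = 4)
  ths <- c(0.01, 0.1, 1, 10)
  probs <- vapply(ths, function(t) {
    exceedance(sim2, t, "hi", "children")$probability
  }, numeric(1))
  expect_true(all(diff(probs) <= 0))
})

test_that("percentiles use type-7 quantiles and collapse for point masses", {
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  sim <- run_simulation(point_specs(conc, reg), reg, iterations = 10, seed = 2)
  q <- mc_percentile(sim, c(0.05, 0.5, 0.95), "hi", "children")
  expect_equal(length(unique(q$value)), 1)

  specs <- mc_default_specs(tiny_samples(), reg)
  sim2 <- run_simulation(specs, reg, iterations = 400, seed = 4)
  q2 <- mc_percentile(sim2, c(0.05, 0.5, 0.95), "hi", "children")
  expect_true(all(diff(q2$value) >= 0))  # nondecreasing in the level
  d <- sim2$draws$hi[sim2$draws$population == "children"]
  expect_equal(q2$value[q2$q == 0.95], quantile(d, 0.95, names = FALSE, type = 7))
})

test_that("sensitivity ranks body weight negative and flags degenerate inputs", {
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  specs <- point_specs(conc, reg)
  i <- specs$variable == "BW_children"
  specs$family[i] <- "lognormal"
  specs$sd[i] <- specs$mean[i] * 0.15
  sim <- run_simulation(specs, reg, iterations = 2000, seed = 6)
  sens <- sensitivity(sim, "hi", "children")
  bw <- sens[sens$variable == "BW_children", ]
  expect_lt(bw$rho, -0.99)  # BW only appears in denominators
  expect_false(bw$degenerate)
  zn <- sens[sens$variable == "conc_Zn", ]
  expect_equal(zn$rho, 0)
  expect_true(zn$degenerate)
})
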