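test_that("fit_lognormal matches the moment-matching formulas", {
  # zero-variance limit
  expect_equal(unname(fit_lognormal(7, 0)), c(log(7), 0))
  # hand-evaluated: sigma^2 = log(1 + (493/640)^2), mu = log(640) - sigma^2/2
  f <- fit_lognormal(640, 493)
  expect_equal(f[["sdlog"]]^2, 0.4659, tolerance = 1e-4)
  expect_equal(f[["meanlog"]], 6.2286, tolerance = 1e-4)
  expect_error(fit_lognormal(-1, 1), class = "roaddust_domain_error")
})

test_that("fit/moments are exact inverses across random targets", {
  set.seed(12)
  for (i in 1:50) {
    m <- runif(1, 0.01, 1000); s <- runif(1, 0, 2) * m
    f <- fit_lognormal(m, s)
    mm <- lognormal_moments(f[["meanlog"]], f[["sdlog"]])
    expect_equal(unname(mm), c(m, s), tolerance = 1e-10)
  }
})

test_that("large-sample draws recover the fitted moments", {
  f <- fit_lognormal(640, 493)
  set.seed(20221129)
  x <- rlnorm(1e6, f[["meanlog"]], f[["sdlog"]])
  expect_equal(mean(x), 640, tolerance = 0.01)
  expect_equal(sd(x), 493, tolerance = 0.01)
})

test_that("truncated calibration matches consistent targets and flags impossible ones", {
  cal <- calibrate_truncated_lognormal(640, 493, 46.9, 1770)
  expect_true(cal$consistent)
  expect_lt(cal$rel_err, 0.01)
  mm <- roaddust:::truncated_lognormal_moments(cal$meanlog, cal$sdlog,
                                               46.9, 1770)
  expect_equal(unname(mm[["mean"]]), 640, tolerance = 1e-6)
  expect_equal(unname(mm[["sd"]]), 493, tolerance = 0.01)

  # mean outside the printed range: flagged, not resolved
  expect_false(calibrate_truncated_lognormal(143, 57.5, 236, 558)$consistent)
  # SD unreachable on a narrow interval: flagged
  expect_false(calibrate_truncated_lognormal(19.2, 5.7, 12.8, 23.8)$consistent)
})

test_that("generate_samples is reproducible and honours degenerate specs", {
  spec <- survey_zone_spec()
  s1 <- suppressWarnings(generate_samples(spec, seed = 5))
  s2 <- suppressWarnings(generate_samples(spec, seed = 5))
  expect_identical(s1, s2)
  s3 <- suppressWarnings(generate_samples(spec, seed = 6))
  expect_false(identical(s1$Zn, s3$Zn))

  point <- tibble::tibble(zone = "industrial", n = 7L, metal = "Zn",
                          mean = 100, sd = 0, min = NA_real_, max = NA_real_)
  sp <- generate_samples(point, seed = 1)
  expect_equal(sp$Zn, rep(100, 7))
})

test_that("calibrated truncation keeps draws in range and recovers the mean", {
  spec <- tibble::tibble(zone = "industrial", n = 10000L, metal = "Zn",
                         mean = 640, sd = 493, min = 46.9, max = 1770)
  s <- generate_samples(spec, seed = 20221129)
  expect_true(all(s$Zn >= 46.9 & s$Zn <= 1770))
  expect_equal(mean(s$Zn), 640, tolerance = 0.03)
  expect_equal(sd(s$Zn), 493, tolerance = 0.03)
})

test_that("vanishing truncation mass is caught, not sampled", {
  # direct draws from a nearly massless interval abort with the label
  expect_error(
    roaddust:::rtrunc_lnorm(10, meanlog = 20, sdlog = 0.1,
                            lower = 46.9, upper = 47.1, label = "industrial Zn"),
    "industrial Zn", class = "roaddust_domain_error"
  )
  # via the generator, an unmatchable spec is flagged and falls back instead
  spec <- tibble::tibble(zone = "industrial", n = 10L, metal = "Zn",
                         mean = 47, sd = 1000, min = 46.9, max = 47.1)
  expect_warning(s <- generate_samples(spec, seed = 1), "inconsistent")
  plan <- attr(s, "generator")
  expect_false(plan$range_consistent)
})

test_that("Dirichlet speciation shares converge to their expectations", {
  s <- suppressWarnings(validate_dust_samples(tibble::tibble(
    sample_id = sprintf("s%04d", 1:1000), zone = "industrial", As = 100
  )))
  rec <- generate_speciation(s, seed = 8)
  expect_true(all(rec$f1 >= 0 & rec$f2 >= 0 & rec$f3 >= 0 & rec$f4 >= 0))
  expect_true(all(rec$f1 + rec$f2 + rec$f3 + rec$f4 <= rec$total + 1e-9))
  resid_share <- 1 - (rec$f1 + rec$f2 + rec$f3 + rec$f4) / rec$total
  expect_gte(mean(resid_share), 0.94)
  expect_lte(mean(resid_share), 0.96)
})

test_that("a huge concentration parameter pins shares to the expectation", {
  s <- suppressWarnings(validate_dust_samples(tibble::tibble(
    sample_id = "a", zone = "industrial", Cu = 100
  )))
  rec <- generate_speciation(s, seed = 2, concentration = 1e9)
  spec <- default_fraction_spec()
  cu <- spec[spec$metal == "Cu", ]
  expect_equal(rec$f4 / rec$total, cu$f4, tolerance = 1e-3)
})

test_that("invalid fraction specs are rejected", {
  s <- suppressWarnings(validate_dust_samples(tibble::tibble(
    sample_id = "a", zone = "industrial", Cu = 100
  )))
  bad <- default_fraction_spec()
  bad$f1[1] <- bad$f1[1] + 0.2
  expect_error(generate_speciation(s, spec = bad, seed = 1),
               class = "roaddust_config_error")
})
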