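child_params <- function() {
  exposure_params(default_registry(), "children")
}

test_that("ingestion dose matches hand evaluation and is linear in BA", {
  p <- list(IngR = 200, EF = 350, ED = 6, BW = 15, AT_nc = 2190)
  expect_equal(add_ingestion(100, 0.5, p), 6.3927e-4, tolerance = 1e-4)
  expect_equal(add_ingestion(0, 0.5, p), 0)
  expect_equal(add_ingestion(100, 1, p) / add_ingestion(100, 0.5, p), 2)
  expect_error(add_ingestion(100, 1.2, p), class = "roaddust_domain_error")
})

test_that("inhalation and dermal doses match hand evaluation", {
  p <- list(InhR = 7.6, EF = 350, ED = 6, BW = 15, AT_nc = 2190, PEF = 1.36e9)
  expect_equal(add_inhalation(100, p), 100 * 7.6 * 350 * 6 / (1.36e9 * 15 * 2190))
  expect_equal(add_inhalation(100, p), 3.57e-8, tolerance = 1e-2)
  expect_equal(add_inhalation(0, p), 0)

  pd <- list(AF = 0.2, SA = 2800, ABS = 0, EF = 350, ED = 6, BW = 15,
             AT_nc = 2190)
  expect_equal(add_dermal(100, pd), 0)
  pd$ABS <- 0.001
  expect_equal(add_dermal(100, pd),
               100 * 0.2 * 2800 * 0.001 * 350 * 6 / (15 * 2190) * 1e-6)
})

test_that("two-stage lifetime dose matches the printed bracket form", {
  pc <- list(IngR = 200, ED = 6, BW = 15, EF = 350, AT_ca = 25550, PEF = 1.36e9)
  pa <- list(IngR = 100, ED = 24, BW = 61.8, EF = 350, AT_ca = 25550)
  # bracket: 200*6/15 + 100*24/61.8 = 118.835
  expect_equal(ladd_lifetime(100, 0.5, pc, pa, "ingestion"),
               100 * 0.5 * 350 / 25550 * (80 + 100 * 24 / 61.8) * 1e-6,
               tolerance = 1e-12)
  expect_equal(ladd_lifetime(100, 0.5, pc, pa, "ingestion"), 8.14e-5,
               tolerance = 1e-3)
  expect_equal(ladd_lifetime(0, 0.5, pc, pa, "ingestion"), 0)
  # equal life-stage brackets double a single stage
  expect_equal(ladd_lifetime(100, 0.5, pc, pc, "ingestion"),
               2 * ladd(100, 0.5, pc, "ingestion"))
  # the literal printed form divides by PEF, suppressing the dose
  expect_equal(ladd_lifetime(100, 0.5, pc, pa, "ingestion", include_pef = TRUE),
               ladd_lifetime(100, 0.5, pc, pa, "ingestion") / 1.36e9)
})

test_that("hazard quotients, cancer risks, and sums behave as defined", {
  expect_equal(hq(3e-4, 3e-4), 1)
  expect_equal(hq(6.3927e-4, 3e-4), 2.131, tolerance = 1e-3)
  expect_equal(hi(c(0.2, 0.3, 0.5)), 1.0)
  expect_equal(cr(8.14e-5, 1.5), 1.221e-4, tolerance = 1e-3)
  expect_equal(cr(8.14e-5, 0), 0)
  expect_equal(tcr(5e-6), 5e-6)
})

test_that("advisory labels use the published thresholds", {
  expect_equal(as.character(classify_hi(1.2)), "noncarcinogenic concern")
  expect_equal(as.character(classify_hi(0.9)), "negligible")
  expect_equal(as.character(classify_cr(5e-7)), "negligible")
  expect_equal(as.character(classify_cr(5e-5)), "tolerable")
  expect_equal(as.character(classify_cr(2e-4)), "unacceptable")
})

test_that("compute_risk is homogeneous of degree 1 in concentration", {
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  r1 <- risk_summary(compute_risk(conc, reg))
  conc2 <- dplyr::mutate(conc, concentration = concentration * 2)
  r2 <- risk_summary(compute_risk(conc2, reg))
  expect_equal(r2$hi, 2 * r1$hi, tolerance = 1e-12)
  expect_equal(r2$tcr, 2 * r1$tcr, tolerance = 1e-12)
})

test_that("BA = 1 reproduces total content; BA < 1 only lowers ingestion", {
  reg <- default_registry()
  conc <- mean_conc(tiny_samples())
  total <- compute_risk(conc, reg, ba = NULL)
  ba1 <- compute_risk(conc, reg,
                      ba = tibble::tibble(metal = conc$metal, ba = 1))
  expect_equal(tidy(ba1)$hq, tidy(total)$hq, tolerance = 1e-15)
  expect_equal(tidy(ba1)$cr, tidy(total)$cr, tolerance = 1e-15)

  half <- compute_risk(conc, reg,
                       ba = tibble::tibble(metal = conc$metal, ba = 0.5))
  t_total <- tidy(total); t_half <- tidy(half)
  ing <- t_total$route == "ingestion"
  expect_true(all(t_half$hq[ing] < t_total$hq[ing]))
  expect_equal(t_half$hq[!ing], t_total$hq[!ing])  # other routes untouched
})

test_that("per-metal contribution shares sum to one", {
  reg <- default_registry()
  r <- compute_risk(mean_conc(tiny_samples()), reg)
  contrib <- risk_contributions(r)
  sums <- contrib |>
    dplyr::group_by(population) |>
    dplyr::summarise(hi = sum(hi_share), tcr = sum(tcr_share))
  expect_equal(sums$hi, rep(1, 3), tolerance = 1e-12)
  expect_equal(sums$tcr, rep(1, 3), tolerance = 1e-12)
})

test_that("default exposure parameters order the populations as reported", {
  reg <- default_registry()
  s <- risk_summary(compute_risk(mean_conc(tiny_samples()), reg))
  hi <- setNames(s$hi, s$population)
  tcr <- setNames(s$tcr, s$population)
  expect_gt(hi[["children"]], hi[["adult_women"]])
  expect_gt(hi[["adult_women"]], hi[["adult_men"]])
  expect_gt(tcr[["children"]], tcr[["adult_women"]])
  expect_gt(tcr[["adult_women"]], tcr[["adult_men"]])
})
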