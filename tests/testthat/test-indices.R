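test_that("igeo matches its definition and published one-decimal values", {
  expect_equal(igeo(1.5 * 47.3, 47.3), 0)
  # survey means vs local background, printed to one decimal
  expect_equal(round(igeo(640, 47.3), 1), 3.2)
  expect_equal(round(igeo(0.74, 0.06), 1), 3.0)
  expect_warning(v <- igeo(0, 10), "-Inf")
  expect_identical(v, -Inf)
  expect_error(igeo(10, 0), class = "roaddust_domain_error")
})

test_that("igeo is increasing in concentration and decreasing in background", {
  set.seed(42)
  for (i in 1:50) {
    c1 <- runif(1, 1, 1000); b <- runif(1, 1, 100); eps <- runif(1, 0.1, 10)
    expect_gt(igeo(c1 + eps, b), igeo(c1, b))
    expect_lt(igeo(c1, b + eps), igeo(c1, b))
  }
})

test_that("igeo classes follow the seven-class half-open scheme", {
  expect_equal(as.integer(classify_igeo(3.2)) - 1L, 4L)  # heavily polluted
  expect_equal(as.integer(classify_igeo(2.0)) - 1L, 3L)  # boundary goes up
  expect_equal(as.integer(classify_igeo(-1.0)) - 1L, 0L)
  expect_equal(as.integer(classify_igeo(-Inf)) - 1L, 0L)
  expect_equal(as.integer(classify_igeo(7.3)) - 1L, 6L)
})

test_that("ini matches the quadratic-mean definition", {
  expect_equal(ini(c(1, 2, 3)), sqrt((9 + 4) / 2))
  for (g in c(0, 0.5, 2, 4)) expect_equal(ini(rep(g, 5)), g)
  expect_equal(ini(-2), 2)  # single value: |g|
  expect_error(ini(numeric(0)), class = "roaddust_domain_error")
  # bounds for nonnegative inputs
  set.seed(7)
  for (i in 1:50) {
    v <- runif(sample(2:8, 1), 0, 6)
    expect_gte(ini(v) + 1e-12, abs(mean(v)) / sqrt(2))
    expect_lte(ini(v), max(v) + 1e-12)
  }
})

test_that("er and ri follow the toxicity-weighted contamination sum", {
  expect_equal(er(0.74, 0.06, 30), 370)
  expect_equal(er(12.3, 12.3, 7), 7)   # c = b gives Er = Tr
  ers <- setNames(rep(1, 8), dust_metals)
  expect_equal(ri(ers), 8)
  expect_equal(ri(c(Cd = 370), subset = TRUE), 370)
  expect_error(ri(c(Cd = 370)), "eight metals",
               class = "roaddust_validation_error")
})

test_that("er/ri agree with brute-force re-evaluation on random inputs", {
  set.seed(101)
  for (i in 1:1000) {
    c1 <- runif(1, 0, 2000); b <- runif(1, 0.01, 100); tr <- runif(1, 1, 30)
    direct <- tr * (c1 / b)
    expect_equal(er(c1, b, tr), direct, tolerance = 1e-12)
  }
  # additivity over disjoint metal subsets
  set.seed(102)
  ers <- setNames(runif(8, 0, 500), dust_metals)
  a <- dust_metals[1:3]; b <- dust_metals[4:8]
  expect_equal(ri(ers[a], subset = TRUE) + ri(ers[b], subset = TRUE),
               ri(ers))
})

test_that("ri classes resolve the boundary overlap as half-open bins", {
  expect_equal(as.character(classify_ri(495)), "considerable")
  expect_equal(as.character(classify_ri(150)), "moderate")
  expect_equal(as.character(classify_ri(1698)), "high")
  expect_equal(as.character(classify_ri(0)), "low")
})

test_that("enrichment ratios reproduce the published extremes", {
  expect_equal(round(enrichment_ratio(640, 47.3), 1), 13.5)
  expect_equal(round(enrichment_ratio(0.72, 0.06), 1), 12.0)
  expect_equal(enrichment_ratio(33.3, 33.3), 1)
})

test_that("assess_contamination is internally consistent per sample", {
  s <- tiny_samples()
  reg <- default_registry()
  idx <- assess_contamination(s, reg)
  er_cols <- paste0("er_", dust_metals)
  expect_equal(idx$ri, rowSums(as.matrix(idx[, er_cols])))
  igeo_cols <- paste0("igeo_", dust_metals)
  for (i in seq_len(nrow(idx))) {
    expect_equal(idx$ini[i], ini(unlist(idx[i, igeo_cols])))
  }
  expect_s3_class(idx$ri_class, "factor")
})
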