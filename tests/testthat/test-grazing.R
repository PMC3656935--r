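cc <- model_constants()

# numerically integrate the exponential depletion to get mean concentration
# and ingestion, as an oracle independent of the closed form
frost_oracle <- function(control_k, c0, ct, t, volume, n_copepods) {
  g <- control_k - log(ct / c0) / t
  conc <- function(s) c0 * exp((control_k - g) * s)
  cbar <- stats::integrate(conc, 0, t, rel.tol = 1e-10)$value / t
  Fc <- volume * g / n_copepods
  list(g = g, clearance = Fc, mean_cells = cbar, ingestion = Fc * cbar)
}

test_that("algal growth rate is the log-ratio rate", {
  expect_equal(algal_growth_rate(1000, 1000, 1), 0)
  expect_equal(algal_growth_rate(1000, 2000, 1), log(2))
  expect_equal(algal_growth_rate(1921, 2400, 2), 0.11132, tolerance = 1e-4)
  expect_error(algal_growth_rate(0, 100, 1), "> 0")
  expect_error(algal_growth_rate(100, 100, 0), "duration")
})

test_that("Frost rates match the worked bottle example", {
  fr <- frost_rates(0.1, 1921, 1200, 1, 610, 12)
  expect_equal(fr$g, 0.570524, tolerance = 1e-5)
  expect_equal(fr$clearance, 29.0017, tolerance = 1e-4)
  expect_equal(fr$mean_cells, 1532.33, tolerance = 1e-4)
  expect_equal(fr$ingestion, 44440.2, tolerance = 1e-4)
  expect_false(fr$negative_grazing)
})

test_that("Frost closed form agrees with a numerical-integration oracle", {
  set.seed(14)
  for (i in 1:20) {
    k <- runif(1, 0, 0.7); g <- runif(1, 0.01, 1)
    c0 <- runif(1, 500, 5000); t <- runif(1, 0.5, 3)
    V <- runif(1, 200, 1000); n <- sample(5:20, 1)
    ct <- c0 * exp((k - g) * t)
    fr <- frost_rates(k, c0, ct, t, V, n)
    o <- frost_oracle(k, c0, ct, t, V, n)
    expect_equal(fr$ingestion, o$ingestion, tolerance = 1e-3)
    expect_equal(fr$mean_cells, o$mean_cells, tolerance = 1e-3)
  }
})

test_that("treatment growing exactly like controls gives zero ingestion", {
  fr <- frost_rates(0.3, 1500, 1500 * exp(0.3), 1, 610, 10)
  expect_equal(fr$g, 0, tolerance = 1e-12)
  expect_equal(fr$ingestion, 0, tolerance = 1e-6)
})

test_that("the removable singularity at k = g gives mean cells = c0", {
  # grazing exactly balances growth: ct = c0, so k - g = 0 and Cbar -> c0
  fr <- frost_rates(0.3, 1500, 1500, 1, 610, 10)
  expect_equal(fr$g, 0.3, tolerance = 1e-12)
  expect_equal(fr$mean_cells, 1500, tolerance = 1e-9)
  # approach to the singularity is continuous
  eps <- 1e-7
  near <- frost_rates(0.3, 1500, 1500 * exp(-eps), 1, 610, 10)
  expect_equal(near$mean_cells, 1500, tolerance = 1e-5)
})

test_that("treatment outgrowing controls yields a flagged negative rate", {
  expect_warning(fr <- frost_rates(0.1, 1000, 1500, 1, 610, 10),
                 "negative")
  expect_lt(fr$g, 0)
  expect_true(fr$negative_grazing)
  expect_lt(fr$ingestion, 0)  # reported as-is, not clipped
})

test_that("Frost rates are invariant to joint rescaling of the cell ratio", {
  a <- frost_rates(0.2, 1000, 700, 1, 610, 10)
  b <- frost_rates(0.2, 3000, 2100, 1, 610, 10)
  expect_equal(a$g, b$g, tolerance = 1e-12)
  expect_equal(b$mean_cells, 3 * a$mean_cells, tolerance = 1e-12)
})

test_that("carbon-specific ingestion applies the cell-carbon/dry-weight chain", {
  expect_equal(carbon_specific_ingestion(0, 55, 4.045), 0)
  expect_equal(carbon_specific_ingestion(37582, 55, 4.045), 511.0,
               tolerance = 1e-3)
  # linear in I and cell carbon, inverse-linear in dry weight
  expect_equal(carbon_specific_ingestion(200, 55, 4),
               2 * carbon_specific_ingestion(100, 55, 4))
  expect_equal(carbon_specific_ingestion(100, 110, 4),
               2 * carbon_specific_ingestion(100, 55, 4))
  expect_equal(carbon_specific_ingestion(100, 55, 8),
               carbon_specific_ingestion(100, 55, 4) / 2)
  expect_equal(food_carbon_concentration(1921, 55), 105.655)
})

test_that("t-test modes agree with textbook formulas", {
  # pooled two-sample: means 12 vs 22, s2 = 4 each
  a <- c(10, 12, 14); b <- c(20, 22, 24)
  res <- compare_treatments(a, b, mode = "student")
  se <- sqrt(4 * (1 / 3 + 1 / 3))
  t_hand <- (12 - 22) / se
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-9)
  # Welch on unequal variances
  set.seed(6)
  x <- rnorm(5, 10, 1); y <- rnorm(7, 12, 3)
  w <- compare_treatments(x, y, mode = "welch")
  se_w <- sqrt(var(x) / 5 + var(y) / 7)
  t_w <- (mean(x) - mean(y)) / se_w
  df_w <- se_w^4 / ((var(x) / 5)^2 / 4 + (var(y) / 7)^2 / 6)
  expect_equal(w$t, t_w, tolerance = 1e-9)
  expect_equal(w$df, df_w, tolerance = 1e-9)
  # paired by experiment: df = n_pairs - 1
  p <- compare_treatments(c(1, 2, 3), c(2, 4, 6), mode = "paired")
  d <- c(1, 2, 3) - c(2, 4, 6)
  expect_equal(p$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-9)
  expect_equal(p$df, 2)
  # identical groups
  same <- compare_treatments(c(1, 2, 3), c(1, 2, 3), mode = "student")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  zp <- compare_treatments(c(1, 2, 3), c(1, 2, 3), mode = "paired")
  expect_equal(zp$df, 2)
  expect_error(compare_treatments(1, c(1, 2), mode = "student"),
               "at least 2")
  expect_error(compare_treatments(c(1, 2), c(1, 2, 3), mode = "paired"),
               "equal-length")
})

test_that("the grazing pipeline pools controls per experiment", {
  b <- gen_bottles(seed = 2, cv = 0)
  gr <- grazing_rates(b)
  truth <- attr(b, "truth")
  # control k recovered exactly without noise
  expect_equal(unique(round(gr$control_k, 10)),
               round(truth$control_k, 10))
  rec <- tapply(gr$ingestion_ugC, gr$treatment, mean)
  expect_equal(rec[["normoxic"]], 511, tolerance = 1e-6)
  expect_equal(rec[["hypoxic"]], 146, tolerance = 1e-6)
  expect_equal(nrow(gr), 18)  # 3 experiments x 2 treatments x 3 bottles
  # missing controls are an error
  expect_error(grazing_rates(b[b$role == "grazing", ]), "no control")
})

test_that("bottle CSV reader validates its columns", {
  tmp <- tempfile(fileext = ".csv")
  b <- gen_bottles(seed = 1, cv = 0)
  utils::write.csv(b, tmp, row.names = FALSE)
  back <- read_bottles(tmp)
  expect_equal(nrow(back), nrow(b))
  utils::write.csv(b[, -4], tmp, row.names = FALSE)
  expect_error(read_bottles(tmp), "lacks column")
})
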