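cc <- model_constants()

test_that("the oxygen-limitation line evaluates and floors at zero", {
  expect_equal(arr_at(1.6, cc), 35.34)
  expect_equal(arr_at(0, cc), 0)
  expect_equal(arr_at(0.5, cc), 0)  # below the root at ~0.587 kPa
  expect_gt(arr_at(0.6, cc), 0)
  expect_equal(arr_at(8.0802292, cc), 261.5, tolerance = 1e-6)
  expect_error(arr_at(-1, cc), ">= 0")
})

test_that("thresholds reproduce the published values", {
  expect_equal(round(pcrit(18, 25, cc), 1), 8.1)
  expect_equal(round(pleth(18, 25, cc), 1), 3.2)
  expect_equal(round(pcrit(5, 25, cc), 1), 3.6)    # Q10 = 2.03
  expect_equal(round(pcrit(-1, 25, cc), 1), 2.5)
  expect_equal(round(pcrit(32, 25, cc), 1), 20.8)
  expect_equal(round(pleth(20, 30, cc), 1), 3.6)   # Q10 interpolated 2.125
})

test_that("threshold identity: line at the threshold equals the scaled rate", {
  grid <- expand.grid(T = seq(-1, 32, by = 3), S = seq(0, 40, by = 5))
  q <- q10_for_salinity(grid$S, cc)
  expect_equal(arr_at(pcrit(grid$T, grid$S, cc), cc),
               q10_scale(cc$TRR, 18, grid$T, q), tolerance = 1e-9)
  expect_equal(arr_at(pleth(grid$T, grid$S, cc), cc),
               q10_scale(cc$MRR, 18, grid$T, q), tolerance = 1e-9)
})

test_that("pleth < pcrit everywhere; both increase with T and S", {
  grid <- expand.grid(T = seq(-1, 32, by = 1), S = seq(0, 40, by = 4))
  expect_true(all(pleth(grid$T, grid$S, cc) < pcrit(grid$T, grid$S, cc)))
  expect_true(all(pleth(grid$T, grid$S, cc) > 0))
  tseq <- seq(-1, 32, by = 0.5)
  expect_true(all(diff(pcrit(tseq, 25, cc)) > 0))
  expect_true(all(diff(pleth(tseq, 25, cc)) > 0))
  sseq <- seq(15, 35, by = 1)
  expect_true(all(diff(pcrit(20, sseq, cc)) >= 0))
})

test_that("threshold table carries the quoted standard errors", {
  th <- hypoxia_thresholds(c(5, 18), 25, cc)
  expect_equal(th$pcrit_se, c(1.7, 1.7))
  expect_equal(th$pleth_se, c(1.7, 1.7))
  expect_equal(th$pcrit[2], 8.0802, tolerance = 1e-4)
  expect_equal(th$q10, c(2.03, 2.03))
})

test_that("mortality endpoints: 0 at the lethal threshold, ~1 at half of it", {
  pl <- pleth(18, 25, cc)
  expect_equal(mortality_24h(pl, 18, 25, cc), 0)
  expect_equal(mortality_24h(pl / 2, 18, 25, cc), 1)
  # the paper's rounded endpoints: 3.2 kPa -> ~0, 1.6 kPa -> ~100 %
  expect_lt(mortality_24h(3.2, 18, 25, cc), 0.005)
  expect_gt(mortality_24h(1.6, 18, 25, cc), 0.995)
  expect_equal(mortality_24h(2.4, 18, 25, cc), 0.497578, tolerance = 1e-5)
})

test_that("mortality is non-increasing, continuous, and properly clamped", {
  po2 <- seq(0, 6, by = 0.005)
  m <- mortality_24h(po2, 18, 25, cc)
  expect_true(all(diff(m) <= 1e-12))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(abs(diff(m)) < 0.01))  # no jumps on a fine grid
  expect_equal(m[po2 >= pleth(18, 25, cc)],
               rep(0, sum(po2 >= pleth(18, 25, cc))))
  expect_equal(m[po2 <= pleth(18, 25, cc) / 2],
               rep(1, sum(po2 <= pleth(18, 25, cc) / 2)))
  # raw (unclamped) interpolant is exposed on request
  mr <- mortality_24h(0.2, 18, 25, cc, raw = TRUE)
  expect_gt(mr$m_raw, 1)
  expect_equal(mr$m, 1)
})

test_that("back-conversion coefficients match the published model table", {
  expect_equal(egg_production(1, cc), 1 / 264)
  expect_equal(round(egg_production(1, cc), 5), 0.00379)
  expect_equal(egg_production(100, cc), 0.3788, tolerance = 1e-3)
  expect_equal(somatic_growth(1, cc), 1.014, tolerance = 1e-12)
  expect_equal(somatic_growth(100, cc), 101.4, tolerance = 1e-12)
  expect_equal(egg_production(0, cc), 0)
  expect_equal(somatic_growth(0, cc), 0)
})

test_that("classification splits none / sublethal / lethal at the thresholds", {
  d <- data.frame(temperature = 18, salinity = 10, po2 = c(15, 5, 2))
  pr <- predict_hypoxia_effects(d, cc)
  expect_equal(as.character(pr$effect), c("none", "sublethal", "lethal"))
  # no-effect rows carry no rate predictions
  expect_true(all(is.na(pr[1, c("arr", "egg_production", "somatic_growth",
                                "mortality_24h")])))
  expect_equal(pr$mortality_24h[2], 0)
  expect_true(pr$mortality_24h[3] > 0 && pr$mortality_24h[3] < 1)
  expect_equal(pr$arr[3], arr_at(2, cc))
  expect_equal(pr$egg_production[2], egg_production(arr_at(5, cc), cc))
  expect_equal(pr$somatic_growth[2], somatic_growth(arr_at(5, cc), cc))
})

test_that("classification at exact threshold equality follows the conventions", {
  pc <- pcrit(18, 10, cc); pl <- pleth(18, 10, cc)
  d <- data.frame(temperature = 18, salinity = 10, po2 = c(pc, pl))
  pr <- predict_hypoxia_effects(d, cc)
  expect_equal(as.character(pr$effect), c("none", "sublethal"))
  expect_equal(pr$mortality_24h[2], 0)
})

test_that("rates approach the target-rate predictions just below pcrit", {
  pc <- pcrit(18, 10, cc)
  eps <- 1e-9
  pr <- predict_hypoxia_effects(
    data.frame(temperature = 18, salinity = 10, po2 = pc - eps), cc)
  expect_equal(pr$arr, cc$TRR, tolerance = 1e-6)
  expect_equal(pr$egg_production, egg_production(cc$TRR, cc),
               tolerance = 1e-6)
})

test_that("batch prediction preserves order, labels, and handles empty input", {
  expect_equal(nrow(predict_hypoxia_effects(
    data.frame(temperature = numeric(), salinity = numeric(),
               po2 = numeric()), cc)), 0)
  d <- data.frame(label = c("st1", "st2"), temperature = c(25, 10),
                  salinity = c(12, 30), po2 = c(3, 3))
  pr <- predict_hypoxia_effects(d, cc)
  expect_equal(pr$label, c("st1", "st2"))
  expect_equal(pr$po2_kpa, c(3, 3))
  bad <- data.frame(temperature = 18, salinity = 10, po2 = c(5, -1))
  expect_error(predict_hypoxia_effects(bad, cc), "row")
})
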