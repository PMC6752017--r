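test_that("net product formation subtracts the control change", {
  m <- two_point_measurements(0, 150, 0, 50)
  net <- net_product_formation(m, "glutamate", "control")
  expect_equal(net$net, 100)
  expect_true(net$formed)

  m2 <- two_point_measurements(0, 10, 0, 25)
  net2 <- net_product_formation(m2, "glutamate", "control")
  expect_equal(net2$net, 0)
  expect_false(net2$formed)

  # treatment identical to control: nothing is formed
  m3 <- rbind(two_point_measurements(5, 80, 5, 80),
              two_point_measurements(0, 30, 0, 30, analyte = "co2"))
  net3 <- net_product_formation(m3, "glutamate", "control")
  expect_true(all(!net3$formed))
  expect_true(all(net3$net == 0))
})

test_that("missing control analytes warn; missing endpoints error", {
  m <- two_point_measurements(0, 150, 0, 50)
  m <- rbind(m, data.frame(treatment = "glutamate", replicate = 1,
                           time_h = c(0, 30), analyte = "h2",
                           amount = c(0, 40)))
  expect_warning(net <- net_product_formation(m, "glutamate", "control"),
                 "h2")
  expect_equal(net$net[net$analyte == "h2"], 40)
  expect_error(net_product_formation(m, "glutamate", "control", t_end = 24),
               "t_end = 24")
})

test_that("carbon and electron recoveries match hand arithmetic", {
  # 100 umol/gFW glutamate (5 C, 18 e-), sole product 150 umol/gFW acetate
  m <- two_point_measurements(0, 150, 0, 0)
  net <- net_product_formation(m, "glutamate", "control")
  dose <- substrate_dose("glutamate", 100)
  cc <- carbon_recovery(net, dose)
  re <- electron_recovery(net, dose)
  expect_equal(as.numeric(cc["acetate"]), 150 * 2 / (100 * 5) * 100)  # 60
  expect_equal(attr(cc, "total"), 60)
  expect_equal(as.numeric(re["acetate"]), 150 * 8 / (100 * 18) * 100)
  expect_equal(attr(re, "total"), 200 / 3, tolerance = 1e-12)
})

test_that("NA semantics: H2 has no carbon entry, CO2 no electron entry", {
  m <- rbind(two_point_measurements(0, 100, 0, 0, analyte = "co2"),
             two_point_measurements(0, 40, 0, 0, analyte = "h2"))
  net <- net_product_formation(m, "glutamate", "control")
  rt <- recovery_table(net, substrate_dose("glutamate", 100))
  expect_true(is.na(rt$carbon[rt$product == "h2"]))
  expect_true(is.na(rt$reducing_equivalents[rt$product == "co2"]))
  expect_false(is.na(rt$carbon[rt$product == "co2"]))
  tot <- attr(rt, "totals")
  expect_equal(tot[["carbon"]], 100 * 100 * 1 / (100 * 5))
  expect_equal(tot[["reducing_equivalents"]], 100 * 40 * 2 / (100 * 18))
})

test_that("products that exactly rewrite the substrate recover 100%", {
  # glutamate -> 2 acetate + 1 CO2 + 1 H2 per mol, full consumption
  m <- rbind(two_point_measurements(0, 200, 0, 0, analyte = "acetate"),
             two_point_measurements(0, 100, 0, 0, analyte = "co2"),
             two_point_measurements(0, 100, 0, 0, analyte = "h2"))
  net <- net_product_formation(m, "glutamate", "control")
  rt <- recovery_table(net, substrate_dose("glutamate", 100))
  expect_equal(attr(rt, "totals")[["carbon"]], 100, tolerance = 1e-12)
  expect_equal(attr(rt, "totals")[["reducing_equivalents"]], 100,
               tolerance = 1e-12)
})

test_that("provided and consumed bases agree when consumption is complete", {
  m <- rbind(two_point_measurements(0, 150, 0, 0),
             data.frame(treatment = "glutamate", replicate = 1,
                        time_h = c(0, 30), analyte = "glutamate",
                        amount = c(100, 0)))
  net <- net_product_formation(m, "glutamate", "control",
                               analytes = "acetate")
  d_prov <- substrate_dose("glutamate", 100, basis = "provided")
  d_cons <- substrate_dose("glutamate", 100, basis = "consumed",
                           measurements = m, treatment = "glutamate")
  expect_equal(d_cons$amount, 100)
  expect_equal(carbon_recovery(net, d_prov), carbon_recovery(net, d_cons))
  # apparent negative consumption clamps to zero with a warning
  m_neg <- m
  m_neg$amount[m_neg$analyte == "glutamate"] <- c(100, 120)
  expect_warning(
    d0 <- substrate_dose("glutamate", 100, basis = "consumed",
                         measurements = m_neg, treatment = "glutamate"),
    "clamped")
  expect_equal(d0$amount, 0)
})

test_that("recoveries are invariant under a consistent unit change", {
  m <- two_point_measurements(0, 150, 0, 0)
  net <- net_product_formation(m, "glutamate", "control")
  m_mM <- m
  m_mM$amount <- convert_amount(m$amount, "umol_per_gFW", "mM")
  net_mM <- net_product_formation(m_mM, "glutamate", "control")
  dose_mM <- substrate_dose("glutamate",
                            convert_amount(100, "umol_per_gFW", "mM"))
  expect_equal(as.numeric(carbon_recovery(net_mM, dose_mM)),
               as.numeric(carbon_recovery(net, substrate_dose("glutamate", 100))))
})

test_that("collective products sum per replicate and report mean and SD", {
  m <- two_point_measurements(0, 100, 0, 0, reps = 3)
  cp <- collective_products(m, "glutamate", "control")
  expect_equal(unname(cp$per_replicate), c(100, 100, 100))
  expect_equal(cp$sd, 0)
  # hand-built 3 replicates x 3 analytes with distinct sums
  rows <- list()
  amounts <- rbind(c(10, 20, 30), c(15, 25, 35), c(5, 10, 15))
  for (r in 1:3) for (j in 1:3) {
    rows[[length(rows) + 1]] <- data.frame(
      treatment = "thr", replicate = r, time_h = c(0, 30),
      analyte = paste0("a", j), amount = c(0, amounts[r, j]))
  }
  for (r in 1:3) for (j in 1:3) {
    rows[[length(rows) + 1]] <- data.frame(
      treatment = "control", replicate = r, time_h = c(0, 30),
      analyte = paste0("a", j), amount = c(0, 0))
  }
  cp2 <- collective_products(do.call(rbind, rows), "thr", "control")
  expect_equal(unname(cp2$per_replicate), c(60, 75, 30))
  expect_equal(cp2$mean, 55)
  expect_equal(cp2$sd, sd(c(60, 75, 30)))
})

test_that("the Welch test matches stats::t.test and is antisymmetric", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  ref <- t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-12)
  wr <- welch_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(wr$statistic, -w$statistic)
  expect_equal(wr$p.value, w$p.value)
  # identical groups with spread: t = 0, p = 1
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)
})

test_that("degenerate zero-variance groups are handled explicitly", {
  expect_warning(w1 <- welch_t_test(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(w1$p.value, 1)
  expect_warning(w2 <- welch_t_test(c(2, 2), c(5, 5)), "degenerate")
  expect_equal(w2$p.value, 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("ammonium calibration inverts the standard curve and flags range", {
  std <- data.frame(concentration = c(0, 10), absorbance = c(0, 1))
  out <- ammonium_calibration(std, c(0.5, 1.5))
  expect_equal(out$concentration, c(5, 15))
  expect_identical(out$extrapolated, c(FALSE, TRUE))
  # noisy standards: slope equals the normal-equations solution
  set.seed(11)
  std2 <- data.frame(concentration = c(0, 5, 10, 20, 40))
  std2$absorbance <- 0.02 + 0.031 * std2$concentration + rnorm(5, 0, 0.01)
  fit <- attr(ammonium_calibration(std2, 0.5), "fit")
  x <- std2$concentration; y <- std2$absorbance
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(coef(fit)["concentration"]), slope_hand,
               tolerance = 1e-12)
  expect_error(ammonium_calibration(
    data.frame(concentration = c(5, 5), absorbance = c(1, 1)), 0.5),
    "strictly increasing")
})

test_that("measurement validation catches structural errors", {
  m <- two_point_measurements(0, 150, 0, 50)
  expect_silent(validate_measurements(m))
  dup <- rbind(m, m[1, ])
  expect_error(validate_measurements(dup), "duplicate")
  neg <- m; neg$amount[1] <- -1
  expect_error(validate_measurements(neg), "negative")
  late <- m; late$time_h[late$treatment == "glutamate"] <- c(6, 30)
  expect_error(validate_measurements(late), "start at 0 h")
})
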