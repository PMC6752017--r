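test_that("scenario construction enforces carbon and electron balance", {
  expect_s3_class(stoichiometric_scenario(), "stoichiometric_scenario")
  # 2 acetate + 2 CO2 carries 6 C for a 5-C substrate
  expect_error(stoichiometric_scenario(yields = c(acetate = 2, co2 = 2)),
               "carbon")
  # carbon balanced but electron imbalanced: 2 acetate + 1 CO2 = 16 e- of 18
  expect_error(stoichiometric_scenario(yields = c(acetate = 2, co2 = 1)),
               "electrons")
  # raising the tolerance admits the imbalance
  expect_s3_class(stoichiometric_scenario(yields = c(acetate = 2, co2 = 1),
                                          balance_tol = 2.5),
                  "stoichiometric_scenario")
  expect_error(stoichiometric_scenario(fraction_consumed = 1.5), "\\[0, 1\\]")
})

test_that("microcosm simulation is bit-reproducible given a seed", {
  sc <- stoichiometric_scenario(noise_sd = 0.05)
  m1 <- simulate_microcosm(sc, seed = 123)
  m2 <- simulate_microcosm(sc, seed = 123)
  expect_identical(m1, m2)
  m3 <- simulate_microcosm(sc, seed = 124)
  expect_false(identical(m1, m3))
})

test_that("a noiseless balanced scenario recovers exactly 100% C and RE", {
  sc <- stoichiometric_scenario()
  m <- simulate_microcosm(sc, seed = 1)
  net <- net_product_formation(m, "glutamate", "control",
                               analytes = names(sc$yields))
  rt <- recovery_table(net, substrate_dose("glutamate", sc$dose))
  expect_equal(attr(rt, "totals")[["carbon"]], 100, tolerance = 1e-9)
  expect_equal(attr(rt, "totals")[["reducing_equivalents"]], 100,
               tolerance = 1e-9)
})

test_that("zero consumption leaves the treatment identical to the control", {
  sc <- stoichiometric_scenario(fraction_consumed = 0)
  m <- simulate_microcosm(sc, seed = 5)
  prods <- names(sc$background)
  trt <- m[m$treatment == "glutamate" & m$analyte %in% prods, ]
  ctl <- m[m$treatment == "control" & m$analyte %in% prods, ]
  key <- function(d) d[order(d$replicate, d$analyte, d$time_h), "amount"]
  expect_equal(key(trt), key(ctl))
  sub <- m[m$analyte == "glutamate", ]
  expect_true(all(sub$amount == sc$dose))
})

test_that("noisy control-subtracted nets match the planted yields on average", {
  sc <- stoichiometric_scenario(noise_sd = 0.05)
  nets <- vapply(1:200, function(s) {
    m <- simulate_microcosm(sc, seed = s)
    net <- net_product_formation(m, "glutamate", "control",
                                 analytes = "acetate")
    net$net
  }, numeric(1))
  planted <- sc$dose * sc$yields[["acetate"]]  # 200 umol/gFW
  se <- sd(nets) / sqrt(length(nets))
  expect_lt(abs(mean(nets) - planted), 3 * se)
})

test_that("community simulation plants exact boosts and obeys the layout", {
  cs <- community_scenario(noise_sd = 0,
                           responders = list(glutamate = c(pt_001 = 10)))
  sim <- simulate_community(cs, seed = 2)
  nets <- net_increase_matrix(sim$table, "glutamate", "control")
  expect_equal(nets$net[nets$taxon == "pt_001"], c(10, 10),
               tolerance = 1e-9)
  # the background absorbs the boost as small negative nets
  bg <- nets$net[nets$taxon != "pt_001"]
  expect_true(all(bg <= 1e-12))
  expect_lt(sum(nets$net[nets$molecule == "DNA"]), 1e-9)
  # layout: pooled DNA/RNA-t0, replicated RNA t_end, replicated control
  s <- sim$table$samples
  expect_equal(sum(s$treatment == "glutamate" & s$molecule == "DNA" &
                     s$time == "t0"), 1)
  expect_true(all(is.na(s$replicate[s$treatment == "glutamate" &
                                      s$time == "t0"])))
  expect_equal(sum(s$treatment == "glutamate" & s$molecule == "RNA" &
                     s$time == "t_end"), 3)
  expect_equal(sum(s$treatment == "control"), 12)
  # all compositions closed
  expect_true(all(abs(colSums(sim$table$abund) - 1) < 1e-9))
})

test_that("no responders and no noise give identically zero nets", {
  cs <- community_scenario(noise_sd = 0,
                           responders = list(glutamate = setNames(
                             numeric(0), character(0))))
  sim <- simulate_community(cs, seed = 3)
  nets <- net_increase_matrix(sim$table, "glutamate", "control")
  expect_true(all(abs(nets$net) < 1e-12))
})

test_that("infeasible boosts and unknown responder taxa are rejected", {
  cs <- community_scenario(responders = list(glu = c(pt_001 = 99.9)))
  expect_error(simulate_community(cs, seed = 1), "infeasible")
  cs2 <- community_scenario(responders = list(glu = c(nope = 5)))
  expect_error(simulate_community(cs2, seed = 1), "nope")
})

test_that("sequence simulation hits identity targets deterministically", {
  s1 <- simulate_sequences(4, 250, c(1, 1, 0.98, 0.9), seed = 8)
  s2 <- simulate_sequences(4, 250, c(1, 1, 0.98, 0.9), seed = 8)
  expect_identical(as.character(s1), as.character(s2))
  expect_identical(as.character(s1[[1]]), as.character(s1[[2]]))
  # 0.98 on 250 nt is exactly 5 substitutions
  expect_equal(sum(strsplit(as.character(s1[[1]]), "")[[1]] !=
                     strsplit(as.character(s1[[3]]), "")[[1]]), 5)
  expect_equal(hamming_identity(s1[[1]], s1[[4]]), 0.9)
  expect_error(simulate_sequences(2, 250, c(1, 1.2)), "\\[0, 1\\]")
})
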