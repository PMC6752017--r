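test_that("the three-step net increase matches hand-worked arithmetic", {
  taxa <- c("A", "B", "C")
  tab <- pooled_abundance_fixture(
    taxa,
    trt_t0   = c(0.02, 0.02, 0.96),
    trt_tend = c(0.10, 0.08, 0.82),
    ctl_t0   = c(0.03, 0.03, 0.94),
    ctl_tend = c(0.04, 0.02, 0.94))
  ni <- net_increase(tab, "glutamate", "control", "DNA")
  # A: (10-2) - (4-3) = 7; B: control fell, its delta is ignored -> 8-2 = 6
  expect_equal(ni$net[ni$taxon == "A"], 7, tolerance = 1e-12)
  expect_equal(ni$net[ni$taxon == "B"], 6, tolerance = 1e-12)
  # C shrank; signed audit value kept, reported value clamps at 0
  expect_lt(ni$net[ni$taxon == "C"], 0)
  expect_equal(ni$net_reported[ni$taxon == "C"], 0)
})

test_that("identical treatment and control series report zero net everywhere", {
  taxa <- c("A", "B")
  tab <- pooled_abundance_fixture(taxa, c(0.3, 0.7), c(0.4, 0.6),
                                  c(0.3, 0.7), c(0.4, 0.6))
  ni <- net_increase(tab, "glutamate", "control", "DNA")
  # growing taxa cancel exactly; declining taxa keep their (negative)
  # signed delta because the control's negative delta is ignored, and the
  # reported value clamps at 0
  expect_true(all(ni$net <= 1e-12))
  expect_true(all(ni$net_reported == 0))
  expect_equal(ni$net[ni$taxon == "A"], 0)
})

test_that("replicated cells enter as means, pooled cells as single values", {
  abund <- cbind(t0.p = c(0.2, 0.8),
                 e1 = c(0.3, 0.7), e2 = c(0.5, 0.5), e3 = c(0.4, 0.6),
                 c0.1 = c(0.2, 0.8), c1.1 = c(0.2, 0.8))
  rownames(abund) <- c("A", "B")
  samples <- data.frame(
    sample_id = colnames(abund),
    treatment = c("glu", "glu", "glu", "glu", "control", "control"),
    time = c("t0", "t_end", "t_end", "t_end", "t0", "t_end"),
    molecule = "RNA",
    replicate = c(NA, 1L, 2L, 3L, 1L, 1L))
  tab <- abundance_table(abund, samples)
  ni <- net_increase(tab, "glu", "control", "RNA")
  expect_equal(ni$net[ni$taxon == "A"], 100 * (mean(c(0.3, 0.5, 0.4)) - 0.2))
})

test_that("missing strata are reported by cell", {
  taxa <- c("A", "B")
  tab <- pooled_abundance_fixture(taxa, c(0.3, 0.7), c(0.4, 0.6),
                                  c(0.3, 0.7), c(0.4, 0.6))
  expect_error(net_increase(tab, "glutamate", "control", "RNA"),
               "molecule=RNA")
  expect_error(net_increase(tab, "ribose", "control", "DNA"),
               "treatment=ribose")
})

test_that("time-corrected deltas close compositionally", {
  sim <- simulate_community(community_scenario(seed = 9), seed = 9)
  nets <- net_increase_matrix(sim$table, "glutamate", "control")
  for (mol in c("DNA", "RNA")) {
    sub <- nets[nets$molecule == mol, ]
    expect_lt(abs(sum(sub$delta_treatment)), 1e-9)
    expect_lt(abs(sum(sub$delta_control)), 1e-9)
  }
})

test_that("a constant background taxon does not perturb the other nets", {
  taxa <- c("A", "B", "C")
  tab <- pooled_abundance_fixture(
    taxa, c(0.02, 0.02, 0.96), c(0.10, 0.08, 0.82),
    c(0.03, 0.03, 0.94), c(0.04, 0.02, 0.94))
  ni <- net_increase(tab, "glutamate", "control", "DNA")
  # append a taxon with constant abundance everywhere (no renormalization)
  abund2 <- rbind(tab$abund, K = 0.05)
  tab2 <- abundance_table(abund2, tab$samples, validate = FALSE)
  ni2 <- net_increase(tab2, "glutamate", "control", "DNA")
  expect_equal(ni2$net[match(taxa, ni2$taxon)], ni$net)
  expect_equal(ni2$net[ni2$taxon == "K"], 0)
})

test_that("family aggregation sums abundances before the screen", {
  # two phylotypes of one family: nets 3 and 2 alone, 5 as a family
  abund <- cbind(t0.t = c(0.02, 0.03, 0.95), te.t = c(0.05, 0.05, 0.90),
                 t0.c = c(0.02, 0.03, 0.95), te.c = c(0.02, 0.03, 0.95))
  rownames(abund) <- c("p1", "p2", "p3")
  samples <- data.frame(sample_id = colnames(abund),
                        treatment = c("glu", "glu", "control", "control"),
                        time = c("t0", "t_end", "t0", "t_end"),
                        molecule = "DNA", replicate = NA_integer_)
  taxa <- data.frame(taxon_id = c("p1", "p2", "p3"),
                     lineage = c("Fusobacteria;Fusobacteriaceae",
                                 "Fusobacteria;Fusobacteriaceae",
                                 "Proteobacteria;Aeromonadaceae"))
  tab <- abundance_table(abund, samples, taxa)
  kept <- aggregate_by_rank(tab, "glu", "control", molecules = "DNA",
                            rank = "family", threshold = 4)
  expect_identical(unique(kept$taxon), "Fusobacteriaceae")
  expect_equal(kept$net_reported, 5, tolerance = 1e-12)
  # threshold 0 retains every family
  all_kept <- aggregate_by_rank(tab, "glu", "control", molecules = "DNA",
                                rank = "family", threshold = 0)
  expect_setequal(unique(all_kept$taxon),
                  c("Fusobacteriaceae", "Aeromonadaceae"))
  # sum-after variant sums the signed per-phylotype nets
  after <- aggregate_by_rank(tab, "glu", "control", molecules = "DNA",
                             rank = "family", threshold = 4,
                             collapse = "after")
  expect_equal(after$net[after$taxon == "Fusobacteriaceae"], 5,
               tolerance = 1e-12)
})

test_that("unresolved lineages fall back to unclassified-<parent>", {
  abund <- matrix(c(0.5, 0.5), 2, 1,
                  dimnames = list(c("p1", "p2"), "s1"))
  samples <- data.frame(sample_id = "s1", treatment = "c", time = "t0",
                        molecule = "DNA", replicate = NA_integer_)
  taxa <- data.frame(taxon_id = c("p1", "p2"),
                     lineage = c("Firmicutes;", "Firmicutes;Clostridiaceae"))
  agg <- aggregate_taxa(abundance_table(abund, samples, taxa), "family")
  expect_setequal(rownames(agg$abund),
                  c("unclassified-Firmicutes", "Clostridiaceae"))
})

test_that("the phylotype screen applies an inclusive threshold", {
  nets <- data.frame(taxon = c("a", "b", "c", "d"),
                     treatment = "glu", molecule = "DNA",
                     net_reported = c(2.0, 1.99, 5, 0))
  expect_setequal(screen_phylotypes(nets, threshold = 2), c("a", "c"))
  none <- data.frame(taxon = c("a", "b"), treatment = "glu",
                     molecule = "DNA", net_reported = c(0, 0))
  expect_length(screen_phylotypes(none), 0)
})

test_that("abundance table validation enforces closure and metadata", {
  abund <- matrix(c(0.6, 0.3), 2, 1, dimnames = list(c("A", "B"), "s1"))
  samples <- data.frame(sample_id = "s1", treatment = "c", time = "t0",
                        molecule = "DNA", replicate = NA_integer_)
  expect_error(abundance_table(abund, samples), "sum to 1")
  expect_silent(abundance_table(abund, samples, validate = FALSE))
  bad <- samples; bad$time <- "start"
  good <- abund / colSums(abund)[col(abund)]
  expect_error(abundance_table(good, bad), "t0")
})
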