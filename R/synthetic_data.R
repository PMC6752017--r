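# Seeded generators: microcosm product time courses from known fermentation
# stoichiometries, community tables with planted responder taxa, and
# divergent marker sequences. Every generator is deterministic given
# (scenario, seed), so downstream stages can be tested against known ground
# truth without any external data.

#' Stoichiometric microcosm scenario
#'
#' Describes a supplemented microcosm whose products are an exact
#' stoichiometric rewrite of the consumed substrate: `yields` gives mol
#' product per mol substrate and must conserve both carbon and electrons
#' (checked at construction against the registry, tolerance
#' `balance_tol`). The default scenario is a glutamate fermentation,
#' 10 mM dose (100 umol/gFW) rewritten as
#' glutamate -> 2 acetate + 1 CO2 + 1 H2
#' (carbon 2x2+1 = 5, electrons 2x8+0+2 = 18, both conserved). A matched
#' unsupplemented control shares the background product drift.
#'
#' @param substrate Substrate name (resolved in `registry`).
#' @param dose Substrate provided, umol per g fresh weight.
#' @param yields Named vector: mol product per mol substrate consumed.
#' @param fraction_consumed Fraction of the dose consumed by `t_end`.
#' @param noise_sd Multiplicative log-normal measurement noise (SD of log;
#'   0 = noiseless). Mean-one noise, so expectations are unchanged.
#' @param n_replicates Replicate microcosms per treatment.
#' @param times Sampling times in hours, starting at 0.
#' @param background Named vector of product amounts (umol/gFW) formed by
#'   the unsupplemented gut content itself by the final time point; shared
#'   by treatment and control.
#' @param registry Compound registry for the balance check.
#' @param balance_tol Allowed absolute imbalance in carbon and electrons
#'   per mole of substrate.
#' @param seed Default random seed for [simulate_microcosm()].
#' @return An object of class `"stoichiometric_scenario"`.
#' @export
stoichiometric_scenario <- function(substrate = "glutamate", dose = 100,
                                    yields = c(acetate = 2, co2 = 1, h2 = 1),
                                    fraction_consumed = 1, noise_sd = 0,
                                    n_replicates = 3,
                                    times = seq(0, 30, by = 6),
                                    background = c(acetate = 15, co2 = 10,
                                                   propionate = 5),
                                    registry = default_registry(),
                                    balance_tol = 1e-9, seed = 1) {
  if (fraction_consumed < 0 || fraction_consumed > 1)
    stop("fraction_consumed must lie in [0, 1]")
  if (dose <= 0) stop("dose must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and increase strictly")
  sub <- registry_get(registry, substrate)
  c_out <- sum(vapply(names(yields), function(p)
    yields[[p]] * registry_get(registry, p)$carbons, numeric(1)))
  e_out <- sum(vapply(names(yields), function(p)
    yields[[p]] * registry_get(registry, p)$electrons, numeric(1)))
  if (abs(c_out - sub$carbons) > balance_tol)
    stop(sprintf("yields do not conserve carbon: %.6g C out vs %.6g C in",
                 c_out, sub$carbons))
  if (abs(e_out - sub$electrons) > balance_tol)
    stop(sprintf("yields do not conserve electrons: %.6g e- out vs %.6g e- in",
                 e_out, sub$electrons))
  structure(list(substrate = tolower(substrate), dose = dose,
                 yields = yields, fraction_consumed = fraction_consumed,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 times = times, background = background, seed = seed),
            class = "stoichiometric_scenario")
}

# Logistic accumulation profile normalized to f(0) = 0, f(t_end) = 1.
.accumulation <- function(times, rate = 0.3) {
  t_end <- max(times)
  g <- function(t) 1 / (1 + exp(-rate * (t - t_end / 2)))
  (g(times) - g(0)) / (g(t_end) - g(0))
}

# Mean-one multiplicative log-normal noise.
.lognoise <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  exp(rnorm(n, mean = -sd^2 / 2, sd = sd))
}

#' Simulate microcosm product time courses
#'
#' Generates a long measurement table for a supplemented treatment (named
#' after the substrate) and a matched unsupplemented `"control"`. Products
#' accumulate along a logistic-in-time profile scaled by the scenario
#' yields on top of the shared background drift; the substrate series
#' decreases accordingly (treatment only). Multiplicative log-normal noise
#' is applied independently per observation at times after 0 h.
#'
#' @param scenario A [stoichiometric_scenario()].
#' @param seed Random seed (defaults to the scenario's).
#' @return A long measurement data frame (`treatment`, `replicate`,
#'   `time_h`, `analyte`, `amount`) that passes
#'   [validate_measurements()].
#' @export
simulate_microcosm <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "stoichiometric_scenario"))
  set.seed(seed)
  times <- scenario$times
  f <- .accumulation(times)
  products <- union(names(scenario$yields), names(scenario$background))
  bg <- setNames(rep(0, length(products)), products)
  bg[names(scenario$background)] <- scenario$background
  yl <- setNames(rep(0, length(products)), products)
  yl[names(scenario$yields)] <- scenario$yields
  planted <- scenario$dose * scenario$fraction_consumed
  rows <- list()
  for (trt in c(scenario$substrate, "control")) {
    supplemented <- trt == scenario$substrate
    for (r in seq_len(scenario$n_replicates)) {
      for (p in products) {
        mean_amt <- bg[[p]] * times / max(times) +
          if (supplemented) planted * yl[[p]] * f else 0
        amt <- mean_amt * ifelse(times > 0,
                                 .lognoise(length(times), scenario$noise_sd),
                                 1)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = trt, replicate = r, time_h = times, analyte = p,
          amount = amt, stringsAsFactors = FALSE)
      }
      if (supplemented) {
        mean_sub <- scenario$dose * (1 - scenario$fraction_consumed * f)
        amt <- mean_sub * ifelse(times > 0,
                                 .lognoise(length(times), scenario$noise_sd),
                                 1)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = trt, replicate = r, time_h = times,
          analyte = scenario$substrate, amount = amt,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_measurements(out)
}

#' Community scenario with planted responders
#'
#' Describes a synthetic phylotype community: a soil-like long-tailed
#' background composition drawn from a symmetric Dirichlet, and per
#' supplemented treatment a set of responder taxa whose end-of-incubation
#' relative abundance is raised by a known number of percentage points
#' (exact-add planting: the responder gains exactly the boost, the
#' background is rescaled to keep the composition closed, so zero-noise
#' net increases equal the planted boosts exactly). The sampling layout
#' mirrors the study design: in supplemented treatments the DNA t0, DNA
#' t_end and RNA t0 libraries are pooled across replicates while RNA t_end
#' is replicate-resolved; the control is replicate-resolved throughout.
#'
#' @param n_taxa Number of background phylotypes.
#' @param concentration Symmetric Dirichlet concentration for the
#'   background composition (default 0.5, long-tailed).
#' @param responders Named list: per treatment, a named numeric vector of
#'   boosts in percentage points, e.g.
#'   `list(glutamate = c(pt_001 = 10, pt_002 = 5))`.
#' @param n_replicates Replicates per treatment.
#' @param noise_sd Additive Gaussian sample-to-sample noise on relative
#'   abundances, in percentage points (truncated at 0, then renormalized).
#'   Default 0.25 points, the scale of multinomial counting noise at the
#'   read depths of amplicon surveys.
#' @param control Control treatment id.
#' @param seed Default seed for [simulate_community()].
#' @return An object of class `"community_scenario"`.
#' @export
community_scenario <- function(n_taxa = 60, concentration = 0.5,
                               responders = list(
                                 glutamate = c(pt_001 = 10, pt_002 = 5)),
                               n_replicates = 3, noise_sd = 0.25,
                               control = "control", seed = 1) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  if (concentration <= 0) stop("concentration must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(responders)) || any(!nzchar(names(responders))))
    stop("'responders' must be a named list (one element per treatment)")
  for (trt in names(responders)) {
    b <- responders[[trt]]
    if (length(b) && (is.null(names(b)) || any(b <= 0)))
      stop("boosts for treatment '", trt,
           "' must be a named vector of positive percentage points")
  }
  structure(list(n_taxa = n_taxa, concentration = concentration,
                 responders = responders, n_replicates = n_replicates,
                 noise_sd = noise_sd, control = control, seed = seed),
            class = "community_scenario")
}

# One noisy realization of a composition: truncated additive noise on the
# percentage scale, renormalized to sum 1.
.noisy_composition <- function(base, sd_points) {
  if (sd_points == 0) return(base)
  x <- pmax(base + rnorm(length(base), 0, sd_points / 100), 0)
  x / sum(x)
}

#' Simulate a community abundance table with known responders
#'
#' @param scenario A [community_scenario()].
#' @param seed Random seed (defaults to the scenario's).
#' @return A list with `table` (an [abundance_table()]) and `responders`
#'   (data frame `treatment`, `taxon`, `boost` of planted ground truth).
#' @export
simulate_community <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "community_scenario"))
  set.seed(seed)
  taxa <- sprintf("pt_%03d", seq_len(scenario$n_taxa))
  lineage <- paste0("phylum_", sprintf("%02d", (seq_len(scenario$n_taxa) - 1)
                                       %% 4 + 1),
                    ";family_", sprintf("%02d", (seq_len(scenario$n_taxa) - 1)
                                        %% 12 + 1))
  g <- rgamma(scenario$n_taxa, shape = scenario$concentration)
  p0 <- setNames(g / sum(g), taxa)
  for (trt in names(scenario$responders)) {
    b <- scenario$responders[[trt]]
    unknown <- setdiff(names(b), taxa)
    if (length(unknown))
      stop("responder taxa not in the community: ",
           paste(unknown, collapse = ", "))
  }
  planted_endpoint <- function(b) {
    resp <- names(b)
    q <- p0
    q[resp] <- p0[resp] + b / 100
    if (sum(q[resp]) >= 1)
      stop("infeasible boost: responder abundances reach or exceed 100%")
    rest <- setdiff(taxa, resp)
    q[rest] <- p0[rest] * (1 - sum(q[resp])) / (1 - sum(p0[resp]))
    q
  }
  cols <- list(); meta <- list()
  add_sample <- function(id, treatment, time, molecule, replicate, base) {
    cols[[id]] <<- .noisy_composition(base, scenario$noise_sd)
    meta[[id]] <<- data.frame(sample_id = id, treatment = treatment,
                              time = time, molecule = molecule,
                              replicate = replicate,
                              stringsAsFactors = FALSE)
  }
  reps <- seq_len(scenario$n_replicates)
  # control: replicate-resolved in every stratum
  for (mol in c("DNA", "RNA")) for (tp in c("t0", "t_end")) for (r in reps)
    add_sample(paste(scenario$control, mol, tp, r, sep = "."),
               scenario$control, tp, mol, r, p0)
  # supplemented: pooled except RNA at t_end
  for (trt in names(scenario$responders)) {
    q <- planted_endpoint(scenario$responders[[trt]])
    add_sample(paste(trt, "DNA", "t0", "pooled", sep = "."),
               trt, "t0", "DNA", NA_integer_, p0)
    add_sample(paste(trt, "DNA", "t_end", "pooled", sep = "."),
               trt, "t_end", "DNA", NA_integer_, q)
    add_sample(paste(trt, "RNA", "t0", "pooled", sep = "."),
               trt, "t0", "RNA", NA_integer_, p0)
    for (r in reps)
      add_sample(paste(trt, "RNA", "t_end", r, sep = "."),
                 trt, "t_end", "RNA", r, q)
  }
  abund <- do.call(cbind, cols)
  rownames(abund) <- taxa
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  truth <- do.call(rbind, c(
    list(data.frame(treatment = character(0), taxon = character(0),
                    boost = numeric(0), stringsAsFactors = FALSE)),
    lapply(names(scenario$responders), function(trt) {
      b <- scenario$responders[[trt]]
      data.frame(treatment = rep(trt, length(b)), taxon = names(b),
                 boost = as.numeric(b), stringsAsFactors = FALSE)
    })))
  tab <- abundance_table(abund, samples,
                         taxa = data.frame(taxon_id = taxa,
                                           lineage = lineage,
                                           stringsAsFactors = FALSE))
  list(table = tab, responders = truth)
}

#' Simulate divergent marker sequences
#'
#' Generates `n` nucleotide sequences by mutating a random ancestor: the
#' first sequence is the ancestor, and sequence i carries
#' `round((1 - identities[i]) * length)` substitutions at random positions,
#' so its identity to the ancestor hits the requested target exactly (for
#' substitution-only sequences of equal length). Pairwise identities
#' between two mutated sequences are at least
#' 1 - (d_i + d_j) / length.
#'
#' @param n Number of sequences.
#' @param length Sequence length (nt).
#' @param identities Target identities of each sequence to the first
#'   (ancestor); the first entry must be 1.
#' @param seed Random seed.
#' @return A named [Biostrings::DNAStringSet] (`seq_01`, `seq_02`, ...).
#' @export
simulate_sequences <- function(n, length = 250,
                               identities = rep(1, n), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (length(identities) != n)
    stop("'identities' must have one entry per sequence")
  if (any(identities < 0 | identities > 1))
    stop("identities must lie in [0, 1]")
  if (identities[1] != 1)
    stop("the first sequence is the ancestor; identities[1] must be 1")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    d <- round((1 - identities[i]) * length)
    s <- anc
    if (d > 0) {
      pos <- sample(length, d)
      s[pos] <- vapply(s[pos], function(bb)
        sample(setdiff(bases, bb), 1), character(1))
    }
    seqs[i] <- paste(s, collapse = "")
  }
  setNames(Biostrings::DNAStringSet(seqs),
           sprintf("seq_%02d", seq_len(n)))
}
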