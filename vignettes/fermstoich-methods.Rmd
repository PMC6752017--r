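---
title: "Methods: stoichiometric recovery accounting and the net-increase community screen"
author: "fermstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometric recovery accounting and the net-increase community screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermstoich)
```

# The experimental system

The package analyses short (tens of hours) anoxic microcosm incubations of
gut-content slurry challenged with a single fermentable substrate — an
amino acid such as glutamate, a saccharide such as ribose or glucose, or a
transient intermediate such as succinate or formate — next to an
unsupplemented control. Two complementary read-outs are supported:

* **chemistry**: time courses of fermentation products (fatty acids,
  alcohols, H~2~, CO~2~) in µmol per g fresh weight of gut content, from
  which the package computes control-corrected net product formation and
  the percentage of the substrate's carbon and reducing equivalents
  recovered in those products;
* **community**: 16S rRNA gene (DNA) and 16S rRNA (RNA) relative sequence
  abundances of phylotypes at the start and end of the incubation, from
  which the package computes a time- and control-corrected *net increase*
  per taxon and screens for substrate-responsive phylotypes.

# Electron bookkeeping

Reducing-equivalent accounting uses the classical degree-of-reduction
convention with reference compounds CO~2~, H~2~O and NH~3~: each carbon
contributes +4 electrons, each hydrogen +1, each oxygen −2, each nitrogen
−3 (sulfur, when present, +6; phosphorus carries weight 0 and triggers a
warning). Dividing by the carbon count gives electrons per carbon atom,
e.g.

```{r}
degree_of_reduction_per_carbon("C5H9NO4")   # glutamate
degree_of_reduction_per_carbon("C5H11NO2")  # valine
electrons_per_molecule("H2")                # no carbon, 2 electrons
```

This is the unique atom-weight convention that reproduces the standard
coefficients for all the substrates handled here (valine 4.8, glutamate
3.6, aspartate/glycine 3.0, threonine/alanine/ribose/glucose 4.0,
succinate 3.5, formate 2.0 e^-^/C). Casamino Acids, an acid-hydrolyzed
casein mixture with no molecular formula, is modeled as a pseudo-compound
with a fixed 4.2 e^-^/C; its carbon-per-mole basis (default 4, from the
mean amino-acid-residue picture with residue mass 100 g/mol) is a
documented assumption, not a measurement, and both values are arguments of
`default_registry()`.

Amount units interconvert linearly given the slurry make-up (default 1 g
fresh weight in 10 ml, dry fraction 0.45): 100 µmol/gFW = 10 mM = 222
µmol/gDW. The cytoplasm worked example (`cytoplasm_concentration()`)
additionally fixes the cytoplasm density at 1 g/ml; under 20 % dry mass,
50 % protein and a 100 g/mol mean residue it returns exactly 1 M polymeric
amino acids, and ~0.107 M polymeric ribose under 20 % RNA of which 40 % is
ribose.

# Gas partitioning

Headspace gas measurements arrive as mixing ratios. The vessel total is
assembled from three equilibrium pools:

* headspace, by the ideal gas law: $n = x P V_{head} / (R T)$;
* dissolved, by Henry's law: $n = K_H \, x P_{atm} V_{liq}$;
* for CO~2~ only, bicarbonate by Henderson–Hasselbalch:
  $n_{HCO_3^-} = n_{CO_2,diss} \cdot 10^{pH - pK_{a1}}$.

Defaults are 25 °C constants, $K_H$(CO~2~) = 0.0339 and $K_H$(H~2~) =
7.8×10^-4^ mol L^-1^ atm^-1^, $pK_{a1}$ = 6.35, all overridable through
`gas_constants()`. Two genuinely ambiguous experimental parameters are
deliberately exposed instead of guessed silently: whether a reported
pressurization (e.g. "60 kPa N~2~") is gauge or absolute (the default
vessel assumes gauge, i.e. 161.325 kPa absolute), and the incubation
temperature (default 298.15 K; room-temperature incubations span roughly
294–297 K). Carbonate (CO~3~^2-^) is neglected: below pH 7.5 it
contributes under 1 % of the dissolved inorganic carbon.

# Recovery accounting

Net product formation subtracts the unsupplemented control on replicate
means: $net = (T_{end} - T_0) - (C_{end} - C_0)$ per analyte; non-positive
nets are flagged "no net increase" and rendered as an em dash. Percent
recovery of carbon for product $i$ is
$100 \cdot net_i \cdot C_i / (dose \cdot C_{substrate})$ and likewise for
electrons with the per-molecule electron counts; H~2~ has no carbon entry
and CO~2~ no electron entry (rendered NA). The dose can be the amount
*provided* or the amount *consumed* (initial minus final measured
substrate); with complete consumption the two coincide. Negative apparent
consumption is clamped to zero with a warning so noise can never produce a
negative denominator. Reports round to 2 significant figures; all internal
arithmetic is full precision.

Replicate-level collective product sums feed the unequal-variance (Welch)
t test, implemented in closed form with Welch–Satterthwaite degrees of
freedom; when both group variances vanish the test degenerates to p = 1
(equal means) or p = 0 with a warning.

# The net-increase community screen

The screen is a three-step procedure applied separately to DNA and RNA
(never averaged):

1. within each (treatment, time, molecule) cell, take the mean relative
   abundance over replicate libraries, or the single value where the
   replicates were pooled into one library;
2. subtract the start-of-incubation value from the end value for both the
   supplemented treatment and the control (time correction);
3. subtract the control's time-corrected change from the treatment's,
   *ignoring negative control changes* (they count as 0, never as a
   credit).

The result can still be negative when the treatment itself declined; the
procedure's source leaves that case unstated, so the package keeps the
signed value in the audit columns (`net`) and clamps at zero only for
reporting and thresholding (`net_reported`). Abundances are used as given
— no renormalization after taxon filtering — because the procedure
operates on whole-table relative abundances; compositional closure (taxon
deltas summing to zero within a sample pair) is asserted in the tests.

Family- and phylum-level views sum abundances to the rank *before* the
net-increase arithmetic (the default; summing per-phylotype signed nets
afterwards is available via `collapse = "after"` since the original
procedure does not state the order) and retain ranks reaching ≥ 4
percentage points in at least one treatment × molecule stratum. Phylotypes
are called *stimulated* at an inclusive ≥ 2-point threshold in any
supplemented treatment.

Stimulated phylotypes are grouped into **group phylotypes** by greedy
clustering at ≥ 97 % identity: seeds ordered by descending maximal net
increase (ties broken lexicographically), each sequence joining the first
seed within threshold. Identity is defined as matches divided by alignment
length under a global end-gap-free (overlap) alignment scored match = 1,
mismatch = 0, unit gap cost — no specific published aligner is implied;
this definition is fixed, documented, and verified in the tests against a
brute-force identity oracle on substitution-only sequences.

Diversity summaries use the natural-log Shannon index, the bias-corrected
Chao1 estimator $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$ (the classic
form is available by flag but is undefined without doubletons), the exact
hypergeometric rarefaction expectation, and Bray–Curtis dissimilarity.
Shannon, rarefaction and Bray–Curtis are computed through vegan; ordination
(NMDS) of the dissimilarity matrix is intentionally out of scope.

# Synthetic data: what it emulates, and what it does not

The generators define the package's test bed; their defaults are fixed
study conditions, not tuning knobs.

**Microcosms** (`simulate_microcosm()`): products accumulate along a
logistic-in-time profile scaled by molar yields that must conserve carbon
and electrons exactly (checked at construction). The default scenario is a
balanced glutamate rewrite, 100 µmol/gFW dose, glutamate → 2 acetate +
1 CO~2~ + 1 H~2~ (5 C and 18 e^-^ on both sides), 3 replicates, sampling
0–30 h every 6 h, on top of a modest endogenous background drift shared
with the control (acetate 15, CO~2~ 10, propionate 5 µmol/gFW by 30 h).
Measurement noise is multiplicative mean-one log-normal (chromatographic
peak-area-like); 5 % noise with 3 replicates leaves recovery totals within
100 ± 10 % in well over 95 % of runs.

**Communities** (`simulate_community()`): the background composition is a
symmetric Dirichlet draw (concentration 0.5, 60 taxa by default), a
soil-like long-tailed profile — a modeling choice, not a claim about any
particular data set. Responders are planted *exact-add*: their endpoint
abundance is raised by the stated number of percentage points and the
background is rescaled to keep the composition closed, so with zero noise
the net increase equals the planted boost exactly. Sample-to-sample noise
is additive Gaussian on the percentage scale (truncated at 0, then
renormalized) with a default SD of 0.25 points, the magnitude of
multinomial counting noise at the 10^5^–10^6^ read depths typical of
amplicon surveys. The pooling layout mirrors the replicated study design:
supplemented treatments pool DNA t~0~, DNA t~end~ and RNA t~0~ across the
three replicates and sequence RNA t~end~ per replicate; controls are
replicate-resolved throughout.

What the generators do *not* emulate: real sequencing artifacts (chimeras,
primer bias, copy-number variation), taxon–taxon interactions, kinetic gas
transfer, or fermentation kinetics beyond the fixed accumulation profile.
Passing tests therefore demonstrate the correctness of the arithmetic and
the screen's behaviour under controlled noise, not the biological fidelity
of any particular data set.

**Sequences** (`simulate_sequences()`): a random ancestor is mutated by
`round((1 - identity) * length)` substitutions per sequence, so identities
to the ancestor are hit exactly for substitution-only sequences; this is
what lets a plain Hamming count serve as the independent identity oracle
in the clustering tests.

# Numerical choices and degenerate inputs

* Recovery conservation is asserted to 1e-9; the net-increase hand example
  to 1e-12; unit round-trips to 1e-12 relative.
* Zero-variance Welch inputs, zero-carbon substrates, empty product
  tables, all-zero abundance vectors and empty FASTA inputs all raise
  explicit errors or warnings rather than returning NaN.
* Clustering ties (equal ranking scores) break on lexicographic id, so
  results are deterministic.
* All simulation entry points take an explicit seed and are
  bit-reproducible given (scenario, seed).
* Test problem sizes — 200 seeded microcosm runs, 100 seeded community
  screens, 50 clustering sets of up to 20 sequences of 250 nt, 10,000
  Monte-Carlo rarefaction draws — were chosen so the whole suite exercises
  the Monte-Carlo claims at tight tolerances while remaining quick on a
  single CPU.

# Interfaces

The package is used from R: readers (`read_measurements()`,
`read_abundances()`, `read_phylotype_fasta()`, `read_registry()`) accept
tab-separated text canonically (comma auto-detected), writers render the
recovery and net-increase reports with the em-dash / NA conventions and a
provenance header (package version, config hash, seed, input checksums)
so every rendered table is traceable. No shell executable is shipped; the
exported functions plus this vignette are the pipeline interface, and
`scripts/acceptance.R` shows a complete scripted run.

# Known limitations

* The Casamino Acids carbon basis is an assumption; recoveries on that
  substrate inherit its uncertainty.
* The screen's behaviour at abundances near the threshold depends on the
  sequencing-noise magnitude; the planted-responder guarantees quoted in
  the tests hold for boosts ≥ 2× threshold and noise SD ≤ 0.25× threshold.
* Identity under the overlap alignment can differ slightly from a global
  alignment with penalized end gaps for highly divergent pairs; both are
  legitimate definitions, and only the documented one is implemented.
* LEfSe-style effect sizes, NMDS embedding and phylogenetic tree
  construction are out of scope by design.
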