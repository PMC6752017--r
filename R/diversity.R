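# Alpha and beta diversity summaries used alongside the community screen.

#' Shannon diversity index
#'
#' H = -sum p log p over taxa with p > 0, natural logarithm (the log base
#' is a convention; natural log is used throughout this package).
#'
#' @param p Relative abundances summing to 1 (tolerance 1e-6).
#' @return The Shannon index.
#' @export
shannon <- function(p) {
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("abundances must sum to 1")
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Chao1 expected richness
#'
#' Bias-corrected Chao1 estimator S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with
#' F1 and F2 the singleton and doubleton counts; the bias-corrected form
#' stays defined when no doubletons are observed. The classic form
#' S_obs + F1^2 / (2 F2) is available via `bias_corrected = FALSE` (it is
#' infinite when F1 > 0 and F2 = 0).
#'
#' @param counts Non-negative integer counts per taxon.
#' @param bias_corrected Use the bias-corrected (+1) form (default).
#' @return Expected richness.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 == 0) {
    if (f1 == 0) return(s_obs)
    warning("classic Chao1 is undefined with singletons but no doubletons")
    return(Inf)
  }
  s_obs + f1^2 / (2 * f2)
}

#' Analytic rarefaction curve
#'
#' Expected number of taxa observed in a random subsample of each depth,
#' from the exact hypergeometric expectation
#' E\[S_d\] = sum_i (1 - choose(N - n_i, d) / choose(N, d)).
#'
#' @param counts Non-negative integer counts per taxon.
#' @param depths Subsampling depths, each between 1 and `sum(counts)`.
#' @return A data frame with columns `depth` and `expected_taxa`.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n_tot <- sum(counts)
  if (any(depths < 1) || any(depths > n_tot))
    stop("depths must lie between 1 and the total count (", n_tot, ")")
  ex <- as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = depths))
  data.frame(depth = depths, expected_taxa = ex)
}

#' Bray-Curtis dissimilarity
#'
#' 1 - 2 sum min(a_i, b_i) / sum (a_i + b_i), in \[0, 1\]: 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param a,b Equal-length non-negative abundance vectors, not both all
#'   zero.
#' @return The dissimilarity.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  if (sum(a) == 0 && sum(b) == 0)
    stop("Bray-Curtis is undefined for two all-zero vectors")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}
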