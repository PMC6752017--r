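# Time- and control-corrected net increases of relative sequence abundance,
# rank-level aggregation, the stimulated-phylotype screen, and greedy
# group-phylotype clustering of representative sequences.

#' Phylotype-by-sample relative abundance table
#'
#' Couples a taxa x samples matrix of relative abundances (fractions
#' summing to 1 per sample) with per-sample metadata and per-taxon lineage
#' strings. Samples are either pooled (one library from the pooled
#' replicates; `replicate = NA`) or replicate-resolved (`replicate` >= 1).
#'
#' @param abundances Numeric matrix, rows = taxa, columns = samples; row
#'   and column names required.
#' @param samples Data frame with columns `sample_id`, `treatment`, `time`
#'   (`"t0"` or `"t_end"`), `molecule` (`"DNA"` or `"RNA"`), `replicate`
#'   (integer, `NA` for pooled samples). Row order must cover every matrix
#'   column.
#' @param taxa Optional data frame with columns `taxon_id` and `lineage`
#'   (`"phylum;family"`); defaults to unclassified lineages.
#' @param validate If `TRUE` (default), check column sums against 1.
#' @param tol Tolerance on the per-sample abundance sum.
#' @return An object of class `"abundance_table"`: a list with elements
#'   `abund`, `samples`, `taxa`.
#' @export
abundance_table <- function(abundances, samples, taxa = NULL,
                            validate = TRUE, tol = 1e-9) {
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop("abundance matrix needs row (taxon) and column (sample) names")
  need <- c("sample_id", "treatment", "time", "molecule", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(colnames(abundances) %in% samples$sample_id))
    stop("sample(s) missing from the sample sheet: ",
         paste(setdiff(colnames(abundances), samples$sample_id),
               collapse = ", "))
  samples <- samples[match(colnames(abundances), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$time %in% c("t0", "t_end")))
    stop("sample 'time' must be 't0' or 't_end'")
  if (!all(samples$molecule %in% c("DNA", "RNA")))
    stop("sample 'molecule' must be 'DNA' or 'RNA'")
  if (any(!is.na(samples$replicate) & samples$replicate < 1))
    stop("replicate indices must be >= 1 (NA marks pooled samples)")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (validate) {
    sums <- colSums(abundances)
    off <- which(abs(sums - 1) > tol)
    if (length(off))
      stop("abundance column(s) do not sum to 1: ",
           paste(colnames(abundances)[off], collapse = ", "))
  }
  if (is.null(taxa))
    taxa <- data.frame(taxon_id = rownames(abundances),
                       lineage = "unclassified;unclassified",
                       stringsAsFactors = FALSE)
  if (!all(rownames(abundances) %in% taxa$taxon_id))
    stop("taxa missing lineage entries: ",
         paste(setdiff(rownames(abundances), taxa$taxon_id), collapse = ", "))
  taxa <- taxa[match(rownames(abundances), taxa$taxon_id), , drop = FALSE]
  rownames(taxa) <- NULL
  structure(list(abund = abundances, samples = samples, taxa = taxa),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples (%d pooled)\n",
              nrow(x$abund), ncol(x$abund), sum(is.na(x$samples$replicate))))
  invisible(x)
}

# Mean relative abundance per taxon over the samples of one
# (treatment, time, molecule) cell; pooled cells contribute their single
# library.
.cell_mean <- function(tab, treatment, time, molecule) {
  sel <- tab$samples$treatment == treatment & tab$samples$time == time &
    tab$samples$molecule == molecule
  if (!any(sel))
    stop(sprintf("no sample for (treatment=%s, time=%s, molecule=%s)",
                 treatment, time, molecule))
  rowMeans(tab$abund[, sel, drop = FALSE])
}

#' Net increase of relative sequence abundance
#'
#' The three-step procedure used to call substrate-responsive taxa:
#' (i) within each (treatment, time, molecule) cell, take the mean relative
#' abundance over replicate libraries, or the single value where the
#' replicates were pooled into one library; (ii) subtract the start-of-
#' incubation value from the end-of-incubation value for both the
#' supplemented treatment and the unsupplemented control (time correction);
#' (iii) subtract the control's time-corrected change from the treatment's,
#' ignoring negative control changes (they are treated as 0, never added
#' back). The signed result is retained for audit; `net_reported` clamps
#' negatives at 0 for threshold screens.
#'
#' @param tab An [abundance_table()].
#' @param treatment,control Treatment ids.
#' @param molecule `"DNA"` or `"RNA"`; strata are never averaged.
#' @return A data frame of class `"net_increase"` with per-taxon columns
#'   `delta_treatment`, `delta_control`, `net` (signed) and `net_reported`,
#'   all in percentage points.
#' @export
net_increase <- function(tab, treatment, control, molecule = c("DNA", "RNA")) {
  stopifnot(inherits(tab, "abundance_table"))
  molecule <- match.arg(molecule)
  d_trt <- .cell_mean(tab, treatment, "t_end", molecule) -
    .cell_mean(tab, treatment, "t0", molecule)
  d_ctl <- .cell_mean(tab, control, "t_end", molecule) -
    .cell_mean(tab, control, "t0", molecule)
  net <- d_trt - pmax(d_ctl, 0)
  out <- data.frame(taxon = rownames(tab$abund),
                    delta_treatment = 100 * d_trt,
                    delta_control = 100 * d_ctl,
                    net = 100 * net,
                    net_reported = 100 * pmax(net, 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "treatment") <- treatment
  attr(out, "control") <- control
  attr(out, "molecule") <- molecule
  class(out) <- c("net_increase", "data.frame")
  out
}

#' Net increases for several treatments and molecules at once
#'
#' @inheritParams net_increase
#' @param treatments Character vector of supplemented treatment ids.
#' @param molecules Molecules to analyse as separate strata.
#' @return A long data frame with columns `taxon`, `treatment`, `molecule`,
#'   `delta_treatment`, `delta_control`, `net`, `net_reported`.
#' @export
net_increase_matrix <- function(tab, treatments, control,
                                molecules = c("DNA", "RNA")) {
  parts <- list()
  for (trt in treatments) {
    for (mol in molecules) {
      ni <- net_increase(tab, trt, control, mol)
      ni$treatment <- trt
      ni$molecule <- mol
      parts[[paste(trt, mol)]] <- as.data.frame(ni)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("taxon", "treatment", "molecule", "delta_treatment",
          "delta_control", "net", "net_reported")]
}

.lineage_rank <- function(lineage, rank) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    phylum <- if (length(p) >= 1 && nzchar(p[1]) && !is.na(p[1])) p[1]
              else "unclassified"
    if (rank == "phylum") return(phylum)
    if (length(p) >= 2 && nzchar(p[2]) && !is.na(p[2])) p[2]
    else paste0("unclassified-", phylum)
  }, character(1))
}

#' Collapse an abundance table to a taxonomic rank
#'
#' Sums relative abundances over all phylotypes sharing the requested rank.
#' Phylotypes whose lineage does not resolve the rank are pooled into
#' `"unclassified-<parent>"`.
#'
#' @param tab An [abundance_table()].
#' @param rank `"family"` or `"phylum"`.
#' @return A new `abundance_table` whose taxa are the rank labels.
#' @export
aggregate_taxa <- function(tab, rank = c("family", "phylum")) {
  stopifnot(inherits(tab, "abundance_table"))
  rank <- match.arg(rank)
  labels <- .lineage_rank(tab$taxa$lineage, rank)
  agg <- rowsum(tab$abund, group = labels, reorder = TRUE)
  phyla <- .lineage_rank(tab$taxa$lineage, "phylum")
  lin <- if (rank == "phylum") rownames(agg) else
    vapply(rownames(agg), function(f)
      paste0(phyla[match(f, labels)], ";", f), character(1))
  abundance_table(agg, tab$samples,
                  taxa = data.frame(taxon_id = rownames(agg), lineage = lin,
                                    stringsAsFactors = FALSE),
                  validate = FALSE)
}

#' Rank-level net increases with a retention threshold
#'
#' Collapses phylotypes to families or phyla and screens the rank-level net
#' increases: a rank is retained when its reported net increase reaches the
#' threshold in at least one treatment x molecule stratum. By default
#' abundances are summed to the rank before the net-increase arithmetic
#' (`collapse = "before"`); `collapse = "after"` instead sums the signed
#' per-phylotype nets within each rank.
#'
#' @inheritParams net_increase_matrix
#' @param rank `"family"` or `"phylum"`.
#' @param threshold Retention threshold in percentage points (default 4,
#'   the family-level display threshold).
#' @param collapse Sum abundances `"before"` (default) or sum per-phylotype
#'   nets `"after"` the net-increase arithmetic.
#' @return A long data frame as in [net_increase_matrix()], restricted to
#'   the retained ranks; the full set of rank labels is in attribute
#'   `all_ranks`.
#' @export
aggregate_by_rank <- function(tab, treatments, control,
                              molecules = c("DNA", "RNA"),
                              rank = c("family", "phylum"), threshold = 4,
                              collapse = c("before", "after")) {
  rank <- match.arg(rank)
  collapse <- match.arg(collapse)
  if (collapse == "before") {
    rtab <- aggregate_taxa(tab, rank)
    nets <- net_increase_matrix(rtab, treatments, control, molecules)
  } else {
    nets <- net_increase_matrix(tab, treatments, control, molecules)
    labels <- .lineage_rank(
      tab$taxa$lineage[match(nets$taxon, tab$taxa$taxon_id)], rank)
    agg <- stats::aggregate(
      cbind(delta_treatment, delta_control, net) ~ taxon + treatment +
        molecule,
      data = transform(nets, taxon = labels), FUN = sum)
    agg$net_reported <- pmax(agg$net, 0)
    nets <- agg
  }
  keep <- unique(nets$taxon[nets$net_reported >= threshold])
  out <- nets[nets$taxon %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_ranks") <- sort(unique(nets$taxon))
  attr(out, "threshold") <- threshold
  out
}

#' Screen for stimulated phylotypes
#'
#' A phylotype is considered stimulated when its reported net increase
#' reaches the threshold (inclusive, default 2 percentage points) in at
#' least one supplemented treatment x molecule stratum.
#'
#' @param nets Long net-increase data frame from [net_increase_matrix()].
#' @param threshold Threshold in percentage points.
#' @return Sorted character vector of stimulated phylotype ids; the
#'   per-phylotype maximum reported net is attached as attribute
#'   `max_net`.
#' @export
screen_phylotypes <- function(nets, threshold = 2) {
  stopifnot(all(c("taxon", "net_reported") %in% names(nets)))
  mx <- tapply(nets$net_reported, nets$taxon, max)
  hits <- sort(names(mx)[mx >= threshold])
  structure(hits, max_net = mx[hits])
}
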