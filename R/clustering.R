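# Greedy clustering of stimulated-phylotype representative sequences into
# group phylotypes at >= 97% pairwise identity.

#' Pairwise sequence identity (global, end-gap-free)
#'
#' Identity between two nucleotide sequences defined as matches divided by
#' alignment length under a global alignment with free end gaps (overlap
#' alignment), scored match = 1, mismatch = 0, unit gap cost. IUPAC
#' ambiguity codes are tolerated. No published aligner is implied by this
#' choice; it is the package's fixed, documented definition.
#'
#' @param a,b Sequences as single character strings or
#'   [Biostrings::DNAString] objects.
#' @return Identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)),
    Biostrings::DNAString(as.character(b)),
    type = "overlap", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (len == 0) return(0)
  Biostrings::nmatch(aln) / len
}

# Coerce input to a named DNAStringSet, rejecting non-IUPAC characters with
# the offending record named.
.as_dna_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named")
    out <- vector("list", length(sequences))
    for (i in seq_along(sequences)) {
      out[[i]] <- tryCatch(Biostrings::DNAString(sequences[[i]]),
        error = function(e)
          stop("record '", names(sequences)[i],
               "' contains non-IUPAC nucleotide characters"))
    }
    return(setNames(Biostrings::DNAStringSet(out), names(sequences)))
  }
  stop("sequences must be a named character vector or a DNAStringSet")
}

#' Greedy group-phylotype clustering
#'
#' Clusters representative sequences of stimulated phylotypes into group
#' phylotypes: seeds are taken in order of descending ranking score
#' (typically the maximal net increase across treatments; ties broken by
#' lexicographic id), and each sequence joins the first seed to which its
#' pairwise identity (see [pairwise_identity()]) reaches the threshold;
#' otherwise it founds a new group. Singleton groups are phylotypes that
#' remain ungrouped.
#'
#' @param sequences Named character vector or `DNAStringSet` of
#'   representative sequences.
#' @param ranking Optional named numeric scores used to order the seeds
#'   (missing ids score 0).
#' @param identity_threshold Minimum identity to join a group (default
#'   0.97).
#' @return A data frame of class `"group_phylotypes"` with columns
#'   `phylotype`, `representative`, `identity` (identity to the group
#'   representative) and `group_size`.
#' @export
cluster_group_phylotypes <- function(sequences, ranking = NULL,
                                     identity_threshold = 0.97) {
  seqs <- .as_dna_set(sequences)
  if (length(seqs) == 0) stop("no sequences to cluster")
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  score <- setNames(rep(0, length(ids)), ids)
  if (!is.null(ranking)) {
    known <- intersect(names(ranking), ids)
    score[known] <- as.numeric(ranking[known])
  }
  ord <- ids[order(-score, ids)]
  reps <- character(0)
  assign_rep <- character(0)
  assign_id <- numeric(0)
  for (id in ord) {
    placed <- FALSE
    for (r in reps) {
      idy <- pairwise_identity(seqs[[id]], seqs[[r]])
      if (idy >= identity_threshold) {
        assign_rep[id] <- r
        assign_id[id] <- idy
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign_rep[id] <- id
      assign_id[id] <- 1
    }
  }
  sizes <- table(assign_rep)
  out <- data.frame(phylotype = ids,
                    representative = assign_rep[ids],
                    identity = as.numeric(assign_id[ids]),
                    group_size = as.integer(sizes[assign_rep[ids]]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "identity_threshold") <- identity_threshold
  class(out) <- c("group_phylotypes", "data.frame")
  out
}

#' @export
print.group_phylotypes <- function(x, ...) {
  ng <- length(unique(x$representative))
  cat(sprintf("<group_phylotypes> %d phylotypes in %d groups (>= %s%% id)\n",
              nrow(x), ng, 100 * attr(x, "identity_threshold")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
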