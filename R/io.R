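# Delimited-text readers/writers, FASTA input, report rendering with the
# em-dash / NA conventions of the recovery tables, and the provenance block
# written at the head of every report.

# Auto-detect tab vs comma from the header line; tab is the canonical
# dialect, comma is accepted on read.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a long-format measurement table
#'
#' Reads a delimited text file (tab-separated canonically; comma
#' auto-detected) with columns `treatment`, `replicate`, `time_h`,
#' `analyte`, `amount` and validates it (see [validate_measurements()]):
#' non-numeric amounts, duplicate keys and malformed series are rejected
#' with the offending rows named.
#'
#' @param path File path.
#' @return A validated measurement data frame.
#' @export
read_measurements <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("treatment", "replicate", "time_h", "analyte", "amount")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement file is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("time_h", "amount")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric '", col, "' in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  validate_measurements(df)
}

#' Write a measurement table as tab-separated text
#'
#' @param df A measurement data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  validate_measurements(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylotype abundance table plus sample sheet
#'
#' The taxa table holds columns `taxon_id`, `lineage`, then one column per
#' sample; the sample sheet holds `sample_id`, `treatment`, `time`,
#' `molecule`, `replicate` (empty = pooled). Sample ids must match
#' one-to-one. Columns whose abundance sum deviates from 1 by more than
#' `tol` are rejected under the default policy, or rescaled under
#' `policy = "renormalize"`; columns within tolerance are rescaled to sum
#' exactly 1.
#'
#' @param path_table Taxa table path.
#' @param path_samples Sample sheet path.
#' @param policy `"reject"` (default) or `"renormalize"`.
#' @param tol Allowed deviation of a column sum from 1 (default 1e-6).
#' @return An [abundance_table()].
#' @export
read_abundances <- function(path_table, path_samples,
                            policy = c("reject", "renormalize"),
                            tol = 1e-6) {
  policy <- match.arg(policy)
  tdf <- utils::read.table(path_table, header = TRUE,
                           sep = .detect_sep(path_table),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (!all(c("taxon_id", "lineage") %in% names(tdf)))
    stop("taxa table needs columns 'taxon_id' and 'lineage'")
  sdf <- utils::read.table(path_samples, header = TRUE,
                           sep = .detect_sep(path_samples),
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "treatment", "time", "molecule", "replicate")
  miss <- setdiff(need, names(sdf))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sdf$replicate <- suppressWarnings(as.integer(sdf$replicate))
  sample_cols <- setdiff(names(tdf), c("taxon_id", "lineage"))
  orphan <- setdiff(sample_cols, sdf$sample_id)
  if (length(orphan))
    stop("sample column(s) missing from the sample sheet: ",
         paste(orphan, collapse = ", "))
  orphan2 <- setdiff(sdf$sample_id, sample_cols)
  if (length(orphan2))
    stop("sample sheet row(s) with no abundance column: ",
         paste(orphan2, collapse = ", "))
  abund <- as.matrix(tdf[, sample_cols, drop = FALSE])
  rownames(abund) <- tdf$taxon_id
  if (any(is.na(abund))) stop("non-numeric abundance values")
  if (any(abund < 0)) stop("negative abundance values")
  sums <- colSums(abund)
  off <- which(abs(sums - 1) > tol)
  if (length(off) && policy == "reject")
    stop("abundance column(s) do not sum to 1 (policy 'reject'): ",
         paste(sample_cols[off], collapse = ", "))
  abund <- sweep(abund, 2, sums, "/")
  abundance_table(abund, sdf,
                  taxa = tdf[, c("taxon_id", "lineage")])
}

#' Write an abundance table plus sample sheet as tab-separated text
#'
#' @param tab An [abundance_table()].
#' @param path_table,path_samples Output paths.
#' @return `path_table`, invisibly.
#' @export
write_abundances <- function(tab, path_table, path_samples) {
  stopifnot(inherits(tab, "abundance_table"))
  tdf <- data.frame(taxon_id = tab$taxa$taxon_id,
                    lineage = tab$taxa$lineage,
                    tab$abund, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tdf, path_table, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tab$samples, path_samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path_table)
}

#' Read representative phylotype sequences from FASTA
#'
#' Wrapped lines are tolerated; records containing characters outside the
#' IUPAC nucleotide alphabet are rejected with the record id named.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_phylotype_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  out <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    out[[i]] <- tryCatch(Biostrings::DNAString(as.character(raw[[i]])),
      error = function(e)
        stop("record '", names(raw)[i],
             "' contains non-IUPAC nucleotide characters"))
  }
  setNames(Biostrings::DNAStringSet(out), names(raw))
}

#' Provenance header lines for rendered reports
#'
#' Every report starts with a comment block recording the package version,
#' the seed, a hash of the configuration, and checksums of the input
#' files, so a rendered table can be traced back to the run that produced
#' it.
#'
#' @param config A list of configuration values (hashed after
#'   deparsing).
#' @param seed Seed used for the run (or `NA`).
#' @param inputs Character vector of input file paths to checksum.
#' @return Character vector of `#`-prefixed lines.
#' @export
provenance_lines <- function(config = list(), seed = NA, inputs = character()) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(deparse(config), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  lines <- c(sprintf("# fermstoich %s", as.character(packageVersion("fermstoich"))),
             sprintf("# config_md5 %s", cfg_hash),
             sprintf("# seed %s", as.character(seed)))
  for (p in inputs)
    lines <- c(lines, sprintf("# input %s md5 %s", basename(p),
                              unname(tools::md5sum(p))))
  lines
}

#' Render a recovery table to tab-separated text
#'
#' Layout mirrors the published recovery tables: one row per product,
#' percent recoveries at two significant figures, `NA` for not-applicable
#' cells (no carbon in H2, no electrons in CO2) and an em dash for
#' products with no net increase, followed by a totals row. Output is
#' deterministic and byte-identical for identical inputs and config.
#'
#' @param rt A [recovery_table()].
#' @param path Output path.
#' @param config,seed,inputs Passed to [provenance_lines()].
#' @return `path`, invisibly.
#' @export
write_recovery_report <- function(rt, path, config = list(), seed = NA,
                                  inputs = character()) {
  stopifnot(inherits(rt, "recovery_table"))
  header <- c(provenance_lines(config, seed, inputs),
              sprintf("# substrate %s (basis: %s)", attr(rt, "substrate"),
                      attr(rt, "basis")),
              paste("product", "carbon", "reducing_equivalents", sep = "\t"))
  body <- character(0)
  if (nrow(rt)) {
    cc <- .fmt_recovery_cell(rt$carbon, rt$formed)
    re <- .fmt_recovery_cell(rt$reducing_equivalents, rt$formed)
    body <- paste(rt$product, cc, re, sep = "\t")
    tot <- attr(rt, "totals")
    body <- c(body, paste("Total",
                          format(signif(tot[["carbon"]], 2), trim = TRUE),
                          format(signif(tot[["reducing_equivalents"]], 2),
                                 trim = TRUE), sep = "\t"))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Render a net-increase matrix to tab-separated text
#'
#' Wide layout: taxa in rows, one column per treatment x molecule stratum,
#' reported net increases in percentage points.
#'
#' @param nets Long net-increase data frame from [net_increase_matrix()]
#'   or [aggregate_by_rank()].
#' @param path Output path.
#' @param config,seed,inputs Passed to [provenance_lines()].
#' @return `path`, invisibly.
#' @export
write_net_increase_report <- function(nets, path, config = list(),
                                      seed = NA, inputs = character()) {
  stopifnot(all(c("taxon", "treatment", "molecule", "net_reported") %in%
                  names(nets)))
  header <- provenance_lines(config, seed, inputs)
  if (!nrow(nets)) {
    writeLines(c(header, "taxon"), path)
    return(invisible(path))
  }
  strata <- unique(paste(nets$treatment, nets$molecule, sep = "."))
  taxa <- sort(unique(nets$taxon))
  wide <- matrix(NA_real_, nrow = length(taxa), ncol = length(strata),
                 dimnames = list(taxa, strata))
  wide[cbind(match(nets$taxon, taxa),
             match(paste(nets$treatment, nets$molecule, sep = "."),
                   strata))] <- nets$net_reported
  lines <- c(paste(c("taxon", strata), collapse = "\t"),
             vapply(seq_along(taxa), function(i)
               paste(c(taxa[i], format(signif(wide[i, ], 3), trim = TRUE)),
                     collapse = "\t"), character(1)))
  writeLines(c(header, lines), path)
  invisible(path)
}
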