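# Shared fixtures and independent oracles used across the suite.

# Long measurement table with one product measured at 0 and 30 h.
two_point_measurements <- function(trt_start, trt_end, ctl_start, ctl_end,
                                   analyte = "acetate",
                                   treatment = "glutamate",
                                   control = "control", reps = 1) {
  rows <- list()
  for (r in seq_len(reps)) {
    rows[[length(rows) + 1]] <- data.frame(
      treatment = treatment, replicate = r, time_h = c(0, 30),
      analyte = analyte, amount = c(trt_start, trt_end))
    rows[[length(rows) + 1]] <- data.frame(
      treatment = control, replicate = r, time_h = c(0, 30),
      analyte = analyte, amount = c(ctl_start, ctl_end))
  }
  do.call(rbind, rows)
}

# Four-sample pooled abundance table (one molecule, DNA): columns are
# per-taxon fractions for treatment/control at t0/t_end; each column must
# sum to 1.
pooled_abundance_fixture <- function(taxa, trt_t0, trt_tend, ctl_t0,
                                     ctl_tend, treatment = "glutamate",
                                     control = "control") {
  abund <- cbind(trt.t0 = trt_t0, trt.tend = trt_tend,
                 ctl.t0 = ctl_t0, ctl.tend = ctl_tend)
  rownames(abund) <- taxa
  samples <- data.frame(
    sample_id = colnames(abund),
    treatment = c(treatment, treatment, control, control),
    time = c("t0", "t_end", "t0", "t_end"),
    molecule = "DNA",
    replicate = NA_integer_)
  abundance_table(abund, samples)
}

# Hamming identity: exact identity oracle for equal-length,
# substitution-only sequences (no indels, so the optimal end-gap-free
# alignment is the ungapped one).
hamming_identity <- function(a, b) {
  av <- strsplit(as.character(a), "")[[1]]
  bv <- strsplit(as.character(b), "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av == bv)
}

# Independent greedy clustering oracle on a precomputed identity function.
greedy_cluster_oracle <- function(ids, identity_fun, ranking, threshold) {
  ord <- ids[order(-ranking[ids], ids)]
  reps <- character(0)
  assign <- character(0)
  for (id in ord) {
    placed <- FALSE
    for (r in reps) {
      if (identity_fun(id, r) >= threshold) {
        assign[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[id] <- id
    }
  }
  assign[ids]
}
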