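# Control-subtracted net product formation and the percent recovery of
# substrate carbon and reducing equivalents, plus the collective-product
# significance test and the linear ammonium standard-curve calibration.

#' Validate a long-format measurement table
#'
#' Measurement tables are long data frames with columns `treatment`,
#' `replicate`, `time_h`, `analyte` and `amount` (umol per g fresh weight).
#' Each (treatment, replicate, analyte) series must start at 0 h, have
#' strictly increasing times, and non-negative amounts.
#'
#' @param df A data frame of measurements.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_measurements <- function(df) {
  need <- c("treatment", "replicate", "time_h", "analyte", "amount")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(df$time_h)) stop("'time_h' must be numeric")
  if (!is.numeric(df$amount)) stop("'amount' must be numeric")
  bad <- which(is.na(df$amount) | df$amount < 0)
  if (length(bad))
    stop("non-numeric or negative amount in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(df$treatment, df$replicate, df$time_h, df$analyte, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (treatment, replicate, time, analyte) in row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  series <- split(df$time_h,
                  paste(df$treatment, df$replicate, df$analyte, sep = "\r"))
  for (nm in names(series)) {
    tt <- sort(series[[nm]])
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    lab <- sprintf("(%s, %s, %s)", parts[1], parts[2], parts[3])
    if (tt[1] != 0)
      stop("series ", lab, " does not start at 0 h")
    if (any(diff(tt) <= 0))
      stop("series ", lab, " has non-increasing time points")
  }
  df
}

# Replicate-mean amount per analyte at one time point for one treatment.
.endpoint_means <- function(df, treatment, time, analytes) {
  sub <- df[df$treatment == treatment & df$time_h == time &
              df$analyte %in% analytes, , drop = FALSE]
  means <- tapply(sub$amount, factor(sub$analyte, levels = analytes), mean)
  as.numeric(means)
}

#' Net product formation relative to an unsupplemented control
#'
#' For each analyte, the replicate-mean amount change over the incubation in
#' the supplemented treatment minus the corresponding change in the control:
#' net = (treatment\[t_end\] - treatment\[0\]) - (control\[t_end\] -
#' control\[0\]). Analytes whose net change is not positive carry a net of 0
#' and `formed = FALSE` (rendered as an em dash in reports). Analytes absent
#' from the control are treated as a control change of 0, with a warning.
#'
#' @param measurements A validated long measurement table (see
#'   [validate_measurements()]).
#' @param treatment,control Treatment ids present in `measurements`.
#' @param t_end Endpoint time in hours (default 30).
#' @param analytes Optional character vector restricting the analytes
#'   (e.g. to exclude the supplemented substrate itself); defaults to all
#'   analytes of the treatment.
#' @return A data frame of class `"net_product_table"` with columns
#'   `analyte`, `delta_treatment`, `delta_control`, `net`, `formed`.
#' @export
net_product_formation <- function(measurements, treatment, control,
                                  t_end = 30, analytes = NULL) {
  df <- validate_measurements(measurements)
  trt <- df[df$treatment == treatment, , drop = FALSE]
  if (!nrow(trt)) stop("treatment '", treatment, "' not found")
  if (is.null(analytes)) analytes <- sort(unique(trt$analyte))
  if (!any(trt$time_h == t_end))
    stop("treatment '", treatment, "' has no measurements at t_end = ",
         t_end, " h")
  ctl <- df[df$treatment == control, , drop = FALSE]
  if (!nrow(ctl)) stop("control '", control, "' not found")
  if (!any(ctl$time_h == t_end))
    stop("control '", control, "' has no measurements at t_end = ",
         t_end, " h")
  missing_ctl <- setdiff(analytes, unique(ctl$analyte))
  if (length(missing_ctl))
    warning("analyte(s) missing from control, assuming control change 0: ",
            paste(missing_ctl, collapse = ", "))
  d_trt <- .endpoint_means(df, treatment, t_end, analytes) -
    .endpoint_means(df, treatment, 0, analytes)
  d_ctl <- .endpoint_means(df, control, t_end, analytes) -
    .endpoint_means(df, control, 0, analytes)
  d_ctl[is.na(d_ctl)] <- 0
  if (any(is.na(d_trt)))
    stop("analyte(s) missing an endpoint in the treatment: ",
         paste(analytes[is.na(d_trt)], collapse = ", "))
  net_raw <- d_trt - d_ctl
  formed <- net_raw > 0
  out <- data.frame(analyte = analytes, delta_treatment = d_trt,
                    delta_control = d_ctl,
                    net = ifelse(formed, net_raw, 0), formed = formed,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "treatment") <- treatment
  attr(out, "control") <- control
  attr(out, "t_end") <- t_end
  class(out) <- c("net_product_table", "data.frame")
  out
}

#' Per-replicate net product tables
#'
#' Same arithmetic as [net_product_formation()] but with one table per
#' treatment replicate (each replicate's change minus the control
#' replicate-mean change), used for replicate-level statistics.
#'
#' @inheritParams net_product_formation
#' @return A named list of `net_product_table` data frames, one per
#'   replicate.
#' @export
net_product_formation_by_replicate <- function(measurements, treatment,
                                               control, t_end = 30,
                                               analytes = NULL) {
  df <- validate_measurements(measurements)
  trt <- df[df$treatment == treatment, , drop = FALSE]
  if (!nrow(trt)) stop("treatment '", treatment, "' not found")
  if (is.null(analytes)) analytes <- sort(unique(trt$analyte))
  d_ctl <- .endpoint_means(df, control, t_end, analytes) -
    .endpoint_means(df, control, 0, analytes)
  d_ctl[is.na(d_ctl)] <- 0
  reps <- sort(unique(trt$replicate))
  out <- lapply(reps, function(r) {
    sub <- trt[trt$replicate == r, , drop = FALSE]
    a0 <- .endpoint_means(sub, treatment, 0, analytes)
    a1 <- .endpoint_means(sub, treatment, t_end, analytes)
    net_raw <- (a1 - a0) - d_ctl
    formed <- !is.na(net_raw) & net_raw > 0
    data.frame(analyte = analytes,
               net = ifelse(formed, net_raw, 0), formed = formed,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  setNames(out, as.character(reps))
}

#' Substrate dose for recovery calculations
#'
#' Recoveries can be based on the amount of substrate provided or on the
#' amount consumed (initial minus final measured substrate, replicate
#' means). Consumed amounts are clamped to \[0, provided\] with a warning,
#' so measurement noise can never produce a negative or inflated
#' denominator.
#'
#' @param compound Substrate name (must resolve in the registry used later).
#' @param provided Amount provided (umol per g fresh weight), > 0.
#' @param basis `"provided"` (default) or `"consumed"`.
#' @param measurements Long measurement table containing the substrate
#'   series (required when `basis = "consumed"`).
#' @param treatment Treatment id holding the substrate series.
#' @param t_end Endpoint hour used for the consumed amount.
#' @return An object of class `"substrate_dose"` with the resolved `amount`
#'   on the requested basis.
#' @export
substrate_dose <- function(compound, provided,
                           basis = c("provided", "consumed"),
                           measurements = NULL, treatment = NULL,
                           t_end = 30) {
  basis <- match.arg(basis)
  if (!is.numeric(provided) || provided <= 0)
    stop("'provided' must be a positive amount")
  amount <- provided
  if (basis == "consumed") {
    if (is.null(measurements) || is.null(treatment))
      stop("basis = 'consumed' requires 'measurements' and 'treatment'")
    df <- validate_measurements(measurements)
    a0 <- .endpoint_means(df, treatment, 0, compound)
    a1 <- .endpoint_means(df, treatment, t_end, compound)
    if (any(is.na(c(a0, a1))))
      stop("no measured series for substrate '", compound,
           "' in treatment '", treatment, "'")
    consumed <- a0 - a1
    if (consumed < 0) {
      warning("negative consumed-substrate estimate clamped to 0")
      consumed <- 0
    }
    if (consumed > provided) {
      warning("consumed-substrate estimate exceeds the amount provided; ",
              "clamped to the provided amount")
      consumed <- provided
    }
    amount <- consumed
  }
  structure(list(compound = tolower(compound), provided = provided,
                 basis = basis, amount = amount, t_end = t_end),
            class = "substrate_dose")
}

.recovery_one <- function(net, dose, registry, what = c("carbon", "electron")) {
  what <- match.arg(what)
  stopifnot(inherits(net, "net_product_table"),
            inherits(dose, "substrate_dose"))
  substrate <- registry_get(registry, dose$compound)
  denom_per_mol <- if (what == "carbon") substrate$carbons
                   else substrate$electrons
  if (denom_per_mol <= 0)
    stop("substrate '", dose$compound, "' has no ",
         if (what == "carbon") "carbon" else "electrons",
         "; recovery is undefined")
  if (dose$amount <= 0)
    stop("substrate dose amount is 0; recovery is undefined")
  vals <- vapply(seq_len(nrow(net)), function(i) {
    cm <- registry_get(registry, net$analyte[i])
    num_per_mol <- if (what == "carbon") cm$carbons else cm$electrons
    if (num_per_mol <= 0) return(NA_real_)  # H2 carries no C; CO2 no e-
    if (!net$formed[i]) return(NA_real_)    # rendered as em dash
    100 * net$net[i] * num_per_mol / (dose$amount * denom_per_mol)
  }, numeric(1))
  total <- sum(vals[net$formed], na.rm = TRUE)
  structure(setNames(vals, net$analyte), total = total)
}

#' Percent recovery of substrate carbon in each product
#'
#' 100 * net_product * C_product / (dose * C_substrate) per formed product.
#' Products without carbon (H2) are `NA` ("not applicable"); products with
#' no net increase are `NA` and rendered as an em dash. The `"total"`
#' attribute sums the formed products.
#'
#' @param net A [net_product_formation()] table.
#' @param dose A [substrate_dose()].
#' @param registry A compound registry (see [default_registry()]).
#' @return Named numeric vector of percent recoveries with a `total`
#'   attribute.
#' @export
carbon_recovery <- function(net, dose, registry = default_registry()) {
  .recovery_one(net, dose, registry, "carbon")
}

#' Percent recovery of substrate reducing equivalents in each product
#'
#' 100 * net_product * e_product / (dose * e_substrate), with electrons per
#' molecule from the degree-of-reduction rule. CO2 carries no electrons and
#' is `NA`; H2 contributes 2 electrons per molecule and no carbon.
#'
#' @inheritParams carbon_recovery
#' @return Named numeric vector of percent recoveries with a `total`
#'   attribute.
#' @export
electron_recovery <- function(net, dose, registry = default_registry()) {
  .recovery_one(net, dose, registry, "electron")
}

#' Combined carbon / reducing-equivalent recovery table
#'
#' Assembles the per-product carbon and reducing-equivalent (RE) percent
#' recoveries and their totals, mirroring the layout of the published
#' recovery tables: `NA` marks a not-applicable cell (no carbon in H2, no
#' electrons in CO2) and products with no net increase are flagged via
#' `formed` and rendered as an em dash by [write_recovery_report()].
#'
#' @inheritParams carbon_recovery
#' @return A data frame of class `"recovery_table"` with columns `product`,
#'   `formed`, `carbon`, `reducing_equivalents`, and attributes `totals`,
#'   `substrate`, `basis`.
#' @export
recovery_table <- function(net, dose, registry = default_registry()) {
  cc <- carbon_recovery(net, dose, registry)
  re <- electron_recovery(net, dose, registry)
  out <- data.frame(product = net$analyte, formed = net$formed,
                    carbon = as.numeric(cc),
                    reducing_equivalents = as.numeric(re),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "totals") <- c(carbon = attr(cc, "total"),
                           reducing_equivalents = attr(re, "total"))
  attr(out, "substrate") <- dose$compound
  attr(out, "basis") <- dose$basis
  class(out) <- c("recovery_table", "data.frame")
  out
}

#' @export
print.recovery_table <- function(x, ...) {
  cat(sprintf("Recovery of %s (basis: %s)\n", attr(x, "substrate"),
              attr(x, "basis")))
  df <- as.data.frame(x)
  df$carbon <- .fmt_recovery_cell(x$carbon, x$formed)
  df$reducing_equivalents <- .fmt_recovery_cell(x$reducing_equivalents,
                                                x$formed)
  print(df[, c("product", "carbon", "reducing_equivalents")],
        row.names = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf("Total: %s%% C, %s%% RE\n", signif(tot[["carbon"]], 2),
              signif(tot[["reducing_equivalents"]], 2)))
  invisible(x)
}

# Rendering rule shared by print and the report writer: 2 significant
# figures, em dash for no-net-increase, NA for not-applicable cells.
.fmt_recovery_cell <- function(values, formed) {
  vapply(seq_along(values), function(i) {
    if (!formed[i]) return("—")
    if (is.na(values[i])) return("NA")
    format(signif(values[i], 2), trim = TRUE, scientific = FALSE)
  }, character(1))
}

#' Collective amount of fermentation products per replicate
#'
#' Per replicate, the sum over products of the control-corrected net amount
#' formed by the incubation endpoint (negative per-product nets count as
#' 0). With `control = NULL` no control subtraction is applied (used for
#' the control treatment itself).
#'
#' @inheritParams net_product_formation
#' @param control Control treatment id, or `NULL` for no subtraction.
#' @return A list with `per_replicate` (named numeric vector), `mean` and
#'   `sd`.
#' @export
collective_products <- function(measurements, treatment, control = NULL,
                                t_end = 30, analytes = NULL) {
  df <- validate_measurements(measurements)
  trt <- df[df$treatment == treatment, , drop = FALSE]
  if (!nrow(trt)) stop("treatment '", treatment, "' not found")
  if (is.null(analytes)) analytes <- sort(unique(trt$analyte))
  d_ctl <- if (is.null(control)) rep(0, length(analytes)) else {
    d <- .endpoint_means(df, control, t_end, analytes) -
      .endpoint_means(df, control, 0, analytes)
    d[is.na(d)] <- 0
    d
  }
  reps <- sort(unique(trt$replicate))
  sums <- vapply(reps, function(r) {
    sub <- trt[trt$replicate == r, , drop = FALSE]
    a0 <- .endpoint_means(sub, treatment, 0, analytes)
    a1 <- .endpoint_means(sub, treatment, t_end, analytes)
    net <- (a1 - a0) - d_ctl
    sum(pmax(net, 0), na.rm = TRUE)
  }, numeric(1))
  sums <- setNames(sums, as.character(reps))
  list(per_replicate = sums, mean = mean(sums),
       sd = if (length(sums) > 1) sd(sums) else 0)
}

#' Unequal-variance (Welch) t test
#'
#' Closed-form Welch statistic t = (m_a - m_b) / sqrt(s_a^2/n_a +
#' s_b^2/n_b) with the Welch-Satterthwaite degrees of freedom and a
#' two-sided p value. When both group variances are zero the test is
#' degenerate: p = 1 for equal means, p = 0 (with a warning) otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `statistic`, `df`, `p.value` and the two group
#'   means.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(c(a, b)))) stop("non-finite observations")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    warning("both group variances are zero; degenerate test")
    if (ma == mb)
      return(list(statistic = 0, df = na + nb - 2, p.value = 1,
                  means = c(a = ma, b = mb)))
    return(list(statistic = sign(ma - mb) * Inf, df = na + nb - 2,
                p.value = 0, means = c(a = ma, b = mb)))
  }
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * pt(-abs(tstat), df), means = c(a = ma, b = mb))
}

#' Linear standard-curve calibration (ammonium colorimetry)
#'
#' Ordinary least-squares line through (concentration, absorbance)
#' standards; sample absorbances are inverted through the fitted line.
#' Samples outside the standard absorbance range are flagged as
#' extrapolated.
#'
#' @param standards Data frame with columns `concentration` (strictly
#'   increasing) and `absorbance`; at least two standards.
#' @param absorbances Numeric vector of sample absorbances.
#' @return A data frame with `absorbance`, `concentration`,
#'   `extrapolated`; the fitted `lm` is attached as attribute `fit`.
#' @export
ammonium_calibration <- function(standards, absorbances) {
  need <- c("concentration", "absorbance")
  if (!all(need %in% names(standards)))
    stop("standards need columns 'concentration' and 'absorbance'")
  if (nrow(standards) < 2) stop("at least two standards are required")
  if (any(diff(standards$concentration) <= 0))
    stop("standard concentrations must be strictly increasing")
  fit <- lm(absorbance ~ concentration, data = standards)
  slope <- coef(fit)[["concentration"]]
  if (!is.finite(slope) || slope == 0)
    stop("singular standard curve (zero slope)")
  conc <- (absorbances - coef(fit)[["(Intercept)"]]) / slope
  rng <- range(standards$absorbance)
  out <- data.frame(absorbance = absorbances, concentration = conc,
                    extrapolated = absorbances < rng[1] |
                      absorbances > rng[2])
  attr(out, "fit") <- fit
  out
}
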