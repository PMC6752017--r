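# Elemental formulas, degree-of-reduction electron accounting, and the unit
# conversions used throughout the microcosm bookkeeping.

# Electrons liberated per atom on complete oxidation to CO2, H2O and NH3
# (degree-of-reduction convention; S referenced to sulfate, P carries no
# electrons under this convention and is ignored with a warning).
.electron_weights <- c(C = 4, H = 1, N = -3, O = -2, S = 6, P = 0)

#' Parse a molecular formula string
#'
#' Parses formulas such as `"C5H9NO4"` into element counts. Only the
#' biologically relevant elements C, H, N, O, S and P are accepted; an
#' element symbol without a trailing number has an implicit count of 1.
#'
#' @param text A single formula string, e.g. `"C6H12O6"`.
#' @return A named integer vector of element counts with class
#'   `"elemental_formula"`. `format()` renders the canonical string
#'   (element order C, H, N, O, P, S), so parsing round-trips.
#' @examples
#' parse_formula("C5H9NO4")   # glutamate
#' parse_formula("CH2O2")     # formate
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single formula string")
  if (!nzchar(text)) stop("empty formula string")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1L]]
    if (length(m) == 0L || !nzchar(m[2L]))
      stop(sprintf("malformed formula '%s' at position %d", text, pos))
    sym <- m[2L]
    if (!sym %in% names(.electron_weights))
      stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                   sym, text, pos))
    cnt <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m[1L])
  }
  if (sum(counts) < 1L)
    stop(sprintf("formula '%s' contains no atoms", text))
  structure(counts, class = "elemental_formula")
}

#' @exportS3Method base::format
format.elemental_formula <- function(x, ...) {
  ord <- c("C", "H", "N", "O", "P", "S")
  syms <- ord[ord %in% names(x)[unclass(x) > 0]]
  paste0(vapply(syms, function(s)
    paste0(s, if (x[[s]] > 1L) x[[s]] else ""), character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.elemental_formula <- function(x, ...) format(x)

# Accept either a formula object or a formula string.
as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

formula_count <- function(f, element) {
  if (element %in% names(f)) f[[element]] else 0L
}

#' Degree of reduction per carbon atom
#'
#' Electrons available per carbon atom on complete oxidation, under the
#' standard degree-of-reduction convention with reference compounds CO2, H2O
#' and NH3: \eqn{(4C + 1H - 2O - 3N)/C} (S, if present, contributes +6; P
#' contributes 0 and triggers a warning). This single convention reproduces
#' the electron coefficients used for every substrate in the recovery
#' tables, e.g. 3.6 e/C for glutamate and 4.8 e/C for valine.
#'
#' @param f An `elemental_formula` or a formula string.
#' @return Electrons per carbon atom (numeric scalar).
#' @examples
#' degree_of_reduction_per_carbon("C5H9NO4")  # glutamate: 3.6
#' degree_of_reduction_per_carbon("C4H6O4")   # succinate: 3.5
#' @seealso [electrons_per_molecule()] for carbon-free species such as H2.
#' @export
degree_of_reduction_per_carbon <- function(f) {
  f <- as_formula(f)
  nc <- formula_count(f, "C")
  if (nc < 1L)
    stop("formula has no carbon; electrons per carbon is undefined ",
         "(use electrons_per_molecule() instead)")
  .formula_electrons(f) / nc
}

.formula_electrons <- function(f) {
  if (formula_count(f, "P") > 0L)
    warning("phosphorus carries weight 0 in the degree-of-reduction ",
            "convention and is ignored")
  sum(.electron_weights[names(f)] * unclass(f))
}

#' Electrons available per molecule
#'
#' Total electrons liberated on complete oxidation of one molecule, i.e. the
#' degree of reduction per carbon times the carbon count for carbon
#' compounds, and the same atom-weight rule applied directly for carbon-free
#' species (H2 yields 2 electrons).
#'
#' @param x A [compound()], an `elemental_formula`, or a formula string.
#' @return Electrons per molecule (numeric scalar).
#' @examples
#' electrons_per_molecule("C5H9NO4")  # glutamate: 18
#' electrons_per_molecule("H2")       # 2
#' @export
electrons_per_molecule <- function(x) {
  if (inherits(x, "compound")) return(x$electrons)
  f <- as_formula(x)
  .formula_electrons(f)
}

#' Define a compound for stoichiometric bookkeeping
#'
#' A compound is either backed by a molecular formula (carbons and electrons
#' are derived from it) or, for undefined mixtures such as Casamino Acids,
#' by an explicit carbons-per-molecule and electrons-per-carbon override.
#' When both a formula and an override are supplied the override must agree
#' with the formula-derived value unless `mixture = TRUE`.
#'
#' @param name Compound name (used as the registry key).
#' @param formula Optional formula string or `elemental_formula`.
#' @param carbons Optional carbons per molecule (required when no formula).
#' @param electrons_per_carbon Optional electrons-per-carbon override.
#' @param molar_mass Optional molar mass in g/mol.
#' @param mixture Logical; `TRUE` marks a pseudo-compound (mixture) whose
#'   override may differ from any formula.
#' @return An object of class `"compound"`.
#' @examples
#' compound("glutamate", "C5H9NO4")
#' compound("casamino_acids", carbons = 4, electrons_per_carbon = 4.2,
#'          mixture = TRUE)
#' @export
compound <- function(name, formula = NULL, carbons = NULL,
                     electrons_per_carbon = NULL, molar_mass = NULL,
                     mixture = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(formula) && (is.null(carbons) || is.null(electrons_per_carbon)))
    stop("compound '", name, "' needs a formula or an explicit ",
         "carbons + electrons_per_carbon override")
  f <- if (!is.null(formula)) as_formula(formula) else NULL
  if (!is.null(f)) {
    nc <- formula_count(f, "C")
    epc <- if (nc > 0L) .formula_electrons(f) / nc else NA_real_
    if (is.null(carbons)) carbons <- nc
    if (!is.null(electrons_per_carbon) && !mixture) {
      if (is.na(epc) || abs(electrons_per_carbon - epc) > 1e-9)
        stop("compound '", name, "': electrons_per_carbon override (",
             electrons_per_carbon, ") disagrees with the formula-derived ",
             "value (", epc, "); set mixture = TRUE for pseudo-compounds")
    }
    if (is.null(electrons_per_carbon)) electrons_per_carbon <- epc
  }
  if (carbons < 0) stop("carbons must be >= 0")
  # carbon-free species (H2): store electrons via the per-molecule route
  electrons <- if (!is.null(f) && formula_count(f, "C") == 0L)
    .formula_electrons(f) else carbons * electrons_per_carbon
  if (!is.null(electrons_per_carbon) && !is.na(electrons_per_carbon) &&
      electrons_per_carbon < 0)
    stop("electrons_per_carbon must be >= 0")
  structure(list(name = name, formula = f, carbons = as.numeric(carbons),
                 electrons_per_carbon =
                   if (is.null(electrons_per_carbon)) NA_real_
                   else electrons_per_carbon,
                 electrons = as.numeric(electrons),
                 molar_mass = molar_mass, mixture = isTRUE(mixture)),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s%s: %s C, %s e-/molecule%s\n", x$name,
              if (x$mixture) " (mixture)" else "",
              format(x$carbons), format(x$electrons),
              if (!is.null(x$formula)) paste0(" [", format(x$formula), "]")
              else ""))
  invisible(x)
}

#' Slurry parameters for unit conversion
#'
#' Defaults describe one microcosm: 1 g fresh weight of gut content in a
#' 10-ml slurry, with a dry-mass fraction of 0.45 g dry weight per g fresh
#' weight.
#'
#' @param fresh_weight_g Gut content fresh weight per microcosm (g).
#' @param volume_ml Slurry volume (ml).
#' @param dry_fraction Dry mass per fresh mass (g/g).
#' @return An object of class `"slurry_params"`.
#' @export
slurry_params <- function(fresh_weight_g = 1, volume_ml = 10,
                          dry_fraction = 0.45) {
  if (fresh_weight_g <= 0 || volume_ml <= 0 || dry_fraction <= 0)
    stop("slurry parameters must be positive")
  structure(list(fresh_weight_g = fresh_weight_g, volume_ml = volume_ml,
                 dry_fraction = dry_fraction), class = "slurry_params")
}

.amount_units <- c("umol_per_gFW", "umol_per_gDW", "mM")

#' Convert amounts between per-fresh-weight, per-dry-weight and molarity
#'
#' Linear, invertible conversions between micromoles per gram fresh weight,
#' micromoles per gram dry weight, and millimolar in the slurry aqueous
#' phase. With the default slurry (1 g FW in 10 ml, dry fraction 0.45),
#' 100 umol/gFW equals 10 mM and 222 umol/gDW.
#'
#' @param value Numeric vector of amounts.
#' @param from,to Units, one of `"umol_per_gFW"`, `"umol_per_gDW"`, `"mM"`.
#' @param slurry A [slurry_params()] object.
#' @return Converted numeric vector.
#' @examples
#' convert_amount(100, "umol_per_gFW", "mM")           # 10
#' convert_amount(100, "umol_per_gFW", "umol_per_gDW") # 222.2
#' @export
convert_amount <- function(value, from, to, slurry = slurry_params()) {
  from <- match.arg(from, .amount_units)
  to <- match.arg(to, .amount_units)
  stopifnot(inherits(slurry, "slurry_params"))
  # canonical intermediate: umol per g fresh weight
  fw <- switch(from,
    umol_per_gFW = value,
    umol_per_gDW = value * slurry$dry_fraction,
    mM = value * slurry$volume_ml / slurry$fresh_weight_g)
  switch(to,
    umol_per_gFW = fw,
    umol_per_gDW = fw / slurry$dry_fraction,
    mM = fw * slurry$fresh_weight_g / slurry$volume_ml)
}

#' Monomer concentration in microbial cytoplasm
#'
#' Back-of-envelope estimate of the polymeric monomer concentration in
#' cytoplasm from mass fractions, assuming cytoplasm density 1 g/ml:
#' \deqn{c = 1000 \cdot f_{dry} \cdot f_{polymer} \cdot f_{monomer} / MW}
#' in mol/L. With 20\% dry mass of which 50\% is protein and a mean residue
#' mass of 100 g/mol this yields 1 M polymeric amino acids; with 20\% RNA of
#' which 40\% is ribose (MW 150.13) it yields roughly 0.1 M polymeric
#' ribose.
#'
#' @param dry_fraction Dry mass fraction of cytoplasm, in (0, 1].
#' @param polymer_fraction Polymer mass fraction of the dry mass, in (0, 1].
#' @param monomer_mw Monomer molecular weight (g/mol).
#' @param monomer_fraction Monomer mass fraction of the polymer, in (0, 1].
#' @return Concentration in mol/L.
#' @examples
#' cytoplasm_concentration(0.20, 0.50, 100)          # 1 M amino acids
#' cytoplasm_concentration(0.20, 0.20, 150.13, 0.40) # ~0.107 M ribose
#' @export
cytoplasm_concentration <- function(dry_fraction, polymer_fraction,
                                    monomer_mw, monomer_fraction = 1) {
  fr <- c(dry_fraction, polymer_fraction, monomer_fraction)
  if (any(fr <= 0) || any(fr > 1))
    stop("all mass fractions must lie in (0, 1]")
  if (monomer_mw <= 0) stop("monomer_mw must be positive")
  1000 * dry_fraction * polymer_fraction * monomer_fraction / monomer_mw
}
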