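# Registry of the substrates and products tracked in the recovery tables.

#' Default compound registry
#'
#' All substrates and fermentation products that appear in the recovery
#' tables, keyed by lowercase name. Casamino Acids are an acid-hydrolyzed
#' casein mixture and are modeled as a pseudo-compound with a fixed 4.2
#' electrons per carbon atom; its carbon-per-"molecule" basis and mean
#' residue mass are configurable because no unique molecular formula
#' exists (the defaults, 4 carbons and 100 g/mol, follow the mean
#' amino-acid-residue assumption and are flagged as assumed, not asserted).
#' "methylbutyrate" denotes the chromatographic peak without positional
#' isomer and is assigned the 2-methylbutyrate formula C5H10O2.
#'
#' @param casamino_carbons Carbons per mole basis for Casamino Acids.
#' @param casamino_mw Mean residue molar mass for Casamino Acids (g/mol).
#' @return A named list of [compound()] objects with class
#'   `"compound_registry"`.
#' @export
default_registry <- function(casamino_carbons = 4, casamino_mw = 100) {
  cmp <- list(
    compound("glutamate",      "C5H9NO4",  molar_mass = 147.13),
    compound("aspartate",      "C4H7NO4",  molar_mass = 133.10),
    compound("threonine",      "C4H9NO3",  molar_mass = 119.12),
    compound("alanine",        "C3H7NO2",  molar_mass = 89.09),
    compound("glycine",        "C2H5NO2",  molar_mass = 75.07),
    compound("valine",         "C5H11NO2", molar_mass = 117.15),
    compound("leucine",        "C6H13NO2", molar_mass = 131.17),
    compound("casamino_acids", carbons = casamino_carbons,
             electrons_per_carbon = 4.2, molar_mass = casamino_mw,
             mixture = TRUE),
    compound("ribose",         "C5H10O5",  molar_mass = 150.13),
    compound("glucose",        "C6H12O6",  molar_mass = 180.16),
    compound("succinate",      "C4H6O4",   molar_mass = 118.09),
    compound("formate",        "CH2O2",    molar_mass = 46.03),
    compound("co2",            "CO2",      molar_mass = 44.01),
    compound("h2",             "H2",       molar_mass = 2.016),
    compound("acetate",        "C2H4O2",   molar_mass = 60.05),
    compound("ethanol",        "C2H6O",    molar_mass = 46.07),
    compound("lactate",        "C3H6O3",   molar_mass = 90.08),
    compound("propionate",     "C3H6O2",   molar_mass = 74.08),
    compound("butyrate",       "C4H8O2",   molar_mass = 88.11),
    compound("isobutyrate",    "C4H8O2",   molar_mass = 88.11),
    compound("methylbutyrate", "C5H10O2",  molar_mass = 102.13)
  )
  structure(setNames(cmp, vapply(cmp, `[[`, character(1), "name")),
            class = "compound_registry")
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("<compound_registry> ", length(x), " compounds: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Look up a compound in a registry
#'
#' @param registry A `compound_registry` (see [default_registry()]).
#' @param name Compound name (case-insensitive).
#' @return The matching [compound()].
#' @export
registry_get <- function(registry, name) {
  stopifnot(inherits(registry, "compound_registry"))
  key <- tolower(name)
  if (!key %in% names(registry))
    stop("compound '", name, "' is not in the registry")
  registry[[key]]
}

#' Write / read a compound registry as tab-separated text
#'
#' Columns: name, formula (empty for pure overrides), carbons,
#' electrons_per_carbon, molar_mass, mixture.
#'
#' @param registry A `compound_registry`.
#' @param path File path.
#' @return `read_registry()` returns a `compound_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "compound_registry"))
  df <- data.frame(
    name = names(registry),
    formula = vapply(registry, function(c)
      if (is.null(c$formula)) "" else format(c$formula), character(1)),
    carbons = vapply(registry, `[[`, numeric(1), "carbons"),
    electrons_per_carbon = vapply(registry, `[[`, numeric(1),
                                  "electrons_per_carbon"),
    molar_mass = vapply(registry, function(c)
      if (is.null(c$molar_mass)) NA_real_ else c$molar_mass, numeric(1)),
    mixture = vapply(registry, `[[`, logical(1), "mixture"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "carbons", "electrons_per_carbon", "mixture")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry file is missing column(s): ", paste(miss, collapse = ", "))
  cmp <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    has_formula <- !is.na(r$formula) && nzchar(r$formula)
    compound(r$name,
             formula = if (has_formula) r$formula else NULL,
             carbons = if (!is.na(r$carbons)) r$carbons else NULL,
             electrons_per_carbon =
               if (!is.na(r$electrons_per_carbon)) r$electrons_per_carbon
               else NULL,
             molar_mass = if (!is.na(r$molar_mass)) r$molar_mass else NULL,
             mixture = isTRUE(r$mixture))
  })
  structure(setNames(cmp, tolower(df$name)), class = "compound_registry")
}
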