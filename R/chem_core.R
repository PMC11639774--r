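# Monoisotopic-mass arithmetic and the registries (aglycones, modifications,
# diagnostic losses) that every annotation rule references.

# Monoisotopic masses of the most abundant isotope (CODATA/NIST values).
.ISOTOPE_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268,
  F  = 18.99840322
)

# Mass of a proton; electron mass is accounted for, so [M+H]+ m/z is
# neutral monoisotopic mass + 1.007276, not + 1.007825.
PROTON_MASS <- 1.00727646688

#' Parse a molecular formula string
#'
#' Parses a Hill-notation formula such as `"C15H10O7"` into a named integer
#' vector of element counts. Multi-letter element symbols (Na, Cl, ...) are
#' supported; counts default to 1 when omitted.
#'
#' @param x Formula string, e.g. `"C6H10O5"`.
#' @return A named integer vector of class `mol_formula`.
#' @examples
#' parse_formula("C15H10O7")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  matched <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(matched)) != nchar(x)) {
    stop("malformed formula string: '", x, "'", call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", matched)
  counts <- as.integer(ifelse(grepl("[0-9]+$", matched),
                              sub("^[A-Za-z]+", "", matched), "1"))
  out <- tapply(counts, elems, sum)
  mol_formula(stats::setNames(as.integer(out), names(out)))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector, element symbol -> count.
#' @return Object of class `mol_formula`.
#' @export
mol_formula <- function(counts) {
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  counts <- counts[counts != 0]
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  storage.mode(counts) <- "integer"
  # canonical order: Hill convention (C, H, then alphabetical)
  nm <- names(counts)
  ord <- order(match(nm, c("C", "H"), nomatch = 3L), nm)
  structure(counts[ord], class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Merge molecular formulas by summing element counts
#'
#' @param ... Objects coercible with [parse_formula()] / [mol_formula()].
#' @return A `mol_formula` with summed counts.
#' @export
formula_sum <- function(...) {
  fl <- lapply(list(...), as_formula)
  all_counts <- unlist(lapply(fl, unclass))
  mol_formula(stats::setNames(as.integer(tapply(all_counts, names(all_counts), sum)),
                              sort(unique(names(all_counts)))))
}

as_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  stop("cannot interpret as molecular formula", call. = FALSE)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums per-element monoisotopic masses times counts, from a fixed internal
#' isotope table. Reproducible to better than 1e-6 Da.
#'
#' @param formula A `mol_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")   # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  unknown <- setdiff(names(f), names(.ISOTOPE_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(.ISOTOPE_MASS[names(f)] * unclass(f))
}

#' Protonated m/z of a neutral molecule
#'
#' m/z of the singly protonated even-electron ion \[M+H\]+ in positive mode:
#' the neutral monoisotopic mass plus the proton mass (1.007276 Da; electron
#' mass accounted for).
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Da (charge 1).
#' @examples
#' protonated_mz("C30H48O3")  # oleanolic acid, ~457.3676
#' @export
protonated_mz <- function(formula) {
  monoisotopic_mass(formula) + PROTON_MASS
}

#' Mass tolerance with a ppm bound and an absolute floor
#'
#' The effective window at m/z `x` is `max(ppm * x * 1e-6, absolute_da)`.
#'
#' @param ppm Parts-per-million bound (>= 0).
#' @param absolute_da Absolute floor in Da (>= 0).
#' @export
mass_tolerance <- function(ppm = 10, absolute_da = 0.002) {
  stopifnot(is.numeric(ppm), ppm >= 0, is.numeric(absolute_da), absolute_da >= 0)
  structure(list(ppm = ppm, absolute_da = absolute_da), class = "mass_tolerance")
}

#' Effective tolerance window at a given m/z
#' @param tol A [mass_tolerance()].
#' @param mz m/z value(s) at which to evaluate the window.
#' @return Window half-width(s) in Da.
#' @export
tol_window <- function(tol, mz) {
  pmax(tol$ppm * mz * 1e-6, tol$absolute_da)
}

ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

# ---- registries -------------------------------------------------------------

.VALID_MOD_CLASSES <- c("glycosyl", "acyl", "methyl", "small_loss")
.VALID_COMPOUND_CLASSES <- c("flavonol", "flavanol", "anthocyanidin",
                             "triterpenoid", "other")

#' Read a modification registry from CSV
#'
#' The registry holds the neutral-loss moieties the ladder decomposition can
#' assign: name, formula (Hill notation, the net atoms added to the neutral
#' molecule) and modification class (`glycosyl`, `acyl`, `methyl`,
#' `small_loss`). Monoisotopic and nominal delta masses are derived from the
#' formula at load time.
#'
#' @param path CSV with columns `name`, `formula`, `mod_class`.
#' @return data.frame with columns name, formula, delta_mass, nominal_mass,
#'   mod_class.
#' @export
read_modification_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "mod_class")
  if (!all(need %in% names(df))) {
    stop("modification registry needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$mod_class), .VALID_MOD_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown modification class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$delta_mass <- vapply(df$formula, function(f) monoisotopic_mass(f), 0.0)
  df$nominal_mass <- as.integer(round(df$delta_mass))
  rownames(df) <- df$name
  df[, c("name", "formula", "delta_mass", "nominal_mass", "mod_class")]
}

#' Read an aglycone registry from CSV
#'
#' Aglycones are the non-sugar cores the Y0+ fragment is matched against
#' (e.g. quercetin for flavonol glycosides). `protonated_mz` is derived from
#' the formula.
#'
#' @param path CSV with columns `name`, `formula`, `compound_class`.
#' @return data.frame with columns name, formula, protonated_mz,
#'   compound_class.
#' @export
read_aglycone_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "compound_class")
  if (!all(need %in% names(df))) {
    stop("aglycone registry needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$compound_class), .VALID_COMPOUND_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown compound class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$protonated_mz <- vapply(df$formula, function(f) protonated_mz(f), 0.0)
  rownames(df) <- df$name
  df[, c("name", "formula", "protonated_mz", "compound_class")]
}

#' The default annotation registry
#'
#' Loads the modification and aglycone tables shipped with the package
#' (editable CSVs under `inst/extdata/`). The modification table covers the
#' glycosyl residues (hexosyl 162.0528, deoxyhexosyl 146.0579), the acyl
#' groups (coumaroyl 146.0368, malonyl 86.0004, acetyl 42.0106), methylation
#' (CH2, 14.0157) and the small losses below the aglycone ion (H2O, CO, CH3
#' and OCH3 radicals). Coumaroyl and deoxyhexosyl are nominally isobaric at
#' 146 Da and are resolved by accurate mass.
#'
#' @return list with elements `modifications` and `aglycones`.
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$reg)) {
    .registry_cache$reg <- list(
      modifications = read_modification_registry(
        system.file("extdata", "modifications.csv", package = "vitimet",
                    mustWork = TRUE)),
      aglycones = read_aglycone_registry(
        system.file("extdata", "aglycones.csv", package = "vitimet",
                    mustWork = TRUE))
    )
  }
  .registry_cache$reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Match an observed neutral-loss mass against the modification registry
#'
#' Returns every registry modification whose delta mass lies within the
#' tolerance window of the observed mass difference, ranked by absolute ppm
#' error. Nominally isobaric losses (coumaroyl vs deoxyhexosyl, both 146 Da)
#' are disambiguated when the accurate mass resolves them; when more than one
#' entry falls inside the window all are returned and flagged ambiguous.
#'
#' @param observed_delta Observed mass difference in Da (> 0).
#' @param tolerance A [mass_tolerance()].
#' @param registry Modification table (see [default_registry()]).
#' @param classes Optional subset of modification classes to consider.
#' @return data.frame of matches with `ppm_error` and `ambiguous` columns,
#'   sorted by |ppm error|; zero rows when nothing matches.
#' @export
match_loss <- function(observed_delta,
                       tolerance = mass_tolerance(10, 0.002),
                       registry = default_registry()$modifications,
                       classes = NULL) {
  stopifnot(is.numeric(observed_delta), observed_delta > 0)
  reg <- registry
  if (!is.null(classes)) reg <- reg[reg$mod_class %in% classes, , drop = FALSE]
  dev <- abs(reg$delta_mass - observed_delta)
  win <- tol_window(tolerance, observed_delta)
  hit <- reg[dev <= win, , drop = FALSE]
  if (nrow(hit) == 0L) {
    hit$ppm_error <- numeric(0)
    hit$ambiguous <- logical(0)
    return(hit)
  }
  hit$ppm_error <- ppm_error(observed_delta, hit$delta_mass)
  hit <- hit[order(abs(hit$ppm_error), hit$name), , drop = FALSE]
  hit$ambiguous <- nrow(hit) > 1L
  hit
}
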