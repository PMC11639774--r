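# Diagnostic-ion classification of oleanane-type pentacyclic triterpenoids.
#
# In positive-mode ESI the oleanane skeleton gives a core ion near m/z 457.4
# ([M+H-glycosyl-H2O]+), followed by loss of the carboxyl to a fragment near
# m/z 393.4, plus low-mass skeleton (203.2, 189.2) and isoprene-series ions
# (119.1, 109.1, 95.1). A spectrum passes when both required ions and at
# least `min_optional_matches` optional ions are matched.

# constant core -> carboxyl-loss mass difference, fixed at the ion level as
# the 457.3676/393.3513 pair difference
CARBOXYL_LOSS_DA <- 64.0163

#' Diagnostic rule set for a triterpenoid skeleton
#'
#' @param skeleton_name Name of the carbon skeleton.
#' @param ions data.frame with columns `target_mz`, `label`, `required`.
#' @param min_optional_matches Minimum number of optional ions that must
#'   match in addition to every required ion.
#' @export
diagnostic_ruleset <- function(skeleton_name, ions, min_optional_matches = 2L) {
  stopifnot(is.data.frame(ions),
            all(c("target_mz", "label", "required") %in% names(ions)),
            all(ions$target_mz > 0),
            any(ions$required))
  structure(list(skeleton_name = skeleton_name, ions = ions,
                 min_optional_matches = as.integer(min_optional_matches)),
            class = "diagnostic_ruleset")
}

#' The oleanane diagnostic rule set
#'
#' Required: the core ion at 457.367 and the carboxyl-loss ion at 393.351.
#' Optional: skeleton ions 203.179 and 189.164, and the isoprene series
#' 119.086, 109.102, 95.086; at least two optional ions must match.
#' @export
oleanane_ruleset <- function() {
  diagnostic_ruleset(
    "oleanane",
    data.frame(
      target_mz = c(457.367, 393.351, 203.179, 189.164, 119.086, 109.102, 95.086),
      label = c("core [M+H-glycosyl-H2O]+", "carboxyl loss", "skeleton 203",
                "skeleton 189", "isoprene 119", "isoprene 109", "isoprene 95"),
      required = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    min_optional_matches = 2L)
}

#' Empty rule-set stubs for the other pentacyclic skeletons
#'
#' Ursane, lupane and friedelane are recognised skeleton names but no
#' diagnostic ions are specified; these stubs are configuration extension
#' points and never pass.
#' @param skeleton One of "ursane", "lupane", "friedelane".
#' @export
skeleton_ruleset_stub <- function(skeleton = c("ursane", "lupane", "friedelane")) {
  skeleton <- match.arg(skeleton)
  structure(list(skeleton_name = skeleton,
                 ions = data.frame(target_mz = numeric(0), label = character(0),
                                   required = logical(0)),
                 min_optional_matches = 0L),
            class = "diagnostic_ruleset")
}

#' Classify a spectrum against a triterpenoid diagnostic rule set
#'
#' Each rule ion is matched to the nearest unclaimed peak inside the
#' tolerance window (one peak can satisfy only one rule; required ions are
#' matched first, largest target first). Matching uses only fragment m/z, so
#' the result is invariant to peak order and intensity scaling.
#'
#' The default tolerance (20 ppm with a 0.005 Da floor) is wider than the
#' ladder-matching tolerance because rule targets are quoted at millidalton
#' precision; the window covers quoting precision plus instrument error.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param ruleset A [diagnostic_ruleset()]; default [oleanane_ruleset()].
#' @param tolerance A [mass_tolerance()].
#' @return list of class `skeleton_match`: `spectrum_id`, `skeleton_name`,
#'   `matched_ions` (data.frame target_mz, observed_mz, ppm_error, label,
#'   required), `passed`.
#' @export
classify_skeleton <- function(spectrum, ruleset = oleanane_ruleset(),
                              tolerance = mass_tolerance(20, 0.005)) {
  stopifnot(inherits(spectrum, "ms2_spectrum"),
            inherits(ruleset, "diagnostic_ruleset"))
  pk <- spectrum$peaks$mz
  ions <- ruleset$ions
  if (nrow(ions) == 0L) {
    return(.skeleton_match(spectrum, ruleset, ions[0, ], passed = FALSE))
  }
  ord <- order(!ions$required, -ions$target_mz)
  ions <- ions[ord, , drop = FALSE]
  used <- rep(FALSE, length(pk))
  rows <- list()
  for (i in seq_len(nrow(ions))) {
    tgt <- ions$target_mz[i]
    win <- tol_window(tolerance, tgt)
    avail <- which(!used & abs(pk - tgt) <= win)
    if (length(avail) == 0L) next
    j <- avail[which.min(abs(pk[avail] - tgt))]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      target_mz = tgt, observed_mz = pk[j],
      ppm_error = ppm_error(pk[j], tgt),
      label = ions$label[i], required = ions$required[i])
  }
  matched <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(target_mz = numeric(0), observed_mz = numeric(0),
               ppm_error = numeric(0), label = character(0),
               required = logical(0))
  n_req <- sum(ions$required)
  passed <- sum(matched$required) == n_req &&
    sum(!matched$required) >= ruleset$min_optional_matches
  .skeleton_match(spectrum, ruleset, matched, passed)
}

.skeleton_match <- function(spectrum, ruleset, matched, passed) {
  structure(list(spectrum_id = spectrum$spectrum_id,
                 skeleton_name = ruleset$skeleton_name,
                 matched_ions = matched,
                 passed = passed),
            class = "skeleton_match")
}

#' @export
print.skeleton_match <- function(x, ...) {
  cat(sprintf("<skeleton_match> %s vs %s: %s (%d ions matched)\n",
              x$spectrum_id, x$skeleton_name,
              if (x$passed) "PASSED" else "not passed",
              nrow(x$matched_ions)))
  invisible(x)
}

#' Expected core and carboxyl-loss ions for a triterpenoid precursor
#'
#' The core ion is the precursor after loss of a glycosyl residue plus water
#' (for a glycoside) or the precursor itself (aglycone-only spectra, where
#' the glycosyl-loss step is vacuous). The carboxyl-loss fragment sits a
#' fixed 64.0163 Da below the core, the difference encoded from the
#' oleanolic-acid ion pair 457.3676/393.3513.
#'
#' @param precursor_mz Precursor m/z in Da.
#' @param glycosyl Name of the glycosyl residue lost (e.g. "hexosyl"), or
#'   NULL for an aglycone-only precursor.
#' @param registry Registry list from [default_registry()].
#' @return Named numeric vector `c(core_mz, carboxyl_loss_mz)`.
#' @export
core_ion_relation <- function(precursor_mz, glycosyl = NULL,
                              registry = default_registry()) {
  stopifnot(precursor_mz > 0)
  core <- precursor_mz
  if (!is.null(glycosyl)) {
    mt <- registry$modifications
    if (!glycosyl %in% mt$name) stop("unknown glycosyl: ", glycosyl, call. = FALSE)
    core <- precursor_mz - mt[glycosyl, "delta_mass"] -
      monoisotopic_mass("H2O")
  }
  c(core_mz = core, carboxyl_loss_mz = core - CARBOXYL_LOSS_DA)
}

#' Classify a batch of spectra against a rule set
#'
#' @inheritParams classify_skeleton
#' @param spectra list of [ms2_spectrum()].
#' @return data.frame: spectrum_id, skeleton, passed, n_required_matched,
#'   n_optional_matched.
#' @export
classify_spectra <- function(spectra, ruleset = oleanane_ruleset(),
                             tolerance = mass_tolerance(20, 0.005)) {
  rows <- lapply(spectra, function(sp) {
    m <- classify_skeleton(sp, ruleset, tolerance)
    data.frame(spectrum_id = sp$spectrum_id, skeleton = m$skeleton_name,
               passed = m$passed,
               n_required_matched = sum(m$matched_ions$required),
               n_optional_matched = sum(!m$matched_ions$required))
  })
  do.call(rbind, rows)
}
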