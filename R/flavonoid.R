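# Neutral-loss ladder decomposition of flavonoid MS2 spectra.
#
# Glycosylated/acylated flavonoids fragment by successive cleavage of the
# glycosidic and ester bonds: each sugar loss gives [M+H-162]+ (hexosyl) and
# so on down to the protonated aglycone, the Y0+ ion. decompose() runs a
# depth-bounded search from the precursor over peak-to-peak mass differences,
# assigning registry losses to build ladders that terminate at a Y0+
# candidate, then ranks candidate annotations.

ELECTRON_MASS <- 0.00054857990907

#' Annotation configuration
#'
#' @param tol_fragment Tolerance for fragment-difference (neutral-loss)
#'   matching; default 10 ppm with a 0.002 Da floor (Orbitrap-class
#'   accuracy).
#' @param tol_precursor Tolerance for precursor reconstruction; default
#'   5 ppm.
#' @param max_mods Maximum number of modifications in a ladder (default 4).
#' @param allowed_classes Modification classes the ladder may assign.
#'   Small losses (H2O, CO, CH3, OCH3) occur below the aglycone ion and are
#'   excluded from the ladder by default.
#' @param lambda Score penalty per ppm of mean absolute step error
#'   (default 0.1): score = matched steps - lambda * mean |ppm|. Step error
#'   is expressed in ppm of the summed parent and child ion masses (the
#'   scale the matching window is applied on), so a step inside the window
#'   always costs less than one matched step.
#' @param allow_composite Match a parent-to-child difference as a composite
#'   of two or three losses when the intermediate peak is absent (prevents a
#'   broken ladder from losing its annotation while never double-counting a
#'   difference whose intermediate is present).
#' @param flavylium Treat anthocyanidin aglycones as [M]+ flavylium cations
#'   (m/z = monoisotopic mass - electron mass) instead of [M+H]+. Default
#'   off: all ions are assumed singly protonated.
#' @param rt_window Retention-time window (minutes) for standard
#'   confirmation.
#' @export
annotation_config <- function(tol_fragment = mass_tolerance(10, 0.002),
                              tol_precursor = mass_tolerance(5, 0),
                              max_mods = 4L,
                              allowed_classes = c("glycosyl", "acyl", "methyl"),
                              lambda = 0.1,
                              allow_composite = TRUE,
                              flavylium = FALSE,
                              rt_window = 0.15) {
  stopifnot(max_mods >= 0, lambda >= 0, rt_window >= 0)
  list(tol_fragment = tol_fragment, tol_precursor = tol_precursor,
       max_mods = as.integer(max_mods), allowed_classes = allowed_classes,
       lambda = lambda, allow_composite = allow_composite,
       flavylium = flavylium, rt_window = rt_window)
}

# m/z of the bare aglycone ion under the configured ion convention
aglycone_ion_mz <- function(aglycone_row, flavylium = FALSE) {
  if (flavylium && aglycone_row$compound_class == "anthocyanidin") {
    monoisotopic_mass(aglycone_row$formula) - ELECTRON_MASS
  } else {
    aglycone_row$protonated_mz
  }
}

#' Reconstruct the precursor m/z of an aglycone plus modifications
#'
#' Sums the neutral formulas of the aglycone and every modification, then
#' protonates. The worked-example consistency check: quercetin plus two
#' hexosyl and one coumaroyl reconstructs to ~773.1924.
#'
#' @param aglycone Aglycone name (looked up in the registry) or a one-row
#'   registry entry.
#' @param modifications Character vector of modification names (repeats
#'   allowed, e.g. `c("hexosyl", "hexosyl", "coumaroyl")`).
#' @param registry Registry list from [default_registry()].
#' @return Reconstructed \[M+H\]+ m/z in Da.
#' @export
reconstruct_precursor <- function(aglycone, modifications = character(0),
                                  registry = default_registry()) {
  ag <- .lookup_aglycone(aglycone, registry)
  mass <- monoisotopic_mass(ag$formula)
  if (length(modifications) > 0L) {
    mt <- registry$modifications
    missing <- setdiff(modifications, mt$name)
    if (length(missing) > 0L) {
      stop("unknown modification(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    mass <- mass + sum(mt[modifications, "delta_mass"])
  }
  mass + PROTON_MASS
}

.lookup_aglycone <- function(aglycone, registry) {
  if (is.data.frame(aglycone)) return(aglycone)
  ag <- registry$aglycones
  if (!aglycone %in% ag$name) stop("unknown aglycone: ", aglycone, call. = FALSE)
  ag[aglycone, , drop = FALSE]
}

#' Decompose an MS2 spectrum into aglycone + modification ladder
#'
#' Candidate Y0+ peaks are those matching a registry aglycone ion within the
#' fragment tolerance (if none match, every peak is a candidate with aglycone
#' "unknown"). From the precursor, a depth-bounded search assigns registry
#' losses to parent-to-child m/z differences, building loss ladders that
#' terminate at a Y0+ candidate. Each distinct (aglycone, modification
#' multiset) is scored as `matched steps - lambda * mean |ppm error|`;
#' results are ranked by confidence tier (`standard_confirmed` >
#' `rule_annotated` > `partial`), then score, with deterministic tie-breaks
#' (fewer modifications first, then lexicographic modification names).
#'
#' The `rule_annotated` tier requires a known aglycone whose reconstructed
#' precursor (see [reconstruct_precursor()]) agrees with the observed
#' precursor within the precursor tolerance; `standard_confirmed` further
#' requires a retention-time match against `standards`.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param registry Registry list from [default_registry()].
#' @param config An [annotation_config()].
#' @param standards Optional data.frame of authentic standards with columns
#'   `name`, `precursor_mz`, `rt` (minutes); a result matching in precursor
#'   m/z and RT (within `rt_window`) is upgraded to `standard_confirmed`.
#' @return list of annotation results (class `annotation_result`), ranked;
#'   empty when no ladder reaches a Y0+ candidate.
#' @export
decompose <- function(spectrum, registry = default_registry(),
                      config = annotation_config(), standards = NULL) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  pk <- spectrum$peaks$mz
  if (length(pk) == 0L) stop("spectrum has no peaks", call. = FALSE)
  prec <- spectrum$precursor_mz
  if (all(pk > prec + tol_window(config$tol_fragment, prec))) {
    stop("precursor m/z is smaller than every fragment peak", call. = FALSE)
  }
  mods <- registry$modifications
  mods <- mods[mods$mod_class %in% config$allowed_classes, , drop = FALSE]
  aglycones <- registry$aglycones
  ag_mz <- vapply(seq_len(nrow(aglycones)), function(i)
    aglycone_ion_mz(aglycones[i, ], config$flavylium), 0.0)

  # Y0+ candidates: peak index -> matching aglycone names (NA = unknown)
  frag_win <- tol_window(config$tol_fragment, pk)
  cand <- list()
  for (j in seq_along(pk)) {
    hit <- which(abs(ag_mz - pk[j]) <= frag_win[j])
    if (length(hit) > 0L) cand[[length(cand) + 1L]] <-
        data.frame(peak = j, aglycone = aglycones$name[hit])
  }
  cand <- if (length(cand) > 0L) do.call(rbind, cand) else
    data.frame(peak = seq_along(pk), aglycone = NA_character_)
  cand_by_peak <- split(cand$aglycone, cand$peak)

  # composite losses (pairs/triples) for bridging dropped-out intermediates
  composites <- if (config$allow_composite && nrow(mods) > 0L)
    .composite_table(mods, max_size = min(3L, config$max_mods)) else NULL

  results <- list()
  emit <- function(peak_j, mods_used, steps) {
    ags <- cand_by_peak[[as.character(peak_j)]]
    if (is.null(ags)) return(invisible())
    for (a in ags) {
      results[[length(results) + 1L]] <<- list(
        aglycone = a, y0_peak = peak_j, mods = mods_used, steps = steps)
    }
  }

  # A parent-to-child difference inherits mass error from both ions, so the
  # matching window for a loss between ions at m and c is evaluated on the
  # summed ion masses (triangle-inequality propagation), not on the small
  # delta itself: max(ppm * (m + c) * 1e-6, absolute floor).
  loss_tol <- function(parent, child) {
    mass_tolerance(config$tol_fragment$ppm,
                   max(config$tol_fragment$absolute_da,
                       config$tol_fragment$ppm * 1e-6 * (parent + child)))
  }

  # depth-first search downward from the precursor
  search <- function(node_mz, mods_used, steps, depth) {
    for (j in which(pk < node_mz - 13)) {
      delta <- node_mz - pk[j]
      if (depth < config$max_mods) {
        m <- match_loss(delta, loss_tol(node_mz, pk[j]), mods)
        for (k in seq_len(nrow(m))) {
          # step error in ppm of the summed ion masses, the scale the
          # tolerance window is applied on (a Da-scale error on two heavy
          # ions is misleading as ppm of a small delta)
          st <- rbind(steps, data.frame(
            parent_mz = node_mz, child_mz = pk[j], observed_delta = delta,
            assigned_mod = m$name[k],
            ppm_error = (delta - m$delta_mass[k]) /
              (node_mz + pk[j]) * 1e6))
          mu <- c(mods_used, m$name[k])
          emit(j, mu, st)
          search(pk[j], mu, st, depth + 1L)
        }
        if (nrow(m) == 0L && !is.null(composites)) {
          cm <- composites[abs(composites$delta - delta) <=
                             tol_window(loss_tol(node_mz, pk[j]), delta) &
                             composites$size <= config$max_mods - depth, ,
                           drop = FALSE]
          for (k in seq_len(nrow(cm))) {
            parts <- strsplit(cm$mods[k], ";", fixed = TRUE)[[1]]
            # only bridge when no single-loss intermediate peak is present
            inter <- node_mz - mods[unique(parts), "delta_mass"]
            if (any(vapply(inter, function(im)
              any(abs(pk - im) <= tol_window(config$tol_fragment, im)), TRUE)))
              next
            st <- rbind(steps, data.frame(
              parent_mz = node_mz, child_mz = pk[j], observed_delta = delta,
              assigned_mod = cm$mods[k],
              ppm_error = (delta - cm$delta[k]) / (node_mz + pk[j]) * 1e6))
            mu <- c(mods_used, parts)
            emit(j, mu, st)
            search(pk[j], mu, st, depth + cm$size[k])
          }
        }
      }
    }
  }

  empty_steps <- data.frame(parent_mz = numeric(0), child_mz = numeric(0),
                            observed_delta = numeric(0),
                            assigned_mod = character(0),
                            ppm_error = numeric(0))
  # zero-modification annotations: the precursor directly matches an
  # aglycone ion, or a Y0+ candidate peak coincides with the precursor
  # (the precursor surviving into the MS2 scan, measured twice)
  direct <- which(abs(ag_mz - prec) <= tol_window(config$tol_precursor, prec))
  for (a in aglycones$name[direct]) {
    results[[length(results) + 1L]] <- list(
      aglycone = a, y0_peak = NA_integer_, mods = character(0),
      steps = empty_steps)
  }
  coincide_win <- max(config$tol_fragment$absolute_da,
                      config$tol_fragment$ppm * 1e-6 * 2 * prec)
  for (j in which(abs(pk - prec) <= coincide_win)) {
    ags <- cand_by_peak[[as.character(j)]]
    for (a in if (is.null(ags)) NA_character_ else ags) {
      results[[length(results) + 1L]] <- list(
        aglycone = a, y0_peak = j, mods = character(0), steps = empty_steps)
    }
  }
  search(prec, character(0), empty_steps, 0L)

  if (length(results) == 0L) return(list())
  .finalize_annotations(results, spectrum, registry, config, standards, pk)
}

.composite_table <- function(mods, max_size = 3L) {
  out <- list()
  nm <- mods$name
  dm <- mods$delta_mass
  if (max_size >= 2L) {
    for (i in seq_along(nm)) for (j in i:length(nm)) {
      out[[length(out) + 1L]] <- data.frame(
        mods = paste(sort(c(nm[i], nm[j])), collapse = ";"),
        delta = dm[i] + dm[j], size = 2L)
      if (max_size >= 3L) for (k in j:length(nm)) {
        out[[length(out) + 1L]] <- data.frame(
          mods = paste(sort(c(nm[i], nm[j], nm[k])), collapse = ";"),
          delta = dm[i] + dm[j] + dm[k], size = 3L)
      }
    }
  }
  unique(do.call(rbind, out))
}

.finalize_annotations <- function(results, spectrum, registry, config,
                                  standards, pk) {
  prec <- spectrum$precursor_mz
  keyed <- vapply(results, function(r)
    paste(r$aglycone, paste(sort(r$mods), collapse = ";"), sep = "|"), "")
  out <- list()
  for (key in unique(keyed)) {
    grp <- results[keyed == key]
    scores <- vapply(grp, function(r) {
      n <- nrow(r$steps)
      if (n == 0L) 0 else n - config$lambda * mean(abs(r$steps$ppm_error))
    }, 0.0)
    r <- grp[[which.max(scores)]]
    known <- !is.na(r$aglycone)
    y0 <- if (is.na(r$y0_peak)) prec else pk[r$y0_peak]
    if (known) {
      rec <- reconstruct_precursor(r$aglycone, r$mods, registry)
    } else {
      mt <- registry$modifications
      rec <- y0 + if (length(r$mods) > 0L) sum(mt[r$mods, "delta_mass"]) else 0
    }
    rp <- ppm_error(prec, rec)  # signed: observed precursor vs reconstruction
    within_prec <- abs(rp) <= max(config$tol_precursor$ppm,
                                  1e6 * config$tol_precursor$absolute_da / prec)
    tier <- if (known && within_prec) "rule_annotated" else "partial"
    if (tier == "rule_annotated" && !is.null(standards)) {
      sm <- standards[abs(standards$precursor_mz - prec) <=
                        tol_window(config$tol_precursor, prec) &
                        abs(standards$rt - spectrum$retention_time) <=
                        config$rt_window, , drop = FALSE]
      if (nrow(sm) > 0L) tier <- "standard_confirmed"
    }
    out[[length(out) + 1L]] <- structure(list(
      spectrum_id = spectrum$spectrum_id,
      aglycone = if (known) r$aglycone else "unknown",
      y0_mz = y0,
      modifications = sort(r$mods),
      ladder = r$steps,
      score = max(scores),
      reconstructed_precursor_mz = rec,
      reconstruction_ppm = rp,
      confidence_tier = tier), class = "annotation_result")
  }
  tier_rank <- c(standard_confirmed = 1L, rule_annotated = 2L, partial = 3L)
  ord <- order(tier_rank[vapply(out, `[[`, "", "confidence_tier")],
               -vapply(out, `[[`, 0.0, "score"),
               lengths(lapply(out, `[[`, "modifications")),
               vapply(out, function(r) paste(r$modifications, collapse = ";"), ""),
               vapply(out, `[[`, "", "aglycone"))
  out[ord]
}

#' Human-readable annotation name
#'
#' Deterministic rendering such as `"quercetin + 2xhexosyl + 1xcoumaroyl"`;
#' modification groups ordered by descending count then name. An unknown
#' aglycone is rendered with its Y0+ m/z, e.g. `"aglycone(287.0550)"`. No
#' attachment positions are claimed: ladder decomposition establishes the
#' modification multiset, not positional isomery.
#'
#' @param result An annotation result from [decompose()].
#' @return Character name.
#' @export
name_annotation <- function(result) {
  base <- if (identical(result$aglycone, "unknown"))
    sprintf("aglycone(%.4f)", result$y0_mz) else result$aglycone
  if (length(result$modifications) == 0L) return(base)
  tab <- table(result$modifications)
  ord <- order(-as.integer(tab), names(tab))
  paste(c(base, sprintf("%d×%s", as.integer(tab)[ord], names(tab)[ord])),
        collapse = " + ")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation> %s: %s  [%s]  score %.3f  recon %.4f (%+.2f ppm)\n",
              x$spectrum_id, name_annotation(x), x$confidence_tier, x$score,
              x$reconstructed_precursor_mz, x$reconstruction_ppm))
  invisible(x)
}

#' Annotate a batch of spectra
#'
#' Runs [decompose()] on each spectrum and returns the top-ranked annotation
#' per spectrum as a data.frame (one row per spectrum; unannotated spectra
#' get NA fields).
#'
#' @inheritParams decompose
#' @param spectra list of [ms2_spectrum()].
#' @return data.frame with columns spectrum_id, name, aglycone, mods, y0_mz,
#'   reconstruction_ppm, score, tier.
#' @export
annotate_spectra <- function(spectra, registry = default_registry(),
                             config = annotation_config(), standards = NULL) {
  rows <- lapply(spectra, function(sp) {
    res <- tryCatch(decompose(sp, registry, config, standards),
                    error = function(e) list())
    if (length(res) == 0L) {
      return(data.frame(spectrum_id = sp$spectrum_id, name = NA_character_,
                        aglycone = NA_character_, mods = NA_character_,
                        y0_mz = NA_real_, reconstruction_ppm = NA_real_,
                        score = NA_real_, tier = NA_character_))
    }
    top <- res[[1]]
    data.frame(spectrum_id = top$spectrum_id, name = name_annotation(top),
               aglycone = top$aglycone,
               mods = paste(top$modifications, collapse = ";"),
               y0_mz = top$y0_mz, reconstruction_ppm = top$reconstruction_ppm,
               score = top$score, tier = top$confidence_tier)
  })
  do.call(rbind, rows)
}
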