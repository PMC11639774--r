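# Independent oracles, deliberately implemented without reusing the package's
# search/decomposition code paths.

# Exhaustive-enumeration oracle for ladder decomposition: enumerates every
# (aglycone, modification multiset) up to max_depth, keeps candidates whose
# reconstructed precursor agrees with the observed precursor, and scores each
# by walking every permutation of the multiset down from the precursor and
# counting the observed peaks it explains (the walk must end on an observed
# Y0+ peak, or be the empty multiset with a direct precursor match).
# Returns NULL when no candidate reconstructs within tolerance.
oracle_decompose <- function(spectrum, registry = default_registry(),
                             max_depth = 3, tol_ppm_prec = 5,
                             tol_ppm_frag = 10, tol_abs_frag = 0.002) {
  prec <- spectrum$precursor_mz
  pk <- spectrum$peaks$mz
  mods <- registry$modifications
  mods <- mods[mods$mod_class %in% c("glycosyl", "acyl", "methyl"), ]
  win <- function(a, b) max(tol_ppm_frag * 1e-6 * (a + b), tol_abs_frag)

  # all multisets of mod names with size 0..max_depth
  multisets <- list(character(0))
  frontier <- list(character(0))
  for (d in seq_len(max_depth)) {
    nxt <- list()
    for (ms in frontier) {
      last <- if (length(ms) == 0) "" else ms[length(ms)]
      for (nm in mods$name[mods$name >= last]) nxt[[length(nxt) + 1]] <- c(ms, nm)
    }
    multisets <- c(multisets, nxt)
    frontier <- nxt
  }

  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }

  best <- NULL
  for (ai in seq_len(nrow(registry$aglycones))) {
    ag <- registry$aglycones[ai, ]
    for (ms in multisets) {
      recon <- monoisotopic_mass(ag$formula) + 1.00727646688 +
        (if (length(ms) > 0) sum(mods[ms, "delta_mass"]) else 0)
      if (abs(recon - prec) / recon * 1e6 > tol_ppm_prec) next
      if (length(ms) == 0) {
        n_matched <- 0  # direct precursor match, no ladder
      } else {
        n_matched <- -1
        for (p in unique(perms(ms))) {
          cur <- prec
          cnt <- 0
          terminus_hit <- FALSE
          for (k in seq_along(p)) {
            target <- cur - mods[p[k], "delta_mass"]
            hit <- which(abs(pk - target) <= win(cur, target))
            if (length(hit) > 0) {
              j <- hit[which.min(abs(pk[hit] - target))]
              cnt <- cnt + 1
              if (k == length(p)) terminus_hit <- TRUE
              cur <- pk[j]
            } else {
              cur <- target
            }
          }
          if (terminus_hit && cnt > n_matched) n_matched <- cnt
        }
        if (n_matched < 0) next  # never reached an observed Y0+ peak
      }
      cand <- list(aglycone = ag$name, mods = sort(ms), n_matched = n_matched)
      if (is.null(best) ||
          cand$n_matched > best$n_matched ||
          (cand$n_matched == best$n_matched &&
             (length(cand$mods) < length(best$mods) ||
                (length(cand$mods) == length(best$mods) &&
                   paste(cand$mods, collapse = ";") <
                     paste(best$mods, collapse = ";"))))) {
        best <- cand
      }
    }
  }
  best
}

# Loop-based nested ANOVA sums of squares, written from the definition with
# explicit loops over groups (independent of the vectorised implementation).
oracle_nested_ss <- function(values, color, variety) {
  grand <- sum(values) / length(values)
  ss_color <- 0; ss_variety <- 0; ss_error <- 0
  for (cl in unique(color)) {
    vc <- values[color == cl]
    mc <- sum(vc) / length(vc)
    ss_color <- ss_color + length(vc) * (mc - grand)^2
    for (vr in unique(variety[color == cl])) {
      vv <- values[variety == vr]
      mv <- sum(vv) / length(vv)
      ss_variety <- ss_variety + length(vv) * (mv - mc)^2
      for (y in vv) ss_error <- ss_error + (y - mv)^2
    }
  }
  c(color = ss_color, variety = ss_variety, error = ss_error)
}
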