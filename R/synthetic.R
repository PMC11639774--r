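# Ground-truthed synthetic data: compound libraries, MS2 spectra and
# color-structured abundance matrices. Every output carries machine-readable
# truth so annotation recovery, DAM power and intersection counts can be
# scored without hand derivation.

.COMPOUND_CLASSES <- c("simple_flavonoid", "mono_glycoside", "di_glycoside",
                       "acylated_glycoside", "triterpenoid", "lipid",
                       "amino_acid", "vitamin", "other")

#' Default compound-class x color enrichment matrix
#'
#' Multiplicative abundance enrichment per (compound class, berry color).
#' The default plants the accumulation pattern the profiling stage is meant
#' to detect: purple berries enriched 4-fold in acylated flavonoid
#' glycosides and triterpenoids and 2-fold in diglycosides, with milder
#' enrichment in red and pink; all other cells 1.
#' @export
default_class_effect <- function() {
  eff <- matrix(1, length(.COMPOUND_CLASSES), 4,
                dimnames = list(.COMPOUND_CLASSES,
                                c("white", "pink", "red", "purple")))
  eff["acylated_glycoside", c("pink", "red", "purple")] <- c(1.5, 2, 4)
  eff["triterpenoid", c("red", "purple")] <- c(2, 4)
  eff["di_glycoside", "purple"] <- 2
  eff
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: four berry colors over 66
#' varieties (17/16/16/17) with three biological replicates each,
#' Orbitrap-class 5 ppm mass error, and purple-enriched modified-flavonoid
#' and triterpenoid classes.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param ppm_noise_sd Gaussian m/z jitter SD in ppm (default 5).
#' @param n_noise_peaks Uniform random noise peaks added per spectrum.
#' @param ladder_dropout_prob Probability that each intermediate ladder
#'   fragment is missing (the Y0+ terminus is always retained).
#' @param varieties_per_color Named integer vector of varieties per color.
#' @param replicates Biological replicates per variety (default 3).
#' @param class_proportions Sampling proportions of compound classes.
#' @param class_effect Enrichment matrix, see [default_class_effect()].
#' @param base_abundance_logsd SD of log base abundance across compounds.
#' @param injection_logsd SD of the log per-sample injection factor.
#' @param replicate_cv Coefficient of variation of replicate noise
#'   (default 0.2).
#' @param hostile_noise Allow noise peaks inside +-3x tolerance windows of
#'   true peaks (stress-test mode; default FALSE so that recovery failures
#'   measure search behavior, not label noise).
#' @export
sim_config <- function(seed = 1L,
                       ppm_noise_sd = 5,
                       n_noise_peaks = 5L,
                       ladder_dropout_prob = 0.1,
                       varieties_per_color = c(white = 17L, pink = 16L,
                                               red = 16L, purple = 17L),
                       replicates = 3L,
                       class_proportions = c(simple_flavonoid = 0.15,
                                             mono_glycoside = 0.20,
                                             di_glycoside = 0.15,
                                             acylated_glycoside = 0.15,
                                             triterpenoid = 0.10,
                                             lipid = 0.08,
                                             amino_acid = 0.07,
                                             vitamin = 0.05,
                                             other = 0.05),
                       class_effect = default_class_effect(),
                       base_abundance_logsd = 1,
                       injection_logsd = 0.2,
                       replicate_cv = 0.2,
                       hostile_noise = FALSE) {
  stopifnot(ppm_noise_sd >= 0, n_noise_peaks >= 0,
            ladder_dropout_prob >= 0, ladder_dropout_prob <= 1,
            replicates >= 1, all(class_effect > 0),
            all(class_proportions >= 0))
  stopifnot(all(names(varieties_per_color) %in% .VALID_COLORS))
  list(seed = as.integer(seed), ppm_noise_sd = ppm_noise_sd,
       n_noise_peaks = as.integer(n_noise_peaks),
       ladder_dropout_prob = ladder_dropout_prob,
       varieties_per_color = varieties_per_color,
       replicates = as.integer(replicates),
       class_proportions = class_proportions / sum(class_proportions),
       class_effect = class_effect,
       base_abundance_logsd = base_abundance_logsd,
       injection_logsd = injection_logsd,
       replicate_cv = replicate_cv,
       hostile_noise = hostile_noise)
}

#' Generate a ground-truth compound library
#'
#' Samples compound classes per the configured proportions and assembles
#' each compound from a registry aglycone plus a modification multiset
#' (glycosylation, acylation, methylation; at most 4 modifications).
#' Triterpenoids are oleanolic acid; non-phenolic classes (lipid, amino
#' acid, vitamin, other) get random CHNO formulas and serve as background.
#' Deterministic given `config$seed`.
#'
#' @param n Number of compounds.
#' @param config A [sim_config()].
#' @param registry Registry list from [default_registry()].
#' @return list of compounds (class `synthetic_library`); see
#'   [library_truth()] for the flat truth table.
#' @export
generate_library <- function(n = 200L, config = sim_config(),
                             registry = default_registry()) {
  set.seed(config$seed)
  ag <- registry$aglycones
  flav <- ag[ag$compound_class %in% c("flavonol", "flavanol"), ]
  glycosyls <- c(hexosyl = 0.75, deoxyhexosyl = 0.25)
  acyls <- c(coumaroyl = 0.4, malonyl = 0.3, acetyl = 0.3)
  classes <- sample(names(config$class_proportions), n, replace = TRUE,
                    prob = config$class_proportions)
  lib <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (cls %in% c("simple_flavonoid", "mono_glycoside", "di_glycoside",
                   "acylated_glycoside")) {
      a <- flav[sample(nrow(flav), 1L), ]
      mods <- switch(cls,
        simple_flavonoid = if (stats::runif(1) < 0.3) "methyl" else character(0),
        mono_glycoside = sample(names(glycosyls), 1L, prob = glycosyls),
        di_glycoside = sample(names(glycosyls), 2L, replace = TRUE,
                              prob = glycosyls),
        acylated_glycoside = c(
          sample(names(glycosyls), sample(1:2, 1L), replace = TRUE,
                 prob = glycosyls),
          sample(names(acyls), 1L, prob = acyls)))
      formula <- Reduce(formula_sum,
                        c(list(parse_formula(a$formula)),
                          lapply(registry$modifications[mods, "formula"],
                                 parse_formula)))
      lib[[i]] <- list(compound_id = sprintf("CPD%04d", i),
                       compound_class = cls,
                       aglycone = a$name,
                       modifications = sort(mods),
                       formula = format(formula),
                       true_precursor_mz = protonated_mz(formula))
    } else if (cls == "triterpenoid") {
      a <- ag["oleanolic acid", ]
      lib[[i]] <- list(compound_id = sprintf("CPD%04d", i),
                       compound_class = cls,
                       aglycone = a$name,
                       modifications = character(0),
                       formula = a$formula,
                       true_precursor_mz = protonated_mz(a$formula))
    } else {
      # background compound with a random small-molecule CHNO formula
      nc <- sample(8:30, 1L)
      nh <- sample(seq(nc, 2L * nc + 2L), 1L)
      no <- sample(1:8, 1L)
      nn <- if (cls == "amino_acid") sample(1:2, 1L) else
        sample(0:1, 1L, prob = c(0.8, 0.2))
      counts <- c(C = nc, H = nh, O = no)
      if (nn > 0) counts <- c(counts, N = nn)
      f <- mol_formula(counts)
      lib[[i]] <- list(compound_id = sprintf("CPD%04d", i),
                       compound_class = cls,
                       aglycone = NA_character_,
                       modifications = character(0),
                       formula = format(f),
                       true_precursor_mz = protonated_mz(f))
    }
  }
  structure(lib, class = "synthetic_library")
}

#' Flat ground-truth table of a synthetic library
#' @param library A [generate_library()] result.
#' @return data.frame: compound_id, compound_class, aglycone, mods
#'   (";"-joined), formula, true_precursor_mz.
#' @export
library_truth <- function(library) {
  data.frame(
    compound_id = vapply(library, `[[`, "", "compound_id"),
    compound_class = vapply(library, `[[`, "", "compound_class"),
    aglycone = vapply(library, `[[`, "", "aglycone"),
    mods = vapply(library, function(cp)
      paste(cp$modifications, collapse = ";"), ""),
    formula = vapply(library, `[[`, "", "formula"),
    true_precursor_mz = vapply(library, `[[`, 0.0, "true_precursor_mz"))
}

.jitter_ppm <- function(mz, sd_ppm) mz * (1 + stats::rnorm(length(mz), 0, sd_ppm) * 1e-6)

#' Simulate one MS2 spectrum from a ground-truth compound
#'
#' Flavonoid-type compounds emit the full sequential-loss ladder (each
#' modification cleaved in random order); every intermediate is retained
#' with probability `1 - ladder_dropout_prob`, while the Y0+ terminus is
#' always retained. Triterpenoids emit the oleanane diagnostic series
#' instead of a ladder. All m/z values (including the precursor) receive
#' Gaussian ppm jitter, and uniform random noise peaks are added below the
#' precursor, avoiding +-3x tolerance windows around true peaks unless
#' `hostile_noise` is set. Fragment intensities decay exponentially down the
#' ladder (arbitrary units; the annotation engine ignores intensity).
#'
#' @param compound One element of a [generate_library()] result.
#' @param config A [sim_config()].
#' @param registry Registry list from [default_registry()].
#' @param rt Retention time to stamp on the spectrum (minutes).
#' @return An [ms2_spectrum()] whose id is the compound id.
#' @export
simulate_spectrum <- function(compound, config = sim_config(),
                              registry = default_registry(), rt = 5) {
  prec_true <- compound$true_precursor_mz
  cls <- compound$compound_class
  if (cls == "triterpenoid") {
    core <- protonated_mz("C30H48O3")
    true_mz <- c(core, core - CARBOXYL_LOSS_DA,
                 203.179, 189.164, 119.086, 109.102, 95.086)
    keep <- rep(TRUE, length(true_mz))
  } else if (!is.na(compound$aglycone)) {
    mods <- compound$modifications
    y0 <- protonated_mz(registry$aglycones[compound$aglycone, "formula"])
    if (length(mods) > 0L) {
      order_ <- sample(length(mods))
      deltas <- registry$modifications[mods[order_], "delta_mass"]
      true_mz <- prec_true - cumsum(deltas)  # ends at y0
      keep <- c(stats::runif(length(true_mz) - 1L) >=
                  config$ladder_dropout_prob, TRUE)
    } else {
      true_mz <- y0
      keep <- TRUE
    }
  } else {
    # unstructured background fragments
    true_mz <- sort(stats::runif(sample(2:4, 1L), 60, max(61, prec_true - 20)))
    keep <- rep(TRUE, length(true_mz))
  }
  frag_mz <- true_mz[keep]
  inten <- 1000 * 0.5^(seq_along(true_mz))[keep]
  frag_obs <- .jitter_ppm(frag_mz, config$ppm_noise_sd)
  # noise peaks: rejection-sample outside 3x tolerance windows of true peaks
  noise <- numeric(0)
  guard <- pmax(3 * 10e-6 * true_mz, 3 * 0.002)
  while (length(noise) < config$n_noise_peaks) {
    cand <- stats::runif(1, 60, max(61, prec_true - 5))
    if (!config$hostile_noise &&
        any(abs(cand - true_mz) <= guard)) next
    noise <- c(noise, cand)
  }
  mz <- c(frag_obs, noise)
  intensity <- c(inten, stats::runif(length(noise), 1, 50))
  ms2_spectrum(compound$compound_id,
               .jitter_ppm(prec_true, config$ppm_noise_sd),
               rt, mz, intensity)
}

#' Simulate spectra for a whole library (seeded)
#'
#' @inheritParams simulate_spectrum
#' @param library A [generate_library()] result.
#' @return list of [ms2_spectrum()], one per compound, deterministic given
#'   `config$seed`.
#' @export
simulate_spectra <- function(library, config = sim_config(),
                             registry = default_registry()) {
  set.seed(config$seed + 1L)
  rts <- stats::runif(length(library), 1, 14)
  lapply(seq_along(library), function(i)
    simulate_spectrum(library[[i]], config, registry, rt = rts[i]))
}

#' Simulate a color-structured abundance matrix
#'
#' Each compound gets a log-normal base abundance; each value is the base
#' times the class x color enrichment, times a stored per-sample injection
#' factor, times log-normal replicate noise. An internal-standard feature
#' (`IS_lidocaine`) carrying only the injection factor is appended, so
#' internal-standard normalization removes the injection effect exactly.
#' Optionally, whole compound classes can be planted absent from chosen
#' colors to give known presence/absence structure.
#'
#' @param library A [generate_library()] result.
#' @param config A [sim_config()].
#' @param absent_classes Optional named list, color -> character vector of
#'   compound classes absent (value 0) in that color.
#' @return A [quant_table()] including the IS row; attribute `truth` holds
#'   the injection factors, the enrichment matrix, the library truth table
#'   and the planted presence matrix.
#' @export
simulate_abundance_matrix <- function(library, config = sim_config(),
                                      absent_classes = NULL) {
  set.seed(config$seed + 2L)
  colors <- names(config$varieties_per_color)
  meta <- do.call(rbind, lapply(colors, function(cl) {
    nv <- config$varieties_per_color[[cl]]
    do.call(rbind, lapply(seq_len(nv), function(v) {
      data.frame(sample_id = sprintf("%s%02d_r%d", substr(cl, 1, 2), v,
                                     seq_len(config$replicates)),
                 variety = sprintf("%s%02d", substr(cl, 1, 2), v),
                 color = cl, replicate = seq_len(config$replicates))
    }))
  }))
  n <- length(library)
  ns <- nrow(meta)
  truth <- library_truth(library)
  base <- stats::rlnorm(n, log(1e4), config$base_abundance_logsd)
  injection <- stats::setNames(stats::rlnorm(ns, 0, config$injection_logsd),
                               meta$sample_id)
  sdlog <- sqrt(log(1 + config$replicate_cv^2))
  eff <- config$class_effect
  vals <- matrix(0, n, ns, dimnames = list(truth$compound_id, meta$sample_id))
  present <- matrix(TRUE, n, length(colors),
                    dimnames = list(truth$compound_id, colors))
  for (cl in colors) {
    if (!is.null(absent_classes[[cl]])) {
      present[truth$compound_class %in% absent_classes[[cl]], cl] <- FALSE
    }
  }
  for (s in seq_len(ns)) {
    cl <- meta$color[s]
    e <- eff[truth$compound_class, cl]
    v <- base * e * injection[s] * stats::rlnorm(n, 0, sdlog)
    v[!present[, cl]] <- 0
    vals[, s] <- v
  }
  vals <- rbind(vals, IS_lidocaine = 1e5 * injection)
  qt <- quant_table(vals, meta)
  attr(qt, "truth") <- list(injection_factors = injection,
                            class_effect = eff,
                            library = truth,
                            presence = present)
  qt
}
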