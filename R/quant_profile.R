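# The quantitative pipeline: internal-standard and Z-score normalization,
# absolute quantitation from calibration lines, differential-accumulation
# screening (Student's t), nested ANOVA (variety within color), presence
# intersections across the four color classes, PCA and hierarchical
# clustering.

#' Normalize a quant table by an internal standard
#'
#' Divides every feature value by its sample's internal-standard (IS)
#' response and removes the IS row, removing per-sample instrument response
#' variation (injection effects). The study design spikes lidocaine at
#' 0.1 mg/L as the IS.
#'
#' @param table A [quant_table()].
#' @param is_feature Feature id of the internal standard row.
#' @return A [quant_table()] without the IS row; attribute `normalization`
#'   set to `"internal_standard"`.
#' @export
normalize_internal_standard <- function(table, is_feature = "IS_lidocaine") {
  stopifnot(inherits(table, "quant_table"))
  if (!is_feature %in% rownames(table$values)) {
    stop("internal standard feature '", is_feature, "' not found", call. = FALSE)
  }
  is_row <- table$values[is_feature, ]
  bad <- which(!(is_row > 0))
  if (length(bad) > 0L) {
    stop("internal standard is zero or missing in sample(s): ",
         paste(colnames(table$values)[bad], collapse = ", "), call. = FALSE)
  }
  vals <- sweep(table$values[setdiff(rownames(table$values), is_feature), ,
                             drop = FALSE], 2, is_row, "/")
  out <- quant_table(vals, table$sample_meta)
  attr(out, "normalization") <- "internal_standard"
  attr(out, "is_feature") <- is_feature
  out
}

#' Z-score normalize a quant table per feature
#'
#' Each feature row is centered to mean 0 and scaled to sample SD 1.
#' Constant rows cannot be scaled; they are set to all zeros and listed in
#' the `constant_features` attribute.
#'
#' @param table A [quant_table()].
#' @return Z-scored table; attributes `normalization = "zscore"` and
#'   `constant_features`.
#' @export
zscore <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  vals <- table$values
  mu <- rowMeans(vals)
  sd_ <- apply(vals, 1, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  z <- (vals - mu) / ifelse(const, 1, sd_)
  z[const, ] <- 0
  out <- structure(list(values = z, sample_meta = table$sample_meta),
                   class = "quant_table")
  attr(out, "normalization") <- "zscore"
  attr(out, "constant_features") <- rownames(vals)[const]
  out
}

#' Absolute quantitation from a calibration series
#'
#' Fits the ordinary least-squares calibration line
#' `response = a * concentration + b`, inverts it at the observed response,
#' and scales to tissue content by `extract_volume / sample_mass` (ug/mL *
#' mL / g = ug/g). Responses implying a concentration outside \[0, 2x the
#' top calibration level\] are flagged as extrapolations.
#'
#' @param series A [calibration_series()].
#' @param response Observed instrument response(s).
#' @return data.frame with columns `response`, `concentration` (ug/mL),
#'   `ug_per_g`, `extrapolated`.
#' @export
absolute_quant <- function(series, response) {
  stopifnot(inherits(series, "calibration_series"))
  fit <- stats::lm(r ~ c, data = data.frame(c = series$concentrations,
                                            r = series$responses))
  a <- stats::coef(fit)[["c"]]
  b <- stats::coef(fit)[["(Intercept)"]]
  if (a == 0) stop("degenerate calibration: zero slope", call. = FALSE)
  conc <- (response - b) / a
  extrap <- conc < 0 | conc > 2 * max(series$concentrations)
  if (any(extrap)) {
    warning("response outside the extended calibration range for '",
            series$analyte, "'; flagged as extrapolation", call. = FALSE)
  }
  data.frame(response = response,
             concentration = conc,
             ug_per_g = conc * series$extract_volume / series$sample_mass,
             extrapolated = extrap)
}

#' Screen differentially accumulated metabolites between two colors
#'
#' Per-feature two-sample Student's t-test (classical equal-variance form;
#' set `var_equal = FALSE` for Welch). Features with p below the threshold
#' are called DAMs; no multiple-testing correction is applied by default
#' (screening at raw p < 0.05), but Benjamini-Hochberg adjusted p-values are
#' reported alongside when `bh = TRUE`.
#'
#' Degenerate features (zero variance in both groups) get t = 0, p = 1 when
#' the group means are equal, and infinite t, p = 0 otherwise.
#'
#' @param table A [quant_table()].
#' @param color_a,color_b Color labels of the two groups.
#' @param p_threshold DAM p-value threshold (default 0.05).
#' @param var_equal Use the pooled-variance Student form (default TRUE).
#' @param bh Also report Benjamini-Hochberg adjusted p-values.
#' @return data.frame: feature_id, group_a, group_b, mean_a, mean_b,
#'   log2_fold_change, t_statistic, p_value, (p_adjust_bh,) is_dam.
#' @export
dam_screen <- function(table, color_a, color_b, p_threshold = 0.05,
                       var_equal = TRUE, bh = FALSE) {
  stopifnot(inherits(table, "quant_table"))
  col <- table$sample_meta$color
  ia <- which(col == color_a)
  ib <- which(col == color_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  res <- t(apply(table$values, 1, function(v) {
    a <- v[ia]; b <- v[ib]
    tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      if (isTRUE(all.equal(mean(a), mean(b)))) c(t = 0, p = 1)
      else c(t = sign(mean(a) - mean(b)) * Inf, p = 0)
    } else c(t = unname(tt$statistic), p = tt$p.value)
  }))
  out <- data.frame(feature_id = rownames(table$values),
                    group_a = color_a, group_b = color_b,
                    mean_a = rowMeans(table$values[, ia, drop = FALSE]),
                    mean_b = rowMeans(table$values[, ib, drop = FALSE]),
                    t_statistic = res[, "t"], p_value = res[, "p"],
                    row.names = NULL)
  out$log2_fold_change <- log2(out$mean_a / out$mean_b)
  if (bh) out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$is_dam <- out$p_value < p_threshold
  out
}

#' Two-level nested analysis of variance (variety within color)
#'
#' Decomposes the total sum of squares into between-color, variety-within-
#' color, and residual components from the explicit group-mean formulas. The
#' color effect is tested against the variety-within-color mean square (the
#' correct denominator when varieties are the sampled units within a color);
#' the variety effect is tested against the residual.
#'
#' @param values Numeric response vector (one feature across samples).
#' @param color Color label per observation.
#' @param variety Variety label per observation; every variety must map to
#'   exactly one color and have >= 2 replicates.
#' @return list of class `nested_anova`: sums of squares (`ss_color`,
#'   `ss_variety_within_color`, `ss_error`, `ss_total`), df triplet, F and p
#'   for both effects (NA when all values are equal).
#' @export
nested_anova <- function(values, color, variety) {
  stopifnot(length(values) == length(color), length(color) == length(variety))
  color <- as.character(color); variety <- as.character(variety)
  v2c <- tapply(color, variety, function(x) length(unique(x)))
  if (any(v2c > 1L)) {
    stop("variety appearing under two colors: ",
         paste(names(v2c)[v2c > 1L], collapse = ", "), call. = FALSE)
  }
  reps <- table(variety)
  if (any(reps < 2L)) {
    stop("every variety needs >= 2 replicates", call. = FALSE)
  }
  n <- length(values)
  grand <- mean(values)
  color_mean <- tapply(values, color, mean)
  variety_mean <- tapply(values, variety, mean)
  variety_color <- tapply(color, variety, `[`, 1)
  n_color <- table(color)
  ss_color <- sum(n_color * (color_mean[names(n_color)] - grand)^2)
  ss_variety <- sum(reps * (variety_mean[names(reps)] -
                              color_mean[variety_color[names(reps)]])^2)
  ss_error <- sum((values - variety_mean[variety])^2)
  a <- length(color_mean)
  b_tot <- length(variety_mean)
  df_color <- a - 1L
  df_variety <- b_tot - a
  df_error <- n - b_tot
  ms_color <- ss_color / df_color
  ms_variety <- ss_variety / df_variety
  ms_error <- ss_error / df_error
  if (ss_color + ss_variety + ss_error <= 0) {
    f_color <- f_variety <- p_color <- p_variety <- NA_real_
  } else {
    f_color <- if (ms_variety > 0) ms_color / ms_variety else NA_real_
    f_variety <- if (ms_error > 0) ms_variety / ms_error else NA_real_
    p_color <- if (is.na(f_color)) NA_real_ else
      stats::pf(f_color, df_color, df_variety, lower.tail = FALSE)
    p_variety <- if (is.na(f_variety)) NA_real_ else
      stats::pf(f_variety, df_variety, df_error, lower.tail = FALSE)
  }
  structure(list(ss_color = ss_color,
                 ss_variety_within_color = ss_variety,
                 ss_error = ss_error,
                 ss_total = ss_color + ss_variety + ss_error,
                 df = c(color = df_color, variety = df_variety,
                        error = df_error),
                 f_color = f_color, f_variety = f_variety,
                 p_color = p_color, p_variety = p_variety),
            class = "nested_anova")
}

#' Nested ANOVA across every feature of a quant table
#'
#' @param table A [quant_table()].
#' @return data.frame with one row per feature (SS, F and p columns).
#' @export
nested_anova_table <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  m <- table$sample_meta
  rows <- lapply(rownames(table$values), function(f) {
    r <- nested_anova(table$values[f, ], m$color, m$variety)
    data.frame(feature_id = f, ss_color = r$ss_color,
               ss_variety_within_color = r$ss_variety_within_color,
               ss_error = r$ss_error, f_color = r$f_color,
               f_variety = r$f_variety, p_color = r$p_color,
               p_variety = r$p_variety)
  })
  do.call(rbind, rows)
}

#' Presence-intersection counts across color classes
#'
#' A feature is present in a color when its abundance exceeds the threshold
#' in at least one sample of that color. Returns the exclusive
#' (UpSet-style) counts for every non-empty color combination, the
#' per-color unique counts, and superset-inclusive joint counts. The
#' exclusive counts partition the features present in >= 1 color.
#'
#' @param table A [quant_table()].
#' @param presence_threshold Abundance above which a feature counts as
#'   detected (default 0, i.e. anything positive).
#' @return list of class `intersection_counts`: `exclusive` (named by
#'   "+"-joined color combination), `unique_per_color`, `joint`
#'   (superset-inclusive), `total_present`.
#' @export
intersection_counts <- function(table, presence_threshold = 0) {
  stopifnot(inherits(table, "quant_table"))
  colors <- intersect(.VALID_COLORS, unique(table$sample_meta$color))
  pres <- matrix(FALSE, nrow(table$values), length(colors),
                 dimnames = list(rownames(table$values), colors))
  for (cl in colors) {
    idx <- table$sample_meta$color == cl
    if (nrow(pres) > 0L) {
      pres[, cl] <- apply(table$values[, idx, drop = FALSE] >
                            presence_threshold, 1, any)
    }
  }
  combos <- unlist(lapply(seq_along(colors), function(k)
    utils::combn(colors, k, paste, collapse = "+", simplify = FALSE)))
  pattern <- if (nrow(pres) == 0L) character(0) else
    apply(pres, 1, function(p) paste(colors[p], collapse = "+"))
  exclusive <- stats::setNames(
    vapply(combos, function(cb) sum(pattern == cb), 0L), combos)
  joint <- stats::setNames(vapply(combos, function(cb) {
    cls <- strsplit(cb, "+", fixed = TRUE)[[1]]
    sum(rowSums(pres[, cls, drop = FALSE]) == length(cls))
  }, 0L), combos)
  structure(list(exclusive = exclusive,
                 unique_per_color = exclusive[colors],
                 joint = joint,
                 total_present = sum(pattern != "")),
            class = "intersection_counts")
}

#' Principal component analysis of samples
#'
#' Column-centered SVD (via [stats::prcomp()]) with samples as observations
#' and features as variables. By default features are Z-scored first (the
#' covariance/correlation choice is thereby explicit: Z-scoring makes this a
#' correlation PCA); constant features are dropped.
#'
#' @param table A [quant_table()].
#' @param n_components Number of components to keep.
#' @param scale_features Z-score the features first (default TRUE).
#' @return list: `scores` (samples x components), `loadings`
#'   (features x components), `variance_fractions`, `sample_meta`.
#' @export
pca_profile <- function(table, n_components = 2L, scale_features = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  tab <- if (scale_features) zscore(table) else table
  keep <- apply(tab$values, 1, function(v) stats::sd(v) > 0)
  x <- t(tab$values[keep, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       variance_fractions = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       sample_meta = table$sample_meta)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples with correlation distance
#' (1 - Pearson, the common metabolomics convention) or Euclidean distance,
#' and a configurable linkage (default average). Operates on Z-scored
#' features by default.
#'
#' @param table A [quant_table()].
#' @param distance "correlation" or "euclidean".
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param k Optional number of flat clusters to cut.
#' @param scale_features Z-score the features first (default TRUE).
#' @return list: `hclust` (the tree), `clusters` (if `k` given), `newick`
#'   (Newick serialization of the dendrogram).
#' @export
hca_profile <- function(table, distance = c("correlation", "euclidean"),
                        linkage = "average", k = NULL,
                        scale_features = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  distance <- match.arg(distance)
  tab <- if (scale_features) zscore(table) else table
  keep <- apply(tab$values, 1, function(v) stats::sd(v) > 0)
  vals <- tab$values[keep, , drop = FALSE]
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(vals))
  } else {
    stats::dist(t(vals))
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc,
              clusters = if (!is.null(k)) stats::cutree(hc, k = k),
              newick = ape::write.tree(ape::as.phylo(hc)))
  out
}
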