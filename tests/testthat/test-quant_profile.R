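test_that("internal-standard normalization divides by the IS row and drops it", {
  qt <- make_quant(list(F1 = rep(4, 6), F2 = 1:6, IS_lidocaine = rep(2, 6)),
                   n_var = 1)
  qn <- normalize_internal_standard(qt)
  expect_false("IS_lidocaine" %in% rownames(qn$values))
  expect_equal(unname(qn$values["F1", ]), rep(2, 6))
  expect_equal(unname(qn$values["F2", ]), (1:6) / 2)
  # IS zero in one sample is a hard error naming it
  qt2 <- make_quant(list(F1 = rep(4, 6), IS_lidocaine = c(2, 0, 2, 2, 2, 2)),
                    n_var = 1)
  expect_error(normalize_internal_standard(qt2), "white1_r2")
  expect_error(normalize_internal_standard(qt, "nope"), "not found")
})

test_that("IS normalization removes known injection factors exactly", {
  cfg <- sim_config(seed = 19)
  lib <- generate_library(30, cfg)
  qt <- simulate_abundance_matrix(lib, cfg)
  inj <- attr(qt, "truth")$injection_factors
  qn <- normalize_internal_standard(qt)
  # multiplying the normalized table back by 1e5*injection recovers the raw
  recon <- sweep(qn$values, 2, 1e5 * inj[colnames(qn$values)], "*")
  raw <- qt$values[rownames(qn$values), ]
  expect_equal(recon / raw, matrix(1, nrow(raw), ncol(raw),
                                   dimnames = dimnames(raw)),
               tolerance = 1e-12)
})

test_that("zscore centers and scales each feature; constant rows are flagged zeros", {
  qt <- make_quant(list(F1 = c(1, 2, 3, 4, 5, 6), F2 = rep(7, 6),
                        F3 = c(0, 0, 0, 1, 1, 1)), n_var = 1)
  z <- zscore(qt)
  expect_lt(max(abs(rowMeans(z$values[c("F1", "F3"), ]))), 1e-9)
  expect_lt(max(abs(apply(z$values[c("F1", "F3"), ], 1, sd) - 1)), 1e-9)
  expect_equal(unname(z$values["F2", ]), rep(0, 6))
  expect_equal(attr(z, "constant_features"), "F2")
  # hand-computed 3-value row
  v <- c(2, 4, 9)
  expect_equal(unname(zscore(make_quant(list(A = v), n_var = 1, n_rep = 3,
                                        colors = "red"))$values["A", ]),
               (v - 5) / sd(v))
})

test_that("absolute quantitation inverts the calibration line and scales to ug/g", {
  cs <- calibration_series("vitamin C", c(0, 10), c(0, 100), 0.1, 1)
  expect_equal(absolute_quant(cs, 50)$ug_per_g, 50)
  expect_equal(absolute_quant(cs, 0)$ug_per_g, 0)
  expect_false(absolute_quant(cs, 50)$extrapolated)
  expect_warning(out <- absolute_quant(cs, 10000), "extrapolation")
  expect_true(out$extrapolated)
})

test_that("absolute quantitation recovers simulated truth within noise", {
  set.seed(5)
  conc <- c(1, 2, 5, 10, 20)
  slope <- 8.5; noise_sd <- 2
  for (i in 1:10) {
    resp <- slope * conc + rnorm(5, 0, noise_sd)
    cs <- calibration_series("x", conc, resp, 0.1, 1)
    true_c <- 7.3
    est <- absolute_quant(cs, slope * true_c)$concentration
    expect_lt(abs(est - true_c), 2 * noise_sd)
  }
})

test_that("dam_screen matches the textbook pooled-variance t formula", {
  a <- c(5.1, 6.2, 4.9); b <- c(8.0, 7.5, 9.1)
  qt <- make_quant(list(F1 = c(a, b)), n_var = 1, n_rep = 3)
  out <- dam_screen(qt, "white", "purple")
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)
  expect_true(out$is_dam)
})

test_that("identical groups give t = 0, p = 1 and no DAM call", {
  qt <- make_quant(list(F1 = rep(3, 6), F2 = c(1, 2, 3, 1, 2, 3)),
                   n_var = 1)
  out <- dam_screen(qt, "white", "purple")
  expect_equal(out$t_statistic, c(0, 0))
  expect_equal(out$p_value, c(1, 1))
  expect_false(any(out$is_dam))
})

test_that("planted 4-fold purple enrichment is recovered as DAMs with high power", {
  cfg <- sim_config(seed = 23)
  lib <- generate_library(120, cfg)
  qt <- simulate_abundance_matrix(lib, cfg)
  qn <- normalize_internal_standard(qt)
  truth <- attr(qt, "truth")$library
  planted <- truth$compound_id[truth$compound_class == "acylated_glycoside"]
  out <- dam_screen(qn, "purple", "white")
  hit <- out$is_dam[out$feature_id %in% planted]
  expect_gt(length(hit), 5)
  expect_gte(mean(hit), 0.9)
})

test_that("nested ANOVA equals the loop oracle and aov sequential SS", {
  set.seed(11)
  color <- rep(c("white", "purple"), each = 6)
  variety <- rep(c("w1", "w2", "p1", "p2"), each = 3)
  y <- rnorm(12, rep(c(0, 0, 2, 3), each = 3))
  r <- nested_anova(y, color, variety)
  ora <- oracle_nested_ss(y, color, variety)
  expect_equal(r$ss_color, ora[["color"]], tolerance = 1e-10)
  expect_equal(r$ss_variety_within_color, ora[["variety"]], tolerance = 1e-10)
  expect_equal(r$ss_error, ora[["error"]], tolerance = 1e-10)
  expect_equal(r$ss_total, sum((y - mean(y))^2), tolerance = 1e-8)
  expect_equal(sum(r$df), length(y) - 1L)
  # independent cross-check: aov sequential decomposition
  fit <- summary(aov(y ~ color + variety))[[1]]
  expect_equal(r$ss_color, fit["color", "Sum Sq"], tolerance = 1e-8)
  expect_equal(r$ss_variety_within_color, fit["variety", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(r$ss_error, fit["Residuals", "Sum Sq"], tolerance = 1e-8)
  # the color F is tested against the variety-within-color mean square
  expect_equal(r$f_color, (r$ss_color / 1) / (r$ss_variety_within_color / 2),
               tolerance = 1e-10)
})

test_that("nested ANOVA handles degenerate and invalid designs", {
  expect_error(nested_anova(1:6, rep(c("white", "purple"), each = 3),
                            c("v1", "v1", "v1", "v1", "v2", "v2")),
               "two colors")
  expect_error(nested_anova(1:4, rep("white", 4), c("a", "b", "c", "d")),
               "replicates")
  r <- nested_anova(rep(2, 12), rep(c("white", "red"), each = 6),
                    rep(c("a", "b", "c", "d"), each = 3))
  expect_equal(r$ss_total, 0)
  expect_true(is.na(r$f_color) && is.na(r$p_color))
})

test_that("nested ANOVA is invariant to replicate permutation", {
  set.seed(3)
  color <- rep(c("white", "purple"), each = 6)
  variety <- rep(c("w1", "w2", "p1", "p2"), each = 3)
  y <- rnorm(12)
  r1 <- nested_anova(y, color, variety)
  perm <- sample(12)
  r2 <- nested_anova(y[perm], color[perm], variety[perm])
  expect_equal(r1$ss_color, r2$ss_color)
  expect_equal(r1$f_variety, r2$f_variety)
})

test_that("intersection counts partition present features across color sets", {
  # planted design: F1 everywhere, F2 white-only, F3 white+purple, F4 absent
  qt <- make_quant(list(F1 = rep(1, 12), F2 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                        F3 = c(1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0),
                        F4 = rep(0, 12)),
                   colors = c("white", "red", "purple", "pink"), n_var = 1)
  ic <- intersection_counts(qt)
  expect_equal(unname(ic$exclusive[["white+pink+red+purple"]]), 1L)
  expect_equal(unname(ic$exclusive[["white"]]), 1L)
  expect_equal(unname(ic$exclusive[["white+purple"]]), 1L)
  expect_equal(ic$total_present, 3L)
  expect_equal(sum(ic$exclusive), ic$total_present)
  # joint counts are superset-inclusive
  expect_equal(unname(ic$joint[["white"]]), 3L)
  expect_equal(unname(ic$joint[["white+purple"]]), 2L)
  # empty table
  qt0 <- qt; qt0$values <- qt$values[0, , drop = FALSE]
  ic0 <- intersection_counts(qt0)
  expect_equal(ic0$total_present, 0L)
  expect_true(all(ic0$exclusive == 0))
})

test_that("planted class absences give exact per-color unique counts", {
  cfg <- sim_config(seed = 41)
  lib <- generate_library(100, cfg)
  qt <- simulate_abundance_matrix(
    lib, cfg, absent_classes = list(white = "lipid", pink = "lipid",
                                    red = "lipid"))
  qn <- normalize_internal_standard(qt)
  n_lipid <- sum(attr(qt, "truth")$library$compound_class == "lipid")
  ic <- intersection_counts(qn)
  expect_equal(unname(ic$exclusive[["purple"]]), n_lipid)
  expect_equal(sum(ic$exclusive), ic$total_present)
})

test_that("PCA mechanics: non-increasing variance fractions, orthogonal scores, planted subspace", {
  cfg <- sim_config(seed = 47)
  lib <- generate_library(50, cfg)
  qt <- simulate_abundance_matrix(lib, cfg)
  p <- pca_profile(normalize_internal_standard(qt), n_components = 5)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  expect_lte(sum(p$variance_fractions), 1 + 1e-9)
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-10)
  # rank-2 planted subspace is recovered to principal angles < 1e-6
  set.seed(8)
  lat <- matrix(rnorm(24 * 2), 24, 2)          # samples x 2
  load <- matrix(rnorm(2 * 40), 2, 40)         # 2 x features
  vals <- t(lat %*% load) + 100                # features x samples, positive
  meta <- data.frame(sample_id = paste0("s", 1:24),
                     variety = rep(paste0("v", 1:8), each = 3),
                     color = rep(c("white", "pink", "red", "purple"), each = 6),
                     replicate = rep(1:3, 8))
  dimnames(vals) <- list(paste0("F", 1:40), meta$sample_id)
  qt2 <- quant_table(vals - min(vals), meta)
  p2 <- pca_profile(qt2, n_components = 2, scale_features = FALSE)
  expect_gt(sum(p2$variance_fractions), 1 - 1e-9)
  cl <- scale(lat, scale = FALSE)
  ang <- svd(crossprod(qr.Q(qr(cl)), qr.Q(qr(p2$scores))))$d
  expect_lt(max(abs(ang - 1)), 1e-6)
})

test_that("HCA merges identical samples first and recovers planted color clusters", {
  vals <- matrix(rnorm(5 * 4), 5, 4,
                 dimnames = list(paste0("F", 1:5), paste0("s", 1:4)))
  vals[, 2] <- vals[, 1]  # two identical samples
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     variety = c("a", "a", "b", "b"),
                     color = c("white", "white", "red", "red"),
                     replicate = c(1, 2, 1, 2))
  h <- hca_profile(quant_table(abs(vals), meta), scale_features = FALSE)
  expect_equal(sort(h$hclust$merge[1, ]), c(-2, -1))
  expect_true(all(diff(h$hclust$height) >= -1e-12))
  expect_match(h$newick, "^\\(")
  # four well-separated synthetic color groups recovered exactly at k = 4
  cfg <- sim_config(seed = 53,
                    class_effect = {
                      e <- default_class_effect()
                      e["mono_glycoside", ] <- c(50, 1, 1, 1)
                      e["di_glycoside", ] <- c(1, 50, 1, 1)
                      e["acylated_glycoside", ] <- c(1, 1, 50, 1)
                      e["simple_flavonoid", ] <- c(1, 1, 1, 50)
                      e
                    },
                    varieties_per_color = c(white = 2, pink = 2, red = 2,
                                            purple = 2),
                    replicate_cv = 0.05, injection_logsd = 0)
  lib <- generate_library(80, cfg)
  qt <- simulate_abundance_matrix(lib, cfg)
  h2 <- hca_profile(normalize_internal_standard(qt), k = 4)
  cl <- h2$clusters
  colors <- qt$sample_meta$color
  expect_equal(length(unique(tapply(cl, colors, function(x)
    length(unique(x))))), 1L)
  expect_true(all(tapply(cl, colors, function(x) length(unique(x))) == 1))
  expect_equal(length(unique(cl)), 4L)
})
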