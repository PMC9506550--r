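# Block ANOVA, fold changes, DAM selection, effect partition, PCA.

toy_table_16 <- function(values) {
  design <- tidyr::expand_grid(organ = c("leaf", "root"),
                               line = c("Bd21", "Bd3-1"),
                               experiment = c("E1", "E2"), replicate = 1:2)
  design$sample_id <- sprintf("s%02d", seq_len(nrow(design)))
  design <- design[, c("sample_id", "organ", "line", "experiment",
                       "replicate")]
  features <- tibble::tibble(feature_id = "F001", mz = 300, rt = 1,
                             polarity = "negative")
  feature_table(features, design, matrix(values, nrow = 1),
                transformed = "log2")
}

test_that("ANOVA matches a hand sums-of-squares decomposition", {
  # fixed 16-value toy table written down before the implementation
  vals <- c(10.1, 9.8, 10.6, 10.3, 12.2, 12.0, 12.7, 12.4,
            8.9, 9.2, 9.5, 9.7, 11.5, 11.1, 12.0, 11.6)
  ft <- toy_table_16(vals)
  got <- ft_anova(ft)

  # manual decomposition: on the balanced design the factor subspaces are
  # orthogonal, so sequential SS equal marginal group-mean SS
  d <- ft$samples
  y <- as.vector(ft$intensities)
  grand <- mean(y)
  ss_of <- function(f) {
    m <- tapply(y, f, mean)
    n <- tapply(y, f, length)
    sum(n * (m - grand)^2)
  }
  ss_block <- ss_of(d$experiment)
  ss_organ <- ss_of(d$organ)
  ss_line <- ss_of(d$line)
  cellm <- tapply(y, list(d$organ, d$line), mean)
  om <- tapply(y, d$organ, mean)
  lm_ <- tapply(y, d$line, mean)
  ss_int <- 4 * sum((cellm - outer(om, rep(1, 2)) -
                       outer(rep(1, 2), lm_) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_block - ss_organ - ss_line - ss_int
  df_res <- 16 - 1 - 1 - 1 - 1 - 1
  expect_equal(got$F_organ, (ss_organ / 1) / (ss_res / df_res),
               tolerance = 1e-10)
  expect_equal(got$F_line, (ss_line / 1) / (ss_res / df_res),
               tolerance = 1e-10)
  expect_equal(got$F_interaction, (ss_int / 1) / (ss_res / df_res),
               tolerance = 1e-10)

  # independent cross-check: sequential ANOVA via stats::lm
  dd <- d
  dd$y <- y
  fit <- stats::anova(stats::lm(y ~ experiment + organ * line, data = dd))
  expect_equal(got$F_organ, fit["organ", "F value"], tolerance = 1e-10)
  expect_equal(got$F_line, fit["line", "F value"], tolerance = 1e-10)
  expect_equal(got$F_interaction, fit["organ:line", "F value"],
               tolerance = 1e-10)
  expect_equal(got$p_line, fit["line", "Pr(>F)"], tolerance = 1e-10)
})

test_that("matrix ANOVA equals per-feature lm on the canonical design", {
  ft <- preprocess(random_feature_table(15, seed = 31, missing_frac = 0.05))
  got <- ft_anova(ft)
  d <- ft$samples
  for (i in c(1, 7, 15)) {
    d$y <- ft$intensities[i, ]
    fit <- stats::anova(stats::lm(y ~ experiment + organ * line, data = d))
    expect_equal(got$F_organ[i], fit["organ", "F value"], tolerance = 1e-9)
    expect_equal(got$F_interaction[i], fit["organ:line", "F value"],
                 tolerance = 1e-9)
  }
})

test_that("constant features give F = 0, p = 1", {
  ft <- random_feature_table(2, seed = 32)
  ft$intensities[1, ] <- 5
  ft <- log2_transform(ft)
  got <- ft_anova(ft)
  expect_identical(got$F_organ[1], 0)
  expect_identical(got$p_line[1], 1)
  expect_identical(got$p_interaction[1], 1)
})

test_that("Type I and Type III coincide on the balanced 48-sample design", {
  ft <- preprocess(random_feature_table(5, seed = 33))
  got <- ft_anova(ft)
  d <- ft$samples
  for (i in 1:5) {
    d$y <- ft$intensities[i, ]
    # reversing the order of the fixed factors leaves sequential F
    # unchanged only under orthogonality (= Type III equality)
    fit <- stats::anova(stats::lm(y ~ experiment + line * organ, data = d))
    expect_equal(got$F_organ[i], fit["organ", "F value"], tolerance = 1e-9)
    expect_equal(got$F_line[i], fit["line", "F value"], tolerance = 1e-9)
  }
})

test_that("p-values travel with sample permutation", {
  ft <- preprocess(random_feature_table(10, seed = 34))
  perm <- sample(48)
  ft2 <- ft
  ft2$samples <- ft$samples[perm, ]
  ft2$intensities <- ft$intensities[, perm]
  expect_equal(ft_anova(ft2)$p_line, ft_anova(ft)$p_line, tolerance = 1e-12)
})

test_that("fold changes are log2 mean differences per organ", {
  ft <- random_feature_table(3, seed = 35)
  # feature 1: Bd3-1 exactly 4x Bd21 everywhere
  base <- 100
  ft$intensities[1, ] <- ifelse(ft$samples$line == "Bd3-1", 4 * base, base)
  ft$intensities[2, ] <- base
  ft <- log2_transform(ft)
  fc <- fold_change_per_organ(ft)
  expect_equal(fc$log2_fc_leaf[1], 2)
  expect_equal(fc$log2_fc_spike[1], 2)
  expect_equal(fc$log2_fc_root[2], 0)
  # direct arithmetic oracle
  i31 <- ft$samples$organ == "leaf" & ft$samples$line == "Bd3-1"
  i21 <- ft$samples$organ == "leaf" & ft$samples$line == "Bd21"
  expect_equal(fc$log2_fc_leaf[3],
               mean(ft$intensities[3, i31]) - mean(ft$intensities[3, i21]))
})

test_that("DAM selection applies the p/fold-change rule and is monotone", {
  anova <- tibble::tibble(
    feature_id = c("A", "B"),
    p_organ = c(0.5, 0.5), p_line = c(0.02, 0.001),
    p_interaction = c(0.5, 0.5))
  fcs <- tibble::tibble(feature_id = c("A", "B"),
                        log2_fc_leaf = c(3, 1.5), log2_fc_root = c(0.2, 0.5))
  dams <- select_dams(anova, fcs, p_max = 0.01, min_abs_log2_fc = 1)
  # A: large FC but p = 0.02 > 0.01 -> never a DAM
  expect_false(any(dams$passes[dams$feature_id == "A"]))
  # B: p 0.001, |FC| 1.5 > 1 in leaf
  expect_true(dams$passes[dams$feature_id == "B" & dams$organ == "leaf"])
  expect_false(dams$passes[dams$feature_id == "B" & dams$organ == "root"])

  # monotonicity: tightening either threshold never adds a call
  set.seed(36)
  anova_r <- tibble::tibble(feature_id = sprintf("F%02d", 1:50),
                            p_organ = runif(50), p_line = runif(50),
                            p_interaction = runif(50))
  fcs_r <- tibble::tibble(feature_id = anova_r$feature_id,
                          log2_fc_leaf = rnorm(50, sd = 2))
  loose <- select_dams(anova_r, fcs_r, p_max = 0.1, min_abs_log2_fc = 0.5)
  for (pm in c(0.05, 0.01)) for (fcm in c(1, 2)) {
    tight <- select_dams(anova_r, fcs_r, p_max = pm, min_abs_log2_fc = fcm)
    expect_true(all(loose$passes[tight$passes]))
  }
})

test_that("effect partition matches brute-force set enumeration", {
  set.seed(37)
  anova <- tibble::tibble(feature_id = sprintf("F%02d", 1:60),
                          p_organ = runif(60), p_line = runif(60),
                          p_interaction = runif(60))
  part <- effect_partition(anova, p_max = 0.3)
  O <- which(anova$p_organ < 0.3)
  L <- which(anova$p_line < 0.3)
  X <- which(anova$p_interaction < 0.3)
  venn <- setNames(part$venn$count, part$venn$region)
  expect_identical(venn[["O"]], length(setdiff(O, union(L, X))))
  expect_identical(venn[["O&L"]], length(setdiff(intersect(O, L), X)))
  expect_identical(venn[["O&L&OxL"]],
                   length(intersect(O, intersect(L, X))))
  expect_identical(sum(venn), length(union(O, union(L, X))))
  # all p = 1 -> empty everywhere
  anova$p_organ <- anova$p_line <- anova$p_interaction <- 1
  expect_identical(sum(effect_partition(anova, 0.5)$venn$count), 0L)
})

test_that("PCA separates planted clusters and matches eigendecomposition", {
  ft <- random_feature_table(50, seed = 38)
  # rank-1 signal: roots shifted strongly on all features
  shift <- ifelse(ft$samples$organ == "root", 6, 0)
  ft$intensities <- ft$intensities * 2^matrix(shift, nrow = 50, ncol = 48,
                                              byrow = TRUE)
  ft <- log2_transform(ft)
  pca <- ft_pca(ft)
  expect_gt(pca$explained[1], pca$explained[2])
  pc1_root <- pca$scores$PC1[pca$scores$organ == "root"]
  pc1_rest <- pca$scores$PC1[pca$scores$organ != "root"]
  expect_true(max(pc1_root) < min(pc1_rest) ||
                min(pc1_root) > max(pc1_rest))

  # eigendecomposition oracle (sign-adjusted)
  X <- t(ft$intensities)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  for (k in 1:3) {
    s_or <- Xc %*% ev$vectors[, k]
    s_my <- pca$scores[[paste0("PC", k)]]
    expect_lt(min(max(abs(s_my - s_or)), max(abs(s_my + s_or))), 1e-8)
  }
  expect_equal(pca$explained[1],
               ev$values[1] / sum(ev$values), tolerance = 1e-10)

  # duplicated samples get identical coordinates
  ft2 <- ft
  ft2$intensities[, 2] <- ft2$intensities[, 1]
  p2 <- ft_pca(ft2)
  expect_equal(unlist(p2$scores[1, c("PC1", "PC2", "PC3")]),
               unlist(p2$scores[2, c("PC1", "PC2", "PC3")]),
               tolerance = 1e-10)
  expect_error(ft_pca(ft, n_components = 100), "fewer samples")
})

test_that("tidy/glance summarise a DAM analysis", {
  sim <- simulate_feature_table(sim_config(n_features = 80, seed = 39,
                                           fraction_line_affected = 0.2))
  res <- dam_analysis(sim$table)
  td <- tidy(res)
  expect_identical(nrow(td), 80L * 3L)
  expect_true(all(c("log2_fc", "passes", "p_line") %in% names(td)))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_features, 80L)
})
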