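# The statistical stage: per-feature two-way ANOVA with the experiment as a
# block, organ-wise fold changes, DAM selection, effect partition (Venn),
# and PCA of the preprocessed table.
#
# With two blocks and a balanced design, fitting the experiment as an
# additive fixed block gives F tests for the fixed factors identical to the
# random-block analysis, so the block enters as a fixed term. Sequential
# (Type I) sums of squares are taken in the order block, organ, line,
# organ:line; on the balanced design these coincide with Type III.

#' Per-feature two-way block ANOVA
#'
#' Fits `log2 intensity ~ experiment + organ * line` for every feature and
#' returns sequential-SS F tests for organ, line and the organ x line
#' interaction against the residual mean square. Implemented as successive
#' orthogonal projections (one QR per nested model, applied to the whole
#' intensity matrix), so thousands of features are tested in one pass.
#'
#' @param x A preprocessed (`log2`) `feature_table`.
#' @return A tibble with one row per feature: F and p for each effect plus
#'   the degrees of freedom, of class `dam_anova`.
#' @export
ft_anova <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$transformed != "log2") {
    stop("ft_anova() expects a log2-preprocessed table", call. = FALSE)
  }
  d <- x$samples
  cell <- table(d$organ, d$line)
  if (any(cell < 2)) {
    stop("each organ x line cell needs >= 2 observations", call. = FALSE)
  }
  d$organ <- factor(d$organ)
  d$line <- factor(d$line)
  d$experiment <- factor(d$experiment)

  terms <- list(
    block = stats::model.matrix(~experiment, d),
    organ = stats::model.matrix(~experiment + organ, d),
    line = stats::model.matrix(~experiment + organ + line, d),
    interaction = stats::model.matrix(~experiment + organ * line, d)
  )
  Y <- t(x$intensities) # samples x features
  n <- nrow(Y)
  # residual sums of squares under each nested model
  rss <- lapply(terms, function(X) {
    qr_x <- qr(X)
    res <- qr.resid(qr_x, Y)
    colSums(res^2)
  })
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  df <- vapply(terms, function(X) qr(X)$rank, numeric(1))
  df_effect <- c(organ = df[["organ"]] - df[["block"]],
                 line = df[["line"]] - df[["organ"]],
                 interaction = df[["interaction"]] - df[["line"]])
  df_resid <- n - df[["interaction"]]
  ms_resid <- rss$interaction / df_resid

  f_stat <- function(upper, lower, dfe) {
    ss <- pmax(rss[[lower]] - rss[[upper]], 0)
    f <- ifelse(ms_resid > 0, (ss / dfe) / ms_resid, 0)
    # a feature constant across all samples has no variance anywhere
    f[tss == 0] <- 0
    f
  }
  F_organ <- f_stat("organ", "block", df_effect[["organ"]])
  F_line <- f_stat("line", "organ", df_effect[["line"]])
  F_inter <- f_stat("interaction", "line", df_effect[["interaction"]])

  p_of <- function(f, dfe) {
    p <- stats::pf(f, dfe, df_resid, lower.tail = FALSE)
    ifelse(f == 0, 1, p)
  }
  out <- tibble::tibble(
    feature_id = x$features$feature_id,
    F_organ = unname(F_organ),
    p_organ = unname(p_of(F_organ, df_effect[["organ"]])),
    F_line = unname(F_line),
    p_line = unname(p_of(F_line, df_effect[["line"]])),
    F_interaction = unname(F_inter),
    p_interaction = unname(p_of(F_inter, df_effect[["interaction"]])),
    df_organ = df_effect[["organ"]], df_line = df_effect[["line"]],
    df_interaction = df_effect[["interaction"]], df_resid = df_resid
  )
  class(out) <- c("dam_anova", class(out))
  out
}

#' Organ-wise log2 fold changes (Bd3-1 / Bd21)
#'
#' Per feature and organ, the difference of mean log2 intensities between
#' lines (a geometric-mean intensity ratio on the raw scale).
#'
#' @param x A preprocessed (`log2`) `feature_table`.
#' @return A tibble: `feature_id`, one `log2_fc_<organ>` column per organ.
#' @export
fold_change_per_organ <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$transformed != "log2") {
    stop("fold_change_per_organ() expects a log2-preprocessed table",
         call. = FALSE)
  }
  out <- tibble::tibble(feature_id = x$features$feature_id)
  for (org in sort(unique(x$samples$organ))) {
    i31 <- x$samples$organ == org & x$samples$line == "Bd3-1"
    i21 <- x$samples$organ == org & x$samples$line == "Bd21"
    if (!any(i31) || !any(i21)) {
      stop("organ ", org, " lacks one of the lines", call. = FALSE)
    }
    out[[paste0("log2_fc_", org)]] <- unname(
      rowMeans(x$intensities[, i31, drop = FALSE]) -
      rowMeans(x$intensities[, i21, drop = FALSE]))
  }
  out
}

#' Select differentially accumulating metabolites (DAMs)
#'
#' A feature is a DAM in an organ when the line or organ x line interaction
#' effect is significant (`p <= p_max`) and its absolute log2 fold change in
#' that organ exceeds `min_abs_log2_fc` (FC > 2 at the default of 1).
#' Optionally the p-value screen can use BH-adjusted values.
#'
#' @param anova A `dam_anova` tibble from [ft_anova()].
#' @param fcs Fold-change tibble from [fold_change_per_organ()].
#' @param p_max Significance threshold (default 0.01).
#' @param min_abs_log2_fc Fold-change threshold on the log2 scale (default 1).
#' @param bh Apply Benjamini-Hochberg adjustment to the line and interaction
#'   p-values before thresholding (default FALSE, mirroring a raw-p screen).
#' @return A tibble with one row per feature x organ and a `passes` flag.
#' @export
select_dams <- function(anova, fcs, p_max = 0.01, min_abs_log2_fc = 1,
                        bh = FALSE) {
  stopifnot(p_max > 0, min_abs_log2_fc > 0)
  p_line <- anova$p_line
  p_inter <- anova$p_interaction
  if (bh) {
    p_line <- stats::p.adjust(p_line, method = "BH")
    p_inter <- stats::p.adjust(p_inter, method = "BH")
  }
  sig <- p_line <= p_max | p_inter <= p_max
  organ_cols <- grep("^log2_fc_", names(fcs), value = TRUE)
  long <- fcs |>
    dplyr::inner_join(
      tibble::tibble(feature_id = anova$feature_id, significant = sig),
      by = "feature_id"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(organ_cols), names_to = "organ",
                        names_prefix = "log2_fc_", values_to = "log2_fc")
  long |>
    dplyr::mutate(
      passes = .data$significant & abs(.data$log2_fc) > min_abs_log2_fc,
      p_max = p_max, min_abs_log2_fc = min_abs_log2_fc
    ) |>
    dplyr::select("feature_id", "organ", "log2_fc", "significant", "passes",
                  "p_max", "min_abs_log2_fc")
}

#' Partition features by significant effects (Venn counts)
#'
#' Classifies each feature by which effects are significant at `p_max`
#' (organ O, line L, interaction OxL) and counts the seven Venn regions.
#'
#' @param anova A `dam_anova` tibble.
#' @param p_max Significance threshold.
#' @return A list: `membership` tibble (logical `O`, `L`, `OxL` per feature)
#'   and `venn` tibble of the seven region counts.
#' @export
effect_partition <- function(anova, p_max = 0.01) {
  stopifnot(p_max > 0, p_max < 1)
  mem <- tibble::tibble(
    feature_id = anova$feature_id,
    O = anova$p_organ < p_max,
    L = anova$p_line < p_max,
    OxL = anova$p_interaction < p_max
  )
  regions <- tibble::tibble(
    region = c("O", "L", "OxL", "O&L", "O&OxL", "L&OxL", "O&L&OxL"),
    count = c(
      sum(mem$O & !mem$L & !mem$OxL),
      sum(!mem$O & mem$L & !mem$OxL),
      sum(!mem$O & !mem$L & mem$OxL),
      sum(mem$O & mem$L & !mem$OxL),
      sum(mem$O & !mem$L & mem$OxL),
      sum(!mem$O & mem$L & mem$OxL),
      sum(mem$O & mem$L & mem$OxL)
    )
  )
  list(membership = mem, venn = regions)
}

#' PCA of the preprocessed feature table
#'
#' Samples are observations, features are variables; columns are
#' mean-centred (no scaling), mirroring a global metabolite-profile PCA.
#'
#' @param x A preprocessed (`log2`) `feature_table`.
#' @param n_components Number of components to keep (default 3).
#' @return A `dam_pca` list: `scores` tibble (per sample, with design
#'   columns), `explained` variance fractions, and the `prcomp` fit.
#' @export
ft_pca <- function(x, n_components = 3) {
  stopifnot(inherits(x, "feature_table"))
  if (x$transformed != "log2") {
    stop("ft_pca() expects a log2-preprocessed table", call. = FALSE)
  }
  if (nrow(x$samples) < n_components) {
    stop("fewer samples than requested components", call. = FALSE)
  }
  fit <- stats::prcomp(t(x$intensities), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores$sample_id <- x$samples$sample_id
  scores <- dplyr::left_join(scores, x$samples, by = "sample_id")
  structure(list(scores = scores, explained = expl[seq_len(k)], fit = fit),
            class = "dam_pca")
}

#' Full DAM analysis of a raw feature table
#'
#' Preprocesses (half-minimum substitution, log2), runs the block ANOVA,
#' fold changes, DAM selection and the effect partition in one call.
#'
#' @param x A `feature_table` (raw or already log2).
#' @inheritParams select_dams
#' @return A `dam_result` list: `anova`, `fold_changes`, `dams`,
#'   `partition`, `pca`, and the preprocessed `table`.
#' @export
dam_analysis <- function(x, p_max = 0.01, min_abs_log2_fc = 1, bh = FALSE) {
  if (x$transformed == "raw") x <- preprocess(x)
  anova <- ft_anova(x)
  fcs <- fold_change_per_organ(x)
  dams <- select_dams(anova, fcs, p_max = p_max,
                      min_abs_log2_fc = min_abs_log2_fc, bh = bh)
  structure(
    list(anova = anova, fold_changes = fcs, dams = dams,
         partition = effect_partition(anova, p_max = p_max),
         pca = ft_pca(x), table = x),
    class = "dam_result"
  )
}

#' @export
print.dam_result <- function(x, ...) {
  n_dam <- length(unique(x$dams$feature_id[x$dams$passes]))
  cat("<dam_result> ", nrow(x$anova), " features; ",
      n_dam, " DAM features (p_max=", x$dams$p_max[1],
      ", |log2FC|>", x$dams$min_abs_log2_fc[1], ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DAM analysis: one row per feature x organ
#'
#' @param x A `dam_result`.
#' @param ... Unused.
#' @return A tibble joining ANOVA p-values with fold changes and DAM calls.
#' @method tidy dam_result
#' @export
tidy.dam_result <- function(x, ...) {
  x$dams |>
    dplyr::left_join(
      x$anova |>
        dplyr::select("feature_id", "p_organ", "p_line", "p_interaction"),
      by = "feature_id"
    )
}

#' One-line summary of a DAM analysis
#'
#' @param x A `dam_result`.
#' @param ... Unused.
#' @return A one-row tibble with feature, DAM and Venn-region counts.
#' @method glance dam_result
#' @export
glance.dam_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$anova),
    n_dam_features = length(unique(x$dams$feature_id[x$dams$passes])),
    n_dam_calls = sum(x$dams$passes),
    n_sig_organ = sum(x$partition$membership$O),
    n_sig_line = sum(x$partition$membership$L),
    n_sig_interaction = sum(x$partition$membership$OxL),
    pc1_var = x$pca$explained[1]
  )
}
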