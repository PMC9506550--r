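# Aligned LC-MS feature tables with the factorial sample design, and the
# paper-style preprocessing: below-detection-limit substitution by half the
# per-feature minimum non-zero value, then log2.

ORGANS <- c("leaf", "root", "spike")
LINES <- c("Bd21", "Bd3-1")

#' Construct a feature table
#'
#' @param features Tibble with columns `feature_id`, `mz`, `rt`, `polarity`.
#' @param samples Tibble with columns `sample_id`, `organ` (leaf/root/spike),
#'   `line` (Bd21/Bd3-1), `experiment`, `replicate`.
#' @param intensities Numeric matrix, features x samples; `NA` marks
#'   below-detection-limit observations.
#' @param transformed `"raw"` or `"log2"`.
#' @return A `feature_table` object.
#' @export
feature_table <- function(features, samples, intensities,
                          transformed = c("raw", "log2")) {
  transformed <- match.arg(transformed)
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("feature_id", "mz", "rt", "polarity") %in% names(features)))
  stopifnot(all(c("sample_id", "organ", "line", "experiment", "replicate")
                %in% names(samples)))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(samples)) {
    stop("intensity matrix is ", nrow(intensities), " x ", ncol(intensities),
         " but there are ", nrow(features), " features and ",
         nrow(samples), " samples", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature ids", call. = FALSE)
  }
  bad_organ <- setdiff(unique(samples$organ), ORGANS)
  if (length(bad_organ)) {
    stop("unknown organ label(s): ", paste(bad_organ, collapse = ", "),
         call. = FALSE)
  }
  bad_line <- setdiff(unique(samples$line), LINES)
  if (length(bad_line)) {
    stop("unknown line label(s): ", paste(bad_line, collapse = ", "),
         call. = FALSE)
  }
  key <- with(samples, paste(organ, line, experiment, replicate))
  if (anyDuplicated(key)) {
    stop("(organ, line, experiment, replicate) must uniquely identify a sample",
         call. = FALSE)
  }
  if (any(!is.na(intensities) & intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  dimnames(intensities) <- list(features$feature_id, samples$sample_id)
  structure(list(features = features, samples = samples,
                 intensities = intensities, transformed = transformed),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      nrow(x$samples), " samples [", x$transformed, "]\n", sep = "")
  cat("  organs: ", paste(sort(unique(x$samples$organ)), collapse = "/"),
      "; lines: ", paste(sort(unique(x$samples$line)), collapse = "/"),
      "; missing: ", sum(is.na(x$intensities)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) {
  c(nrow(x$features), nrow(x$samples))
}

#' The canonical 48-sample factorial design
#'
#' Three organs x two lines x two experiment blocks x four biological
#' replicates.
#'
#' @return A 48-row sample-design tibble.
#' @export
canonical_design <- function() {
  d <- tidyr::expand_grid(organ = ORGANS, line = LINES,
                          experiment = c("E1", "E2"), replicate = 1:4)
  d$sample_id <- sprintf("%s_%s_%s_r%d", substr(d$organ, 1, 1),
                         gsub("-", "", d$line), d$experiment, d$replicate)
  d[, c("sample_id", "organ", "line", "experiment", "replicate")]
}

#' Read a feature table from delimited text
#'
#' The intensity file has one header row of sample ids and leading columns
#' `feature_id`, `mz`, `rt`, `polarity`; the design file has columns
#' `sample_id`, `organ`, `line`, `experiment`, `replicate`. Empty fields are
#' below-detection-limit markers.
#'
#' @param path Path to the intensity TSV.
#' @param design_path Path to the sample-design TSV.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, design_path) {
  # numeric fields come in as text and go through strtod (correctly rounded),
  # so the write/read round trip is bit-exact
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  tab$mz <- as.numeric(tab$mz)
  tab$rt <- as.numeric(tab$rt)
  design <- readr::read_tsv(design_path, show_col_types = FALSE)
  meta_cols <- c("feature_id", "mz", "rt", "polarity")
  missing_meta <- setdiff(meta_cols, names(tab))
  if (length(missing_meta)) {
    stop("feature table lacks column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  if (!setequal(sample_cols, design$sample_id) ||
      length(sample_cols) != nrow(design)) {
    stop("sample columns do not match the design: ",
         length(sample_cols), " intensity columns vs ",
         nrow(design), " design rows", call. = FALSE)
  }
  intens <- matrix(
    unlist(lapply(design$sample_id, function(s) as.numeric(tab[[s]]))),
    nrow = nrow(tab), ncol = nrow(design))
  feature_table(tab[, meta_cols], design, intens, transformed = "raw")
}

#' Write a feature table (and its design) to delimited text
#'
#' Emits the same dialect [read_feature_table()] consumes, so a write/read
#' round trip is bit-identical.
#'
#' @param x A `feature_table`.
#' @param path Intensity TSV path.
#' @param design_path Design TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, design_path) {
  # intensities are serialized at %.17g so the write/read round trip is
  # bit-identical; empty fields mark below-detection-limit observations
  chr <- apply(x$intensities, 2, function(col) {
    ifelse(is.na(col), "", sprintf("%.17g", col))
  })
  out <- dplyr::bind_cols(x$features,
                          tibble::as_tibble(as.data.frame(chr)))
  readr::write_tsv(out, path)
  readr::write_tsv(x$samples, design_path)
  invisible(path)
}

#' Substitute below-detection-limit values by half the row minimum
#'
#' Per feature, every missing or zero entry is replaced by half of that
#' feature's minimum non-zero observation. Features with no non-zero
#' observation at all cannot be imputed and are dropped with a warning.
#' Idempotent.
#'
#' @param x A raw `feature_table`.
#' @return The imputed `feature_table`.
#' @export
impute_half_min <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$transformed != "raw") {
    stop("impute_half_min() expects a raw-scale table", call. = FALSE)
  }
  m <- x$intensities
  below <- is.na(m) | m == 0
  row_min <- apply(m, 1, function(r) {
    r <- r[!is.na(r) & r > 0]
    if (length(r) == 0) NA_real_ else min(r)
  })
  dead <- is.na(row_min)
  if (any(dead)) {
    warning(sum(dead), " feature(s) with no observed value dropped: ",
            paste(utils::head(x$features$feature_id[dead], 5), collapse = ", "),
            if (sum(dead) > 5) ", ..." else "", call. = FALSE)
    m <- m[!dead, , drop = FALSE]
    below <- below[!dead, , drop = FALSE]
    row_min <- row_min[!dead]
    x$features <- x$features[!dead, ]
  }
  fill <- matrix(row_min / 2, nrow = nrow(m), ncol = ncol(m))
  m[below] <- fill[below]
  x$intensities <- m
  x
}

#' Log2-transform an imputed feature table
#'
#' @param x A raw `feature_table` with all entries positive (run
#'   [impute_half_min()] first).
#' @return The table with log2 intensities and `transformed = "log2"`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$transformed == "log2") return(x)
  bad <- is.na(x$intensities) | x$intensities <= 0
  if (any(bad)) {
    offenders <- x$features$feature_id[apply(bad, 1, any)]
    stop("non-positive or missing intensities (impute first); e.g. feature ",
         offenders[1], call. = FALSE)
  }
  x$intensities <- log2(x$intensities)
  x$transformed <- "log2"
  x
}

#' Standard preprocessing: half-minimum substitution then log2
#'
#' @param x A raw `feature_table`.
#' @return A log2 `feature_table` with no missing entries.
#' @export
preprocess <- function(x) {
  log2_transform(impute_half_min(x))
}

#' Feature-table intensities as a long tibble
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) pair, carrying the
#'   design columns.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(x$features$feature_id, times = ncol(x$intensities)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  long |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::left_join(x$features, by = "feature_id")
}
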