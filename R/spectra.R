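# Fragmentation spectrum trees: a precursor ion plus nested MS2..MS5
# product-ion scans in one ionization polarity. Each scan records which
# parent ion was isolated and which product is the base peak (the ion taken
# for further fragmentation in low-resolution MSn work).

#' Construct a spectrum tree
#'
#' @param precursor_mz Precursor ion m/z (Da).
#' @param polarity `"positive"` or `"negative"`.
#' @param scans A list of scans; each scan is a list with `level` (2..5),
#'   `parent_mz` (the isolated ion; the precursor for MS2), and `ions`
#'   (data frame with `mz`, `intensity`, `is_base`).
#' @param resolution `"high"` or `"low"`; governs the matching tolerances
#'   used by the rule engine.
#' @return A `spectrum_tree`.
#' @export
spectrum_tree <- function(precursor_mz, polarity = c("negative", "positive"),
                          scans = list(), resolution = c("high", "low")) {
  polarity <- match.arg(polarity)
  resolution <- match.arg(resolution)
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0)
  scans <- lapply(scans, function(s) {
    stopifnot(all(c("level", "parent_mz", "ions") %in% names(s)))
    ions <- tibble::as_tibble(s$ions)
    stopifnot(all(c("mz", "intensity") %in% names(ions)))
    if (!"is_base" %in% names(ions)) {
      ions$is_base <- ions$intensity == max(ions$intensity)
    }
    if (any(ions$mz > s$parent_mz + 0.5)) {
      stop("product ion heavier than its parent (", s$parent_mz, "): ",
           paste(ions$mz[ions$mz > s$parent_mz + 0.5], collapse = ", "),
           call. = FALSE)
    }
    # normalise so the scan's base peak is 1
    if (max(ions$intensity) > 0) {
      ions$intensity <- ions$intensity / max(ions$intensity)
    }
    list(level = as.integer(s$level), parent_mz = s$parent_mz, ions = ions)
  })
  structure(list(precursor_mz = precursor_mz, polarity = polarity,
                 resolution = resolution, scans = scans),
            class = "spectrum_tree")
}

#' @export
print.spectrum_tree <- function(x, ...) {
  cat("<spectrum_tree> precursor ", x$precursor_mz, " (", x$polarity, ", ",
      x$resolution, "-res), ", length(x$scans), " scan(s)\n", sep = "")
  for (s in x$scans) {
    marked <- ifelse(s$ions$is_base, paste0("*", s$ions$mz, "*"), s$ions$mz)
    cat("  MS", s$level, " @", round(s$parent_mz, 4), ": ",
        paste(marked, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Parse an encoded MSn fragmentation pathway
#'
#' Decodes the compact pathway strings bundled with the compound library:
#' scans separated by `|`, e.g. `"MS2:323,*193*,173,135|MS3:149,135"`. Base
#' peaks are marked `*ion*`; an explicit isolation parent is written
#' `MS3@483:...`. When no parent is given, a scan's parent defaults to the
#' base peak of the previous level (the precursor for MS2).
#'
#' @param frag Encoded pathway string.
#' @param precursor_mz Precursor m/z.
#' @param polarity Ionization polarity.
#' @param resolution Resolution tag for the resulting tree.
#' @param base_intensity,other_intensity Relative intensities given to
#'   marked base peaks and remaining ions.
#' @return A `spectrum_tree`.
#' @export
parse_frag_pathway <- function(frag, precursor_mz,
                               polarity = c("negative", "positive"),
                               resolution = "high",
                               base_intensity = 1, other_intensity = 0.5) {
  polarity <- match.arg(polarity)
  if (is.na(frag) || !nzchar(frag)) {
    return(spectrum_tree(precursor_mz, polarity, list(),
                         resolution = resolution))
  }
  parts <- strsplit(frag, "|", fixed = TRUE)[[1]]
  scans <- list()
  last_base <- list() # level -> base-peak m/z
  for (part in parts) {
    m <- regmatches(part, regexec("^MS([2-5])(@([0-9.]+))?:(.*)$", part))[[1]]
    if (length(m) == 0) stop("cannot parse scan: '", part, "'", call. = FALSE)
    level <- as.integer(m[2])
    explicit_parent <- if (nzchar(m[4])) as.numeric(m[4]) else NA_real_
    toks <- strsplit(m[5], ",", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    is_base <- grepl("^\\*.*\\*$", toks)
    mzv <- as.numeric(gsub("\\*", "", toks))
    if (any(is.na(mzv))) stop("bad ion in scan: '", part, "'", call. = FALSE)
    if (!any(is_base)) is_base[1] <- TRUE
    parent <- if (!is.na(explicit_parent)) explicit_parent
      else if (level == 2) precursor_mz
      else {
        prev <- last_base[[as.character(level - 1)]]
        if (is.null(prev)) precursor_mz else prev[1]
      }
    scans[[length(scans) + 1]] <- list(
      level = level, parent_mz = parent,
      ions = tibble::tibble(
        mz = mzv,
        intensity = ifelse(is_base, base_intensity, other_intensity),
        is_base = is_base
      )
    )
    last_base[[as.character(level)]] <- mzv[is_base]
  }
  spectrum_tree(precursor_mz, polarity, scans, resolution = resolution)
}

#' All parent-to-product neutral losses in a tree
#'
#' @param tree A `spectrum_tree`.
#' @return A tibble with one row per product ion: `level`, `parent_mz`,
#'   `product_mz`, `loss`, `is_base`.
#' @export
extract_losses <- function(tree) {
  stopifnot(inherits(tree, "spectrum_tree"))
  purrr::map_dfr(tree$scans, function(s) {
    tibble::tibble(level = s$level, parent_mz = s$parent_mz,
                   product_mz = s$ions$mz, loss = s$parent_mz - s$ions$mz,
                   is_base = s$ions$is_base)
  })
}

#' All product ions observed anywhere in a tree
#' @param tree A `spectrum_tree`.
#' @return Numeric vector of product m/z values.
#' @export
tree_ions <- function(tree) {
  unlist(lapply(tree$scans, function(s) s$ions$mz))
}

#' Spectrum trees for the bundled compound library
#'
#' Decodes every library row's fragmentation pathway into a `spectrum_tree`
#' (in the polarity of the row's ion type, with the printed measured m/z as
#' precursor).
#'
#' @param library Compound library tibble.
#' @return Named list of `spectrum_tree` objects (names = compound ids).
#' @export
library_spectra <- function(library = load_compound_library()) {
  out <- lapply(seq_len(nrow(library)), function(i) {
    parse_frag_pathway(library$frag[i], library$measured_mz[i],
                       polarity = library$polarity[i], resolution = "high")
  })
  names(out) <- as.character(library$compound_id)
  out
}

#' Read a spectrum tree from JSON
#'
#' The JSON dialect mirrors the `spectrum_tree` structure: fields
#' `precursor_mz`, `polarity`, `resolution`, and `scans` (each with `level`,
#' `parent_mz`, and `ions` records of `mz`/`intensity`).
#'
#' @param path JSON file path.
#' @return A `spectrum_tree`.
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scans <- x$scans
  if (is.data.frame(scans)) scans <- split(scans, seq_len(nrow(scans)))
  scans <- lapply(seq_along(x$scans$level %||% scans), function(i) {
    if (is.data.frame(x$scans)) {
      list(level = x$scans$level[i], parent_mz = x$scans$parent_mz[i],
           ions = x$scans$ions[[i]])
    } else {
      x$scans[[i]]
    }
  })
  spectrum_tree(x$precursor_mz, x$polarity, scans,
                resolution = x$resolution %||% "high")
}

#' Write a spectrum tree to JSON
#'
#' @param tree A `spectrum_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_json <- function(tree, path) {
  jsonlite::write_json(
    list(precursor_mz = tree$precursor_mz, polarity = tree$polarity,
         resolution = tree$resolution,
         scans = lapply(tree$scans, function(s) {
           list(level = s$level, parent_mz = s$parent_mz,
                ions = s$ions[, c("mz", "intensity", "is_base")])
         })),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' Minimal MGF support: each `BEGIN IONS` block becomes a single-scan
#' (MS2-only) `spectrum_tree`; deeper MSn levels require the JSON dialect.
#'
#' @param path MGF file path.
#' @return A list of `spectrum_tree` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      pep <- NA_real_
      charge_sign <- "negative"
      ions <- list()
      i <- i + 1
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^PEPMASS=", ln)) {
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", ln)) {
          charge_sign <- if (grepl("-", ln)) "negative" else "positive"
        } else if (grepl("^[0-9]", ln)) {
          v <- as.numeric(strsplit(ln, "\\s+")[[1]])
          ions[[length(ions) + 1]] <- v[1:2]
        }
        i <- i + 1
      }
      im <- do.call(rbind, ions)
      scans <- if (!is.null(im)) {
        list(list(level = 2L, parent_mz = pep,
                  ions = tibble::tibble(mz = im[, 1], intensity = im[, 2])))
      } else list()
      out[[length(out) + 1]] <- spectrum_tree(pep, charge_sign, scans,
                                              resolution = "high")
    }
    i <- i + 1
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
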