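# Exact-mass arithmetic over elemental formulas.
#
# All masses are monoisotopic (most abundant isotope, IUPAC values); ion m/z
# uses the proton mass (i.e. the electron mass is accounted for), which is
# what reconciles the bundled library's printed ppm errors.

#' Monoisotopic masses of the supported elements (Da)
#'
#' Most-abundant-isotope masses for the elements occurring in
#' phenylpropanoid/flavonoid chemistry. Carbon-12 is exact by definition.
#'
#' @format Named numeric vector.
#' @export
ELEMENT_MASSES <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Mass of a proton (Da)
#'
#' Used for `[M+H]+` / `[M-H]-` ion m/z: adding a proton (not a hydrogen
#' atom) folds the electron-mass correction into a single constant.
#'
#' @export
PROTON_MASS <- 1.00727646677

#' Parse an elemental formula string
#'
#' Accepts Hill-style strings such as `"C17H20O9"` or `"H2O"`: element
#' symbols (C, H, N, O, S, P) each followed by an optional positive count.
#'
#' @param text A single formula string.
#' @return An `elemental_formula`: a named integer vector of element counts.
#' @examples
#' parse_formula("C17H20O9")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  bad <- setdiff(syms, names(ELEMENT_MASSES))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " in '", text, "'", call. = FALSE)
  }
  counts <- stats::setNames(rep(0L, length(ELEMENT_MASSES)), names(ELEMENT_MASSES))
  for (i in seq_along(syms)) counts[syms[i]] <- counts[syms[i]] + cnts[i]
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("formula has no atoms: '", text, "'", call. = FALSE)
  structure(counts, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  # Hill order: C, H, then the rest alphabetically
  counts <- unclass(x)
  ord <- c(
    intersect(c("C", "H"), names(counts)),
    sort(setdiff(names(counts), c("C", "H")))
  )
  paste0(vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", round(monoisotopic_mass(x), 5), " Da)\n",
      sep = "")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' @param f An `elemental_formula` or formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C6H10O5") # dehydrated hexose, 162.05282
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(ELEMENT_MASSES[names(f)] * as.numeric(unclass(f)))
}

#' Ion m/z for a protonated or deprotonated molecule
#'
#' `[M+H]+` adds, and `[M-H]-` subtracts, one proton mass from the neutral
#' monoisotopic mass. These are the only two ion species observed in the
#' bundled reference library.
#'
#' @param f An `elemental_formula` or formula string.
#' @param ion `"[M+H]+"` or `"[M-H]-"`.
#' @return Ion m/z in Da.
#' @examples
#' ion_mz("C9H8O4", "[M-H]-") # caffeic acid, 179.03498
#' @export
ion_mz <- function(f, ion = c("[M+H]+", "[M-H]-")) {
  f <- as_formula(f)
  ion <- normalise_ion(ion[1])
  m <- monoisotopic_mass(f)
  if (ion == "[M+H]+") {
    m + PROTON_MASS
  } else {
    if (is.na(f["H"]) || f[["H"]] < 1L) {
      stop("[M-H]- requested on a hydrogen-free formula: ", format(f),
           call. = FALSE)
    }
    m - PROTON_MASS
  }
}

# Accept the unicode minus and superscript variants seen in printed tables.
normalise_ion <- function(ion) {
  x <- gsub("[−–]", "-", ion)
  x <- gsub("[\\^\\s]", "", x)
  if (x %in% c("[M+H]+", "[M+H]")) return("[M+H]+")
  if (x %in% c("[M-H]-", "[M-H]")) return("[M-H]-")
  stop("unsupported ion species: '", ion, "'", call. = FALSE)
}

#' Polarity of an ion species
#' @param ion Ion species string.
#' @return `"positive"` or `"negative"`.
#' @export
ion_polarity <- function(ion) {
  if (normalise_ion(ion) == "[M+H]+") "positive" else "negative"
}

#' Signed mass error in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`, the convention that
#' reproduces the bundled library's printed ppm errors.
#'
#' @param measured,theoretical Masses in Da; `theoretical` must be > 0.
#' @return Signed ppm error (vectorised).
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  (measured - theoretical) / theoretical * 1e6
}

#' Match an observed m/z against candidate library ions
#'
#' Returns every candidate within `tol_ppm` of the observed value, closest
#' first; ties are broken by candidate name.
#'
#' @param observed Observed m/z (Da).
#' @param candidates A data frame with at least columns `name` and
#'   `theoretical_mz` (e.g. a compound library from [load_compound_library()],
#'   which provides `theoretical_mz`).
#' @param tol_ppm Match tolerance in ppm (default 5, the identification
#'   tolerance used throughout the package).
#' @return A tibble of matches with `delta_ppm` and `abs_ppm` columns.
#' @export
match_mz <- function(observed, candidates, tol_ppm = 5) {
  stopifnot(is.numeric(observed), length(observed) == 1)
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) {
    stop("tol_ppm must be > 0", call. = FALSE)
  }
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(tibble::tibble(name = character(), theoretical_mz = numeric(),
                          delta_ppm = numeric(), abs_ppm = numeric()))
  }
  candidates |>
    dplyr::mutate(
      delta_ppm = ppm_error(observed, .data$theoretical_mz),
      abs_ppm = abs(.data$delta_ppm)
    ) |>
    dplyr::filter(.data$abs_ppm <= tol_ppm) |>
    dplyr::arrange(.data$abs_ppm, .data$name)
}

#' Diagnostic neutral-loss dictionary
#'
#' The curated neutral losses used by the fragmentation rule engine:
#' dehydrated sugars, water, CO2, the threonate and acyl moieties, polyamines,
#' and the retro-Diels-Alder / heterocyclic-ring-fission losses of
#' flavan-3-ols. Exact masses are derived from the stored formulas; nominal
#' masses are their integer rounding (used by the low-resolution rule layer).
#'
#' @return A tibble with columns `name`, `formula`, `exact_mass`,
#'   `nominal_mass`, `context`.
#' @export
neutral_losses <- function() {
  path <- system.file("extdata", "neutral_losses.tsv", package = "brachymet")
  nl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  nl$exact_mass <- unname(vapply(nl$formula, monoisotopic_mass, numeric(1)))
  nl$nominal_mass <- as.integer(round(nl$exact_mass))
  if (anyDuplicated(nl$name)) stop("duplicate neutral-loss names")
  nl
}
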