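# Bundled reference resources: the 93-compound library and the miniature
# pathway graph.

#' Load the bundled Brachypodium compound library
#'
#' Reads the 93 specialized metabolites identified in Brachypodium leaves,
#' roots and spikes, recomputes each ion's theoretical m/z from its elemental
#' formula, and compares the recomputed ppm error against the printed one.
#' Rows whose printed values cannot be reconciled with their own formula
#' (beyond `flag_tol_ppm`) are flagged `printed-inconsistency`; the printed
#' numbers are carried as-is, never corrected.
#'
#' @param flag_tol_ppm Tolerance (ppm) for the printed-vs-recomputed
#'   consistency check (default 0.05).
#' @return A tibble with one row per compound: identity, ion type, printed
#'   masses, recomputed `theoretical_mz` and `recomputed_delta_ppm`,
#'   `consistency_flag`, structural `compound_class`, MSI level, `std` flag,
#'   detected organs, and the encoded MSn fragmentation pathway (`frag`).
#' @export
load_compound_library <- function(flag_tol_ppm = 0.05) {
  path <- system.file("extdata", "compound_library.tsv", package = "brachymet")
  lib <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         quote = "",
                         col_types = readr::cols(
                           measured_mz = readr::col_character(),
                           printed_delta_ppm = readr::col_character()))
  decimals <- function(x) {
    ifelse(grepl("\\.", x), nchar(sub("^[^.]*\\.", "", x)), 0L)
  }
  dec_mz <- decimals(lib$measured_mz)
  dec_ppm <- decimals(lib$printed_delta_ppm)
  lib$measured_mz <- as.numeric(lib$measured_mz)
  lib$printed_delta_ppm <- as.numeric(lib$printed_delta_ppm)
  lib$theoretical_mz <- vapply(seq_len(nrow(lib)), function(i) {
    f <- lib$formula[i]
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    ion_mz(f, lib$ion_type[i])
  }, numeric(1))
  lib$recomputed_delta_ppm <- ifelse(
    is.na(lib$theoretical_mz), NA_real_,
    ppm_error(lib$measured_mz, ifelse(is.na(lib$theoretical_mz), 1,
                                      lib$theoretical_mz))
  )
  # the printed measured mass and ppm error are rounded; allow for exactly
  # that rounding on top of the agreement band before flagging a row
  rounding_ppm <- 0.5 * 10^(-dec_mz) / lib$measured_mz * 1e6 +
    0.5 * 10^(-dec_ppm)
  lib$consistency_flag <- ifelse(
    !is.na(lib$recomputed_delta_ppm) &
      abs(lib$recomputed_delta_ppm - lib$printed_delta_ppm) <=
        flag_tol_ppm + rounding_ppm,
    "ok", "printed-inconsistency"
  )
  lib$polarity <- vapply(lib$ion_type, ion_polarity, character(1))
  lib$name <- as.character(lib$name)
  lib
}

#' Load the bundled miniature pathway graph
#'
#' A synthetic pathway resource over the bundled compound library using the
#' twelve pathway names reported as enriched in Brachypodium. Returned as a
#' `pathway_graph`: a membership table plus one undirected igraph per pathway
#' (substrate/product adjacency), used for enrichment and impact scoring.
#'
#' @return An object of class `pathway_graph` with elements `membership`
#'   (tibble: pathway, compound_id, neighbors) and `graphs` (named list of
#'   igraph objects).
#' @export
load_pathway_graph <- function() {
  path <- system.file("extdata", "pathways.tsv", package = "brachymet")
  mem <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         quote = "")
  mem$compound_id <- as.character(mem$compound_id)
  graphs <- lapply(split(mem, mem$pathway), function(d) {
    edges <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
      nbs <- strsplit(d$neighbors[i], ";", fixed = TRUE)[[1]]
      nbs <- nbs[nzchar(nbs)]
      if (length(nbs) == 0) return(NULL)
      cbind(d$compound_id[i], nbs)
    }))
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(unique(d$compound_id))
    if (!is.null(edges)) {
      # de-duplicate undirected pairs
      key <- apply(edges, 1, function(r) paste(sort(r), collapse = "--"))
      edges <- edges[!duplicated(key), , drop = FALSE]
      g <- igraph::add_edges(g, t(edges))
    }
    g
  })
  if (any(vapply(graphs, igraph::vcount, numeric(1)) == 0)) {
    stop("pathway graph contains an empty pathway", call. = FALSE)
  }
  structure(list(membership = mem[, c("pathway", "compound_id")],
                 graphs = graphs),
            class = "pathway_graph")
}

#' Build a pathway graph from membership and edge tables
#'
#' @param membership Data frame with columns `pathway`, `compound_id`.
#' @param edges Optional data frame with columns `pathway`, `from`, `to`
#'   (within-pathway substrate/product links); omitted pathways get no edges.
#' @return A `pathway_graph`.
#' @export
pathway_graph <- function(membership, edges = NULL) {
  membership <- tibble::as_tibble(membership)
  stopifnot(all(c("pathway", "compound_id") %in% names(membership)))
  membership$compound_id <- as.character(membership$compound_id)
  if (any(!nzchar(membership$pathway))) stop("empty pathway name")
  graphs <- lapply(split(membership, membership$pathway), function(d) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(unique(d$compound_id))
    if (!is.null(edges)) {
      e <- edges[edges$pathway == d$pathway[1], , drop = FALSE]
      if (nrow(e)) {
        g <- igraph::add_edges(g, rbind(as.character(e$from),
                                        as.character(e$to)))
      }
    }
    g
  })
  structure(list(membership = membership[, c("pathway", "compound_id")],
                 graphs = graphs),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  sizes <- vapply(x$graphs, igraph::vcount, numeric(1))
  cat("<pathway_graph> ", length(x$graphs), " pathways over ",
      length(unique(x$membership$compound_id)), " compounds\n", sep = "")
  for (p in names(sizes)) cat("  ", p, " (", sizes[[p]], ")\n", sep = "")
  invisible(x)
}

#' Export the compound library as a minimal mzTab-M-like small-molecule table
#'
#' Writes an "SML"-style minimal section (identifier, name, adduct, exact
#' mass) for interoperability with mzTab-M consumers.
#'
#' @param library Compound library tibble (default: the bundled one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mztab_sml <- function(library = load_compound_library(), path) {
  rows <- c(
    "SMH\tSML_ID\tchemical_name\tchemical_formula\tadduct_ions\ttheoretical_neutral_mass\texp_mass_to_charge",
    vapply(seq_len(nrow(library)), function(i) {
      f <- library$formula[i]
      m <- if (is.na(f) || !nzchar(f)) NA_real_ else monoisotopic_mass(f)
      paste("SML", library$compound_id[i], library$name[i],
            ifelse(is.na(f), "null", f), library$ion_type[i],
            ifelse(is.na(m), "null", sprintf("%.5f", m)),
            sprintf("%.5f", library$measured_mz[i]), sep = "\t")
    }, character(1))
  )
  writeLines(rows, path)
  invisible(path)
}
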