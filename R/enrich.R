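# m/z annotation against the compound library and mummichog-style pathway
# enrichment: hypergeometric over-representation per pathway, a seeded
# permutation null alongside, BH-FDR across pathways, and a
# betweenness-centrality pathway impact normalised to a maximum of 1.

#' Annotate an m/z list against a compound library
#'
#' Each query is matched against library entries of the same ionization
#' polarity within `tol_ppm` of the theoretical ion m/z (falling back to the
#' printed measured m/z for entries without a formula).
#'
#' @param mzs A data frame with columns `mz` and `polarity` (and optionally
#'   `feature_id`).
#' @param db Compound library tibble (default: bundled).
#' @param tol_ppm Annotation tolerance in ppm (default 5).
#' @return A tibble of annotations: query columns plus `compound_id`, `name`,
#'   `delta_ppm`. A compound can match many queries; deduplicate by
#'   `compound_id` before enrichment.
#' @export
annotate_mz_list <- function(mzs, db = load_compound_library(), tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  mzs <- tibble::as_tibble(mzs)
  stopifnot(all(c("mz", "polarity") %in% names(mzs)))
  if (!"feature_id" %in% names(mzs)) {
    mzs$feature_id <- sprintf("q%04d", seq_len(nrow(mzs)))
  }
  ref_mz <- ifelse(is.na(db$theoretical_mz), db$measured_mz,
                   db$theoretical_mz)
  hits <- purrr::map_dfr(seq_len(nrow(mzs)), function(i) {
    same_pol <- db$polarity == mzs$polarity[i]
    dppm <- (mzs$mz[i] - ref_mz) / ref_mz * 1e6
    ok <- same_pol & abs(dppm) <= tol_ppm
    if (!any(ok)) return(NULL)
    tibble::tibble(
      feature_id = mzs$feature_id[i], mz = mzs$mz[i],
      polarity = mzs$polarity[i],
      compound_id = as.character(db$compound_id[ok]),
      name = db$name[ok], delta_ppm = dppm[ok]
    )
  })
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(feature_id = character(), mz = numeric(),
                           polarity = character(), compound_id = character(),
                           name = character(), delta_ppm = numeric())
  }
  hits |> dplyr::arrange(.data$feature_id, abs(.data$delta_ppm))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (via [stats::p.adjust()]), order-preserving on the
#' input indexing, with input validation.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pathway impact from betweenness centrality
#'
#' For each pathway, impact is the summed betweenness centrality of the hit
#' compounds divided by the summed betweenness of all pathway compounds
#' (0 when the denominator is 0, 1 when every node is hit and the
#' denominator is positive).
#'
#' @param graph A `pathway_graph`.
#' @param hit_compounds Character vector of hit compound ids.
#' @return A tibble: `pathway`, `impact` in `[0, 1]`.
#' @export
pathway_impact <- function(graph, hit_compounds) {
  stopifnot(inherits(graph, "pathway_graph"))
  hit_compounds <- as.character(hit_compounds)
  purrr::map_dfr(names(graph$graphs), function(p) {
    g <- graph$graphs[[p]]
    btw <- igraph::betweenness(g, directed = FALSE)
    denom <- sum(btw)
    hits <- intersect(igraph::V(g)$name, hit_compounds)
    num <- sum(btw[hits])
    impact <- if (denom > 0) num / denom
      else if (length(hits) == igraph::vcount(g) && length(hits) > 0) 1
      else 0
    tibble::tibble(pathway = p, impact = impact)
  })
}

#' Mummichog-style pathway over-representation
#'
#' Per pathway, the hypergeometric upper-tail probability of observing at
#' least the seen number of significant compounds, given the pathway size
#' and the annotated reference universe; a seeded permutation p-value
#' (resampling significant-set-sized draws from the reference) is computed
#' alongside; BH-FDR is applied across pathways on the hypergeometric p;
#' pathway impact comes from [pathway_impact()].
#'
#' @param significant Character vector of significant compound ids (must be
#'   a subset of `reference`).
#' @param reference Character vector: the annotated universe of compound ids.
#' @param graph A `pathway_graph` (default: bundled).
#' @param n_perm Number of permutations (default 2000; 0 disables).
#' @param seed Seed for the permutation null.
#' @param fdr_max,impact_min Reporting thresholds used by the `selected`
#'   flag (defaults 0.03 and 0.3).
#' @return An `enrichment` tibble: pathway, total, hits, p_raw, p_perm, fdr,
#'   impact, selected.
#' @export
enrich_pathways <- function(significant, reference,
                            graph = load_pathway_graph(),
                            n_perm = 2000, seed = 1,
                            fdr_max = 0.03, impact_min = 0.3) {
  significant <- unique(as.character(significant))
  reference <- unique(as.character(reference))
  extra <- setdiff(significant, reference)
  if (length(extra)) {
    stop("significant compounds missing from the reference universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  mem <- graph$membership
  mem <- mem[mem$compound_id %in% reference, ]
  sizes <- table(mem$pathway)
  pathways <- names(graph$graphs)

  n_ref <- length(reference)
  n_sig <- length(significant)
  rows <- purrr::map_dfr(pathways, function(p) {
    members <- mem$compound_id[mem$pathway == p]
    total <- length(members)
    hits <- length(intersect(members, significant))
    p_raw <- if (hits == 0) 1 else {
      stats::phyper(hits - 1, total, n_ref - total, n_sig,
                    lower.tail = FALSE)
    }
    tibble::tibble(pathway = p, total = total, hits = hits, p_raw = p_raw)
  })

  if (n_perm > 0 && n_sig > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    set.seed(seed)
    member_sets <- lapply(rows$pathway, function(p) {
      mem$compound_id[mem$pathway == p]
    })
    exceed <- integer(nrow(rows))
    for (b in seq_len(n_perm)) {
      draw <- sample(reference, n_sig)
      perm_hits <- vapply(member_sets, function(m) {
        length(intersect(m, draw))
      }, integer(1))
      exceed <- exceed + as.integer(perm_hits >= rows$hits)
    }
    rows$p_perm <- (exceed + 1) / (n_perm + 1)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  } else {
    rows$p_perm <- NA_real_
  }

  rows$fdr <- bh_fdr(rows$p_raw)
  rows <- dplyr::left_join(rows, pathway_impact(graph, significant),
                           by = "pathway")
  rows$selected <- rows$fdr < fdr_max & rows$impact > impact_min
  rows <- dplyr::arrange(rows, .data$fdr, .data$p_raw, .data$pathway)
  class(rows) <- c("enrichment", class(rows))
  rows
}
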