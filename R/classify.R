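# Diagnostic rule engine for MSn fragmentation trees: hydroxycinnamoyl-
# quinate regiochemistry, hydroxycinnamate-threonate esters, hydroxycinnamic
# acid amides, flavonoid O-/C-/O,C-/di-C-glycosides, and proanthocyanidins.
# Rules are independent pattern matchers over the tree's product ions and
# neutral losses; class assignment comes only from diagnostic-confidence
# matches, so supporting evidence can never override a diagnostic call.

# product-ion / neutral-loss matching at the ion-trap (nominal) layer
ION_TOL <- 0.5
# precursor gates: ion-trap layer vs high-resolution layer
GATE_LOW <- 0.35
GATE_HIGH <- 0.01
# aglycone + sugar mass-decomposition tolerance (high-resolution precursor)
DECOMP_TOL <- 0.05

has_ion <- function(ions, target, tol = ION_TOL) {
  any(abs(ions - target) < tol)
}
has_loss <- function(losses, target, tol = ION_TOL) {
  any(abs(losses - target) < tol)
}

rule_match <- function(rule_id, class_assigned, evidence, confidence,
                       tags = character()) {
  structure(list(rule_id = rule_id, class_assigned = class_assigned,
                 evidence = evidence, confidence = confidence, tags = tags),
            class = "rule_match")
}

#' @export
print.rule_match <- function(x, ...) {
  cat("<rule_match> ", x$rule_id, " -> ", x$class_assigned,
      " (", x$confidence, ")\n", sep = "")
  if (length(x$tags)) cat("  tags: ", paste(x$tags, collapse = "; "), "\n")
  cat("  evidence: ", paste(x$evidence, collapse = "; "), "\n", sep = "")
  invisible(x)
}

# neutral monoisotopic building blocks, computed lazily on first use
.bm_cache <- new.env(parent = emptyenv())
bm_masses <- function() {
  if (!is.null(.bm_cache$m)) return(.bm_cache$m)
  f <- function(s) monoisotopic_mass(parse_formula(s))
  .bm_cache$m <- list(
    caffeic = f("C9H8O4"), coumaric = f("C9H8O3"), ferulic = f("C10H10O4"),
    quinate_conj = c(caffeoyl = f("C16H18O9"), coumaroyl = f("C16H18O8"),
                     feruloyl = f("C17H20O9")),
    threonate_conj = c(caffeoyl = f("C13H14O8"), coumaroyl = f("C13H14O7"),
                       feruloyl = f("C14H16O8")),
    acid_anion_nominal = c(caffeoyl = 179, coumaroyl = 163, feruloyl = 193),
    amide = c("coumaroyl-putrescine" = f("C13H18N2O2"),
              "caffeoyl-putrescine" = f("C13H18N2O3"),
              "feruloyl-putrescine" = f("C14H20N2O3"),
              "coumaroyl-agmatine" = f("C14H20N4O2"),
              "caffeoyl-agmatine" = f("C14H20N4O3"),
              "feruloyl-agmatine" = f("C15H22N4O3"),
              "coumaroyl-spermidine" = f("C16H25N3O2"),
              "feruloyl-spermidine" = f("C17H27N3O3")),
    aglycone = c(apigenin = f("C15H10O5"), luteolin = f("C15H10O6"),
                 chrysoeriol = f("C16H12O6"), tricin = f("C17H14O7"),
                 quercetin = f("C15H10O7"), isorhamnetin = f("C16H12O7")),
    sugar = c(hexose = f("C6H10O5"), deoxyhexose = f("C6H10O4"),
              pentose = f("C5H8O4")),
    acyl = c(sinapoyl = f("C11H10O4"), malonyl = f("C3H2O3"),
             glucuronyl = f("C6H8O6")),
    flavanol = c(catechin = f("C15H14O6"), gallocatechin = f("C15H14O7")),
    galloyl = f("C7H4O4"), hydroxybenzoyl = f("C7H4O2"),
    H2 = 2 * 1.00782503207
  )
  .bm_cache$m
}

neutral_mass_of <- function(tree) {
  if (tree$polarity == "negative") tree$precursor_mz + PROTON_MASS
  else tree$precursor_mz - PROTON_MASS
}

base_ms2_ion <- function(tree) {
  ms2 <- Filter(function(s) s$level == 2L, tree$scans)
  if (length(ms2) == 0) return(NA_real_)
  ions <- ms2[[1]]$ions
  ions$mz[which(ions$is_base)[1]]
}

#' Classify hydroxycinnamoyl-quinic acid regiochemistry
#'
#' Negative mode; precursor gated on the caffeoyl-, coumaroyl- and
#' feruloyl-quinate masses. A base MS2 peak at nominal 173 (quinate) is
#' diagnostic for the 4-acyl isomer; a base peak at the hydroxycinnamate
#' anion (179/163/193) for the 5-acyl isomer; anything else is an
#' unassigned HQA (supporting confidence only).
#'
#' @param tree A `spectrum_tree`.
#' @return A `rule_match` or `NULL`.
#' @export
classify_hqa <- function(tree) {
  if (tree$polarity != "negative") return(NULL)
  target <- bm_masses()$quinate_conj - PROTON_MASS
  d <- abs(tree$precursor_mz - target)
  if (min(d) >= GATE_LOW) return(NULL)
  acyl <- names(target)[which.min(d)]
  base <- base_ms2_ion(tree)
  if (is.na(base)) return(NULL)
  acid_anion <- bm_masses()$acid_anion_nominal[[acyl]]
  if (abs(base - 173) < ION_TOL) {
    rule_match("hqa-4-acyl", "hydroxycinnamate-quinate",
               sprintf("base MS2 ion %s ~ quinate 173", base), "diagnostic",
               tags = paste0("4-", acyl, "quinic acid"))
  } else if (abs(base - acid_anion) < ION_TOL) {
    rule_match("hqa-5-acyl", "hydroxycinnamate-quinate",
               sprintf("base MS2 ion %s ~ %s anion %s", base, acyl,
                       acid_anion), "diagnostic",
               tags = paste0("5-", acyl, "quinic acid"))
  } else {
    rule_match("hqa-unassigned", "hydroxycinnamate-quinate",
               sprintf("precursor in HQA window but base ion %s not 173/%s",
                       base, acid_anion), "supporting",
               tags = "unassigned-HQA")
  }
}

#' Classify hydroxycinnamate-threonate esters
#'
#' Negative mode, precursor gated tightly (high-resolution layer) on the
#' caffeoyl/coumaroyl/feruloyl-threonate masses. Diagnostic evidence is the
#' threonate neutral loss (~118.027, threonic acid minus water) and/or the
#' complementary hydroxycinnamate anion; the decarboxylated acyl ions are
#' supporting.
#'
#' @param tree A `spectrum_tree`.
#' @return A `rule_match` or `NULL`.
#' @export
classify_threonate_ester <- function(tree) {
  if (tree$polarity != "negative") return(NULL)
  target <- bm_masses()$threonate_conj - PROTON_MASS
  d <- abs(tree$precursor_mz - target)
  if (min(d) >= GATE_HIGH) return(NULL)
  acyl <- names(target)[which.min(d)]
  losses <- extract_losses(tree)$loss
  ions <- tree_ions(tree)
  ev <- character()
  threonate_loss <- monoisotopic_mass("C4H6O4")
  if (has_loss(losses, threonate_loss)) {
    ev <- c(ev, sprintf("neutral loss ~%.3f (threonate - H2O)",
                        threonate_loss))
  }
  acid_anion <- bm_masses()$acid_anion_nominal[[acyl]]
  if (has_ion(ions, acid_anion)) {
    ev <- c(ev, sprintf("complementary %s anion %s", acyl, acid_anion))
  }
  if (length(ev) == 0) return(NULL)
  supp <- c(caffeoyl = 135, coumaroyl = 119, feruloyl = 149)[[acyl]]
  if (has_ion(ions, supp)) {
    ev <- c(ev, sprintf("[acyl-CO2]- ion %s (supporting)", supp))
  }
  rule_match("threonate-ester", "hydroxycinnamate-threonate", ev,
             "diagnostic", tags = paste0(acyl, "threonic acid"))
}

#' Classify hydroxycinnamic acid amides
#'
#' Positive mode; precursor gated on hydroxycinnamoyl conjugates of
#' putrescine, agmatine and spermidine. Diagnostic: the polyamine neutral
#' loss (88/130/145) or its protonated counter-ion (89/131/146); the acyl
#' identity comes from the acylium-type product ions (147 coumaroyl,
#' 163 caffeoyl, 177 feruloyl) or the precursor gate.
#'
#' @param tree A `spectrum_tree`.
#' @return A `rule_match` or `NULL`.
#' @export
classify_amide <- function(tree) {
  if (tree$polarity != "positive") return(NULL)
  target <- bm_masses()$amide + PROTON_MASS
  d <- abs(tree$precursor_mz - target)
  if (min(d) >= GATE_LOW) return(NULL)
  conj <- names(target)[which.min(d)]
  losses <- extract_losses(tree)$loss
  ions <- tree_ions(tree)
  amines <- list(putrescine = c(loss = 88, ion = 89),
                 agmatine = c(loss = 130, ion = 131),
                 spermidine = c(loss = 145, ion = 146))
  ev <- character()
  amine_seen <- character()
  for (a in names(amines)) {
    hit_loss <- has_loss(losses, amines[[a]][["loss"]])
    hit_ion <- has_ion(ions, amines[[a]][["ion"]])
    if (hit_loss || hit_ion) {
      amine_seen <- c(amine_seen, a)
      ev <- c(ev, sprintf("%s evidence (%s)", a,
                          paste(c(if (hit_loss) "neutral loss",
                                  if (hit_ion) "protonated amine ion"),
                                collapse = " + ")))
    }
  }
  if (length(ev) == 0) return(NULL)
  acyl_ions <- c(coumaroyl = 147, caffeoyl = 163, feruloyl = 177)
  acyl_seen <- names(acyl_ions)[vapply(acyl_ions, function(m) {
    has_ion(ions, m)
  }, logical(1))]
  if (length(acyl_seen)) {
    ev <- c(ev, sprintf("acyl ion(s): %s", paste(acyl_seen, collapse = ", ")))
  }
  rule_match("hydroxycinnamic-amide", "amide", ev, "diagnostic", tags = conj)
}

# enumerate aglycone + sugar (+ optional acyl) decompositions of a neutral
# mass at the ion-trap layer; at most 3 sugars and 1 acyl
decompose_glycoside <- function(neutral, tol = DECOMP_TOL) {
  sug <- bm_masses()$sugar
  acyl <- c(none = 0, bm_masses()$acyl)
  out <- list()
  for (ag in names(bm_masses()$aglycone)) {
    rest0 <- neutral - bm_masses()$aglycone[[ag]]
    if (rest0 < -tol) next
    for (nh in 0:3) for (nd in 0:3) for (np in 0:3) {
      if (nh + nd + np > 3) next
      for (ac in names(acyl)) {
        tot <- nh * sug[["hexose"]] + nd * sug[["deoxyhexose"]] +
          np * sug[["pentose"]] + acyl[[ac]]
        if (abs(rest0 - tot) < tol) {
          out[[length(out) + 1]] <- list(
            aglycone = ag, n_hexose = nh, n_deoxyhexose = nd,
            n_pentose = np, acyl = ac, n_sugars = nh + nd + np,
            err = abs(rest0 - tot)
          )
        }
      }
    }
  }
  out
}

#' Classify flavonoid glycosides from MSn evidence
#'
#' Infers the aglycone (apigenin, luteolin, chrysoeriol, tricin, quercetin,
#' isorhamnetin) by mass decomposition of the precursor into aglycone +
#' sugars (+ optional acyl) combined with aglycone-diagnostic product ions,
#' then assigns one of the O-, C-, O,C- or di-C-glycoside classes:
#'
#' * di-C: `[Agly+84-H]-` / `[Agly+114-H]-` ions;
#' * C (cross-ring): `[Agly+42-H]-` / `[Agly+72-H]-`;
#' * 2''-O-glycosylation of a C-sugar: `[Agly+24-H]-` / `[Agly+54-H]-`;
#' * O-glycosylation: clean neutral loss of a dehydrated sugar (162/146/132)
#'   and/or the bare aglycone ion.
#'
#' A bare aglycone ion means every sugar detached, i.e. all-O linkage,
#' unless di-C or 2''-O ions show a retained C-sugar; conversely C-type
#' ions without the bare aglycone plus a clean sugar loss indicate a mixed
#' O,C-glycoside. For monoglycosides, where the cross-ring ions of an
#' O-sugar coincide with the C-type ions, the base peak decides. Sugar
#' identity beyond hexose/deoxyhexose/pentose is not determinable by MS.
#'
#' @param tree A `spectrum_tree`.
#' @return A `rule_match` or `NULL`.
#' @export
classify_flavonoid_glycoside <- function(tree) {
  neutral <- neutral_mass_of(tree)
  decs <- decompose_glycoside(neutral)
  if (length(decs) == 0) return(NULL)
  ions <- tree_ions(tree)
  losses_tbl <- extract_losses(tree)
  losses <- losses_tbl$loss
  neg <- tree$polarity == "negative"

  score_one <- function(dec) {
    ag_nom <- round(bm_masses()$aglycone[[dec$aglycone]])
    D <- if (neg) ag_nom - 1 else ag_nom + 1
    pres <- function(off) has_ion(ions, D + off)
    multi <- dec$n_sugars >= 2 # di-C and 2''-O need two sugars
    ev <- list(
      bare = pres(0),
      c42 = neg && pres(42), c72 = neg && pres(72),
      o2_24 = neg && multi && pres(24), o2_54 = neg && multi && pres(54),
      dic84 = neg && multi && pres(84), dic114 = neg && multi && pres(114)
    )
    # an intact di-C ion pair explains the spectrum; a lone 2''-O ion under
    # the same hypothesis is then a nominal coincidence, not evidence
    if (ev$dic84 && ev$dic114) {
      ev$o2_24 <- FALSE
      ev$o2_54 <- FALSE
    }
    ev
  }
  scored <- lapply(decs, function(dec) {
    ev <- score_one(dec)
    n_ev <- sum(unlist(ev))
    c(dec, list(ev = ev, n_ev = n_ev))
  })
  n_best <- max(vapply(scored, function(s) s$n_ev, numeric(1)))
  if (n_best == 0) return(NULL)
  cand <- scored[vapply(scored, function(s) s$n_ev == n_best, logical(1))]
  # isobaric aglycone hypotheses (e.g. luteolin+hexose vs isorhamnetin+
  # pentose) tie on mass; break by decomposition error, then by a fixed
  # commonness order over the aglycones
  pref <- match(vapply(cand, function(s) s$aglycone, character(1)),
                names(bm_masses()$aglycone))
  errs <- round(vapply(cand, function(s) s$err, numeric(1)), 4)
  cand <- cand[order(errs, pref)]
  best <- cand[[1]]
  if (best$n_sugars == 0) return(NULL) # aglycone-only mass, not a glycoside
  ev <- best$ev

  # a clean O-sugar detachment is read from the first fragmentation step
  # (precursor -> MS2); deeper-level mass differences can mimic a nominal
  # sugar loss through composite cross-ring cleavages
  prec_step <- losses_tbl$loss[losses_tbl$level == 2]
  sugar_losses <- c(hexose = 162, deoxyhexose = 146, pentose = 132)
  o_loss_seen <- names(sugar_losses)[vapply(sugar_losses, function(l) {
    has_loss(prec_step, l)
  }, logical(1))]
  has_o_loss <- length(o_loss_seen) > 0
  di_c <- ev$dic84 || ev$dic114
  two_o <- ev$o2_24 || ev$o2_54
  c_ion <- ev$c42 || ev$c72

  tags <- character()
  if (has_loss(losses, 308)) tags <- c(tags, "O-hexosyldeoxyhexoside")
  if (!neg && has_loss(losses, 164)) {
    tags <- c(tags, "deoxyhexosyl(1->2) interglycosidic bond")
  } else if (!neg && has_loss(losses, 308) &&
             has_loss(losses, 162) && has_loss(losses, 146)) {
    tags <- c(tags, "deoxyhexosyl(1->6) interglycosidic bond")
  }
  prec_losses <- losses_tbl$loss[losses_tbl$level == 2]
  if (neg && has_loss(prec_losses, 90) && has_loss(prec_losses, 102)) {
    tags <- c(tags, "6''-O-glycosylation")
  }
  if (two_o) tags <- c(tags, "2''-O-glycosylation")
  if (neg && di_c && has_loss(prec_losses, 162) &&
      any(losses_tbl$is_base[losses_tbl$level == 2 &
                             abs(losses_tbl$loss - 162) < ION_TOL])) {
    tags <- c(tags, "7-O-glycosylation")
  }
  if (best$acyl != "none") tags <- c(tags, paste0(best$acyl, " acylation"))

  class_assigned <- if (!neg) {
    if (ev$bare) "flavone-O-glycoside" else return(NULL)
  } else if (di_c) {
    if (has_o_loss || ev$bare || two_o) "flavone-O,C-glycoside"
    else "di-C-glycoside"
  } else if (two_o) {
    "flavone-O,C-glycoside"
  } else if (ev$bare) {
    if (best$n_sugars == 1 && ev$c42 && ev$c72) {
      # monoglycoside with both interpretations: the base peak decides
      ag_nom <- round(bm_masses()$aglycone[[best$aglycone]])
      base <- base_ms2_ion(tree)
      if (!is.na(base) && (abs(base - (ag_nom - 1 + 42)) < ION_TOL ||
                           abs(base - (ag_nom - 1 + 72)) < ION_TOL)) {
        "flavone-C-glycoside"
      } else "flavone-O-glycoside"
    } else "flavone-O-glycoside"
  } else if (c_ion) {
    if (best$n_sugars == 1) "flavone-C-glycoside"
    else if (has_o_loss) "flavone-O,C-glycoside"
    else "flavone-C-glycoside"
  } else {
    return(NULL)
  }

  sugars <- c(hexose = best$n_hexose, deoxyhexose = best$n_deoxyhexose,
              pentose = best$n_pentose)
  sugars <- sugars[sugars > 0]
  ev_txt <- c(
    sprintf("aglycone %s by decomposition (+%s)", best$aglycone,
            paste(sprintf("%dx%s", sugars, names(sugars)), collapse = " ")),
    if (ev$bare) "bare aglycone ion",
    if (c_ion) "[Agly+42/72-H]- cross-ring ions",
    if (two_o) "[Agly+24/54-H]- (2''-O) ions",
    if (di_c) "[Agly+84/114-H]- di-C ions",
    if (has_o_loss) paste("clean sugar loss:",
                          paste(o_loss_seen, collapse = ", "))
  )
  rule_match("flavonoid-glycoside", class_assigned, ev_txt, "diagnostic",
             tags = c(paste0("aglycone:", best$aglycone), tags))
}

# enumerate flavan-3-ol candidates: monomers (plus gallate/hydroxybenzoate
# esters) and dimer/trimer compositions with 0 or more A-type bonds
flavanol_candidates <- function() {
  fl <- bm_masses()$flavanol
  h2 <- bm_masses()$H2
  out <- list()
  add <- function(label, mz, n, n_gallo, a_bonds) {
    out[[length(out) + 1]] <<- tibble::tibble(
      label = label, mz = mz, n_units = n, n_gallo = n_gallo,
      a_bonds = a_bonds)
  }
  for (nm in names(fl)) {
    m <- fl[[nm]] - PROTON_MASS
    add(paste0("(epi)", nm), m, 1, as.integer(nm == "gallocatechin"), 0)
    add(paste0("(epi)", nm, " O-gallate"), m + bm_masses()$galloyl, 1,
        as.integer(nm == "gallocatechin"), 0)
    add(paste0("(epi)", nm, " O-hydroxybenzoate"),
        m + bm_masses()$hydroxybenzoyl, 1,
        as.integer(nm == "gallocatechin"), 0)
  }
  for (n in 2:3) {
    for (ng in 0:n) {
      base <- (n - ng) * fl[["catechin"]] + ng * fl[["gallocatechin"]] -
        (n - 1) * h2 - PROTON_MASS
      for (a in 0:(n - 1)) {
        lab <- sprintf("%s %s (%d catechin, %d gallocatechin)",
                       c("dimer", "trimer")[n - 1],
                       if (a > 0) "A-type" else "B-type", n - ng, ng)
        add(lab, base - a * h2, n, ng, a)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Classify proanthocyanidins (flavan-3-ols and their oligomers)
#'
#' Negative mode. The precursor is matched against (epi)catechin /
#' (epi)gallocatechin monomers, their gallate / hydroxybenzoate esters, and
#' dimer/trimer compositions; A-type vs B-type linkage follows from the
#' 2 Da mass parity of the composition. Diagnostic ions: quinone-methide
#' monomer ions (289/305), internal dimer ions, retro-Diels-Alder losses
#' (152/168), heterocyclic ring fission (126), and galloyl/hydroxybenzoyl
#' losses (152.011/120.021). A precursor matching a unique composition
#' within 0.005 Da is itself diagnostic.
#'
#' @param tree A `spectrum_tree`.
#' @return A `rule_match` or `NULL`.
#' @export
classify_proanthocyanidin <- function(tree) {
  if (tree$polarity != "negative") return(NULL)
  cands <- flavanol_candidates()
  d <- abs(tree$precursor_mz - cands$mz)
  if (min(d) >= GATE_LOW) return(NULL)
  best <- cands[which.min(d), ]
  ions <- tree_ions(tree)
  losses <- extract_losses(tree)$loss
  # core evidence: quinone-methide monomer ions, internal dimer ions of a
  # trimer, or a high-resolution precursor match. RDA/HRF and the ester
  # losses are supporting only — nominal 120/152 losses also arise from
  # flavonoid cross-ring cleavages, so they cannot carry the call alone.
  core <- character()
  if (has_ion(ions, 289)) core <- c(core, "QM (epi)catechin ion 289")
  if (has_ion(ions, 305)) core <- c(core, "QM (epi)gallocatechin ion 305")
  for (dm in c(577, 593, 609)) {
    if (best$n_units == 3 && has_ion(ions, dm)) {
      core <- c(core, sprintf("internal dimer ion %d", dm))
    }
  }
  if (min(d) < 0.005) {
    core <- c(core, sprintf("precursor matches %s within 0.005 Da",
                            best$label))
  }
  if (length(core) == 0) return(NULL)
  supp <- character()
  if (has_loss(losses, 152)) supp <- c(supp, "RDA/galloyl loss ~152")
  if (has_loss(losses, 168)) {
    supp <- c(supp, "RDA loss 168 ((epi)gallocatechin)")
  }
  if (has_loss(losses, 126)) supp <- c(supp, "HRF loss 126")
  if (best$n_units == 1 && has_loss(losses, 120)) {
    supp <- c(supp, "hydroxybenzoyl loss ~120")
  }
  rule_match("proanthocyanidin", "proanthocyanidin",
             c(core, if (length(supp)) paste(supp, "(supporting)")),
             "diagnostic", tags = best$label)
}

RULE_CLASSES <- c("hydroxycinnamate-quinate", "hydroxycinnamate-threonate",
                  "amide", "flavone-O-glycoside", "flavone-C-glycoside",
                  "flavone-O,C-glycoside", "di-C-glycoside",
                  "proanthocyanidin")

all_classifiers <- function() {
  list(hqa = classify_hqa, threonate = classify_threonate_ester,
       amide = classify_amide, glycoside = classify_flavonoid_glycoside,
       proanthocyanidin = classify_proanthocyanidin)
}
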