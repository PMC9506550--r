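---
title: "Methods: models, rules and design choices in brachymet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in brachymet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachymet)
```

brachymet reimplements, as a tested pipeline, the untargeted LC-MS analysis
used to characterise specialized metabolism in *Brachypodium distachyon*
organs (leaf, root, spike) and accessions (Bd21, Bd3-1): feature-table
statistics under a factorial block design, exact-mass annotation, pathway
enrichment, and a rule-based structural classifier for MSn fragmentation
trees of phenylpropanoid/flavonoid chemistry. This vignette explains the
models, the tunable parameters, and the choices made where the design was
genuinely open.

## Exact-mass arithmetic

All mass computation rests on monoisotopic element masses (C = 12 exactly,
H = 1.00782503207, N = 14.0030740048, O = 15.9949146196, S = 31.97207100,
P = 30.97376163). Ion m/z adds or subtracts one *proton* mass
(1.00727646677 Da), not a hydrogen atom: the electron-mass correction is
folded into the constant. Mass error is reported in signed ppm with the
*theoretical* mass as denominator. Both conventions were fixed by
reconciling the bundled reference library: only this pair reproduces the
library's printed ppm errors, e.g. caffeic acid (C9H8O4, [M−H]⁻ theoretical
179.03498 Da, measured 179.03439 Da):

```{r}
ppm_error(179.03439, ion_mz("C9H8O4", "[M-H]-"))
```

The default annotation tolerance is 5 ppm, the identification tolerance
used throughout.

### The bundled reference library

`load_compound_library()` returns the 93 identified Brachypodium
metabolites with their printed measured/calculated masses, ppm errors,
organs, MSI identification levels, structural classes, and encoded MSn
fragmentation pathways. The printed values are transcribed as-is; at load
time each row's ppm error is recomputed from its own formula and compared
with the printed one. The agreement band is 0.05 ppm *plus* the rounding
implied by the printed precision (a mass printed to 3 decimals cannot pin
ppm tighter than ~1.5 ppm at m/z 300). Rows that still disagree — for
example rows whose printed "calculated" mass differs between entries of the
same formula — are flagged `printed-inconsistency` and carried unchanged,
never corrected: 74 of 93 rows are consistent.

## Feature tables and preprocessing

A feature table is an m/z-by-sample intensity matrix with feature metadata
(m/z, retention time, polarity; positive- and negative-mode features live
in one table and are analysed jointly) and the factorial sample design:
3 organs × 2 lines × 2 experiment blocks × 4 biological replicates = 48
samples. Preprocessing mirrors standard practice for gap-filled peak
tables: missing or zero entries are treated as below the detection limit
and replaced by half of that feature's minimum non-zero observation
(features observed nowhere are dropped with a warning — imputation has no
anchor for them), then intensities are log2-transformed. `impute_half_min()`
is idempotent, and both steps preserve row and column order. The same
preprocessed matrix feeds PCA and the ANOVA; the source material is
ambiguous on whether PCA used gap-filled zeros or the substitution, and
using one preprocessing for both keeps the two views of the data
comparable.

## The statistical stage

### Two-way ANOVA with the experiment as a block

Each feature's log2 intensities are decomposed by the linear model

  y ~ experiment + organ * line

with sequential (Type I) sums of squares in the order block, organ, line,
organ×line, and F tests against the residual mean square. Two points
deserve justification:

* **Fixed vs random block.** With only two experiment blocks and a
  balanced design, an additive fixed-block fit yields exactly the same F
  statistics for the fixed factors as the random-block (REML) analysis;
  the block simply absorbs one degree of freedom. The tests assert Type I
  = Type III on the canonical design (the factor subspaces are
  orthogonal), so the stated order is immaterial there.
* **Implementation.** The sums of squares come from successive QR
  projections of the four nested model matrices applied to the whole
  intensity matrix at once, so thousands of features are tested in a
  single pass; `stats::anova(stats::lm(...))` serves as the independent
  per-feature oracle in the test suite, never as the implementation.

Features constant across all samples get F = 0, p = 1; a design with an
organ×line cell of fewer than two observations is rejected.

### DAMs, fold changes, and the effect partition

Fold change per organ is the difference of mean log2 intensities between
lines (Bd3-1 − Bd21), i.e. a geometric-mean ratio on the raw scale —
consistent with the log2 transform preceding all analysis. A feature is a
*differentially accumulating metabolite* (DAM) in an organ when the line
or interaction p-value is ≤ `p_max` and |log2 FC| > `min_abs_log2_fc`.

Defaults are `p_max = 0.01` and `min_abs_log2_fc = 1` (FC > 2). The source
material states two threshold pairs in different places (0.01/FC 2 in the
text defining DAMs; 0.05/1.5 in a figure caption); we default to the
definition used in the text and expose both knobs as arguments. No
multiple-testing correction is applied in DAM selection by default — the
screen mirrors a raw-p threshold, with BH adjustment available via
`bh = TRUE` (BH is always applied across pathways in enrichment).
`effect_partition()` reports the seven Venn regions of the organ / line /
interaction significance sets at the same `p_max`.

### PCA

`ft_pca()` is `prcomp` on samples-by-features with column mean-centring
and no scaling (log2 already puts features on comparable scales);
explained-variance fractions are non-increasing and the tests check the
scores against an independent eigendecomposition of the covariance matrix
up to sign.

## Synthetic data: what it emulates and what it does not

`simulate_feature_table()` generates the full 48-sample design with known
ground truth:

  intensity = 2^(base + organ shift + line shift·[Bd3-1] +
                 interaction shift·[Bd3-1] + block + N(0, σ_bio))

| parameter | default | meaning |
|---|---|---|
| `n_features` | 2000 | features in the table |
| `fraction_organ_affected` | 0.5 | organ-shifted features (organ effects dominate real profiles) |
| `fraction_line_affected` | 0.05 | line-shifted features (line effects are sparse) |
| `fraction_interaction` | 0.05 | features with an organ-specific line shift |
| `line_effect` | 2 log2 | planted Bd3-1 − Bd21 shift (sign random) |
| `sigma_bio` | 0.5 log2 | biological replicate SD |
| `sigma_block` | 0.25 log2 | additive experiment-block shift SD |
| `lod_quantile` | 0.05 | fraction of lowest raw intensities censored |
| `library_fraction` | 0 | features given library ion m/z ± ≤3 ppm |

The noise model — log-normal biological variation plus an additive block
shift — is the minimal structure under which the block ANOVA is the
matched analysis. Censoring is rank-based (the lowest raw intensities go
missing), emulating a detection limit rather than missingness at random.
σ values are generator conventions chosen as realistic for replicated
plant LC-MS profiles, not claims about the original data. The generator
does **not** emulate retention-time drift, isotope envelopes, adduct
redundancy, correlated features, or heteroscedastic noise; a green test
suite therefore certifies the statistics under the stated model, not
robustness to all real-data pathologies.

m/z spiking draws library ions with at most ±3 ppm jitter (inside the
5 ppm annotation tolerance by construction) and keeps decoy masses at
least 10 ppm from every library mass, so annotation recovery on synthetic
data has an exact expected answer.

## Pathway enrichment

Annotation matches each query m/z (with its polarity) against library ions
within 5 ppm; compounds are deduplicated before enrichment. Per pathway,
over-representation is the hypergeometric upper tail
P(X ≥ hits | pathway size, annotated universe, significant-set size); a
seeded permutation p-value (default 2000 resamples of significant-set-sized
draws) is reported alongside as a finite-sample check, and BH-FDR is
applied across pathways on the hypergeometric p. Pathway impact is the sum
of betweenness centralities of hit compounds divided by the sum over all
pathway compounds — 1 when every node is hit, 0 for no hits or a pathway
whose graph has no between-node paths. Reporting defaults flag pathways
with FDR < 0.03 and impact > 0.3.

This is a deliberate simplification of the full mummichog activity-score
machinery (which also weighs currency metabolites and adduct ambiguity);
the original analysis delegated those details to an external web platform
and its full rice pathway database, neither reproducible offline. The
bundled pathway graph is therefore **synthetic**: it reuses the twelve
reported pathway names over the 93 library compounds, with membership
curated chemically where defensible (threonate esters under ascorbate and
aldarate metabolism, amino acids under their biosynthesis pathways,
glycosides under sugar pathways) and distributed illustratively otherwise.
It exists to exercise the algorithms with known answers, not to assert
biochemistry; printed FDR/impact values from the original full-database
analysis are out of reach by construction and are not targets.

## The fragmentation rule engine

A `spectrum_tree` is a precursor ion plus nested MS2…MS5 scans in one
polarity; each scan records the isolated parent and the base peak (the ion
taken for further fragmentation). The bundled library's pathways are
encoded as compact strings (`MS2:323,*193*,173,135|MS3:149,135`, `*x*`
marking base peaks, `MS3@483:` explicit isolation parents) and decoded at
load time.

Rules are independent pattern matchers; each returns evidence with
diagnostic or supporting confidence, and only diagnostic matches assign a
class. Product ions are matched at the ion-trap layer (±0.5 Da nominal);
precursor gates use 0.35 Da except where noted.

* **Hydroxycinnamoyl-quinates**: gate on caffeoyl/coumaroyl/feruloyl-
  quinate masses; base MS2 peak at 173 (quinate) ⇒ 4-acyl isomer, base
  peak at the hydroxycinnamate anion (179/163/193) ⇒ 5-acyl; anything
  else is unassigned-HQA, supporting only.
* **Threonate esters**: gate at 0.01 Da — deliberately tight, because the
  discrimination of threonate conjugates rests on high-resolution twin
  ions (135.0288 threonate vs 135.0444 decarboxylated caffeate), and at
  looser gates an unrelated flavone ether 16 mDa away shows
  coincidentally caffeate-like nominal ions. Diagnostic: the 118.027
  threonate−H₂O loss and/or the complementary acid anion.
* **Amides** (positive mode): polyamine neutral loss or protonated amine
  ion (putrescine 88/89, agmatine 130/131, spermidine 145/146), acyl from
  the 147/163/177 acylium ions. Isomers sharing precursor and class are
  reported as a possible cis/trans conformer pair — geometry itself is
  not assignable from one spectrum.
* **Flavonoid glycosides**: the aglycone is inferred by decomposing the
  neutral mass into aglycone + up to three sugars (+ one optional acyl)
  within 0.05 Da, combined with aglycone-diagnostic ions. Class logic in
  negative mode: [Agly+84/114−H]⁻ ⇒ di-C; [Agly+24/54−H]⁻ ⇒ a
  2″-O-glycosylated C-sugar (O,C); the bare aglycone ion ⇒ all sugars
  O-linked; C-type ions without the bare aglycone plus a clean first-step
  sugar loss (162/146/132 from the precursor) ⇒ mixed O,C. Three
  numerical subtleties are handled explicitly: (i) clean O-sugar losses
  are read only from the precursor→MS2 step, because deeper-level mass
  differences can fake a nominal sugar loss through composite cross-ring
  cleavages; (ii) for monoglycosides the cross-ring ions of an O-sugar
  coincide exactly with the C-type ions, so the base peak decides; (iii)
  isobaric aglycone hypotheses (luteolin+hexose ≡ isorhamnetin+pentose)
  are broken by evidence count, then decomposition error, then a fixed
  commonness order, and an intact di-C ion pair suppresses lone 2″-O
  coincidences under the same hypothesis. Sugar identity beyond
  hexose/deoxyhexose/pentose is not determinable by MS and is never
  claimed; 4′-OH/7-OH substitution positions are literature-suggested
  tags, not evidence.
* **Proanthocyanidins**: the precursor is matched against
  (epi)catechin/(epi)gallocatechin monomers, their gallate/
  hydroxybenzoate esters, and dimer/trimer compositions; A- vs B-type
  linkage follows from the 2 Da parity of the composition. Core evidence
  is a quinone-methide monomer ion (289/305), an internal dimer ion of a
  trimer, or a 0.005 Da precursor match; retro-Diels-Alder (152/168) and
  heterocyclic-ring-fission (126) losses are supporting only, because
  nominal 120/152 differences also arise from flavonoid cross-ring
  chemistry. Flavan-3-ol stereochemistry is not assignable by MS.

`classify_spectrum()` runs all rules, intersects with precursor-matched
library candidates (5 ppm at high resolution, 0.3 Da at low), and assigns
MSI levels: 1 requires a standard-linked candidate matching in precursor
and fragmentation (retention time is additionally compared when both sides
record one; the bundled library does not, so the check is vacuous there);
2 is a spectral/literature match; 3 is class- or mass-only. Contradictory
diagnostic classes yield an explicit ambiguous call, never a silent
override.

Replaying all 93 bundled trees yields 92 class-consistent calls and all 13
standard-confirmed rows at MSI 1. The single exception is a row whose
printed measured mass is ~2 Da inconsistent with its own printed formula
(it carries the `printed-inconsistency` flag); the engine declines to
classify it, which we consider the correct behaviour.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → preprocess/statistics → annotate →
enrich → classify in dependency order, logs per-stage row counts, writes
every artifact as delimited text or JSON, and serializes the effective
configuration next to the outputs. Identical configuration and seed give
byte-identical files (intensities are serialized at `%.17g` and re-read
through `strtod`, so write/read round trips are bit-exact). `run_demo()`
is the one-command demonstration on synthetic data.

Problem sizes used by the test suite and the acceptance script — a
2000-feature null calibration, a 200-feature planted-effect recovery, a
300-feature annotation run and two 200-feature demo runs — were chosen as
the smallest sizes at which the binomial/Monte-Carlo bands in the checks
are informative.

## Known limitations

* Raw-spectra processing (peak picking, deconvolution, alignment,
  gap-filling) is out of scope; the pipeline starts at an aligned table.
* The pathway graph is a synthetic miniature; enrichment results on it
  validate the algorithms, not Brachypodium biology.
* The rule engine covers the phenylpropanoid/flavonoid chemistry of the
  bundled library; unrelated chemistry is left unclassified by design.
* Only [M+H]⁺ / [M−H]⁻ ion species are modelled; other adducts, multiple
  charging and in-source fragmentation are not.
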