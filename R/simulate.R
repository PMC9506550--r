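# Synthetic feature-table generator: the 48-sample factorial design
# (3 organs x 2 lines x 2 experiment blocks x 4 replicates) with planted
# organ/line/interaction effects on the log2 scale, log-normal biological
# noise, an additive experiment-block shift, and rank-based detection-limit
# censoring. Ground truth is returned alongside so downstream stages are
# testable end to end.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: the
#' 48-sample design, log2-scale effects, biological SD 0.5 log2, block SD
#' 0.25 log2, 5% rank-based censoring, and a planted line effect of 2 log2
#' units on affected features.
#'
#' @param n_features Number of m/z features.
#' @param fraction_organ_affected,fraction_line_affected,fraction_interaction
#'   Proportions of features carrying each planted effect.
#' @param base_mean Baseline log2 intensity.
#' @param organ_effect_sd SD of planted organ shifts (log2).
#' @param line_effect Planted Bd3-1 minus Bd21 shift (log2) on line-affected
#'   features (sign randomised per feature).
#' @param interaction_effect Planted organ-specific line shift (log2) on
#'   interaction-affected features.
#' @param sigma_bio Biological replicate SD (log2).
#' @param sigma_block Experiment-block SD (log2).
#' @param lod_quantile Proportion of the lowest raw intensities censored as
#'   below the detection limit.
#' @param library_fraction Proportion of features whose m/z is drawn from the
#'   bundled compound library (with ppm jitter); the rest are decoys.
#' @param dam_threshold Absolute planted log2 difference above which a
#'   feature counts as a planted DAM in an organ.
#' @param seed Integer seed; mandatory for provenance.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features = 2000,
                       fraction_organ_affected = 0.5,
                       fraction_line_affected = 0.05,
                       fraction_interaction = 0.05,
                       base_mean = 10,
                       organ_effect_sd = 1,
                       line_effect = 2,
                       interaction_effect = 2,
                       sigma_bio = 0.5,
                       sigma_block = 0.25,
                       lod_quantile = 0.05,
                       library_fraction = 0,
                       dam_threshold = 1,
                       seed = 1L) {
  cfg <- list(n_features = n_features,
              fraction_organ_affected = fraction_organ_affected,
              fraction_line_affected = fraction_line_affected,
              fraction_interaction = fraction_interaction,
              base_mean = base_mean, organ_effect_sd = organ_effect_sd,
              line_effect = line_effect,
              interaction_effect = interaction_effect,
              sigma_bio = sigma_bio, sigma_block = sigma_block,
              lod_quantile = lod_quantile,
              library_fraction = library_fraction,
              dam_threshold = dam_threshold, seed = as.integer(seed))
  probs <- c(cfg$fraction_organ_affected, cfg$fraction_line_affected,
             cfg$fraction_interaction, cfg$lod_quantile,
             cfg$library_fraction)
  if (any(probs < 0 | probs > 1)) stop("proportions must be in [0,1]")
  if (cfg$sigma_bio < 0 || cfg$sigma_block < 0) stop("sigma must be >= 0")
  if (cfg$n_features < 1) stop("n_features must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a feature table with known ground truth
#'
#' Intensities are `2^(base_mean + organ + line + interaction + block +
#' N(0, sigma_bio))`; the lowest `lod_quantile` of raw intensities are set
#' missing (rank-based censoring, emulating a detection limit). Identical
#' seeds give identical output.
#'
#' @param cfg A [sim_config()].
#' @param library Optional compound library for m/z spiking (see
#'   `library_fraction`); defaults to the bundled library when
#'   `library_fraction > 0`.
#' @return A list: `table` (raw `feature_table`), `effects` (per-feature
#'   ground-truth tibble with planted shifts and `dam_<organ>` flags), and
#'   `config`.
#' @export
simulate_feature_table <- function(cfg = sim_config(), library = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  design <- canonical_design()
  n <- cfg$n_features

  feature_id <- sprintf("F%05d", seq_len(n))
  mzprop <- simulate_mz(n, cfg, library)

  organ_on <- stats::runif(n) < cfg$fraction_organ_affected
  line_on <- stats::runif(n) < cfg$fraction_line_affected
  inter_on <- stats::runif(n) < cfg$fraction_interaction

  organ_shift <- matrix(0, n, 3, dimnames = list(NULL, ORGANS))
  organ_shift[organ_on, ] <- stats::rnorm(sum(organ_on) * 3,
                                          sd = cfg$organ_effect_sd)
  line_shift <- ifelse(line_on,
                       cfg$line_effect * sample(c(-1, 1), n, replace = TRUE),
                       0)
  inter_shift <- matrix(0, n, 3, dimnames = list(NULL, ORGANS))
  if (any(inter_on)) {
    # one organ per feature carries the interaction
    pick <- sample.int(3, n, replace = TRUE)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    idx <- which(inter_on)
    inter_shift[cbind(idx, pick[idx])] <- cfg$interaction_effect * sgn[idx]
  }

  block_eff <- stats::rnorm(2, sd = cfg$sigma_block)
  block <- block_eff[match(design$experiment, c("E1", "E2"))]

  is_bd31 <- design$line == "Bd3-1"
  org_idx <- match(design$organ, ORGANS)
  mu <- cfg$base_mean +
    organ_shift[, org_idx, drop = FALSE] +
    outer(line_shift, as.numeric(is_bd31)) +
    inter_shift[, org_idx, drop = FALSE] * rep(as.numeric(is_bd31),
                                               each = n) +
    matrix(block, n, nrow(design), byrow = TRUE)
  y <- mu + matrix(stats::rnorm(n * nrow(design), sd = cfg$sigma_bio),
                   n, nrow(design))
  raw <- 2^y

  if (cfg$lod_quantile > 0) {
    lod <- stats::quantile(raw, cfg$lod_quantile)
    raw[raw < lod] <- NA_real_
  }

  features <- tibble::tibble(feature_id = feature_id, mz = mzprop$mz,
                             rt = mzprop$rt, polarity = mzprop$polarity)
  ft <- feature_table(features, design, raw, transformed = "raw")

  planted_diff <- sweep(inter_shift, 1, line_shift, `+`)
  effects <- tibble::tibble(
    feature_id = feature_id,
    organ_affected = organ_on, line_affected = line_on,
    interaction_affected = inter_on,
    line_shift = line_shift,
    from_library = mzprop$from_library,
    library_compound = mzprop$library_compound
  )
  for (org in ORGANS) {
    effects[[paste0("shift_", org)]] <- planted_diff[, org]
    effects[[paste0("dam_", org)]] <-
      abs(planted_diff[, org]) > cfg$dam_threshold
  }
  list(table = ft, effects = effects, config = cfg)
}

# m/z assignment: optionally spike library ion masses with ppm jitter;
# decoys are kept >= decoy_margin_ppm away from every library mass.
simulate_mz <- function(n, cfg, library, jitter_ppm = 3,
                        decoy_margin_ppm = 10) {
  if (cfg$library_fraction > 0 && is.null(library)) {
    library <- load_compound_library()
  }
  mz <- numeric(n)
  polarity <- sample(c("positive", "negative"), n, replace = TRUE)
  from_library <- rep(FALSE, n)
  library_compound <- rep(NA_character_, n)
  n_spike <- round(n * cfg$library_fraction)
  if (n_spike > 0) {
    if (jitter_ppm >= 5) {
      stop("m/z jitter window must stay inside the 5 ppm annotation tolerance")
    }
    rows <- sample.int(nrow(library), n_spike, replace = n_spike > nrow(library))
    target <- ifelse(is.na(library$theoretical_mz[rows]),
                     library$measured_mz[rows], library$theoretical_mz[rows])
    mz[seq_len(n_spike)] <- target *
      (1 + stats::runif(n_spike, -jitter_ppm, jitter_ppm) * 1e-6)
    polarity[seq_len(n_spike)] <- library$polarity[rows]
    from_library[seq_len(n_spike)] <- TRUE
    library_compound[seq_len(n_spike)] <- as.character(
      library$compound_id[rows])
  }
  if (n_spike < n) {
    ref <- if (!is.null(library)) {
      ifelse(is.na(library$theoretical_mz), library$measured_mz,
             library$theoretical_mz)
    } else numeric(0)
    decoys <- numeric(n - n_spike)
    k <- 0
    while (k < length(decoys)) {
      cand <- stats::runif(length(decoys) - k, 100, 1000)
      if (length(ref)) {
        ok <- vapply(cand, function(m) {
          all(abs((m - ref) / ref) * 1e6 >= decoy_margin_ppm)
        }, logical(1))
        cand <- cand[ok]
      }
      if (length(cand)) {
        decoys[(k + 1):(k + length(cand))] <- cand
        k <- k + length(cand)
      }
    }
    mz[(n_spike + 1):n] <- decoys
  }
  list(mz = mz, rt = stats::runif(n, 0.5, 12), polarity = polarity,
       from_library = from_library, library_compound = library_compound)
}

#' Spike library m/z values into a simulation
#'
#' Convenience wrapper around [simulate_feature_table()] with
#' `library_fraction > 0`: a subset of features receives m/z values equal to
#' library ion m/z within +/-3 ppm, the rest are decoys at least 10 ppm away
#' from every library mass.
#'
#' @param cfg A [sim_config()]; its `library_fraction` must be > 0.
#' @param library Compound library (default: bundled).
#' @return As [simulate_feature_table()].
#' @export
spike_library_features <- function(cfg, library = load_compound_library()) {
  if (cfg$library_fraction <= 0) {
    stop("spike_library_features() needs library_fraction > 0", call. = FALSE)
  }
  simulate_feature_table(cfg, library = library)
}
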