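# Frozen expectations for the bundled-library replay.
#
# The rule engine covers phenylpropanoid/flavonoid chemistry; rows whose
# curated class lies outside this set (amino acids, simple phenolics,
# lignans, 'other') are expected to stay unclassified. One library row is a
# frozen exception: compound 86, whose printed measured mass is ~2 Da
# inconsistent with its own formula, so the engine declines to classify it.
REPLAY_EXCEPTIONS <- c("86")

# small random feature table around the canonical design
random_feature_table <- function(n_features = 20, seed = 1,
                                 missing_frac = 0) {
  set.seed(seed)
  design <- canonical_design()
  m <- matrix(2^rnorm(n_features * nrow(design), mean = 10, sd = 1),
              n_features, nrow(design))
  if (missing_frac > 0) {
    m[sample(length(m), round(missing_frac * length(m)))] <- NA
  }
  features <- tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(n_features)),
    mz = runif(n_features, 100, 1000),
    rt = runif(n_features, 0.5, 12),
    polarity = sample(c("positive", "negative"), n_features, replace = TRUE)
  )
  feature_table(features, design, m, transformed = "raw")
}
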