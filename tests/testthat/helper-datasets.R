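# Build small study datasets in code. `scores` is a nested named list:
# reader -> modality -> numeric vector of continuous scores over cases
# C1..Cn (NA = deferred). Categorical scores are derived from the scale so
# the two score types are consistent unless `categorical` overrides them.

make_dataset <- function(scores, biomarker = "HER2",
                         specimen_format = "whole_slide",
                         categorical = NULL, sufficient = NULL,
                         scales = default_scales()) {
  sc <- scales[[biomarker]]
  rows <- list()
  for (r in names(scores)) {
    for (m in names(scores[[r]])) {
      v <- scores[[r]][[m]]
      cases <- sprintf("C%d", seq_along(v))
      def <- is.na(v)
      cat_lab <- if (!is.null(categorical)) categorical[[r]][[m]] else
        pathagree:::.derive_category(v, sc)
      suff <- if (!is.null(sufficient)) sufficient[[r]][[m]] else
        rep(NA, length(v))
      rows[[length(rows) + 1]] <- data.frame(
        reader_id = r, case_id = cases, modality = m,
        biomarker = biomarker, specimen_format = specimen_format,
        categorical_score = cat_lab,
        continuous_score = as.integer(v),
        deferred = def, sufficient_cells = suff,
        stringsAsFactors = FALSE)
    }
  }
  parse_score_table(do.call(rbind, rows), scales,
                    warn_inconsistent = FALSE)
}

# random tied score vectors for oracle comparisons
random_tied_pair <- function(n = NULL, max_value = 4) {
  if (is.null(n)) n <- sample(2:12, 1)
  list(x = sample(seq_len(max_value), n, replace = TRUE),
       y = sample(seq_len(max_value), n, replace = TRUE))
}

noiseless_config <- function(biomarker, n_cases, seed = 7, ...) {
  synthetic_study_config(biomarker, n_cases = n_cases,
                         reader_bias_sd = 0, reader_noise_sd = 0,
                         modality_shift = 0, defer_rate_base = 0,
                         inadequate_case_fraction = 0,
                         insufficiency_rate = 0, seed = seed, ...)
}
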