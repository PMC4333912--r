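#' Configure the synthetic reader-study generator
#'
#' A latent-trait model of an IHC reader study. Each case carries a latent
#' expression level theta on the 0-100 continuous scale, drawn from a
#' biomarker-specific mixture; each reader a persistent additive bias; each
#' recorded score adds modality shift (digital only) and per-score noise,
#' is clamped to \[0, 100\] and rounded to an integer, and the categorical
#' score is derived from the scale, so the two score types are consistent
#' by construction. Deferral is a case property: a fraction of cases is
#' "inadequate" and deferred with high probability, everything else at a
#' low base rate, independently per (reader, case, modality).
#'
#' Defaults mirror the study design this generator emulates: 8 readers, 25
#' whole slides plus 97 TMA cores per biomarker, reader bias SD 5 and
#' score noise SD 12 on the 0-100 scale, no systematic modality shift,
#' base deferral rates of about 1.5% (HER2) and 12% (Ki-67), and roughly
#' 9% of TMA cores inadequate (deferred with probability 0.9).
#'
#' @param biomarker `"HER2"` (4-category ordinal, within-bin uniform
#'   latents with mixture weights over the bins) or `"Ki67"` (binary at a
#'   strict 10% threshold, latent drawn from a two-component normal mixture
#'   straddling the threshold).
#' @param n_readers Number of readers.
#' @param n_cases Named integer vector of cases per specimen format,
#'   e.g. `c(whole_slide = 25, tma_core = 97)`.
#' @param case_mixture Mixture spec; `NULL` for the biomarker default. For
#'   HER2 a list with `weights` (one per category); for Ki-67 a list with
#'   `weights` (low, high), `low_mean`, `low_sd`, `high_mean`, `high_sd`.
#' @param reader_bias_sd SD of the per-reader additive shift.
#' @param reader_noise_sd SD of the per-score additive noise.
#' @param modality_shift Additive offset applied to digital scores.
#' @param defer_rate_base Deferral probability for adequate cases.
#' @param inadequate_case_fraction Fraction of cases per format with
#'   elevated deferral; scalar or named per format. `NULL` for the
#'   biomarker default (0 for whole slides, about 9/97 for TMA cores).
#' @param defer_rate_inadequate Deferral probability for inadequate cases.
#' @param insufficiency_rate Probability that a Ki-67 score is flagged as
#'   lacking tumor cells (ignored for cut-point biomarkers).
#' @param seed RNG seed; identical configs generate identical studies.
#' @return A validated `synthetic_study_config`.
#' @export
synthetic_study_config <- function(biomarker = c("HER2", "Ki67"),
                                   n_readers = 8,
                                   n_cases = c(whole_slide = 25,
                                               tma_core = 97),
                                   case_mixture = NULL,
                                   reader_bias_sd = 5,
                                   reader_noise_sd = 12,
                                   modality_shift = 0,
                                   defer_rate_base = NULL,
                                   inadequate_case_fraction = NULL,
                                   defer_rate_inadequate = 0.9,
                                   insufficiency_rate = 0,
                                   seed = 1) {
  biomarker <- match.arg(biomarker)
  if (is.null(names(n_cases)) || !all(names(n_cases) %in% FORMATS))
    stop("n_cases must be named with specimen formats (whole_slide, tma_core)",
         call. = FALSE)
  if (is.null(case_mixture))
    case_mixture <- if (biomarker == "HER2")
      list(weights = c(0.3, 0.2, 0.2, 0.3)) else
        list(weights = c(0.5, 0.5), low_mean = 6, low_sd = 3,
             high_mean = 30, high_sd = 15)
  w <- case_mixture$weights
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("case_mixture weights must be nonnegative and sum to 1",
         call. = FALSE)
  if (is.null(defer_rate_base))
    defer_rate_base <- if (biomarker == "HER2") 0.015 else 0.12
  if (is.null(inadequate_case_fraction))
    inadequate_case_fraction <- c(whole_slide = 0,
                                  tma_core = if (biomarker == "HER2")
                                    9 / 97 else 8 / 97)
  if (length(inadequate_case_fraction) == 1 &&
      is.null(names(inadequate_case_fraction)))
    inadequate_case_fraction <- stats::setNames(
      rep(inadequate_case_fraction, length(n_cases)), names(n_cases))
  rates <- c(defer_rate_base, defer_rate_inadequate, insufficiency_rate,
             inadequate_case_fraction)
  if (any(rates < 0 | rates > 1))
    stop("all rates and fractions must lie in [0, 1]", call. = FALSE)
  if (n_readers < 2) stop("need at least 2 readers", call. = FALSE)
  if (reader_bias_sd < 0 || reader_noise_sd < 0)
    stop("standard deviations must be nonnegative", call. = FALSE)
  structure(list(biomarker = biomarker, n_readers = as.integer(n_readers),
                 n_cases = n_cases, case_mixture = case_mixture,
                 reader_bias_sd = reader_bias_sd,
                 reader_noise_sd = reader_noise_sd,
                 modality_shift = modality_shift,
                 defer_rate_base = defer_rate_base,
                 inadequate_case_fraction = inadequate_case_fraction,
                 defer_rate_inadequate = defer_rate_inadequate,
                 insufficiency_rate = insufficiency_rate,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

# latent case values on the continuous scale
.draw_latents <- function(config, n) {
  mix <- config$case_mixture
  if (config$biomarker == "HER2") {
    scale <- her2_scale()
    lo <- scale$cutpoints
    # upper integer bound per bin, so rounding cannot cross a cutpoint
    hi <- c(scale$cutpoints[-1] - 1, 100)
    bin <- sample.int(length(mix$weights), n, replace = TRUE,
                      prob = mix$weights)
    stats::runif(n, lo[bin], hi[bin])
  } else {
    comp <- stats::runif(n) < mix$weights[1]
    mu <- ifelse(comp, mix$low_mean, mix$high_mean)
    sd <- ifelse(comp, mix$low_sd, mix$high_sd)
    pmin(100, pmax(0, stats::rnorm(n, mu, sd)))
  }
}

# observed integer scores for one modality: readers x cases
.observe_scores <- function(theta, bias, shift, noise_sd) {
  R <- length(bias)
  n <- length(theta)
  eps <- if (noise_sd > 0) matrix(stats::rnorm(R * n, 0, noise_sd), R, n)
         else matrix(0, R, n)
  raw <- outer(bias, theta, "+") + shift + eps
  # raw first in pmax/pmin so the matrix dims survive
  round(pmin(pmax(raw, 0), 100))
}

#' Simulate raw score matrices from the latent-trait model
#'
#' Low-level access to the generator for one specimen format: returns the
#' complete (no-deferral) reader-by-case integer score matrices per
#' modality together with the latent case values and reader biases. Useful
#' for large-sample characterization of the generator, where assembling a
#' record table would be wasteful.
#'
#' @param config A [synthetic_study_config()].
#' @param specimen_format Format whose `n_cases` entry to use.
#' @param modalities Subset of modalities to generate.
#' @return List with `scores` (named list of matrices), `theta`, `bias`.
#' @export
simulate_score_matrices <- function(config, specimen_format = "tma_core",
                                    modalities = MODALITIES) {
  stopifnot(inherits(config, "synthetic_study_config"))
  n <- config$n_cases[[specimen_format]]
  if (is.null(n)) stop("config has no n_cases entry for ", specimen_format,
                       call. = FALSE)
  .with_seed(config$seed, {
    bias <- stats::rnorm(config$n_readers, 0, config$reader_bias_sd)
    theta <- .draw_latents(config, n)
    scores <- lapply(modalities, function(mod)
      .observe_scores(theta, bias,
                      if (mod == "digital") config$modality_shift else 0,
                      config$reader_noise_sd))
    names(scores) <- modalities
    list(scores = scores, theta = theta, bias = bias)
  })
}

#' Generate a synthetic reader study
#'
#' Draws a full study for one biomarker — every reader scoring every case
#' under both modalities in each configured specimen format — and returns
#' it as a validated `study_dataset` together with the ground truth that
#' produced it. The same config (including seed) always generates the
#' identical study.
#'
#' @param config A [synthetic_study_config()].
#' @return List of class `synthetic_study`: `dataset` (a `study_dataset`)
#'   and `truth` (reader biases; per format the latent case values and the
#'   inadequate-case ids).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  scale <- if (config$biomarker == "HER2") her2_scale() else ki67_scale()
  readers <- sprintf("R%d", seq_len(config$n_readers))
  R <- config$n_readers
  .with_seed(config$seed, {
    bias <- stats::rnorm(R, 0, config$reader_bias_sd)
    truth <- list(reader_bias = stats::setNames(bias, readers),
                  formats = list())
    blocks <- list()
    for (fmt in names(config$n_cases)) {
      n <- config$n_cases[[fmt]]
      case_ids <- sprintf("%s-%s-%03d", config$biomarker,
                          if (fmt == "whole_slide") "WS" else "TMA",
                          seq_len(n))
      theta <- .draw_latents(config, n)
      frac <- config$inadequate_case_fraction[[fmt]]
      if (is.null(frac) || is.na(frac)) frac <- 0
      n_bad <- round(frac * n)
      inadequate <- sort(sample.int(n, n_bad))
      defer_rate <- rep(config$defer_rate_base, n)
      defer_rate[inadequate] <- config$defer_rate_inadequate
      truth$formats[[fmt]] <- list(theta = stats::setNames(theta, case_ids),
                                   inadequate_cases = case_ids[inadequate])
      for (mod in MODALITIES) {
        score <- .observe_scores(theta, bias,
                                 if (mod == "digital")
                                   config$modality_shift else 0,
                                 config$reader_noise_sd)
        deferred <- matrix(stats::runif(R * n), R, n) <
          matrix(defer_rate, R, n, byrow = TRUE)
        sufficient <- if (is.null(scale$positivity_threshold))
          matrix(NA, R, n) else
            matrix(stats::runif(R * n) >= config$insufficiency_rate, R, n)
        cont <- as.integer(t(score))
        cat_lab <- .derive_category(cont, scale)
        def <- as.vector(t(deferred))
        cont[def] <- NA_integer_
        cat_lab[def] <- NA_character_
        blocks[[length(blocks) + 1]] <- data.frame(
          reader_id = rep(readers, each = n),
          case_id = rep(case_ids, times = R),
          modality = mod, biomarker = config$biomarker,
          specimen_format = fmt,
          categorical_score = cat_lab, continuous_score = cont,
          deferred = def, sufficient_cells = as.vector(t(sufficient)),
          stringsAsFactors = FALSE)
      }
    }
    dataset <- parse_score_table(do.call(rbind, blocks),
                                 default_scales(),
                                 warn_inconsistent = FALSE)
    structure(list(dataset = dataset, truth = truth,
                   config = config), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %s, seed %d\n", x$config$biomarker,
              x$config$seed))
  print(x$dataset)
  invisible(x)
}

#' Generate a two-biomarker study at full design scale
#'
#' Convenience wrapper producing one combined `study_dataset` holding a
#' HER2 and a Ki-67 arm with shared reader labels, each at the default
#' design scale (8 readers, 25 whole slides + 97 TMA cores, both
#' modalities).
#'
#' @param seed Base seed; the two arms use `seed` and `seed + 1`.
#' @param her2,ki67 Optional configs overriding the defaults (their seeds
#'   are used as given).
#' @return List with `dataset` (combined) and `truth` (per biomarker).
#' @export
generate_full_study <- function(seed = 42, her2 = NULL, ki67 = NULL) {
  if (is.null(her2))
    her2 <- synthetic_study_config("HER2", seed = seed)
  if (is.null(ki67))
    ki67 <- synthetic_study_config("Ki67", seed = seed + 1)
  a <- generate_study(her2)
  b <- generate_study(ki67)
  dataset <- parse_score_table(rbind(a$dataset$records, b$dataset$records),
                               default_scales(), warn_inconsistent = FALSE)
  list(dataset = dataset,
       truth = list(HER2 = a$truth, Ki67 = b$truth))
}

#' Write a suite of small fixture studies as CSV files
#'
#' Canned inputs for exercising the pipeline by hand: the worked tau-b
#' example (`taub_04.csv`, pairwise tau-b 0.4 on continuous scores), a
#' perfect-agreement study, a minimal 3-row study with one deferral, a
#' small study containing a majority-deferred case, and a full 8-reader
#' HER2 + Ki-67 study at design scale (`design_scale.csv`). A
#' `manifest.json` records the expected headline value for each fixture.
#'
#' @param out_dir Writable output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  her2 <- her2_scale()
  row <- function(reader, case, modality, cont, fmt = "whole_slide",
                  deferred = FALSE) {
    data.frame(reader_id = reader, case_id = case, modality = modality,
               biomarker = "HER2", specimen_format = fmt,
               categorical_score = if (deferred) NA_character_ else
                 categorize_continuous(cont, her2),
               continuous_score = if (deferred) NA_integer_ else
                 as.integer(cont),
               deferred = deferred, sufficient_cells = NA,
               stringsAsFactors = FALSE)
    }
  files <- character(0)
  put <- function(df, name) {
    ds <- parse_score_table(df, warn_inconsistent = FALSE)
    path <- file.path(out_dir, name)
    write_score_table(ds, path)
    files <<- c(files, path)
  }

  cases4 <- sprintf("C%d", 1:4)
  put(rbind(do.call(rbind, Map(row, "R1", cases4, "optical",
                               c(1, 2, 3, 3))),
            do.call(rbind, Map(row, "R2", cases4, "optical",
                               c(1, 3, 2, 3)))),
      "taub_04.csv")
  put(rbind(do.call(rbind, Map(row, "R1", cases4, "optical",
                               c(10, 30, 60, 90))),
            do.call(rbind, Map(row, "R2", cases4, "optical",
                               c(10, 30, 60, 60)))),
      "pa75.csv")
  perfect <- expand.grid(reader = c("R1", "R2"), case = cases4,
                         modality = MODALITIES, stringsAsFactors = FALSE)
  perfect_scores <- c(C1 = 5, C2 = 30, C3 = 60, C4 = 90)
  put(do.call(rbind, Map(row, perfect$reader, perfect$case,
                         perfect$modality,
                         perfect_scores[perfect$case])),
      "perfect.csv")
  put(rbind(row("R1", "C1", "optical", 60),
            row("R2", "C1", "optical", 55),
            row("R1", "C1", "digital", NA, deferred = TRUE)),
      "minimal.csv")
  defer_grid <- expand.grid(reader = sprintf("R%d", 1:4),
                            case = sprintf("C%d", 1:5),
                            modality = MODALITIES, stringsAsFactors = FALSE)
  defer_scores <- c(C1 = 10, C2 = 30, C3 = 55, C4 = 80, C5 = 45)
  put(do.call(rbind, Map(function(r, cs, m)
    row(r, cs, m, defer_scores[cs],
        deferred = cs == "C5" | (cs == "C4" & r == "R1" & m == "optical")),
    defer_grid$reader, defer_grid$case, defer_grid$modality)),
    "deferral_study.csv")

  full <- generate_full_study(seed = 42)
  path <- file.path(out_dir, "design_scale.csv")
  write_score_table(full$dataset, path)
  files <- c(files, path)

  manifest <- list(
    taub_04.csv = list(expected = list(tau_b_continuous = 0.4),
                       note = "pairwise R1 vs R2, optical"),
    pa75.csv = list(expected = list(percent_overall = 75),
                    note = "pairwise R1 vs R2, optical, categorical"),
    perfect.csv = list(expected = list(tau_b_continuous = 1,
                                       percent_overall = 100)),
    minimal.csv = list(expected = list(n_records = 3, n_deferred = 1)),
    deferral_study.csv = list(expected = list(
      excluded_cases = "C5", retained_cases = 4),
      note = "C5 deferred by all 4 readers; C4 has one residual deferral"),
    design_scale.csv = list(expected = list(
      n_records = 8 * 2 * (25 + 97) * 2),
      note = "8 readers x 2 modalities x (25 WS + 97 TMA) x 2 biomarkers,
generated with seed 42"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, file.path(out_dir, "manifest.json")))
}
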