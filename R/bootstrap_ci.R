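#' Configure the two-way percentile bootstrap
#'
#' Confidence intervals account for both sources of variability in a
#' multi-reader multi-case study: readers and cases are resampled
#' independently with replacement, the estimand is recomputed on each
#' resampled study, and the CI is the percentile interval of the replicate
#' distribution (inverse-ECDF quantiles). Pairs formed from two copies of
#' the same resampled reader are excluded from pairwise averages (they
#' agree trivially); a replicate whose reader draw leaves no valid pair is
#' redrawn up to `max_redraws` times and then dropped.
#'
#' @param B Number of bootstrap replicates.
#' @param alpha Two-sided error rate; the CI spans the `alpha/2` and
#'   `1 - alpha/2` replicate quantiles.
#' @param seed Global RNG seed; every estimand derives its own substream
#'   from (`seed`, statistic name), so adding a statistic never perturbs
#'   the replicates of another.
#' @param resample_readers,resample_cases Toggle either resampling axis;
#'   with both `FALSE` the CI collapses to the point estimate.
#' @param max_redraws Retry cap for degenerate reader draws.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(B = 1000, alpha = 0.05, seed = 1,
                             resample_readers = TRUE, resample_cases = TRUE,
                             max_redraws = 100) {
  stopifnot(B >= 1, alpha > 0, alpha < 1, max_redraws >= 0)
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 resample_readers = isTRUE(resample_readers),
                 resample_cases = isTRUE(resample_cases),
                 max_redraws = as.integer(max_redraws)),
            class = "bootstrap_config")
}

#' Draw one bootstrap resample of readers and cases
#'
#' Readers and cases are drawn independently with replacement, preserving
#' the original sizes; duplicated indices are carried as distinct resampled
#' units. Uses the current RNG state.
#'
#' @param n_readers,n_cases Numbers of readers and cases.
#' @param resample_readers,resample_cases When `FALSE`, the corresponding
#'   index map is the identity.
#' @return List with integer index vectors `readers` and `cases`.
#' @export
resample_study <- function(n_readers, n_cases, resample_readers = TRUE,
                           resample_cases = TRUE) {
  list(readers = if (resample_readers)
         sample.int(n_readers, n_readers, replace = TRUE) else
           seq_len(n_readers),
       cases = if (resample_cases)
         sample.int(n_cases, n_cases, replace = TRUE) else seq_len(n_cases))
}

# deterministic substream seed from (seed, statistic name); < 2^31
.substream_seed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u)) %% 1048573
  as.integer((as.double(seed) %% 65011 + 1) * 32749 + h)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# inverse-ECDF (type 1) percentile interval of the defined replicates
.percentile_ci <- function(v, alpha) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(c(NA_real_, NA_real_))
  stats::quantile(v, c(alpha / 2, 1 - alpha / 2), type = 1, names = FALSE)
}

# Core replicate engine. statfun(reader_idx, case_idx) returns a numeric
# vector of length m (NA components = undefined for that replicate). The
# point estimate is statfun on the identity maps. A replicate needs at
# least `min_distinct` distinct original readers.
.boot_core <- function(statfun, n_readers, n_cases, orig_readers, config,
                       statistic_name, m, min_distinct = 2) {
  point <- statfun(seq_len(n_readers), seq_len(n_cases))
  reps <- matrix(NA_real_, config$B, m)
  dropped <- 0L
  .with_seed(.substream_seed(config$seed, statistic_name), {
    for (b in seq_len(config$B)) {
      ok <- FALSE
      for (try in seq_len(config$max_redraws + 1L)) {
        idx <- resample_study(n_readers, n_cases, config$resample_readers,
                              config$resample_cases)
        if (!config$resample_readers ||
            length(unique(orig_readers[idx$readers])) >= min_distinct) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        dropped <- dropped + 1L
        next
      }
      reps[b, ] <- statfun(idx$readers, idx$cases)
    }
  })
  n_defined <- colSums(!is.na(reps))
  ci <- matrix(NA_real_, 2, m)
  for (j in seq_len(m))
    if (n_defined[j] >= config$B / 2)   # >50% undefined: CI stays undefined
      ci[, j] <- .percentile_ci(reps[, j], config$alpha)
  list(point = point, replicates = reps, ci_low = ci[1, ], ci_high = ci[2, ],
       n_defined = n_defined, dropped_replicates = dropped)
}

#' Bootstrap confidence interval for a named agreement estimand
#'
#' Recomputes an agreement estimand (see [interobserver_agreement()],
#' [intermodality_agreement()], [agreement_difference()]) on `B` resampled
#' studies and attaches the percentile interval. The point estimate always
#' comes from the original data; for modality differences both arms use
#' the same resample (paired).
#'
#' @param dataset A filtered `study_dataset`.
#' @param estimand List naming the quantity: `biomarker`,
#'   `specimen_format`, `comparison` (one of `"interobserver-optical"`,
#'   `"interobserver-digital"`, `"intermodality"`, `"difference"`),
#'   `metric` (`"tau_b"`, `"percent_overall"`, `"percent_category"`),
#'   `score_type` (`"continuous"` or `"categorical"`), and `category` for
#'   the per-category metric.
#' @param config A [bootstrap_config()].
#' @return An `agreement_estimate` with `point`, `ci_low`, `ci_high`,
#'   `n_units`, `replicates` and replicate accounting.
#' @export
bootstrap_ci <- function(dataset, estimand, config = bootstrap_config()) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(config, "bootstrap_config"))
  est <- .normalize_estimand(estimand)
  mats <- .stratum_matrices(dataset, est$biomarker, est$specimen_format)
  kernel <- .estimand_kernel(mats, est)
  boot <- .boot_core(kernel$statfun, length(mats$readers),
                     length(mats$cases), seq_along(mats$readers), config,
                     kernel$name, 1L, kernel$min_distinct)
  detail <- .point_detail(mats, est)
  structure(
    list(metric = est$metric, score_type = est$score_type,
         category = est$category, biomarker = est$biomarker,
         specimen_format = est$specimen_format, comparison = est$comparison,
         point = unname(boot$point), ci_low = unname(boot$ci_low),
         ci_high = unname(boot$ci_high), alpha = config$alpha,
         n_units = detail$n_units, n_units_defined = detail$n_units_defined,
         n_cases_median = detail$n_cases_median,
         per_unit = detail$per_unit,
         replicates = boot$replicates[, 1],
         n_replicates_defined = unname(boot$n_defined),
         dropped_replicates = boot$dropped_replicates),
    class = "agreement_estimate")
}

.normalize_estimand <- function(estimand) {
  est <- as.list(estimand)
  est$comparison <- match.arg(est$comparison,
                              c("interobserver-optical",
                                "interobserver-digital", "intermodality",
                                "difference"))
  est$metric <- match.arg(est$metric,
                          c("tau_b", "percent_overall", "percent_category"))
  est$score_type <- if (is.null(est$score_type)) {
    if (est$metric == "tau_b") "continuous" else "categorical"
  } else match.arg(est$score_type, c("continuous", "categorical"))
  if (est$metric != "percent_category") est$category <- NULL
  else if (is.null(est$category))
    stop("percent_category needs a category", call. = FALSE)
  est
}

#' @export
print.agreement_estimate <- function(x, ...) {
  lbl <- paste0(x$metric,
                if (!is.null(x$category)) paste0("[", x$category, "]"),
                " (", x$score_type, ")")
  cat(sprintf("<agreement_estimate> %s / %s, %s, %s\n", x$biomarker,
              x$specimen_format, x$comparison, lbl))
  if (is.na(x$point)) {
    cat("  undefined\n")
  } else {
    ci <- if (!is.null(x$ci_low) && !is.na(x$ci_low))
      sprintf(" [%.3f, %.3f]", x$ci_low, x$ci_high) else ""
    cat(sprintf("  point = %.3f%s (units: %d defined of %d)\n", x$point, ci,
                x$n_units_defined, x$n_units))
  }
  invisible(x)
}
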