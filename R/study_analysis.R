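# Score matrices (readers x cases) per stratum: the workhorse layout for
# pairwise metrics and bootstrap resampling. Categorical scores are coded
# as integer positions on the scale.
.stratum_matrices <- function(dataset, biomarker, specimen_format) {
  key <- paste(biomarker, specimen_format, sep = ".")
  cases <- dataset$cases[[key]]
  if (is.null(cases))
    stop(sprintf("no records for stratum (%s, %s)", biomarker,
                 specimen_format), call. = FALSE)
  rec <- dataset$records
  sel <- rec$biomarker == biomarker & rec$specimen_format == specimen_format
  rec <- rec[sel, , drop = FALSE]
  readers <- dataset$readers[dataset$readers %in% rec$reader_id]
  scale <- dataset$scales[[biomarker]]
  R <- length(readers); N <- length(cases)
  cont <- list(); catm <- list()
  for (mod in MODALITIES) {
    m <- rec[rec$modality == mod, , drop = FALSE]
    cm <- matrix(NA_real_, R, N, dimnames = list(readers, cases))
    km <- matrix(NA_integer_, R, N, dimnames = list(readers, cases))
    if (nrow(m)) {
      idx <- match(m$reader_id, readers) + (match(m$case_id, cases) - 1L) * R
      cm[idx] <- m$continuous_score
      km[idx] <- match(m$categorical_score, scale$categories)
    }
    cont[[mod]] <- cm; catm[[mod]] <- km
  }
  list(readers = readers, cases = cases, scale = scale, cont = cont,
       cat = catm)
}

# Mean of fun() over unordered reader pairs under resampled indices.
# Pairs of two copies of the same original reader are skipped; pairs with
# fewer than 2 jointly scored cases, and undefined metric components, drop
# out of the average per component.
.interobs_stat <- function(mat, ridx, cidx, orig, fun, m, detail = FALSE) {
  R <- length(ridx)
  total <- numeric(m); count <- numeric(m)
  overlaps <- integer(0)
  for (p in seq_len(R - 1)) {
    xp <- mat[ridx[p], cidx]
    for (q in (p + 1):R) {
      if (orig[ridx[p]] == orig[ridx[q]]) next
      yq <- mat[ridx[q], cidx]
      keep <- !is.na(xp) & !is.na(yq)
      nk <- sum(keep)
      if (detail) overlaps <- c(overlaps, nk)
      if (nk < 2) next
      v <- fun(xp[keep], yq[keep])
      def <- !is.na(v)
      total[def] <- total[def] + v[def]
      count[def] <- count[def] + 1
    }
  }
  out <- ifelse(count > 0, total / count, NA_real_)
  if (!detail) return(out)
  list(mean = out, n_units = R * (R - 1) / 2, n_units_defined = count,
       n_cases_median = if (length(overlaps)) stats::median(overlaps) else
         NA_real_)
}

# Mean of fun() over readers, each compared against themselves across the
# two modality matrices.
.intermod_stat <- function(mat_a, mat_b, ridx, cidx, fun, m,
                           detail = FALSE) {
  R <- length(ridx)
  total <- numeric(m); count <- numeric(m)
  overlaps <- integer(0)
  for (r in seq_len(R)) {
    x <- mat_a[ridx[r], cidx]
    y <- mat_b[ridx[r], cidx]
    keep <- !is.na(x) & !is.na(y)
    nk <- sum(keep)
    if (detail) overlaps <- c(overlaps, nk)
    if (nk < 2) next
    v <- fun(x[keep], y[keep])
    def <- !is.na(v)
    total[def] <- total[def] + v[def]
    count[def] <- count[def] + 1
  }
  out <- ifelse(count > 0, total / count, NA_real_)
  if (!detail) return(out)
  list(mean = out, n_units = R, n_units_defined = count,
       n_cases_median = if (length(overlaps)) stats::median(overlaps) else
         NA_real_)
}

# scalar metric kernel for one estimand
.metric_fun <- function(est, K) {
  switch(est$metric,
         tau_b = .tau_value,
         percent_overall = function(x, y) 100 * sum(x == y) / length(x),
         percent_category = {
           k <- est$category_index
           function(x, y) {
             den <- sum(x == k | y == k)
             if (den == 0) NA_real_ else 100 * sum(x == k & y == k) / den
           }
         })
}

.estimand_matrix <- function(mats, est, modality) {
  if (est$score_type == "continuous") mats$cont[[modality]] else
    mats$cat[[modality]]
}

# statfun(ridx, cidx) + substream name for one estimand
.estimand_kernel <- function(mats, est) {
  K <- length(mats$scale$categories)
  if (est$metric == "percent_category") {
    est$category_index <- match(est$category, mats$scale$categories)
    if (is.na(est$category_index))
      stop(sprintf("unknown category '%s'", est$category), call. = FALSE)
    if (est$score_type == "continuous")
      stop("percent agreement is defined on categorical scores", call. = FALSE)
  }
  fun <- .metric_fun(est, K)
  orig <- seq_along(mats$readers)
  name <- paste(mats$scale$biomarker, est$specimen_format, est$comparison,
                est$metric, est$score_type,
                if (!is.null(est$category)) est$category else "", sep = "/")
  if (est$comparison == "intermodality") {
    A <- .estimand_matrix(mats, est, "optical")
    B <- .estimand_matrix(mats, est, "digital")
    return(list(statfun = function(ridx, cidx)
      .intermod_stat(A, B, ridx, cidx, fun, 1L), name = name,
      min_distinct = 1L))
  }
  if (est$comparison == "difference") {
    A <- .estimand_matrix(mats, est, "optical")
    B <- .estimand_matrix(mats, est, "digital")
    return(list(statfun = function(ridx, cidx)
      .interobs_stat(A, ridx, cidx, orig, fun, 1L) -
        .interobs_stat(B, ridx, cidx, orig, fun, 1L),
      name = name, min_distinct = 2L))
  }
  mod <- sub("interobserver-", "", est$comparison)
  A <- .estimand_matrix(mats, est, mod)
  list(statfun = function(ridx, cidx)
    .interobs_stat(A, ridx, cidx, orig, fun, 1L), name = name,
    min_distinct = 2L)
}

# per-unit values and counts at the identity resample
.point_detail <- function(mats, est) {
  K <- length(mats$scale$categories)
  if (est$metric == "percent_category")
    est$category_index <- match(est$category, mats$scale$categories)
  fun <- .metric_fun(est, K)
  orig <- seq_along(mats$readers)
  id_r <- seq_along(mats$readers); id_c <- seq_along(mats$cases)
  if (est$comparison == "intermodality") {
    A <- .estimand_matrix(mats, est, "optical")
    B <- .estimand_matrix(mats, est, "digital")
    per <- vapply(id_r, function(r) {
      x <- A[r, ]; y <- B[r, ]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 2) NA_real_ else fun(x[keep], y[keep])
    }, numeric(1))
    names(per) <- mats$readers
    d <- .intermod_stat(A, B, id_r, id_c, fun, 1L, detail = TRUE)
  } else {
    mod <- if (est$comparison == "difference") "optical" else
      sub("interobserver-", "", est$comparison)
    A <- .estimand_matrix(mats, est, mod)
    R <- length(id_r)
    per <- c(); nm <- c()
    for (p in seq_len(max(R - 1, 0))) for (q in (p + 1):R) {
      x <- A[p, ]; y <- A[q, ]
      keep <- !is.na(x) & !is.na(y)
      per <- c(per, if (sum(keep) < 2) NA_real_ else fun(x[keep], y[keep]))
      nm <- c(nm, paste(mats$readers[p], mats$readers[q], sep = "|"))
    }
    names(per) <- nm
    d <- .interobs_stat(A, id_r, id_c, orig, fun, 1L, detail = TRUE)
  }
  list(per_unit = per, n_units = d$n_units,
       n_units_defined = unname(d$n_units_defined),
       n_cases_median = d$n_cases_median)
}

.make_estimate <- function(est, detail, point, ci_low = NA_real_,
                           ci_high = NA_real_, n_replicates_defined = NULL,
                           alpha = NA_real_) {
  structure(
    list(metric = est$metric, score_type = est$score_type,
         category = est$category, biomarker = est$biomarker,
         specimen_format = est$specimen_format, comparison = est$comparison,
         point = unname(point), ci_low = unname(ci_low),
         ci_high = unname(ci_high), alpha = alpha,
         n_units = detail$n_units,
         n_units_defined = detail$n_units_defined,
         n_cases_median = detail$n_cases_median, per_unit = detail$per_unit,
         n_replicates_defined = n_replicates_defined),
    class = "agreement_estimate")
}

#' Interobserver agreement: averaged over reader pairs
#'
#' Computes the chosen metric on every unordered pair of readers using the
#' same modality, restricted per pair to jointly scored cases, and averages
#' the defined pair values (unweighted). Pairs with fewer than 2 complete
#' cases, or an undefined metric (e.g. tau-b with a constant vector), are
#' dropped from the average and counted.
#'
#' @param dataset A filtered `study_dataset`.
#' @param biomarker,specimen_format Stratum selectors.
#' @param modality `"optical"` or `"digital"`.
#' @param metric `"tau_b"`, `"percent_overall"` or `"percent_category"`.
#' @param score_type `"continuous"` or `"categorical"`; percent metrics
#'   require categorical.
#' @param category Category label for `percent_category`.
#' @param boot Optional [bootstrap_config()]; when supplied the estimate
#'   carries a percentile CI.
#' @return An `agreement_estimate` with the per-pair values in `per_unit`.
#' @export
interobserver_agreement <- function(dataset, biomarker, specimen_format,
                                    modality = c("optical", "digital"),
                                    metric = "tau_b",
                                    score_type = NULL, category = NULL,
                                    boot = NULL) {
  modality <- match.arg(modality)
  est <- .normalize_estimand(list(
    biomarker = biomarker, specimen_format = specimen_format,
    comparison = paste0("interobserver-", modality), metric = metric,
    score_type = score_type, category = category))
  .estimate_one(dataset, est, boot)
}

#' Intermodality agreement: averaged over readers
#'
#' Per reader, computes the chosen metric between that reader's optical and
#' digital score vectors (jointly scored cases only), then averages the
#' defined per-reader values.
#'
#' @inheritParams interobserver_agreement
#' @return An `agreement_estimate` with the per-reader values in `per_unit`.
#' @export
intermodality_agreement <- function(dataset, biomarker, specimen_format,
                                    metric = "tau_b", score_type = NULL,
                                    category = NULL, boot = NULL) {
  est <- .normalize_estimand(list(
    biomarker = biomarker, specimen_format = specimen_format,
    comparison = "intermodality", metric = metric, score_type = score_type,
    category = category))
  .estimate_one(dataset, est, boot)
}

#' Optical-minus-digital difference in interobserver agreement
#'
#' Point estimate is interobserver agreement under optical minus the same
#' under digital. With a bootstrap config the CI is paired: each replicate
#' applies one reader/case resample to both modality arms.
#'
#' @inheritParams interobserver_agreement
#' @return An `agreement_estimate` for the difference.
#' @export
agreement_difference <- function(dataset, biomarker, specimen_format,
                                 metric = "tau_b", score_type = NULL,
                                 category = NULL, boot = NULL) {
  est <- .normalize_estimand(list(
    biomarker = biomarker, specimen_format = specimen_format,
    comparison = "difference", metric = metric, score_type = score_type,
    category = category))
  .estimate_one(dataset, est, boot)
}

.estimate_one <- function(dataset, est, boot) {
  if (!is.null(boot)) return(bootstrap_ci(dataset, est, boot))
  mats <- .stratum_matrices(dataset, est$biomarker, est$specimen_format)
  kernel <- .estimand_kernel(mats, est)
  point <- kernel$statfun(seq_along(mats$readers), seq_along(mats$cases))
  .make_estimate(est, .point_detail(mats, est), point)
}

#' Run the full agreement analysis on a study dataset
#'
#' Applies the cell-sufficiency rule and the majority-deferral exclusion,
#' then computes, per (biomarker, specimen format) stratum: interobserver
#' agreement per modality with the optical-minus-digital difference, and
#' intermodality agreement, for Kendall's tau-b on continuous and
#' categorical scores, overall percent agreement, and per-category percent
#' agreement; plus pooled disagreement cross-tabulations and the
#' possible-score accounting. Every estimate carries a two-way percentile
#' bootstrap CI; within a stratum each metric family shares one paired set
#' of resamples drawn from its own seed substream.
#'
#' Tau-b on categorical scores is reported only for scales with at least 3
#' categories; on a binary scale (Ki-67) the count of tied pairs dominates
#' and the statistic is not informative, so it is marked not-reported.
#'
#' @param dataset A `study_dataset` (unfiltered; filtering happens here).
#' @param boot A [bootstrap_config()].
#' @param majority_rule `"pooled"` (deferral counted across modalities) or
#'   `"per_modality"`; see [exclude_majority_deferred()].
#' @return A list of class `study_report`: `meta`, `exclusions`,
#'   `consistency`, and `strata` (one entry per biomarker x format).
#' @export
build_report <- function(dataset, boot = bootstrap_config(),
                         majority_rule = c("pooled", "per_modality")) {
  stopifnot(inherits(dataset, "study_dataset"))
  majority_rule <- match.arg(majority_rule)
  ds <- apply_sufficiency_rule(dataset)
  fx <- exclude_majority_deferred(ds, pool_modalities =
                                    majority_rule == "pooled")
  ds <- fx$dataset
  strata_keys <- names(ds$cases)
  ord <- order(sub("\\..*", "", strata_keys),
               match(sub(".*\\.", "", strata_keys), FORMATS))
  strata <- list()
  for (key in strata_keys[ord]) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    strata[[key]] <- .analyze_stratum(ds, parts[1], parts[2], boot)
  }
  structure(
    list(meta = list(n_readers = length(ds$readers), readers = ds$readers,
                     B = boot$B, alpha = boot$alpha, seed = boot$seed,
                     majority_rule = majority_rule),
         exclusions = unclass(fx$report),
         consistency = consistency_report(ds),
         strata = strata),
    class = "study_report")
}

# Each metric family (tau-b continuous / tau-b categorical / percent
# agreement, interobserver or intermodality) shares one replicate stream
# per stratum: all comparisons and categories in the family are recomputed
# on the same resamples, which also makes the modality difference paired.
.analyze_stratum <- function(ds, bm, fmt, boot) {
  mats <- .stratum_matrices(ds, bm, fmt)
  K <- length(mats$scale$categories)
  cats <- mats$scale$categories
  report_cat_tau <- K >= 3
  orig <- seq_along(mats$readers)
  R <- length(mats$readers)
  N <- length(mats$cases)
  pa_fun <- function(x, y) .pa_values(x, y, K)

  boot_io <- function(mat_o, mat_d, fun, m, family) {
    statfun <- function(ridx, cidx) {
      o <- .interobs_stat(mat_o, ridx, cidx, orig, fun, m)
      d <- .interobs_stat(mat_d, ridx, cidx, orig, fun, m)
      c(o, d, o - d)
    }
    .boot_core(statfun, R, N, orig, boot,
               paste(bm, fmt, family, sep = "/"), 3L * m, 2L)
  }
  boot_im <- function(mat_o, mat_d, fun, m, family) {
    statfun <- function(ridx, cidx)
      .intermod_stat(mat_o, mat_d, ridx, cidx, fun, m)
    .boot_core(statfun, R, N, orig, boot,
               paste(bm, fmt, family, sep = "/"), m, 1L)
  }
  mk_est <- function(bc, j, comparison, metric, score_type,
                     category = NULL) {
    est <- .normalize_estimand(list(
      biomarker = bm, specimen_format = fmt, comparison = comparison,
      metric = metric, score_type = score_type, category = category))
    .make_estimate(est, .point_detail(mats, est), bc$point[j],
                   bc$ci_low[j], bc$ci_high[j], bc$n_defined[j],
                   boot$alpha)
  }
  io_comps <- c("interobserver-optical", "interobserver-digital",
                "difference")
  mk_io_set <- function(bc, metric, score_type, category = NULL,
                        m = 1L, offset = 0L) {
    out <- lapply(seq_len(3), function(i)
      mk_est(bc, (i - 1L) * m + offset + 1L, io_comps[i], metric,
             score_type, category))
    names(out) <- c("optical", "digital", "difference")
    out
  }
  not_reported <- list(status = "not_reported",
                       reason = "binary scale: tau-b dominated by ties")

  bc_tau_cont <- boot_io(mats$cont$optical, mats$cont$digital, .tau_value,
                         1L, "interobserver_tau_continuous")
  bc_tau_cat <- if (report_cat_tau)
    boot_io(mats$cat$optical, mats$cat$digital, .tau_value, 1L,
            "interobserver_tau_categorical")
  bc_pa <- boot_io(mats$cat$optical, mats$cat$digital, pa_fun, K + 1L,
                   "interobserver_percent_agreement")
  interobserver <- list(
    tau_b_continuous = mk_io_set(bc_tau_cont, "tau_b", "continuous"),
    tau_b_categorical = if (report_cat_tau)
      mk_io_set(bc_tau_cat, "tau_b", "categorical") else not_reported,
    percent_overall = mk_io_set(bc_pa, "percent_overall", "categorical",
                                m = K + 1L),
    percent_category = stats::setNames(lapply(seq_len(K), function(k)
      mk_io_set(bc_pa, "percent_category", "categorical", cats[k],
                m = K + 1L, offset = k)), cats))

  bm_tau_cont <- boot_im(mats$cont$optical, mats$cont$digital, .tau_value,
                         1L, "intermodality_tau_continuous")
  bm_tau_cat <- if (report_cat_tau)
    boot_im(mats$cat$optical, mats$cat$digital, .tau_value, 1L,
            "intermodality_tau_categorical")
  bm_pa <- boot_im(mats$cat$optical, mats$cat$digital, pa_fun, K + 1L,
                   "intermodality_percent_agreement")
  intermodality <- list(
    tau_b_continuous = mk_est(bm_tau_cont, 1L, "intermodality", "tau_b",
                              "continuous"),
    tau_b_categorical = if (report_cat_tau)
      mk_est(bm_tau_cat, 1L, "intermodality", "tau_b", "categorical") else
        not_reported,
    percent_overall = mk_est(bm_pa, 1L, "intermodality", "percent_overall",
                             "categorical"),
    percent_category = stats::setNames(lapply(seq_len(K), function(k)
      mk_est(bm_pa, k + 1L, "intermodality", "percent_category",
             "categorical", cats[k])), cats))

  list(biomarker = bm, specimen_format = fmt,
       n_readers = length(mats$readers),
       n_cases_retained = length(mats$cases),
       interobserver = interobserver,
       intermodality = intermodality,
       crosstabs = .stratum_crosstabs(mats),
       accounting = .stratum_accounting(ds, bm, fmt, mats))
}

# pooled disagreement cross-tabs: intermodality summed over readers
# (rows = optical), interobserver summed over ordered reader pairs
.stratum_crosstabs <- function(mats) {
  cats <- mats$scale$categories
  K <- length(cats)
  pool <- function(a, b, pairs) {
    counts <- matrix(0, K, K, dimnames = list(cats, cats))
    for (pq in pairs) {
      x <- a[pq[1], ]; y <- b[pq[2], ]
      keep <- !is.na(x) & !is.na(y)
      if (!any(keep)) next
      counts <- counts + unclass(table(factor(x[keep], levels = seq_len(K)),
                                       factor(y[keep], levels = seq_len(K))))
    }
    totals <- rowSums(counts)
    list(categories = cats, counts = counts,
         row_percent = 100 * counts / ifelse(totals == 0, NA, totals))
  }
  R <- nrow(mats$cat$optical)
  self_pairs <- lapply(seq_len(R), function(r) c(r, r))
  ordered_pairs <- list()
  for (p in seq_len(R)) for (q in seq_len(R))
    if (p != q) ordered_pairs[[length(ordered_pairs) + 1]] <- c(p, q)
  list(intermodality = pool(mats$cat$optical, mats$cat$digital, self_pairs),
       interobserver_optical = pool(mats$cat$optical, mats$cat$optical,
                                    ordered_pairs),
       interobserver_digital = pool(mats$cat$digital, mats$cat$digital,
                                    ordered_pairs))
}

.stratum_accounting <- function(ds, bm, fmt, mats) {
  rec <- ds$records
  sel <- rec$biomarker == bm & rec$specimen_format == fmt
  acct <- list(n_readers = length(mats$readers),
               n_cases = length(mats$cases),
               possible_per_modality = length(mats$readers) *
                 length(mats$cases))
  for (m in MODALITIES)
    acct[[paste0("deferred_", m)]] <-
      sum(rec$deferred[sel & rec$modality == m])
  acct
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d readers, B = %d, alpha = %g\n",
              x$meta$n_readers, x$meta$B, x$meta$alpha))
  for (s in x$strata) {
    cat(sprintf("-- %s / %s (%d cases retained) --\n", s$biomarker,
                s$specimen_format, s$n_cases_retained))
    tc <- s$interobserver$tau_b_continuous
    cat(sprintf("  interobserver tau-b (cont): optical %.2f [%.2f, %.2f], digital %.2f [%.2f, %.2f]\n",
                tc$optical$point, tc$optical$ci_low, tc$optical$ci_high,
                tc$digital$point, tc$digital$ci_low, tc$digital$ci_high))
    imc <- s$intermodality$tau_b_continuous
    cat(sprintf("  intermodality tau-b (cont): %.2f [%.2f, %.2f]\n",
                imc$point, imc$ci_low, imc$ci_high))
    pa <- s$interobserver$percent_overall
    cat(sprintf("  interobserver percent agreement: optical %.1f, digital %.1f\n",
                pa$optical$point, pa$digital$point))
  }
  invisible(x)
}
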