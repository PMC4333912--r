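#' Remove cases deferred by a majority of readers
#'
#' A reader may defer a score when a sample is inadequate (poorly prepared
#' tissue, too little tumor). Cases deferred by strictly more than half of
#' the readers in a (biomarker, specimen format) stratum are removed from
#' analysis entirely; remaining deferrals are treated as missing data.
#'
#' With `pool_modalities = TRUE` (default) a reader counts as deferring a
#' case if they deferred it under either modality, giving one exclusion set
#' per (biomarker, format). With `pool_modalities = FALSE` the majority is
#' assessed within each modality separately and a case is excluded when a
#' strict majority deferred it in any single modality.
#'
#' @param dataset A `study_dataset`.
#' @param pool_modalities Pool deferrals across modalities when counting the
#'   majority (default `TRUE`).
#' @return List with `dataset` (cases removed) and `report`, an
#'   `exclusion_report` listing each removal and the residual deferral
#'   accounting per stratum (deferred / possible, where possible = readers
#'   x retained cases).
#' @export
exclude_majority_deferred <- function(dataset, pool_modalities = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) stop("dataset has no records", call. = FALSE)
  excluded <- list()
  for (key in names(dataset$cases)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    bm <- parts[1]; fmt <- parts[2]
    sel <- rec$biomarker == bm & rec$specimen_format == fmt
    sub <- rec[sel, , drop = FALSE]
    readers <- unique(sub$reader_id)
    n_readers <- length(readers)
    for (cs in dataset$cases[[key]]) {
      rows <- sub[sub$case_id == cs, , drop = FALSE]
      if (pool_modalities) {
        n_defer <- length(unique(rows$reader_id[rows$deferred]))
        hit <- n_defer > n_readers / 2
      } else {
        per_mod <- vapply(MODALITIES, function(m)
          sum(rows$deferred[rows$modality == m]), numeric(1))
        n_defer <- max(per_mod)
        hit <- any(per_mod > n_readers / 2)
      }
      if (hit)
        excluded[[length(excluded) + 1]] <- data.frame(
          biomarker = bm, specimen_format = fmt, case_id = cs,
          deferral_count = n_defer, reader_count = n_readers,
          reason = "majority_deferred", stringsAsFactors = FALSE)
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(biomarker = character(), specimen_format = character(),
               case_id = character(), deferral_count = numeric(),
               reader_count = numeric(), reason = character(),
               stringsAsFactors = FALSE)

  if (nrow(excluded)) {
    drop_key <- paste(excluded$biomarker, excluded$specimen_format,
                      excluded$case_id)
    keep <- !(paste(rec$biomarker, rec$specimen_format, rec$case_id) %in%
                drop_key)
    dataset <- .new_study_dataset(rec[keep, , drop = FALSE], dataset$scales)
  }

  report <- structure(
    list(excluded_cases = excluded,
         retained_cases = vapply(dataset$cases, length, integer(1)),
         deferral_counts = .deferral_accounting(dataset),
         pool_modalities = pool_modalities),
    class = "exclusion_report")
  list(dataset = dataset, report = report)
}

# residual deferral counts per (biomarker, format, modality) after exclusion
.deferral_accounting <- function(dataset) {
  rec <- dataset$records
  out <- list()
  for (key in names(dataset$cases)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sel <- rec$biomarker == parts[1] & rec$specimen_format == parts[2]
    readers <- unique(rec$reader_id[sel])
    n_cases <- length(dataset$cases[[key]])
    for (m in MODALITIES) {
      ms <- sel & rec$modality == m
      if (!any(ms)) next
      out[[length(out) + 1]] <- data.frame(
        biomarker = parts[1], specimen_format = parts[2], modality = m,
        deferred = sum(rec$deferred[ms]),
        possible = length(readers) * n_cases, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(biomarker = character(), specimen_format = character(),
               modality = character(), deferred = numeric(),
               possible = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  if (nrow(x$excluded_cases) == 0) {
    cat("  no cases excluded\n")
  } else {
    for (i in seq_len(nrow(x$excluded_cases)))
      with(x$excluded_cases[i, ],
           cat(sprintf("  excluded %s (%s, %s): deferred by %d of %d readers\n",
                       case_id, biomarker, specimen_format, deferral_count,
                       reader_count)))
  }
  d <- x$deferral_counts
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s %s %s: %d of %d possible scores deferred\n",
                d$biomarker[i], d$specimen_format[i], d$modality[i],
                d$deferred[i], d$possible[i]))
  invisible(x)
}

#' Mask Ki-67 scores recorded without enough tumor cells
#'
#' Ki-67 scores are evaluable only with a sufficient number of tumor cells.
#' Records flagged `sufficient_cells = FALSE` keep their row but have both
#' scores set to missing, so downstream they behave exactly like deferrals.
#' Records for cut-point biomarkers (HER2) are untouched.
#'
#' @param dataset A `study_dataset`.
#' @return The dataset with insufficient Ki-67 scores masked.
#' @export
apply_sufficiency_rule <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  thresholded <- names(Filter(function(s) !is.null(s$positivity_threshold),
                              dataset$scales))
  mask <- rec$biomarker %in% thresholded &
    !is.na(rec$sufficient_cells) & !rec$sufficient_cells
  rec$categorical_score[mask] <- NA_character_
  rec$continuous_score[mask] <- NA_integer_
  dataset$records <- rec
  dataset
}

#' Align two scoring units on their jointly scored cases
#'
#' A unit is one (reader, modality) column of the study: the same reader
#' under two modalities for intermodality comparisons, or two readers under
#' one modality for interobserver comparisons. Returns the two score
#' vectors restricted to cases scored (non-missing) by both units, in the
#' dataset's case order.
#'
#' @param dataset A `study_dataset`.
#' @param unit_a,unit_b Lists with elements `reader` and `modality`.
#' @param biomarker,specimen_format Stratum selectors.
#' @param score_type `"continuous"` (numeric vectors) or `"categorical"`
#'   (character vectors).
#' @return List with `x`, `y`, `cases`, `n`, and `ok` (`FALSE` when fewer
#'   than 2 complete pairs remain, in which case downstream metrics report
#'   undefined rather than a number).
#' @export
pairwise_complete <- function(dataset, unit_a, unit_b, biomarker,
                              specimen_format,
                              score_type = c("continuous", "categorical")) {
  stopifnot(inherits(dataset, "study_dataset"))
  score_type <- match.arg(score_type)
  key <- paste(biomarker, specimen_format, sep = ".")
  cases <- dataset$cases[[key]]
  if (is.null(cases))
    stop(sprintf("no records for stratum (%s, %s)", biomarker,
                 specimen_format), call. = FALSE)
  col <- if (score_type == "continuous") "continuous_score" else
    "categorical_score"
  pull <- function(unit) {
    rec <- dataset$records
    sel <- rec$biomarker == biomarker & rec$specimen_format ==
      specimen_format & rec$reader_id == unit$reader &
      rec$modality == unit$modality
    if (!any(sel))
      stop(sprintf("unit (%s, %s) has no records in stratum (%s, %s)",
                   unit$reader, unit$modality, biomarker, specimen_format),
           call. = FALSE)
    v <- rep(if (score_type == "continuous") NA_real_ else NA_character_,
             length(cases))
    v[match(rec$case_id[sel], cases)] <- rec[[col]][sel]
    v
  }
  x <- pull(unit_a)
  y <- pull(unit_b)
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], cases = cases[keep], n = sum(keep),
       ok = sum(keep) >= 2)
}
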