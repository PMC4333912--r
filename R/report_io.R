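#' Write a study report to disk
#'
#' Emits `report.json` (machine-readable, full precision),
#' `exclusions.json`, `run.log` (parameters and counts), and one rounded
#' CSV per summary table under `tables/`: for each biomarker an
#' interobserver tau-b table, an interobserver percent-agreement table
#' (overall plus category rows), and the intermodality analogues. Tau
#' values are rounded to 2 decimals and percents to 1 in the CSVs;
#' `report.json` keeps full precision. `report.json` contains no
#' timestamps, so repeated runs with the same seed are byte-identical.
#'
#' @param report A `study_report` from [build_report()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(file.path(outdir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(.report_payload(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(report$exclusions, file.path(outdir,
                                                    "exclusions.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  for (tab in .report_tables(report))
    utils::write.csv(tab$data,
                     file.path(outdir, "tables", paste0(tab$name, ".csv")),
                     row.names = FALSE)
  writeLines(.run_log_lines(report), file.path(outdir, "run.log"))
  invisible(outdir)
}

# strip per-unit vectors and replicate streams down to JSON-friendly lists
.report_payload <- function(report) {
  clean_est <- function(e) {
    if (!inherits(e, "agreement_estimate")) return(e)
    list(point = e$point, ci_low = e$ci_low, ci_high = e$ci_high,
         alpha = e$alpha, n_units = e$n_units,
         n_units_defined = e$n_units_defined,
         n_cases_median = e$n_cases_median,
         n_replicates_defined = e$n_replicates_defined)
  }
  walk <- function(x) {
    if (inherits(x, "agreement_estimate")) return(clean_est(x))
    if (is.list(x) && is.null(attr(x, "class"))) return(lapply(x, walk))
    x
  }
  list(meta = report$meta,
       exclusions = report$exclusions,
       consistency = list(n_inconsistent = nrow(report$consistency),
                          records = report$consistency),
       strata = lapply(report$strata, walk))
}

.fmt_round <- function(x, digits) ifelse(is.na(x), NA, round(x, digits))

.report_tables <- function(report) {
  tabs <- list()
  by_bm <- split(report$strata,
                 vapply(report$strata, function(s) s$biomarker, ""))
  for (bm in names(by_bm)) {
    strata <- by_bm[[bm]]
    tabs <- c(tabs,
              list(list(name = paste0(bm, "_interobserver_tau"),
                        data = .tab_io_tau(strata)),
                   list(name = paste0(bm, "_interobserver_pa"),
                        data = .tab_io_pa(strata)),
                   list(name = paste0(bm, "_intermodality_tau"),
                        data = .tab_im_tau(strata)),
                   list(name = paste0(bm, "_intermodality_pa"),
                        data = .tab_im_pa(strata))))
  }
  tabs
}

.tau_row <- function(set, fmt, score_type) {
  data.frame(specimen_format = fmt, score_type = score_type,
             optical = .fmt_round(set$optical$point, 2),
             optical_ci_low = .fmt_round(set$optical$ci_low, 2),
             optical_ci_high = .fmt_round(set$optical$ci_high, 2),
             digital = .fmt_round(set$digital$point, 2),
             digital_ci_low = .fmt_round(set$digital$ci_low, 2),
             digital_ci_high = .fmt_round(set$digital$ci_high, 2),
             difference = .fmt_round(set$difference$point, 2),
             difference_ci_low = .fmt_round(set$difference$ci_low, 2),
             difference_ci_high = .fmt_round(set$difference$ci_high, 2),
             stringsAsFactors = FALSE)
}

.tab_io_tau <- function(strata) {
  rows <- list()
  for (s in strata) {
    rows[[length(rows) + 1]] <-
      .tau_row(s$interobserver$tau_b_continuous, s$specimen_format,
               "continuous")
    tc <- s$interobserver$tau_b_categorical
    if (inherits(tc$optical, "agreement_estimate"))
      rows[[length(rows) + 1]] <- .tau_row(tc, s$specimen_format,
                                           "categorical")
  }
  do.call(rbind, rows)
}

.pa_row <- function(set, fmt, category) {
  data.frame(specimen_format = fmt, category = category,
             optical = .fmt_round(set$optical$point, 1),
             optical_ci_low = .fmt_round(set$optical$ci_low, 1),
             optical_ci_high = .fmt_round(set$optical$ci_high, 1),
             digital = .fmt_round(set$digital$point, 1),
             digital_ci_low = .fmt_round(set$digital$ci_low, 1),
             digital_ci_high = .fmt_round(set$digital$ci_high, 1),
             difference = .fmt_round(set$difference$point, 1),
             difference_ci_low = .fmt_round(set$difference$ci_low, 1),
             difference_ci_high = .fmt_round(set$difference$ci_high, 1),
             stringsAsFactors = FALSE)
}

.tab_io_pa <- function(strata) {
  rows <- list()
  for (s in strata) {
    rows[[length(rows) + 1]] <-
      .pa_row(s$interobserver$percent_overall, s$specimen_format, "All")
    for (k in names(s$interobserver$percent_category))
      rows[[length(rows) + 1]] <-
        .pa_row(s$interobserver$percent_category[[k]], s$specimen_format, k)
  }
  do.call(rbind, rows)
}

.im_row <- function(e, fmt, label, digits) {
  data.frame(specimen_format = fmt, measure = label,
             point = .fmt_round(e$point, digits),
             ci_low = .fmt_round(e$ci_low, digits),
             ci_high = .fmt_round(e$ci_high, digits),
             stringsAsFactors = FALSE)
}

.tab_im_tau <- function(strata) {
  rows <- list()
  for (s in strata) {
    rows[[length(rows) + 1]] <-
      .im_row(s$intermodality$tau_b_continuous, s$specimen_format,
              "continuous", 2)
    tc <- s$intermodality$tau_b_categorical
    if (inherits(tc, "agreement_estimate"))
      rows[[length(rows) + 1]] <- .im_row(tc, s$specimen_format,
                                          "categorical", 2)
  }
  do.call(rbind, rows)
}

.tab_im_pa <- function(strata) {
  rows <- list()
  for (s in strata) {
    rows[[length(rows) + 1]] <-
      .im_row(s$intermodality$percent_overall, s$specimen_format, "All", 1)
    for (k in names(s$intermodality$percent_category))
      rows[[length(rows) + 1]] <-
        .im_row(s$intermodality$percent_category[[k]], s$specimen_format,
                k, 1)
  }
  do.call(rbind, rows)
}

.run_log_lines <- function(report) {
  m <- report$meta
  lines <- c(sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("readers: %d (%s)", m$n_readers,
                     paste(m$readers, collapse = ", ")),
             sprintf("bootstrap: B = %d, alpha = %g, seed = %d", m$B,
                     m$alpha, m$seed),
             sprintf("majority rule: %s", m$majority_rule))
  ex <- report$exclusions
  if (nrow(ex$excluded_cases) == 0) {
    lines <- c(lines, "excluded cases: none")
  } else {
    lines <- c(lines, sprintf("excluded cases: %d", nrow(ex$excluded_cases)))
    for (i in seq_len(nrow(ex$excluded_cases)))
      lines <- c(lines, sprintf(
        "  %s (%s, %s): deferred by %d of %d readers",
        ex$excluded_cases$case_id[i], ex$excluded_cases$biomarker[i],
        ex$excluded_cases$specimen_format[i],
        ex$excluded_cases$deferral_count[i],
        ex$excluded_cases$reader_count[i]))
  }
  d <- ex$deferral_counts
  for (i in seq_len(nrow(d)))
    lines <- c(lines, sprintf(
      "deferred scores %s %s %s: %d of %d possible (%d readers x %d cases)",
      d$biomarker[i], d$specimen_format[i], d$modality[i], d$deferred[i],
      d$possible[i],
      d$possible[i] / ex$retained_cases[[paste(d$biomarker[i],
                                               d$specimen_format[i],
                                               sep = ".")]],
      ex$retained_cases[[paste(d$biomarker[i], d$specimen_format[i],
                               sep = ".")]]))
  c(lines, sprintf("inconsistent categorical/continuous records: %d",
                   nrow(report$consistency)))
}

#' Run the full analysis from a score CSV to an output directory
#'
#' Convenience driver: read the score table, build the report with the
#' requested bootstrap settings, and write `report.json`, the summary
#' tables, `exclusions.json` and `run.log` to `out`.
#'
#' @param scores Path to a long-format score CSV (see
#'   [read_score_table()]).
#' @param config Optional path to a JSON scale config (see
#'   [read_scales()]); defaults to the built-in HER2 + Ki-67 scales.
#' @param out Output directory.
#' @param B,alpha,seed Bootstrap settings; see [bootstrap_config()].
#' @param majority_rule `"pooled"` or `"per_modality"`.
#' @return The `study_report`, invisibly.
#' @export
run_analysis <- function(scores, config = NULL, out, B = 1000,
                         alpha = 0.05, seed = 17,
                         majority_rule = c("pooled", "per_modality")) {
  scales <- if (is.null(config)) default_scales() else read_scales(config)
  dataset <- read_score_table(scores, scales)
  report <- build_report(dataset,
                         bootstrap_config(B = B, alpha = alpha, seed = seed),
                         majority_rule = match.arg(majority_rule))
  write_report(report, out)
  invisible(report)
}
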