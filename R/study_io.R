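#' @keywords internal
"_PACKAGE"

SCORE_COLUMNS <- c("reader_id", "case_id", "modality", "biomarker",
                   "specimen_format", "categorical_score", "continuous_score",
                   "deferred", "sufficient_cells")
MODALITIES <- c("optical", "digital")
FORMATS <- c("whole_slide", "tma_core")

#' Read a long-format reader-score table from CSV
#'
#' One row per (reader, case, modality, biomarker, specimen format) with a
#' categorical score, an integer continuous score in \[0, 100\], a deferral
#' flag and (Ki-67) a cell-sufficiency flag. Booleans are serialized as
#' `true`/`false`; absent scores are empty fields.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row
#'   containing exactly the columns `reader_id, case_id, modality, biomarker,
#'   specimen_format, categorical_score, continuous_score, deferred,
#'   sufficient_cells`.
#' @param scales Named list of [scale_definition()] objects covering every
#'   biomarker in the file.
#' @param warn_inconsistent Warn when a recorded categorical score differs
#'   from the bin of the recorded continuous score (they are stored
#'   independently; see [consistency_report()]).
#' @return A validated `study_dataset`.
#' @export
read_score_table <- function(path, scales = default_scales(),
                             warn_inconsistent = TRUE) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, fileEncoding = "UTF-8")
  parse_score_table(df, scales, warn_inconsistent = warn_inconsistent)
}

#' Build a validated study dataset from a score table
#'
#' Validates the factor structure and score values of a long-format score
#' table and assembles the `study_dataset` container used by every analysis
#' function: the record table (row order preserved), the ordered reader
#' list, the ordered case list per (biomarker, specimen format) and the
#' scale map.
#'
#' Validation errors: missing columns; unknown modality/format/biomarker;
#' duplicate (reader, case, modality, biomarker) key; a deferred row
#' carrying a score; a non-deferred row with a missing score (unless
#' `sufficient_cells` is `false`); non-integer or out-of-range continuous
#' scores; categorical labels outside the biomarker's scale.
#'
#' @param records A data frame with the columns listed in
#'   [read_score_table()]. Character columns are parsed (`""` means absent;
#'   booleans `true`/`false`); already-typed columns are accepted as-is.
#' @inheritParams read_score_table
#' @return An object of class `study_dataset` with elements `records`,
#'   `readers`, `cases` (list keyed `"<biomarker>.<format>"`), `scales`.
#' @export
parse_score_table <- function(records, scales = default_scales(),
                              warn_inconsistent = TRUE) {
  missing_cols <- setdiff(SCORE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("score table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[SCORE_COLUMNS]
  n <- nrow(records)
  if (n == 0) stop("score table is empty", call. = FALSE)

  chr <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }
  rec <- data.frame(
    reader_id = chr(records$reader_id),
    case_id = chr(records$case_id),
    modality = chr(records$modality),
    biomarker = chr(records$biomarker),
    specimen_format = chr(records$specimen_format),
    categorical_score = chr(records$categorical_score),
    continuous_score = .parse_integer_score(records$continuous_score),
    deferred = .parse_bool(records$deferred, "deferred", required = TRUE),
    sufficient_cells = .parse_bool(records$sufficient_cells, "sufficient_cells",
                                   required = FALSE),
    stringsAsFactors = FALSE)

  for (col in c("reader_id", "case_id", "modality", "biomarker",
                "specimen_format"))
    if (anyNA(rec[[col]]))
      stop(sprintf("column '%s' has empty values (row %d)", col,
                   which(is.na(rec[[col]]))[1]), call. = FALSE)
  .check_levels(rec$modality, MODALITIES, "modality")
  .check_levels(rec$specimen_format, FORMATS, "specimen_format")
  unknown_bm <- setdiff(unique(rec$biomarker), names(scales))
  if (length(unknown_bm))
    stop("no scale definition for biomarker(s): ",
         paste(unknown_bm, collapse = ", "), call. = FALSE)

  key <- paste(rec$reader_id, rec$case_id, rec$modality, rec$biomarker,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (reader, case, modality, biomarker) key: (",
         gsub("\r", ", ", d, fixed = TRUE), ")", call. = FALSE)
  }

  has_cat <- !is.na(rec$categorical_score)
  has_cont <- !is.na(rec$continuous_score)
  bad <- rec$deferred & (has_cat | has_cont)
  if (any(bad))
    stop(sprintf("deferred row %d carries a score; deferred rows must be blank",
                 which(bad)[1]), call. = FALSE)
  insufficient <- !is.na(rec$sufficient_cells) & !rec$sufficient_cells
  bad <- !rec$deferred & !insufficient & !(has_cat & has_cont)
  if (any(bad))
    stop(sprintf("non-deferred row %d is missing a score", which(bad)[1]),
         call. = FALSE)

  .check_score_range(rec$continuous_score)
  for (bm in unique(rec$biomarker)) {
    sc <- scales[[bm]]
    lab <- rec$categorical_score[rec$biomarker == bm]
    bad_lab <- setdiff(unique(lab[!is.na(lab)]), sc$categories)
    if (length(bad_lab))
      stop(sprintf("categorical score '%s' is not on the %s scale {%s}",
                   bad_lab[1], bm, paste(sc$categories, collapse = ", ")),
           call. = FALSE)
  }

  ds <- .new_study_dataset(rec, scales)
  if (warn_inconsistent) {
    cr <- consistency_report(ds)
    if (nrow(cr) > 0)
      warning(sprintf(paste("%d record(s) have a categorical score that",
                            "disagrees with the bin of their continuous score;",
                            "see consistency_report()"), nrow(cr)),
              call. = FALSE)
  }
  ds
}

.new_study_dataset <- function(rec, scales) {
  strata <- unique(rec[c("biomarker", "specimen_format")])
  cases <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- rec$biomarker == strata$biomarker[i] &
      rec$specimen_format == strata$specimen_format[i]
    cases[[paste(strata$biomarker[i], strata$specimen_format[i], sep = ".")]] <-
      unique(rec$case_id[sel])
  }
  structure(list(records = rec,
                 readers = unique(rec$reader_id),
                 cases = cases,
                 scales = scales[intersect(names(scales),
                                           unique(rec$biomarker))]),
            class = "study_dataset")
}

.parse_integer_score <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & x != trunc(x)
    if (any(bad))
      stop(sprintf("continuous_score must be an integer (row %d: %s)",
                   which(bad)[1], format(x[bad][1])), call. = FALSE)
    return(as.integer(x))
  }
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  ok <- is.na(x) | grepl("^-?[0-9]+$", x)
  if (!all(ok))
    stop(sprintf("continuous_score must be an integer (row %d: '%s')",
                 which(!ok)[1], x[!ok][1]), call. = FALSE)
  as.integer(x)
}

.parse_bool <- function(x, col, required) {
  if (is.logical(x)) {
    if (required && anyNA(x))
      stop(sprintf("column '%s' has missing values", col), call. = FALSE)
    return(x)
  }
  x <- tolower(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  ok <- is.na(x) | x %in% c("true", "false")
  if (!all(ok))
    stop(sprintf("column '%s' must be true/false (row %d: '%s')",
                 col, which(!ok)[1], x[!ok][1]), call. = FALSE)
  if (required && anyNA(x))
    stop(sprintf("column '%s' has missing values (row %d)", col,
                 which(is.na(x))[1]), call. = FALSE)
  x == "true"
}

.check_levels <- function(x, levels, col) {
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop(sprintf("column '%s' has unknown value '%s' (expected %s)",
                 col, bad[1], paste(levels, collapse = "/")), call. = FALSE)
  invisible(TRUE)
}

#' Write a study dataset back to the long CSV format
#'
#' Inverse of [read_score_table()]: booleans come out as `true`/`false`,
#' absent scores as empty fields, rows in record order.
#'
#' @param dataset A `study_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  out <- dataset$records
  fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
  out$deferred <- fmt_bool(out$deferred)
  out$sufficient_cells <- fmt_bool(out$sufficient_cells)
  out$continuous_score <- ifelse(is.na(out$continuous_score), "",
                                 as.character(out$continuous_score))
  out$categorical_score[is.na(out$categorical_score)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Report records whose two score types disagree
#'
#' Readers record a categorical and a continuous score independently, so the
#' recorded category can differ from the bin of the continuous score. The
#' parser warns about such records but keeps both values; this report lists
#' them.
#'
#' @param dataset A `study_dataset`.
#' @return Data frame with one row per inconsistent record: identifiers,
#'   the recorded category and the category derived from the continuous
#'   score.
#' @export
consistency_report <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  derived <- rep(NA_character_, nrow(rec))
  for (bm in names(dataset$scales)) {
    sel <- rec$biomarker == bm & !is.na(rec$continuous_score)
    if (any(sel))
      derived[sel] <- .derive_category(rec$continuous_score[sel],
                                       dataset$scales[[bm]])
  }
  bad <- !is.na(rec$categorical_score) & !is.na(derived) &
    rec$categorical_score != derived
  out <- rec[bad, c("reader_id", "case_id", "modality", "biomarker",
                    "specimen_format", "categorical_score",
                    "continuous_score")]
  out$derived_category <- derived[bad]
  rownames(out) <- NULL
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  rec <- x$records
  cat(sprintf("<study_dataset> %d records, %d readers\n", nrow(rec),
              length(x$readers)))
  for (key in names(x$cases)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sel <- rec$biomarker == parts[1] & rec$specimen_format == parts[2]
    cat(sprintf("  %s / %s: %d cases, %d deferred of %d records\n",
                parts[1], parts[2], length(x$cases[[key]]),
                sum(rec$deferred[sel]), sum(sel)))
  }
  invisible(x)
}
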