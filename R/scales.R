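#' Define a biomarker scoring scale
#'
#' A scale ties a biomarker's ordered category labels to the continuous
#' 0-100 score that readers record alongside them. Ordinal scales (HER2)
#' carry cut-points: ascending lower bounds that partition the integer range
#' \[0, 100\] into one bin per category. Binary scales (Ki-67) instead carry a
#' positivity threshold (strict greater-than) and, optionally, minimum
#' tumor-cell counts below which a score is not evaluable.
#'
#' @param biomarker Biomarker label, e.g. `"HER2"` or `"Ki67"`.
#' @param categories Character vector of ordered category labels (low to high).
#' @param cutpoints Integer vector of ascending lower bounds, one per
#'   category, starting at 0. `NULL` for threshold-based scales.
#' @param positivity_threshold Percent cut for binary positivity; a score is
#'   positive iff it strictly exceeds this value. `NULL` for cut-point scales.
#' @param sufficiency_minimum Named numeric vector of minimum tumor-cell
#'   counts per specimen format (names `whole_slide`, `tma_core`), or `NULL`.
#' @return An object of class `scale_definition`.
#' @seealso [her2_scale()], [ki67_scale()], [categorize_continuous()]
#' @export
#' @examples
#' scale_definition("HER2", c("0", "1+", "2+", "3+"), cutpoints = c(0, 25, 50, 75))
scale_definition <- function(biomarker, categories, cutpoints = NULL,
                             positivity_threshold = NULL,
                             sufficiency_minimum = NULL) {
  if (!is.character(categories) || length(categories) < 2 || anyDuplicated(categories))
    stop("categories must be at least two distinct labels", call. = FALSE)
  if (is.null(cutpoints) && is.null(positivity_threshold))
    stop("a scale needs either cutpoints or a positivity_threshold", call. = FALSE)
  if (!is.null(cutpoints)) {
    cutpoints <- as.numeric(cutpoints)
    if (length(cutpoints) != length(categories))
      stop("cutpoints must supply one lower bound per category", call. = FALSE)
    if (cutpoints[1] != 0 || is.unsorted(cutpoints, strictly = TRUE) ||
        max(cutpoints) > 100)
      stop("cutpoints must be strictly ascending, start at 0 and stay within [0, 100]",
           call. = FALSE)
  }
  if (!is.null(positivity_threshold)) {
    positivity_threshold <- as.numeric(positivity_threshold)
    if (length(categories) != 2)
      stop("a positivity threshold requires exactly two categories", call. = FALSE)
    if (positivity_threshold < 0 || positivity_threshold >= 100)
      stop("positivity_threshold must lie in [0, 100)", call. = FALSE)
  }
  structure(
    list(biomarker = as.character(biomarker),
         categories = categories,
         continuous_range = c(0L, 100L),
         cutpoints = cutpoints,
         positivity_threshold = positivity_threshold,
         sufficiency_minimum = sufficiency_minimum),
    class = "scale_definition")
}

#' Default HER2 scale: 0 / 1+ / 2+ / 3+ binned at 25, 50, 75
#'
#' Continuous scores 0-24 map to category `0`, 25-49 to `1+`, 50-74 to `2+`
#' and 75-100 to `3+` (Herceptest-style ordinal scoring).
#'
#' @return A `scale_definition`.
#' @export
her2_scale <- function() {
  scale_definition("HER2", c("0", "1+", "2+", "3+"), cutpoints = c(0, 25, 50, 75))
}

#' Default Ki-67 scale: negative / positive at a strict 10% threshold
#'
#' A case is positive iff strictly more than 10% of tumor cells stain, and a
#' score is evaluable only with at least 500 tumor cells on a whole slide or
#' 100 in a TMA core.
#'
#' @return A `scale_definition`.
#' @export
ki67_scale <- function() {
  scale_definition("Ki67", c("negative", "positive"),
                   positivity_threshold = 10,
                   sufficiency_minimum = c(whole_slide = 500, tma_core = 100))
}

#' Default scale set for a HER2 + Ki-67 study
#'
#' @return Named list of `scale_definition` objects keyed by biomarker.
#' @export
default_scales <- function() {
  list(HER2 = her2_scale(), Ki67 = ki67_scale())
}

#' Read scale definitions from a JSON config
#'
#' The config maps biomarker names to objects with `categories` plus either
#' `cutpoints` or `positivity_threshold` (and optionally
#' `sufficiency_minimum` as a format-keyed object), e.g.
#' `{"HER2": {"categories": ["0","1+","2+","3+"], "cutpoints": [0,25,50,75]}}`.
#'
#' @param path Path to a JSON file.
#' @return Named list of `scale_definition` objects.
#' @export
read_scales <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(cfg), function(bm) {
    x <- cfg[[bm]]
    suff <- x$sufficiency_minimum
    if (!is.null(suff)) suff <- unlist(suff)
    scale_definition(bm, as.character(x$categories),
                     cutpoints = x$cutpoints,
                     positivity_threshold = x$positivity_threshold,
                     sufficiency_minimum = suff)
  })
  names(out) <- names(cfg)
  out
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %s\n", x$biomarker,
              paste(x$categories, collapse = " < ")))
  if (!is.null(x$cutpoints))
    cat("  cutpoints (lower bounds):", paste(x$cutpoints, collapse = ", "), "\n")
  if (!is.null(x$positivity_threshold))
    cat(sprintf("  positive iff score > %g\n", x$positivity_threshold))
  if (!is.null(x$sufficiency_minimum))
    cat("  sufficiency minima:",
        paste(sprintf("%s >= %g", names(x$sufficiency_minimum),
                      x$sufficiency_minimum), collapse = ", "), "\n")
  invisible(x)
}

#' Map a continuous score to its ordinal category
#'
#' Finds the cut-point bin containing each value. For the default HER2 scale
#' the bins are \[0,24\], \[25,49\], \[50,74\], \[75,100\].
#'
#' @param value Integer score(s) in \[0, 100\]; `NA` passes through.
#' @param scale A `scale_definition` with cutpoints.
#' @return Character vector of category labels.
#' @export
#' @examples
#' categorize_continuous(c(24, 25, 75), her2_scale())
categorize_continuous <- function(value, scale) {
  if (is.null(scale$cutpoints))
    stop("scale has no cutpoints; use ki67_binary() for threshold scales",
         call. = FALSE)
  .check_score_range(value)
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- scale$categories[findInterval(value[ok], scale$cutpoints)]
  out
}

#' Binarize a Ki-67 percentage at the positivity threshold
#'
#' Positive iff the score strictly exceeds the threshold (default 10), so a
#' score of exactly 10 is negative.
#'
#' @param value Integer score(s) in \[0, 100\]; `NA` passes through.
#' @param scale A `scale_definition` with a positivity threshold.
#' @return Character vector, `"negative"` or `"positive"`.
#' @export
#' @examples
#' ki67_binary(c(10, 11))
ki67_binary <- function(value, scale = ki67_scale()) {
  if (is.null(scale$positivity_threshold))
    stop("scale has no positivity threshold", call. = FALSE)
  .check_score_range(value)
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- ifelse(value[ok] > scale$positivity_threshold,
                    scale$categories[2], scale$categories[1])
  out
}

.check_score_range <- function(value) {
  bad <- !is.na(value) & (value < 0 | value > 100)
  if (any(bad))
    stop(sprintf("continuous score out of [0, 100]: %s",
                 paste(value[bad][seq_len(min(3, sum(bad)))], collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

# category of a continuous score under either kind of scale
.derive_category <- function(value, scale) {
  if (!is.null(scale$cutpoints)) categorize_continuous(value, scale)
  else ki67_binary(value, scale)
}
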