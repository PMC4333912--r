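#' Kendall's tau-b with full ties decomposition
#'
#' Rank correlation for paired scores: the difference between concordant
#' and discordant pair rates, corrected for ties. With `n` cases, `n0 =
#' n(n-1)/2` case pairs, `C` concordant, `D` discordant, and `n1`/`n2`
#' pairs tied within `x`/`y`,
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}.}
#' The statistic is undefined (not zero) when either vector is constant,
#' i.e. when a denominator factor vanishes; such results carry
#' `defined = FALSE` and `tau_b = NA`, and aggregation drops them rather
#' than coercing to a number. All counts use exact integer arithmetic;
#' division happens last.
#'
#' @param x,y Equal-length score vectors of at least 2 entries: numeric, or
#'   factors whose level order is the category order.
#' @return An object of class `tau_b_decomposition`: `n`, `C`, `D`, `n0`,
#'   `n1`, `n2`, `tau_b`, `defined`.
#' @export
#' @examples
#' kendall_tau_b(c(1, 2, 3, 3), c(1, 3, 2, 3)) # tau_b = 0.4
kendall_tau_b <- function(x, y) {
  x <- .as_ordinal(x)
  y <- .as_ordinal(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values: align vectors with pairwise_complete() first",
         call. = FALSE)
  n <- length(x)
  if (n < 2) stop("tau-b needs at least 2 paired cases", call. = FALSE)
  cnt <- .tau_counts(x, y)
  d1 <- cnt$n0 - cnt$n1
  d2 <- cnt$n0 - cnt$n2
  defined <- d1 > 0 && d2 > 0
  structure(
    list(n = n, C = cnt$C, D = cnt$D, n0 = cnt$n0, n1 = cnt$n1, n2 = cnt$n2,
         tau_b = if (defined) (cnt$C - cnt$D) / sqrt(d1 * d2) else NA_real_,
         defined = defined),
    class = "tau_b_decomposition")
}

.as_ordinal <- function(v) {
  if (is.factor(v)) return(as.integer(v))
  if (is.character(v))
    stop("character scores carry no order; pass a factor with ordered levels",
         call. = FALSE)
  as.numeric(v)
}

# Exact pair counts. Moderate n: compiled enumeration of all pairs.
# Large n: joint contingency table with suffix sums, O(K^2) in the number of
# distinct values, so tau-b on millions of integer scores stays cheap.
.tau_counts <- function(x, y) {
  n <- length(x)
  if (n <= 2048) return(.tau_counts_pairs(x, y))
  .tau_counts_table(x, y)
}

.tau_counts_table <- function(x, y) {
  n <- length(x)
  ux <- sort(unique(x))
  uy <- sort(unique(y))
  K1 <- length(ux)
  K2 <- length(uy)
  tt <- matrix(tabulate(match(x, ux) + (match(y, uy) - 1L) * K1, K1 * K2),
               K1, K2)
  storage.mode(tt) <- "double"  # cell products overflow integers at large n
  rs <- rowSums(tt)
  cs <- colSums(tt)
  # SS[i,j] = sum over rows >= i, cols >= j; PS[i,j] = rows >= i, cols <= j
  SS <- tt; PS <- tt
  if (K1 > 1) for (i in (K1 - 1):1) {
    SS[i, ] <- SS[i, ] + SS[i + 1, ]
    PS[i, ] <- PS[i, ] + PS[i + 1, ]
  }
  if (K2 > 1) {
    for (j in (K2 - 1):1) SS[, j] <- SS[, j] + SS[, j + 1]
    for (j in 2:K2) PS[, j] <- PS[, j] + PS[, j - 1]
  }
  C <- 0; D <- 0
  for (i in seq_len(K1)) for (j in seq_len(K2)) {
    nij <- tt[i, j]
    if (nij == 0) next
    if (i < K1 && j < K2) C <- C + nij * SS[i + 1, j + 1]
    if (i < K1 && j > 1)  D <- D + nij * PS[i + 1, j - 1]
  }
  list(C = C, D = D, n0 = n * (n - 1) / 2,
       n1 = sum(rs * (rs - 1)) / 2, n2 = sum(cs * (cs - 1)) / 2)
}

# lean scalar used in bootstrap loops: NA when undefined, no class dispatch
.tau_value <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  cnt <- .tau_counts(x, y)
  d1 <- cnt$n0 - cnt$n1
  d2 <- cnt$n0 - cnt$n2
  if (d1 <= 0 || d2 <= 0) return(NA_real_)
  (cnt$C - cnt$D) / sqrt(d1 * d2)
}

#' @export
print.tau_b_decomposition <- function(x, ...) {
  cat(sprintf("<tau_b> n = %d, C = %.0f, D = %.0f, n0 = %.0f, n1 = %.0f, n2 = %.0f\n",
              x$n, x$C, x$D, x$n0, x$n1, x$n2))
  if (x$defined) cat(sprintf("  tau_b = %.4f\n", x$tau_b))
  else cat("  tau_b undefined (a score vector is constant)\n")
  invisible(x)
}

#' Overall percent correct agreement
#'
#' The percentage of cases on which two categorical score vectors coincide.
#'
#' @param x,y Equal-length categorical vectors (character or factor).
#' @return List of class `percent_agreement`: `percent`, `matches`, `n`,
#'   `defined` (`FALSE` for empty input, where the percent is `NA`).
#' @export
#' @examples
#' overall_percent_agreement(c("0", "1+", "2+", "3+"),
#'                           c("0", "1+", "2+", "2+")) # 75%
overall_percent_agreement <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values: align vectors with pairwise_complete() first",
         call. = FALSE)
  n <- length(x)
  matches <- sum(as.character(x) == as.character(y))
  structure(list(percent = if (n > 0) 100 * matches / n else NA_real_,
                 matches = matches, n = n, defined = n > 0),
            class = "percent_agreement")
}

#' @export
print.percent_agreement <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<percent_agreement> %.1f%% (%d of %d cases)\n", x$percent,
                x$matches, x$n))
  else cat("<percent_agreement> undefined (no cases)\n")
  invisible(x)
}

#' Category-specific percent correct agreement
#'
#' For one category: the number of cases scored in that category by both
#' readers, divided by the number of cases scored in that category by at
#' least one of them (a Jaccard-style ratio). Undefined when the category
#' appears in neither vector.
#'
#' @param x,y Equal-length categorical vectors.
#' @param category The category label to assess.
#' @param categories Optional full label set; when given, an unknown
#'   `category` is an error.
#' @return List of class `category_agreement`: `category`, `numerator`,
#'   `denominator`, `percent`, `defined`.
#' @export
#' @examples
#' category_percent_agreement(c("0", "1+", "2+", "3+"),
#'                            c("0", "1+", "2+", "2+"), "2+") # 1/2 = 50%
category_percent_agreement <- function(x, y, category, categories = NULL) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (!is.null(categories) && !category %in% categories)
    stop(sprintf("unknown category '%s'", category), call. = FALSE)
  x <- as.character(x); y <- as.character(y)
  num <- sum(x == category & y == category)
  den <- sum(x == category | y == category)
  structure(list(category = category, numerator = num, denominator = den,
                 percent = if (den > 0) 100 * num / den else NA_real_,
                 defined = den > 0),
            class = "category_agreement")
}

#' @export
print.category_agreement <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<category_agreement> '%s': %d/%d = %.1f%%\n", x$category,
                x$numerator, x$denominator, x$percent))
  else
    cat(sprintf("<category_agreement> '%s': undefined (absent from both)\n",
                x$category))
  invisible(x)
}

#' Disagreement cross-tabulation between two categorical score vectors
#'
#' Counts `M[a, b]` = number of cases scored `a` in `x` and `b` in `y`,
#' with row-normalized percentages: of the cases scored `a` in `x`, the
#' percent scored `b` in `y`. Rows with no cases carry `NA` percentages.
#' This is the table behind statements such as "28% of cores scored 1+
#' under one modality were scored 2+ under the other".
#'
#' @param x,y Equal-length categorical vectors.
#' @param categories Character vector of category labels fixing row/column
#'   order.
#' @return Object of class `disagreement_crosstab`: `counts` (K x K
#'   matrix), `row_percent`, `categories`, `n`.
#' @export
disagreement_crosstab <- function(x, y, categories) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  fx <- factor(as.character(x), levels = categories)
  fy <- factor(as.character(y), levels = categories)
  if (anyNA(fx) || anyNA(fy))
    stop("scores outside the supplied categories", call. = FALSE)
  counts <- unclass(table(fx, fy))
  dimnames(counts) <- list(categories, categories)
  totals <- rowSums(counts)
  row_percent <- 100 * counts / ifelse(totals == 0, NA, totals)
  structure(list(counts = counts, row_percent = row_percent,
                 categories = categories, n = length(x)),
            class = "disagreement_crosstab")
}

#' @export
print.disagreement_crosstab <- function(x, ...) {
  cat(sprintf("<disagreement_crosstab> %d cases\n", x$n))
  print(x$counts)
  cat("row percentages:\n")
  print(round(x$row_percent, 1))
  invisible(x)
}

# percent-agreement kernel on integer category codes 1..K:
# c(overall, per-category...), NA where undefined
.pa_values <- function(x, y, K) {
  n <- length(x)
  out <- rep(NA_real_, K + 1)
  if (n > 0) out[1] <- 100 * sum(x == y) / n
  for (k in seq_len(K)) {
    den <- sum(x == k | y == k)
    if (den > 0) out[k + 1] <- 100 * sum(x == k & y == k) / den
  }
  out
}
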