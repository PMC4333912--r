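# Independent brute-force oracles: explicit enumeration over case pairs /
# categories, kept deliberately naive and separate from the package's
# counting code paths.

oracle_tau_counts <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; n1 <- 0; n2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tx <- x[i] == x[j]
      ty <- y[i] == y[j]
      if (tx) n1 <- n1 + 1
      if (ty) n2 <- n2 + 1
      if (!tx && !ty) {
        if ((x[i] < x[j]) == (y[i] < y[j])) C <- C + 1 else D <- D + 1
      }
    }
  }
  list(C = C, D = D, n0 = n * (n - 1) / 2, n1 = n1, n2 = n2)
}

oracle_tau <- function(x, y) {
  cnt <- oracle_tau_counts(x, y)
  d1 <- cnt$n0 - cnt$n1
  d2 <- cnt$n0 - cnt$n2
  cnt$tau_b <- if (d1 > 0 && d2 > 0) (cnt$C - cnt$D) / sqrt(d1 * d2) else
    NA_real_
  cnt
}

oracle_overall_pa <- function(x, y) {
  hits <- 0
  for (i in seq_along(x)) if (x[i] == y[i]) hits <- hits + 1
  100 * hits / length(x)
}

oracle_category_pa <- function(x, y, k) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    if (x[i] == k && y[i] == k) num <- num + 1
    if (x[i] == k || y[i] == k) den <- den + 1
  }
  list(numerator = num, denominator = den,
       percent = if (den > 0) 100 * num / den else NA_real_)
}
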