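test_that("tau-b decomposition matches hand-enumerated pair counts", {
  t1 <- kendall_tau_b(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t1$tau_b, 1)
  t2 <- kendall_tau_b(c(1, 2, 3), c(3, 2, 1))
  expect_equal(t2$tau_b, -1)

  t3 <- kendall_tau_b(c(1, 2, 3, 3), c(1, 3, 2, 3))
  expect_equal(t3$C, 3)
  expect_equal(t3$D, 1)
  expect_equal(t3$n0, 6)
  expect_equal(t3$n1, 1)
  expect_equal(t3$n2, 1)
  expect_equal(t3$tau_b, 0.4)

  t4 <- kendall_tau_b(c(2, 2, 2), c(1, 2, 3))
  expect_false(t4$defined)
  expect_true(is.na(t4$tau_b))
})

test_that("tau-b rejects unusable input", {
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
  expect_error(kendall_tau_b(1, 1), "at least 2")
  expect_error(kendall_tau_b(c("a", "b"), c("a", "b")), "factor")
  expect_error(kendall_tau_b(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("tau-b equals the brute-force oracle on random tied vectors", {
  set.seed(401)
  for (i in 1:300) {
    p <- random_tied_pair()
    got <- kendall_tau_b(p$x, p$y)
    want <- oracle_tau(p$x, p$y)
    expect_identical(got$C, want$C)
    expect_identical(got$D, want$D)
    expect_identical(got$n1, want$n1)
    expect_identical(got$n2, want$n2)
    expect_equal(got$tau_b, want$tau_b, tolerance = 1e-14)
  }
})

test_that("the pair-enumeration and contingency-table counting paths agree", {
  set.seed(402)
  for (i in 1:20) {
    n <- sample(c(5, 50, 600), 1)
    x <- sample(0:100, n, replace = TRUE)
    y <- sample(0:10, n, replace = TRUE)
    expect_equal(pathagree:::.tau_counts_pairs(as.numeric(x), as.numeric(y)),
                 pathagree:::.tau_counts_table(x, y))
  }
})

test_that("on binary vectors tau-b reduces to the phi coefficient", {
  set.seed(403)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(0:1, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    t <- kendall_tau_b(x, y)
    a <- sum(x == 0 & y == 0); b <- sum(x == 0 & y == 1)
    c_ <- sum(x == 1 & y == 0); d <- sum(x == 1 & y == 1)
    denom <- sqrt((a + b) * (c_ + d)) * sqrt((a + c_) * (b + d))
    if (denom == 0) {
      expect_false(t$defined)
    } else {
      expect_equal(t$tau_b, (a * d - b * c_) / denom, tolerance = 1e-12)
    }
  }
})

test_that("tau-b and percent agreement are symmetric in their arguments", {
  set.seed(404)
  for (i in 1:30) {
    p <- random_tied_pair()
    expect_equal(kendall_tau_b(p$x, p$y)$tau_b,
                 kendall_tau_b(p$y, p$x)$tau_b)
    expect_equal(overall_percent_agreement(p$x, p$y)$percent,
                 overall_percent_agreement(p$y, p$x)$percent)
    for (k in unique(c(p$x, p$y))) {
      a <- category_percent_agreement(p$x, p$y, k)
      b <- category_percent_agreement(p$y, p$x, k)
      expect_equal(a$numerator, b$numerator)
      expect_equal(a$denominator, b$denominator)
    }
  }
})

test_that("overall percent agreement counts coinciding scores", {
  pa <- overall_percent_agreement(c("0", "1+", "2+", "3+"),
                                  c("0", "1+", "2+", "2+"))
  expect_equal(pa$percent, 75)
  expect_equal(pa$matches, 3)
  x <- sample(c("neg", "pos"), 10, replace = TRUE)
  expect_equal(overall_percent_agreement(x, x)$percent, 100)
  expect_equal(overall_percent_agreement(rep("neg", 5),
                                         rep("pos", 5))$percent, 0)
  expect_false(overall_percent_agreement(character(0),
                                         character(0))$defined)
})

test_that("category agreement divides both-agree by at-least-one counts", {
  x <- c("0", "1+", "2+", "3+")
  y <- c("0", "1+", "2+", "2+")
  two <- category_percent_agreement(x, y, "2+")
  expect_equal(two$numerator, 1)
  expect_equal(two$denominator, 2)
  expect_equal(two$percent, 50)
  expect_equal(category_percent_agreement(x, y, "3+")$percent, 0)
  expect_equal(category_percent_agreement(x, y, "0")$percent, 100)
  absent <- category_percent_agreement(x, y, "4+",
                                       categories = c(x, "4+"))
  expect_false(absent$defined)
  expect_error(category_percent_agreement(x, y, "4+",
                                          categories = unique(x)),
               "unknown category")
})

test_that("percent agreement matches direct counting on random vectors", {
  set.seed(405)
  cats <- her2_scale()$categories
  for (i in 1:200) {
    n <- sample(1:15, 1)
    x <- sample(cats, n, replace = TRUE)
    y <- sample(cats, n, replace = TRUE)
    expect_equal(overall_percent_agreement(x, y)$percent,
                 oracle_overall_pa(x, y))
    for (k in cats) {
      got <- category_percent_agreement(x, y, k)
      want <- oracle_category_pa(x, y, k)
      expect_equal(got$numerator, want$numerator)
      expect_equal(got$denominator, want$denominator)
    }
  }
})

test_that("the disagreement crosstab row-normalizes score shifts", {
  ct <- disagreement_crosstab(c("1+", "1+", "2+"), c("2+", "1+", "3+"),
                              her2_scale()$categories)
  expect_equal(ct$counts["1+", "1+"], 1)
  expect_equal(ct$counts["1+", "2+"], 1)
  expect_equal(ct$row_percent["1+", "1+"], 50)
  expect_equal(ct$row_percent["1+", "2+"], 50)
  expect_equal(ct$row_percent["2+", "3+"], 100)
  expect_true(all(is.na(ct$row_percent["0", ])))
  expect_true(all(ct$counts["0", ] == 0))

  x <- sample(her2_scale()$categories, 20, replace = TRUE)
  self <- disagreement_crosstab(x, x, her2_scale()$categories)
  expect_equal(sum(diag(self$counts)), 20)
  expect_true(all(self$counts[upper.tri(self$counts)] == 0))
})

test_that("crosstab transposes under argument swap and its diagonal gives overall PA", {
  set.seed(406)
  cats <- her2_scale()$categories
  for (i in 1:20) {
    x <- sample(cats, 15, replace = TRUE)
    y <- sample(cats, 15, replace = TRUE)
    a <- disagreement_crosstab(x, y, cats)
    b <- disagreement_crosstab(y, x, cats)
    expect_equal(a$counts, t(b$counts))
    expect_equal(100 * sum(diag(a$counts)) / a$n,
                 overall_percent_agreement(x, y)$percent)
  }
})
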