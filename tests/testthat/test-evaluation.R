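test_that("confusion matrices count correctly and validate labels", {
  cm <- confusion_matrix(c(1L, 2L, 3L), c(1L, 2L, 3L), 3L)
  expect_identical(cm, diag(1L, 3L) * 1L)
  expect_identical(sum(confusion_matrix(sample(1:3, 50, TRUE),
                                        sample(1:3, 50, TRUE), 3L)), 50L)
  # 2-class toy: swapping the prediction vector moves the off-diagonal mass
  labs <- c(1L, 1L, 2L, 2L)
  pred <- c(1L, 2L, 2L, 2L)
  cm1 <- confusion_matrix(pred, labs, 2L)
  expect_identical(cm1, matrix(c(1L, 0L, 1L, 2L), 2, 2))
  pred_sw <- c(2L, 1L, 1L, 1L)
  cm2 <- confusion_matrix(pred_sw, labs, 2L)
  expect_identical(cm2, matrix(c(1L, 2L, 1L, 0L), 2, 2))
  expect_error(confusion_matrix(c(1L, 4L), c(1L, 1L), 3L), "range")
})

test_that("macro metrics match hand-computed one-vs-rest arithmetic", {
  perfect <- diag(5L, 3L)
  mm <- macro_metrics(perfect)
  expect_equal(unlist(mm[c("accuracy", "macro_precision", "macro_recall",
                           "macro_f1", "macro_specificity", "g_means")]),
               setNames(rep(1, 6), c("accuracy", "macro_precision",
                                     "macro_recall", "macro_f1",
                                     "macro_specificity", "g_means")))
  # binary cm with TP=9, FN=1, TN=90, FP=10 (class 1 = positive)
  cm <- matrix(c(9L, 1L, 10L, 90L), 2, 2, byrow = TRUE)
  mm2 <- macro_metrics(cm)
  expect_equal(mm2$per_class$recall[1], 0.9)
  expect_equal(mm2$per_class$specificity[1], 0.9)
  expect_equal(sqrt(mm2$per_class$recall[1] * mm2$per_class$specificity[1]),
               0.9)
  # 3-class with one empty-prediction class
  cm3 <- matrix(c(5L, 0L, 0L,
                  0L, 5L, 0L,
                  5L, 0L, 0L), 3, 3, byrow = TRUE)
  mm3 <- macro_metrics(cm3)
  expect_equal(mm3$macro_recall, 2 / 3, tolerance = 1e-12)
  expect_equal(mm3$per_class$precision[3], 0)   # no predicted positives
  expect_error(macro_metrics(matrix(0L, 2, 2)), "nonempty")
})

test_that("macro metrics are invariant to class relabelling and G-means is bounded", {
  set.seed(81)
  for (i in 1:20) {
    C <- sample(2:5, 1)
    cm <- matrix(rpois(C * C, 3), C, C)
    cm[1, 1] <- cm[1, 1] + 5
    mm <- macro_metrics(cm)
    perm <- sample(C)
    mmp <- macro_metrics(cm[perm, perm])
    for (k in c("accuracy", "macro_precision", "macro_recall", "macro_f1",
                "macro_specificity", "g_means"))
      expect_equal(mm[[k]], mmp[[k]], tolerance = 1e-12)
    expect_gte(mm$g_means, 0)
    expect_lte(mm$g_means, min(1, sqrt(mm$macro_recall)) + 1e-12)
  }
  # G-means = 0 iff macro recall or macro specificity is 0
  cm0 <- matrix(c(0L, 3L, 0L, 3L), 2, 2, byrow = TRUE)  # everything -> class 2
  mm0 <- macro_metrics(cm0)
  expect_identical(mm0$g_means == 0,
                   mm0$macro_recall == 0 || mm0$macro_specificity == 0)
})

test_that("McNemar matches the closed form, the exact binomial and the oracle", {
  labs <- rep(1L, 40)
  # b = 10, c = 2 via constructed prediction patterns... use counts >= 25
  mk <- function(b, c_, n_both_right = 30) {
    labs <- rep(1L, b + c_ + n_both_right)
    pa <- labs; pb <- labs
    if (b) pb[seq_len(b)] <- 2L
    if (c_) pa[b + seq_len(c_)] <- 2L
    list(a = pa, b = pb, labs = labs)
  }
  # chi-squared branch: b=20, c=10 -> (20-10)^2/30
  x <- mk(20, 10)
  r <- mcnemar_compare(x$a, x$b, x$labs)
  expect_equal(r$statistic, 100 / 30, tolerance = 1e-12)
  expect_equal(r$branch, "chisq")
  expect_equal(r$p_value, pchisq(100 / 30, 1, lower.tail = FALSE))
  ref <- mcnemar.test(table(x$a == x$labs, x$b == x$labs), correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  # closed form from the worked example b=10, c=2: chi^2 = 64/12
  expect_equal((10 - 2)^2 / (10 + 2), 5.3333, tolerance = 1e-4)
  # exact branch: b=3, c=0 -> p = 2 * (1/2)^3 = 0.25
  y <- mk(3, 0)
  re <- mcnemar_compare(y$a, y$b, y$labs)
  expect_equal(re$branch, "exact")
  expect_equal(re$p_value, 0.25, tolerance = 1e-12)
  # b = c -> statistic 0 (chisq) or p = 1
  z <- mk(15, 15)
  rz <- mcnemar_compare(z$a, z$b, z$labs)
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p_value, 1)
  # degenerate: no discordant pairs
  w <- mk(0, 0)
  rw <- mcnemar_compare(w$a, w$b, w$labs)
  expect_true(rw$degenerate)
  expect_equal(rw$p_value, 1)
})

test_that("paired comparison gates on normality and handles degenerate inputs", {
  set.seed(82)
  a <- rnorm(10, 1)
  expect_true(paired_comparison(a, a)$degenerate)
  # constant nonzero difference: zero variance -> deterministic flag
  r <- paired_comparison(a + 0.5, a)
  expect_true(r$degenerate)
  expect_identical(r$branch, "deterministic")
  # normal differences -> t branch with CI
  b <- a + rnorm(10, 0.3, 0.1)
  rt <- paired_comparison(b, a)
  expect_identical(rt$branch, "t")
  expect_length(rt$conf_int, 2L)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(rt$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(paired_comparison(1:2, 1:2), "n >= 3")
})

test_that("the Wilcoxon branch matches exhaustive sign-assignment enumeration", {
  d <- c(1, 2, 3, -1.5, 4, 5) / 10
  a <- rep(0, 6) + d; b <- rep(0, 6)
  # force the wilcoxon branch by adding a heavy outlier pattern that fails
  # Shapiro... instead enumerate directly and compare to wilcox.test exact
  n <- length(d)
  ranks <- rank(abs(d))
  Wobs <- sum(ranks[d > 0])
  # exhaustive null distribution of the positive-rank sum
  all_w <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(ranks[signs == 1])
  }, 1)
  p_exact <- mean(abs(all_w - n * (n + 1) / 4) >=
                    abs(Wobs - n * (n + 1) / 4))
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(unname(ref$statistic), Wobs)
  expect_equal(ref$p.value, p_exact, tolerance = 1e-12)
  # and our wrapper reports the same statistic when it takes that branch
  skewed_a <- c(0.01, 0.02, 0.03, 0.05, 0.08, 4, 5, 9, 0.025, 0.04)
  skewed_b <- rep(0, 10)
  rw <- paired_comparison(skewed_a, skewed_b)
  if (rw$branch == "wilcoxon") {
    refw <- wilcox.test(skewed_a, skewed_b, paired = TRUE, exact = TRUE)
    expect_equal(rw$statistic, unname(refw$statistic))
    expect_equal(rw$p_value, refw$p.value, tolerance = 1e-12)
  }
})

test_that("group comparison: ANOVA equals squared pooled t for 2 groups; KW matches ranks", {
  set.seed(83)
  g1 <- rnorm(8); g2 <- rnorm(8, 0.5)
  r <- group_comparison(list(g1, g2))
  expect_identical(r$branch, "anova")
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(unname(r$statistic), unname(tt$statistic)^2, tolerance = 1e-10)
  # identical groups -> F ~ 0
  rid <- group_comparison(list(g1, g1, g1))
  expect_lt(abs(rid$statistic), 1e-20)
  # Kruskal-Wallis on {1,2,3},{4,5,6},{7,8,9} against the rank formula
  gs <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal.test(unlist(gs), factor(rep(1:3, each = 3)))
  N <- 9; Rbar <- c(2, 5, 8)
  H <- 12 / (N * (N + 1)) * sum(3 * (Rbar - (N + 1) / 2)^2)
  expect_equal(unname(kw$statistic), H, tolerance = 1e-12)
  # non-normal data routes to the KW branch
  skew <- lapply(1:3, function(i) c(rep(0.01, 6), 5 + i, 20 * i))
  rk <- group_comparison(skew)
  expect_identical(rk$branch, "kruskal")
  expect_equal(unname(rk$statistic),
               unname(kruskal.test(unlist(skew),
                                   factor(rep(1:3, each = 8)))$statistic),
               tolerance = 1e-12)
  expect_error(group_comparison(list(1:5)), "2 nonempty")
})

test_that("reports round-trip through JSON and the per-class CSV has C rows", {
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE)
  rep <- macro_metrics(cm)
  path <- file.path(tempfile("rep_"), "report")
  tests <- list(mcnemar = mcnemar_compare(c(1L, 1L, 2L), c(1L, 2L, 2L),
                                          c(1L, 1L, 2L)))
  files <- write_report(rep, path, tests)
  back <- read_report(files$json)
  for (k in c("accuracy", "macro_precision", "macro_recall", "macro_f1",
              "macro_specificity", "g_means"))
    expect_equal(back[[k]], rep[[k]], tolerance = 1e-12)
  expect_equal(back$per_class$recall, rep$per_class$recall, tolerance = 1e-12)
  csv <- read.csv(files$csv)
  expect_identical(nrow(csv), 2L)
  expect_false(is.null(attr(back, "tests")$mcnemar))
})

test_that("p-values lie in [0,1] across random comparisons", {
  set.seed(84)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    r <- paired_comparison(a, b)
    expect_gte(r$p_value, 0); expect_lte(r$p_value, 1)
    labs <- sample(1:2, 30, TRUE)
    rm_ <- mcnemar_compare(sample(1:2, 30, TRUE), sample(1:2, 30, TRUE), labs)
    expect_gte(rm_$p_value, 0); expect_lte(rm_$p_value, 1)
  }
})
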