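# Evaluation: confusion matrix, macro-averaged one-vs-rest metrics with
# G-means, and the statistical-test battery for comparing classifiers
# (normality-gated paired t / Wilcoxon, ANOVA / Kruskal-Wallis, McNemar).

#' Confusion matrix (rows = true class, columns = predicted)
#' @param predictions,labels integer vectors of 1-based class indices
#' @param C number of classes
#' @return C x C integer matrix
#' @export
confusion_matrix <- function(predictions, labels, C) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (any(predictions < 1 | predictions > C | labels < 1 | labels > C))
    stop("class label out of range 1..", C)
  cm <- matrix(0L, C, C)
  for (i in seq_along(labels))
    cm[labels[i], predictions[i]] <- cm[labels[i], predictions[i]] + 1L
  cm
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Per class (one-vs-rest): precision, recall, F1 and specificity; macro
#' values are their unweighted means.  Accuracy is trace/total and G-means is
#' sqrt(macro recall * macro specificity) — the binary geometric mean of
#' sensitivity and specificity extended by macro-averaging.  A class with no
#' predicted positives receives precision 0 (and F1 0).
#' @param cm confusion matrix from [confusion_matrix()]
#' @return a `metrics_report`: list with accuracy, macro_precision,
#'   macro_recall, macro_f1, macro_specificity, g_means and `per_class`
#'   data.frame
#' @export
macro_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    stop("cm must be a nonempty square confusion matrix")
  C <- nrow(cm)
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  rep <- list(accuracy = sum(tp) / n,
              macro_precision = mean(precision),
              macro_recall = mean(recall),
              macro_f1 = mean(f1),
              macro_specificity = mean(specificity),
              g_means = sqrt(mean(recall) * mean(specificity)),
              per_class = data.frame(class = seq_len(C) - 1L,
                                     precision = precision, recall = recall,
                                     f1 = f1, specificity = specificity,
                                     support = rowSums(cm)))
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | macro P %.4f R %.4f F1 %.4f | ",
                     "specificity %.4f | G-means %.4f\n"),
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$macro_specificity, x$g_means))
  invisible(x)
}

.test_result <- function(test, statistic, p, alpha = 0.05, ci = NULL,
                         degenerate = FALSE, branch = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p),
                 significant = !degenerate && p < alpha,
                 alpha = alpha, conf_int = ci, degenerate = degenerate,
                 branch = branch),
            class = "cyto_test_result")
}

#' @export
print.cyto_test_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g%s\n", x$test,
              if (!is.null(x$branch)) paste0(" [", x$branch, "]") else "",
              x$statistic, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' McNemar test on two classifiers' paired predictions
#'
#' Uses the discordant counts b (A right, B wrong) and c (A wrong, B right).
#' For b + c >= 25 the chi-squared statistic (b-c)^2/(b+c) is used (with an
#' optional continuity correction); below that, the exact two-sided binomial
#' test on (b, b+c) at p = 1/2.
#' @param pred_a,pred_b predictions of the two models (1-based)
#' @param labels true labels
#' @param correct continuity correction for the chi-squared branch
#' @param alpha significance level
#' @return a `cyto_test_result` (fields b and c attached as attributes)
#' @export
mcnemar_compare <- function(pred_a, pred_b, labels, correct = FALSE,
                            alpha = 0.05) {
  if (length(pred_a) != length(labels) || length(pred_b) != length(labels))
    stop("both prediction vectors must match the labels")
  ra <- pred_a == labels
  rb <- pred_b == labels
  b <- sum(ra & !rb)
  c_ <- sum(!ra & rb)
  if (b + c_ == 0) {
    res <- .test_result("mcnemar", 0, 1, alpha, degenerate = TRUE,
                        branch = "degenerate")
  } else if (b + c_ < 25) {
    n <- b + c_
    p <- if (b == c_) 1 else min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    res <- .test_result("mcnemar", min(b, c_), p, alpha, branch = "exact")
  } else {
    adj <- if (correct) (abs(b - c_) - 1)^2 else (b - c_)^2
    stat <- adj / (b + c_)
    res <- .test_result("mcnemar", stat,
                        stats::pchisq(stat, 1, lower.tail = FALSE), alpha,
                        branch = "chisq")
  }
  attr(res, "b") <- b
  attr(res, "c") <- c_
  res
}

#' Normality-gated paired comparison of two metric samples
#'
#' A Shapiro-Wilk test on the paired differences (at `alpha`) routes to a
#' paired t-test (normal) or a Wilcoxon signed-rank test (non-normal; exact
#' distribution for n <= 25 without ties).  All-zero differences are flagged
#' degenerate; zero-variance nonzero differences are reported as a
#' deterministic difference.
#' @param a,b equal-length paired samples (n >= 3)
#' @param alpha significance level
#' @return a `cyto_test_result`
#' @export
paired_comparison <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need equal-length paired samples with n >= 3")
  d <- a - b
  if (all(d == 0))
    return(.test_result("paired", 0, 1, alpha, degenerate = TRUE,
                        branch = "degenerate"))
  if (stats::sd(d) <= 1e-12 * max(abs(d)))
    return(.test_result("paired", Inf, 0, alpha, degenerate = TRUE,
                        branch = "deterministic",
                        ci = c(d[1], d[1])))
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(a, b, paired = TRUE, conf.level = 1 - alpha)
    .test_result("paired", tt$statistic, tt$p.value, alpha,
                 ci = as.numeric(tt$conf.int), branch = "t")
  } else {
    wt <- stats::wilcox.test(a, b, paired = TRUE,
                             exact = length(d) <= 25 && !any(duplicated(abs(d))) &&
                               !any(d == 0))
    .test_result("paired", wt$statistic, wt$p.value, alpha,
                 branch = "wilcoxon")
  }
}

#' Normality-gated comparison of k groups
#'
#' Shapiro-Wilk per group gates classical one-way ANOVA (equal-variance F)
#' versus the Kruskal-Wallis rank test.
#' @param groups list of numeric vectors (k >= 2, each n >= 3)
#' @param alpha significance level
#' @return a `cyto_test_result`
#' @export
group_comparison <- function(groups, alpha = 0.05) {
  if (length(groups) < 2 || any(!vapply(groups, length, 1L)))
    stop("need at least 2 nonempty groups")
  if (any(vapply(groups, length, 1L) < 3))
    stop("each group needs n >= 3")
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  normal <- all(vapply(groups, function(x)
    stats::sd(x) == 0 || stats::shapiro.test(x)$p.value >= alpha, TRUE))
  if (normal && all(vapply(groups, stats::sd, 1) > 0)) {
    ow <- stats::oneway.test(vals ~ g, var.equal = TRUE)
    .test_result("group", ow$statistic, ow$p.value, alpha, branch = "anova")
  } else if (all(vapply(groups, stats::sd, 1) == 0) &&
             length(unique(vapply(groups, function(x) x[1], 1))) == 1) {
    .test_result("group", 0, 1, alpha, degenerate = TRUE,
                 branch = "degenerate")
  } else {
    kw <- stats::kruskal.test(vals, g)
    .test_result("group", kw$statistic, kw$p.value, alpha,
                 branch = "kruskal")
  }
}

#' Write a metrics report (and optional test results) to JSON + CSV
#'
#' The JSON file holds every scalar metric, the per-class table and the test
#' results; the CSV holds the per-class table.  [read_report()] round-trips
#' the JSON.
#' @param report a `metrics_report`
#' @param path output path without extension (writes `<path>.json` and
#'   `<path>_per_class.csv`)
#' @param tests optional named list of `cyto_test_result`
#' @return named list of the files written, invisibly
#' @export
write_report <- function(report, path, tests = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  json_file <- paste0(path, ".json")
  csv_file <- paste0(path, "_per_class.csv")
  payload <- list(
    accuracy = report$accuracy,
    macro_precision = report$macro_precision,
    macro_recall = report$macro_recall,
    macro_f1 = report$macro_f1,
    macro_specificity = report$macro_specificity,
    g_means = report$g_means,
    per_class = report$per_class,
    tests = lapply(tests, function(t)
      list(test = t$test, branch = t$branch, statistic = t$statistic,
           p_value = t$p_value, significant = t$significant,
           degenerate = t$degenerate)))
  jsonlite::write_json(payload, json_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(report$per_class, csv_file, row.names = FALSE)
  invisible(list(json = json_file, csv = csv_file))
}

#' Read back a JSON report written by [write_report()]
#' @param json_file path to the `.json` file
#' @return a `metrics_report` (tests attached as attribute "tests")
#' @export
read_report <- function(json_file) {
  x <- jsonlite::read_json(json_file, simplifyVector = TRUE)
  rep <- list(accuracy = x$accuracy, macro_precision = x$macro_precision,
              macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
              macro_specificity = x$macro_specificity, g_means = x$g_means,
              per_class = as.data.frame(x$per_class))
  class(rep) <- "metrics_report"
  attr(rep, "tests") <- x$tests
  rep
}

#' Evaluate a model on a manifest
#' @param m a `cyto_model`
#' @param manifest a `cyto_manifest`
#' @param config run configuration (for the image size)
#' @return a `metrics_report` with the confusion matrix attached as
#'   attribute "cm"
#' @export
evaluate_model <- function(m, manifest, config = m$config) {
  dat <- load_images(manifest, preproc_config(config$data$image_size))
  probs <- model_predict(m, dat$x)
  preds <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(preds, dat$y, m$n_classes)
  rep <- macro_metrics(cm)
  attr(rep, "cm") <- cm
  rep
}
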