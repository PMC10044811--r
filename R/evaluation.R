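#' @title Performance and comparison statistics
#' @description ROC/AUC with DeLong confidence intervals, confusion
#'   metrics with exact Clopper-Pearson intervals, DeLong's paired AUC
#'   test, Cohen's kappa, Bonferroni-corrected Mann-Whitney feature
#'   screens and demographic-table tests.  Malignant (ALT/WDLS) is the
#'   positive class throughout.
#' @name evaluation
NULL

# DeLong structural components: list(auc, v10 (per malignant), v01)
delong_components <- function(labels, scores) {
  pos <- scores[labels == "malignant"]
  neg <- scores[labels == "benign"]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' ROC AUC with a DeLong-variance confidence interval
#'
#' AUC equals the Mann-Whitney statistic divided by `n1 * n0` with ties
#' counted one-half; the 95% CI uses the DeLong structural-component
#' variance with normal quantiles, clamped to \\[0, 1\\].
#'
#' @param labels `"benign"`/`"malignant"` vector.
#' @param scores numeric scores, larger = more malignant (binary reader
#'   calls may be coded 0/1).
#' @param conf_level confidence level.
#' @return List with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores, conf_level = 0.95) {
  cmp <- delong_components(labels, scores)
  n1 <- length(cmp$v10); n0 <- length(cmp$v01)
  v <- (if (n1 > 1) var(cmp$v10) / n1 else 0) +
       (if (n0 > 1) var(cmp$v01) / n0 else 0)
  se <- sqrt(v)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(cmp$auc + c(-1, 1) * z * se, 0), 1)
  list(auc = cmp$auc, ci = ci, se = se, n_pos = n1, n_neg = n0)
}

#' DeLong's test for two paired ROC curves
#'
#' Compares the AUCs of two score vectors over the same lesions via the
#' difference of AUCs divided by its DeLong covariance; two-sided p.
#' Identical score vectors give z = 0 and p = 1.
#'
#' @param labels shared true labels.
#' @param scores_a,scores_b paired score vectors.
#' @return List with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) ||
      length(labels) != length(scores_a))
    stop("inputs must be paired (equal lengths)")
  ca <- delong_components(labels, scores_a)
  cb <- delong_components(labels, scores_b)
  n1 <- length(ca$v10); n0 <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- ca$auc - cb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Confusion metrics with exact binomial confidence intervals
#'
#' Sensitivity is computed on the malignant class, specificity on the
#' benign class; 95% CIs are Clopper-Pearson exact intervals.
#'
#' @param labels true labels (`"benign"`/`"malignant"`).
#' @param scores numeric scores or probabilities (binary calls coded 0/1
#'   work unchanged).
#' @param threshold score threshold for calling malignancy.
#' @param conf_level confidence level.
#' @return An object of class `classification_report`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5,
                              conf_level = 0.95) {
  call_pos <- scores >= threshold
  is_pos <- labels == "malignant"
  tp <- sum(call_pos & is_pos); fn <- sum(!call_pos & is_pos)
  tn <- sum(!call_pos & !is_pos); fp <- sum(call_pos & !is_pos)
  if (tp + fn == 0) stop("no malignant lesions: sensitivity undefined")
  if (tn + fp == 0) stop("no benign lesions: specificity undefined")
  cp <- function(x, n) {
    bt <- binom.test(x, n, conf.level = conf_level)
    c(est = x / n, lo = bt$conf.int[1], hi = bt$conf.int[2])
  }
  structure(list(sensitivity = cp(tp, tp + fn),
                 specificity = cp(tn, tn + fp),
                 accuracy = cp(tp + tn, tp + tn + fp + fn),
                 auc = roc_auc(labels, scores, conf_level),
                 threshold = threshold,
                 counts = c(TP = tp, FN = fn, TN = tn, FP = fp)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f (%.1f-%.1f)", 100 * v[1], 100 * v[2],
                             100 * v[3])
  cat("AUC (95% CI): ", sprintf("%.2f (%.2f-%.2f)", x$auc$auc,
                                x$auc$ci[1], x$auc$ci[2]), "\n", sep = "")
  cat("Sensitivity % (95% CI): ", pct(x$sensitivity), "\n", sep = "")
  cat("Specificity % (95% CI): ", pct(x$specificity), "\n", sep = "")
  cat("Accuracy    % (95% CI): ", pct(x$accuracy), "\n", sep = "")
  cat("Counts: ", paste(names(x$counts), x$counts, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Cohen's kappa for two raters' binary calls
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with an asymptotic
#' normal confidence interval.  Two identical constant vectors (perfect,
#' chance-saturated agreement) return kappa 1 by convention.
#'
#' @param calls_a,calls_b paired categorical vectors.
#' @param conf_level confidence level.
#' @return List with `kappa`, `ci`, `po`, `pe`, `n`.
#' @export
cohen_kappa <- function(calls_a, calls_b, conf_level = 0.95) {
  if (length(calls_a) != length(calls_b))
    stop("call vectors differ in length")
  n <- length(calls_a)
  lev <- union(unique(calls_a), unique(calls_b))
  a <- factor(calls_a, levels = lev)
  b <- factor(calls_b, levels = lev)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    kappa <- if (po == 1) 1 else 0
    return(list(kappa = kappa, ci = c(kappa, kappa), po = po, pe = pe,
                n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(kappa + c(-1, 1) * z * se, -1), 1)
  list(kappa = kappa, ci = ci, po = po, pe = pe, n = n)
}

#' Bonferroni-corrected Mann-Whitney feature screens
#'
#' Two-sided Mann-Whitney U test of each feature between benign and
#' malignant lesions (exact for small tie-free samples, tie-corrected
#' normal approximation otherwise, as in [stats::wilcox.test]); adjusted
#' p = `min(1, m * p)` over the `m` tested features.
#'
#' @param table feature table with `label` and feature columns.
#' @param feature_names features to test (default: all feature columns).
#' @return data.frame with `feature`, `U`, `p`, `p_adj`.
#' @export
group_feature_tests <- function(table, feature_names = NULL) {
  if (is.null(feature_names))
    feature_names <- setdiff(names(table), c("case_id", "label"))
  if (length(unique(table$label)) < 2)
    stop("both classes must be present")
  m <- length(feature_names)
  rows <- lapply(feature_names, function(f) {
    x <- table[[f]][table$label == "benign"]
    y <- table[[f]][table$label == "malignant"]
    if (length(unique(c(x, y))) == 1L) {
      warning("feature '", f, "' is constant; p set to 1")
      return(data.frame(feature = f, U = length(x) * length(y) / 2,
                        p = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y))
    data.frame(feature = f, U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p)
  out
}

#' Demographic-table tests
#'
#' Categorical covariates: Pearson chi-squared without continuity
#' correction, falling back to Fisher's exact test when any expected cell
#' count is below 5.  Continuous covariates: Welch's t test (or
#' Mann-Whitney when `continuous = "wilcox"`).
#'
#' @param data data.frame of per-case covariates including `label`.
#' @param covariates character vector of column names to test.
#' @param continuous `"t"` or `"wilcox"`.
#' @param correct apply the chi-squared continuity correction.
#' @return data.frame with `covariate`, `test`, `statistic`, `p`.
#' @export
demographics_tests <- function(data, covariates,
                               continuous = c("t", "wilcox"),
                               correct = FALSE) {
  continuous <- match.arg(continuous)
  rows <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    g <- data$label
    if (is.numeric(x)) {
      ht <- if (continuous == "t") t.test(x ~ g)
            else suppressWarnings(wilcox.test(x ~ g))
      data.frame(covariate = cv, test = ht$method,
                 statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      tab <- table(x, g)
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_counts < 5)) {
        ht <- fisher.test(tab)
        data.frame(covariate = cv, test = "Fisher exact",
                   statistic = NA_real_, p = ht$p.value)
      } else {
        ht <- chisq.test(tab, correct = correct)
        data.frame(covariate = cv, test = "Pearson chi-squared",
                   statistic = unname(ht$statistic), p = ht$p.value)
      }
    }
  })
  do.call(rbind, rows)
}
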