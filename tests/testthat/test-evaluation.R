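test_that("AUC equals the pairwise concordance probability", {
  lab <- c("malignant", "malignant", "benign", "benign")
  expect_equal(roc_auc(lab, c(0.9, 0.8, 0.7, 0.6))$auc, 1)
  expect_equal(roc_auc(lab, c(0.9, 0.6, 0.7, 0.8))$auc, 0.5)  # one pair swapped both ways
  expect_equal(roc_auc(lab, c(0.9, 0.7, 0.8, 0.6))$auc, 0.75)
  expect_equal(roc_auc(lab, c(0.5, 0.5, 0.5, 0.5))$auc, 0.5)  # all ties
  expect_error(roc_auc(rep("benign", 4), 1:4), "both classes")
})

test_that("AUC is invariant under monotone transforms and matches pROC with DeLong CI", {
  set.seed(71)
  lab <- sample(rep(c("benign", "malignant"), c(30, 25)))
  sc <- rnorm(55) + (lab == "malignant")
  a1 <- roc_auc(lab, sc)
  a2 <- roc_auc(lab, exp(2 * sc))
  expect_equal(a1$auc, a2$auc)
  r <- pROC::roc(lab, sc, levels = c("benign", "malignant"),
                 direction = "<", quiet = TRUE)
  expect_equal(a1$auc, as.numeric(pROC::auc(r)))
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(a1$ci, ci[c(1, 3)], tolerance = 1e-9)
})

test_that("random scores give a null AUC near one half", {
  set.seed(72)
  lab <- sample(rep(c("benign", "malignant"), each = 500))
  auc <- roc_auc(lab, rnorm(1000))$auc
  expect_gt(auc, 0.44); expect_lt(auc, 0.56)
})

test_that("confusion metrics and Clopper-Pearson intervals are exact", {
  lab <- c(rep("malignant", 10), rep("benign", 10))
  sc <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  rep_ <- confusion_metrics(lab, sc, threshold = 0.5)
  expect_equal(unname(rep_$counts), c(9, 1, 8, 2))  # TP FN TN FP
  expect_equal(unname(rep_$sensitivity["est"]), 0.9)
  expect_equal(unname(rep_$specificity["est"]), 0.8)
  expect_equal(unname(rep_$accuracy["est"]), 0.85)
  all_right <- confusion_metrics(lab, as.numeric(lab == "malignant"))
  expect_equal(unname(all_right$sensitivity["est"]), 1)
  expect_equal(unname(all_right$specificity["est"]), 1)
  expect_equal(unname(all_right$accuracy["est"]), 1)
  # 10/10 successes: exact lower bound 0.025^(1/10)
  expect_equal(unname(all_right$sensitivity["lo"]), 0.025^(1 / 10),
               tolerance = 1e-9)
  expect_equal(unname(all_right$sensitivity["hi"]), 1)
  expect_error(confusion_metrics(rep("benign", 3), c(1, 0, 1)),
               "no malignant")
})

test_that("DeLong's paired test: identity, symmetry, oracle and power", {
  set.seed(73)
  lab <- sample(rep(c("benign", "malignant"), each = 100))
  strong <- rnorm(200) + 2 * (lab == "malignant")
  weak <- rnorm(200)
  expect_equal(delong_test(lab, strong, strong)$p, 1)
  d1 <- delong_test(lab, strong, weak)
  d2 <- delong_test(lab, weak, strong)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$z, -d2$z)
  expect_lt(d1$p, 0.01)
  # cross-check z and p against the pROC DeLong implementation
  pr <- pROC::roc.test(
    pROC::roc(lab, strong, levels = c("benign", "malignant"),
              direction = "<", quiet = TRUE),
    pROC::roc(lab, weak, levels = c("benign", "malignant"),
              direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(d1$z, unname(pr$statistic), tolerance = 1e-9)
  expect_equal(d1$p, pr$p.value, tolerance = 1e-9)
  expect_error(delong_test(lab, strong, weak[1:50]), "paired")
})

test_that("Cohen's kappa follows the direct formula and its null is centred", {
  a <- rep(c("pos", "neg"), c(30, 20))
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  # 2x2 agreement: both+ 20, both- 15, a+b- 5, a-b+ 10
  calls_a <- rep(c("pos", "pos", "neg", "neg"), c(20, 5, 10, 15))
  calls_b <- rep(c("pos", "neg", "pos", "neg"), c(20, 5, 10, 15))
  po <- 35 / 50
  pe <- (25 / 50) * (30 / 50) + (25 / 50) * (20 / 50)
  k <- cohen_kappa(calls_a, calls_b)
  expect_equal(k$kappa, (po - pe) / (1 - pe))
  expect_equal(k$kappa, 0.4)
  # swapping the raters leaves kappa unchanged
  expect_equal(cohen_kappa(calls_b, calls_a)$kappa, k$kappa)
  set.seed(74)
  r1 <- sample(c("pos", "neg"), 1000, replace = TRUE)
  r2 <- sample(c("pos", "neg"), 1000, replace = TRUE)
  k0 <- cohen_kappa(r1, r2)$kappa
  expect_gt(k0, -0.1); expect_lt(k0, 0.1)
  expect_error(cohen_kappa(r1, r2[1:10]), "length")
})

test_that("Mann-Whitney screens report exact small-sample p and Bonferroni caps", {
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 3),
                    f1 = c(1, 2, 3, 4, 5, 6),
                    f2 = c(1, 2, 3, 1, 2, 3))
  res <- group_feature_tests(tab, c("f1", "f2"))
  expect_equal(res$U[res$feature == "f1"], 0)
  expect_equal(res$p[res$feature == "f1"], 0.1)   # exact enumeration
  expect_equal(res$p_adj[res$feature == "f1"], 0.2)
  expect_equal(res$p[res$feature == "f2"], 1)
  expect_true(all(res$p_adj >= res$p & res$p_adj <= 1))
  const <- data.frame(label = tab$label, f3 = rep(1, 6))
  expect_warning(res3 <- group_feature_tests(const, "f3"), "constant")
  expect_equal(res3$p_adj, 1)
})

test_that("a planted shift among 14 features is the only discovery", {
  hits_planted <- 0; hits_null <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 100
    dat <- as.data.frame(matrix(rnorm(2 * n * 14), 2 * n, 14))
    names(dat) <- paste0("f", 1:14)
    dat$label <- rep(c("benign", "malignant"), each = n)
    dat$f1 <- dat$f1 + 0.8 * (dat$label == "malignant")
    res <- group_feature_tests(dat, paste0("f", 1:14))
    if (res$p_adj[1] < 0.05) hits_planted <- hits_planted + 1
    if (any(res$p_adj[-1] < 0.05)) hits_null <- hits_null + 1
  }
  expect_gte(hits_planted, 18)
  expect_lte(hits_null, 2)
})

test_that("demographic tests reproduce the printed gender contrast", {
  dat <- data.frame(
    label = rep(c("benign", "malignant"), c(38, 30)),
    gender = c(rep(c("M", "F"), c(10, 28)), rep(c("M", "F"), c(16, 14))),
    age = c(rnorm(38, 55, 10), rnorm(30, 57, 10)))
  res <- demographics_tests(dat, c("gender", "age"))
  expect_equal(res$test[1], "Pearson chi-squared")
  expect_equal(round(res$p[1], 2), 0.02)
  expect_equal(res$test[2], "Welch Two Sample t-test")
  # identical groups: p = 1
  same <- data.frame(label = rep(c("benign", "malignant"), each = 4),
                     sex = rep(c("M", "F"), 4))
  expect_equal(demographics_tests(same, "sex")$p, 1)
})

test_that("small expected counts trigger Fisher's exact hypergeometric p", {
  dat <- data.frame(label = rep(c("benign", "malignant"), c(12, 5)),
                    site = c(rep("thigh", 11), "calf",
                             rep("thigh", 1), rep("calf", 4)))
  res <- demographics_tests(dat, "site")
  expect_equal(res$test, "Fisher exact")
  # enumeration oracle: two-sided Fisher sums hypergeometric tables
  tab <- table(dat$site, dat$label)
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  probs <- dhyper(0:k, m, n, k)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  expect_equal(res$p, p_oracle, tolerance = 1e-9)
})
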