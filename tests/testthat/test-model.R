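std_mat <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  sweep(sweep(x, 2, ctr), 2, scl, `/`)
}

test_that("the stratified split reproduces the documented 48/20 partition", {
  labels <- setNames(c(rep("benign", 38), rep("malignant", 30)),
                     sprintf("case_%03d", 1:68))
  plan <- make_split(labels, ratio = 0.7, folds = 10, seed = 3)
  expect_length(plan$learning_ids, 48L)
  expect_length(plan$testing_ids, 20L)
  expect_setequal(c(plan$learning_ids, plan$testing_ids), names(labels))
  # folds partition the learning set, stratified by class
  expect_setequal(names(plan$fold_assignment), plan$learning_ids)
  expect_equal(sort(unique(plan$fold_assignment)), 1:10)
  plan2 <- make_split(labels, ratio = 0.7, folds = 10, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_split(labels, ratio = 1.0), "ratio")
  expect_error(make_split(labels[1:12], folds = 10), "fewer")
})

test_that("full shrinkage zeroes all coefficients and leaves the prior log-odds", {
  set.seed(61)
  x <- std_mat(matrix(rnorm(200 * 8), 200, 8))
  colnames(x) <- paste0("f", 1:8)
  y <- rbinom(200, 1, 0.3)
  fit <- lasso_logistic(x, y, lambda = 10)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, log(mean(y) / (1 - mean(y))), tolerance = 1e-6)
  # just above lambda_max everything stays zero as well
  lmax <- max(abs(crossprod(x, y - mean(y)))) / nrow(x)
  fit2 <- lasso_logistic(x, y, lambda = lmax * 1.0001)
  expect_true(all(fit2$beta == 0))
})

test_that("the unpenalized fit matches the glm Newton oracle", {
  set.seed(62)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4)
  colnames(x) <- paste0("f", 1:4)
  eta <- 0.5 + x %*% c(1, -0.5, 0, 0.8)
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  xs <- std_mat(x)
  fit <- lasso_logistic(xs, y, lambda = 0)
  oracle <- glm(y ~ xs, family = binomial())
  expect_lt(max(abs(fit$beta - coef(oracle)[-1])), 1e-4)
  expect_lt(abs(fit$intercept - coef(oracle)[1]), 1e-4)
})

test_that("KKT conditions hold along the path and glmnet agrees", {
  set.seed(63)
  n <- 200; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", 1:p)
  y <- rbinom(n, 1, 1 / (1 + exp(-(1.5 * x[, 1] - x[, 2]))))
  xs <- std_mat(x)
  for (lam in c(0.2, 0.05, 0.01)) {
    fit <- lasso_logistic(xs, y, lam)
    expect_lt(kkt_violation(xs, y, fit, lam), 1e-6)
  }
  library(glmnet)
  lam <- 0.05
  gn <- glmnet(xs, y, family = "binomial", lambda = lam,
               standardize = FALSE, thresh = 1e-12)
  fit <- lasso_logistic(xs, y, lam)
  expect_lt(max(abs(fit$beta - as.vector(gn$beta))), 1e-4)
  expect_lt(abs(fit$intercept - gn$a0), 1e-4)
})

test_that("moderate penalties keep the informative feature and drop noise", {
  set.seed(64)
  n <- 200
  x <- cbind(info = rnorm(n), matrix(rnorm(n * 9), n, 9))
  colnames(x)[2:10] <- paste0("noise", 1:9)
  y <- rbinom(n, 1, 1 / (1 + exp(-2 * x[, 1])))
  fit <- lasso_logistic(std_mat(x), y, lambda = 0.08)
  expect_true(fit$beta["info"] != 0)
  expect_gte(sum(fit$beta[2:10] == 0), 7)
})

test_that("CV selects zero-error penalties for separable data and behaves under the null", {
  set.seed(65)
  n <- 100
  sep <- rep(c(0, 1), each = n / 2)
  x <- cbind(s1 = sep + rnorm(n, 0, 0.01), s2 = sep + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 4), n, 4))
  colnames(x)[3:6] <- paste0("n", 1:4)
  y <- ifelse(sep == 1, "malignant", "benign")
  fit <- cv_lasso_logistic(x, y, ratio = 0.7, folds = 5, seed = 1)
  expect_equal(min(fit$cv_error), 0)
  expect_true(all(c("s1", "s2") %in% fit$feature_names))
  # permuted labels: CV error of the chosen model close to the prior error
  set.seed(66)
  xn <- matrix(rnorm(100 * 6), 100, 6)
  colnames(xn) <- paste0("f", 1:6)
  yn <- sample(rep(c("benign", "malignant"), each = 50))
  fit0 <- cv_lasso_logistic(xn, yn, ratio = 0.7, folds = 5, seed = 2)
  expect_lt(abs(min(fit0$cv_error) - 0.5), 0.1 + 1e-9)
  # grid of length 1: that penalty is chosen
  fit1 <- cv_lasso_logistic(xn, yn, ratio = 0.7, folds = 5, seed = 2,
                            lambda = 0.07)
  expect_equal(fit1$lambda_min, 0.07)
})

test_that("ties at the minimum go to the larger (sparser) penalty", {
  set.seed(67)
  x <- matrix(rnorm(80 * 3), 80, 3)
  colnames(x) <- paste0("f", 1:3)
  y <- sample(rep(c("benign", "malignant"), each = 40))
  fit <- cv_lasso_logistic(x, y, ratio = 0.7, folds = 5, seed = 4,
                           lambda = c(5, 1))
  # both penalties shrink everything to zero, so CV errors tie
  expect_equal(fit$cv_error[1], fit$cv_error[2])
  expect_equal(fit$lambda_min, 5)
})

test_that("the fitted classifier is deterministic, sparse and predicts sensibly", {
  tab <- default_table()
  fit <- cv_lasso_logistic(tab, seed = 9)
  fit2 <- cv_lasso_logistic(tab, seed = 9)
  expect_identical(coef(fit), coef(fit2))
  expect_gt(length(fit$selected), 0)
  expect_true(all(fit$selected %in% setdiff(names(tab),
                                            c("case_id", "label"))))
  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  cls <- predict(fit, type = "class")
  expect_setequal(unique(cls), c("benign", "malignant"))
  bad <- tab[, !(names(tab) %in% c(fit$selected))]
  expect_error(predict(fit, newdata = bad), "missing selected feature")
})

test_that("hand-computed logistic predictions and importance ordering hold", {
  fit <- structure(list(
    coefficients = c(a = 0.5, b = -0.9, c = 0),
    intercept = 0.2, selected = c("a", "b"),
    centre = c(a = 1, b = 2, c = 0), scale = c(a = 2, b = 1, c = 1),
    threshold = 0.5, feature_names = c("a", "b", "c")),
    class = "cv_lasso_logistic")
  nd <- cbind(a = c(1, 3), b = c(2, 1), c = c(0, 0))
  eta <- 0.2 + 0.5 * (nd[, "a"] - 1) / 2 - 0.9 * (nd[, "b"] - 2)
  expect_equal(predict(fit, nd), 1 / (1 + exp(-eta)))
  expect_equal(unname(predict(fit, cbind(a = 1, b = 2, c = 9))), 1 / (1 + exp(-0.2)))
  imp <- importance_ranking(fit)
  expect_equal(imp$feature, c("b", "a"))
  expect_equal(imp$importance, c(0.9, 0.5))
  # order of feature columns in the data does not matter
  expect_equal(predict(fit, nd[, c("b", "c", "a")]), predict(fit, nd))
  fit$coefficients[] <- 0
  expect_equal(nrow(importance_ranking(fit)), 0L)
})
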