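#' Stratified learning/testing split with CV fold assignment
#'
#' Splits lesions 70/30 into learning and testing sets stratified by
#' label (the learning share of each class is `ceiling(ratio * n_class)`,
#' so 68 lesions at ratio 0.7 give 48 learning / 20 testing), and assigns
#' stratified cross-validation folds within the learning set.
#'
#' @param labels factor/character vector of class labels, named by lesion
#'   id (or a `data.frame` with `case_id` and `label` columns).
#' @param ratio learning-set proportion, in (0, 1).
#' @param folds number of CV folds.
#' @param seed RNG seed.
#' @return An object of class `split_plan` with `learning_ids`,
#'   `testing_ids` and `fold_assignment` (named integer vector).
#' @export
make_split <- function(labels, ratio = 0.7, folds = 10, seed = 1) {
  if (is.data.frame(labels))
    labels <- setNames(labels$label, labels$case_id)
  if (is.null(names(labels)))
    names(labels) <- sprintf("case_%03d", seq_along(labels))
  if (ratio <= 0 || ratio >= 1)
    stop("`ratio` must be strictly between 0 and 1")
  set.seed(seed)
  learning <- character(0)
  for (cl in unique(labels)) {
    ids <- names(labels)[labels == cl]
    n_learn <- ceiling(ratio * length(ids))
    learning <- c(learning, sample(ids, n_learn))
  }
  testing <- setdiff(names(labels), learning)
  if (length(testing) == 0L) stop("testing set is empty")
  fold <- integer(0)
  for (cl in unique(labels)) {
    ids <- sample(intersect(learning, names(labels)[labels == cl]))
    if (length(ids) < folds)
      stop("class '", cl, "' has fewer learning lesions than folds")
    fold <- c(fold, setNames(rep_len(seq_len(folds), length(ids)), ids))
  }
  structure(list(learning_ids = sort(learning), testing_ids = sort(testing),
                 fold_assignment = fold[order(names(fold))],
                 ratio = ratio, folds = folds, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> learning ", length(x$learning_ids), " / testing ",
      length(x$testing_ids), ", ", x$folds, " folds, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' L1-penalized logistic regression by cyclic coordinate descent
#'
#' Minimizes `(1/n) * sum(log(1 + exp(-(2y-1) eta))) + lambda * sum(|beta|)`
#' with an unpenalized intercept, by iteratively reweighted least squares
#' with cyclic coordinate descent on the quadratic approximation.  `x` is
#' expected to be standardized column-wise by the caller.
#'
#' @param x numeric matrix (n x p), standardized columns.
#' @param y 0/1 response vector.
#' @param lambda non-negative penalty.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum outer iterations.
#' @return List with `beta` (named), `intercept`, `iterations`,
#'   `converged`.
#' @export
lasso_logistic <- function(x, y, lambda, tol = 1e-10, max_iter = 200) {
  x <- as.matrix(x)
  if (lambda < 0) stop("`lambda` must be non-negative")
  fit <- cpp_lasso_path(x, as.numeric(y), lambda, tol, max_iter)
  if (!fit$converged[1])
    stop("lasso_logistic did not converge in ", max_iter,
         " IRLS iterations (lambda = ", format(lambda), ")")
  beta <- drop(fit$beta)
  names(beta) <- colnames(x)
  list(beta = beta, intercept = fit$intercept[1],
       iterations = fit$iterations[1], converged = fit$converged[1])
}

# full solution path with warm starts (lambdas must be decreasing)
lasso_logistic_path <- function(x, y, lambdas, tol = 1e-9, max_iter = 200) {
  fit <- cpp_lasso_path(as.matrix(x), as.numeric(y), lambdas, tol, max_iter)
  rownames(fit$beta) <- colnames(x)
  fit
}

# lambda grid: log-spaced from lambda_max down to ratio * lambda_max
lambda_grid <- function(x, y, nlambda = 100, min_ratio = 1e-4) {
  n <- nrow(x)
  lmax <- max(abs(crossprod(x, y - mean(y)))) / n
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(centre = ctr, scale = scl,
       xs = sweep(sweep(x, 2, ctr), 2, scl, `/`))
}

#' Cross-validated LASSO logistic classifier
#'
#' The core modelling workflow: a stratified 70/30 learning/testing split,
#' tenfold cross-validation on the learning set in which feature selection
#' and model fitting are one and the same LASSO logistic fit re-run inside
#' each training fold, the penalty chosen at the minimum mean CV
#' misclassification error (ties resolved toward the larger, sparser
#' penalty), and a final refit on the full learning set.
#'
#' @param x numeric feature matrix (lesions x features) with lesion ids as
#'   row names, or a feature table `data.frame` containing `case_id`,
#'   `label` and feature columns.
#' @param y class labels (`"benign"`/`"malignant"`); malignant is the
#'   positive class.  Ignored when `x` is a feature table.
#' @param plan optional [make_split] plan; built from `ratio`/`folds`/
#'   `seed` when absent.
#' @param ratio,folds,seed split parameters when `plan` is `NULL`.
#' @param lambda optional decreasing penalty grid; default 100 log-spaced
#'   values from the smallest all-zero penalty down by 1e-4.
#' @param threshold classification probability threshold.
#' @return An object of class `cv_lasso_logistic` with the penalty path,
#'   CV error curve, chosen penalty, standardized coefficients of the
#'   final refit, and the split plan.  Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`.
#' @export
cv_lasso_logistic <- function(x, y = NULL, plan = NULL, ratio = 0.7,
                              folds = 10, seed = 1, lambda = NULL,
                              threshold = 0.5) {
  if (is.data.frame(x) && "label" %in% names(x)) {
    ids <- if ("case_id" %in% names(x)) x$case_id else rownames(x)
    y <- setNames(x$label, ids)
    x <- as.matrix(x[, setdiff(names(x), c("case_id", "label")),
                     drop = FALSE])
    rownames(x) <- ids
  } else {
    x <- as.matrix(x)
    if (is.null(rownames(x)))
      rownames(x) <- sprintf("case_%03d", seq_len(nrow(x)))
    if (is.null(names(y))) y <- setNames(y, rownames(x))
  }
  y01 <- as.integer(y == "malignant")
  if (all(y01 == 0L) && any(y %in% c(0, 1)))
    y01 <- as.integer(as.numeric(y))     # numeric 0/1 labels
  names(y01) <- names(y)
  if (length(unique(y01)) < 2L) stop("both classes must be present")
  if (is.null(plan))
    plan <- make_split(setNames(ifelse(y01 == 1, "malignant", "benign"),
                                names(y01)),
                       ratio = ratio, folds = folds, seed = seed)

  xl <- x[plan$learning_ids, , drop = FALSE]
  yl <- y01[plan$learning_ids]
  std <- standardize_fit(xl)
  if (is.null(lambda))
    lambda <- lambda_grid(std$xs, yl)
  lambda <- sort(lambda, decreasing = TRUE)

  fold <- plan$fold_assignment[plan$learning_ids]
  nfold <- max(fold)
  err <- matrix(NA_real_, length(lambda), nfold)
  for (f in seq_len(nfold)) {
    tr <- fold != f
    if (length(unique(yl[tr])) < 2L || length(unique(yl[!tr])) < 1L)
      stop("stratification error: fold ", f, " lacks a class")
    stdf <- standardize_fit(xl[tr, , drop = FALSE])
    xv <- sweep(sweep(xl[!tr, , drop = FALSE], 2, stdf$centre), 2,
                stdf$scale, `/`)
    path <- lasso_logistic_path(stdf$xs, yl[tr], lambda, tol = 1e-7)
    eta <- sweep(xv %*% path$beta, 2, path$intercept, `+`)
    pv <- 1 / (1 + exp(-eta))
    err[, f] <- colMeans((pv >= threshold) != (yl[!tr] == 1L))
  }
  cv_mean <- rowMeans(err)
  cv_sd <- apply(err, 1, sd)
  best <- which(cv_mean == min(cv_mean))[1]  # grid descending: largest lambda
  lambda_min <- lambda[best]

  fit <- lasso_logistic(std$xs, yl, lambda_min)
  sel <- names(fit$beta)[fit$beta != 0]
  structure(list(lambda = lambda, cv_error = cv_mean, cv_sd = cv_sd,
                 lambda_min = lambda_min,
                 coefficients = fit$beta, intercept = fit$intercept,
                 selected = sel,
                 centre = std$centre, scale = std$scale,
                 threshold = threshold, plan = plan,
                 x = x, y = y01, feature_names = colnames(x)),
            class = "cv_lasso_logistic")
}

#' @export
print.cv_lasso_logistic <- function(x, ...) {
  cat("Cross-validated LASSO logistic classifier\n")
  cat("  learning/testing: ", length(x$plan$learning_ids), "/",
      length(x$plan$testing_ids), " lesions, ", x$plan$folds,
      "-fold CV\n", sep = "")
  cat("  lambda (min CV misclassification): ",
      format(x$lambda_min, digits = 3), "  [log(lambda) = ",
      round(log(x$lambda_min), 2), "]\n", sep = "")
  cat("  CV error at minimum: ",
      round(min(x$cv_error), 3), "\n", sep = "")
  cat("  selected features (", length(x$selected), "): ",
      paste(head(x$selected, 8), collapse = ", "),
      if (length(x$selected) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
coef.cv_lasso_logistic <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict method for the LASSO classifier
#'
#' @param object a fitted `cv_lasso_logistic`.
#' @param newdata matrix or data.frame of features on the original scale;
#'   must contain every selected feature.  Defaults to the testing set.
#' @param type `"response"` (probability of malignancy), `"class"`, or
#'   `"link"`.
#' @param ... unused.
#' @export
predict.cv_lasso_logistic <- function(object,
                                      newdata = NULL,
                                      type = c("response", "class", "link"),
                                      ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- object$x[object$plan$testing_ids, , drop = FALSE]
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, setdiff(names(newdata),
                                           c("case_id", "label")),
                                 drop = FALSE])
  need <- object$selected
  missing <- setdiff(need, colnames(newdata))
  if (length(missing) > 0)
    stop("newdata is missing selected feature(s): ",
         paste(missing, collapse = ", "))
  link <- rep(object$intercept, nrow(newdata))
  for (j in need) {
    xs <- (newdata[, j] - object$centre[j]) / object$scale[j]
    link <- link + xs * object$coefficients[j]
  }
  switch(type,
         link = link,
         response = 1 / (1 + exp(-link)),
         class = ifelse(1 / (1 + exp(-link)) >= object$threshold,
                        "malignant", "benign"))
}

#' @export
summary.cv_lasso_logistic <- function(object, ...) {
  imp <- importance_ranking(object)
  test_scores <- predict(object)
  test_labels <- ifelse(object$y[object$plan$testing_ids] == 1L,
                        "malignant", "benign")
  rep <- confusion_metrics(test_labels, test_scores, object$threshold)
  out <- list(model = object, importance = imp, test_report = rep)
  class(out) <- "summary.cv_lasso_logistic"
  out
}

#' @export
print.summary.cv_lasso_logistic <- function(x, ...) {
  print(x$model)
  cat("\nFeature importance (|standardized coefficient|):\n")
  print(x$importance, row.names = FALSE)
  cat("\nTesting-set performance:\n")
  print(x$test_report)
  invisible(x)
}

#' CV misclassification curve
#'
#' @param x a `cv_lasso_logistic`.
#' @param ... passed to [plot].
#' @export
plot.cv_lasso_logistic <- function(x, ...) {
  plot(log(x$lambda), x$cv_error, type = "b", pch = 16, cex = 0.6,
       xlab = expression(log(lambda)),
       ylab = "CV misclassification error", ...)
  graphics::abline(v = log(x$lambda_min), lty = 2, col = "darkgreen")
  invisible(x)
}

#' Feature importance ranking
#'
#' Features with nonzero coefficient, ordered by decreasing absolute
#' standardized coefficient (ties broken by feature name).
#'
#' @param model a fitted `cv_lasso_logistic`.
#' @return data.frame with `feature`, `coefficient`, `importance`.
#' @export
importance_ranking <- function(model) {
  b <- model$coefficients[model$coefficients != 0]
  if (length(b) == 0)
    return(data.frame(feature = character(0), coefficient = numeric(0),
                      importance = numeric(0)))
  ord <- order(-abs(b), names(b))
  data.frame(feature = names(b)[ord], coefficient = unname(b[ord]),
             importance = unname(abs(b[ord])))
}

#' KKT optimality check for a LASSO logistic fit
#'
#' Returns the maximum violation of the subgradient conditions
#' `|g_j| <= lambda` for zero coefficients and `g_j = -lambda * sign(beta_j)`
#' at nonzero ones, where `g = -(1/n) t(x) %*% (y - p)`.
#'
#' @param x standardized design matrix.
#' @param y 0/1 response.
#' @param fit result of [lasso_logistic].
#' @param lambda penalty used.
#' @return Maximum KKT violation (numeric scalar).
#' @export
kkt_violation <- function(x, y, fit, lambda) {
  eta <- fit$intercept + drop(as.matrix(x) %*% fit$beta)
  p <- 1 / (1 + exp(-eta))
  g <- -drop(crossprod(as.matrix(x), y - p)) / nrow(x)
  viol <- ifelse(fit$beta == 0,
                 pmax(abs(g) - lambda, 0),
                 abs(g + lambda * sign(fit$beta)))
  max(c(viol, abs(mean(y - p))))
}
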