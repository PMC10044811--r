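#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA mean squares of an n-lesion x k-rater matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#' Negative values are reported as computed (they always fail the
#' reproducibility filter).
#'
#' @param ratings numeric matrix, lesions in rows, raters/sessions in
#'   columns; no missing cells.
#' @return ICC(2,1) value (scalar in (-Inf, 1]).
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 lesions and 2 raters")
  if (any(!is.finite(ratings))) stop("ratings contain missing values")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den == 0) return(NaN)
  (msr - mse) / den
}

#' Feature-wise agreement between two extractions
#'
#' For each feature shared by two feature tables (same lesions, e.g. two
#' segmentation sessions or two observers), computes ICC(2,1), Pearson r
#' and Spearman rho, and flags the feature as reproducible when
#' ICC strictly exceeds the threshold.
#'
#' @param table_a,table_b feature tables as returned by [extract_cohort]
#'   (matched `case_id` order is enforced by id).
#' @param threshold ICC reproducibility cutoff (default 0.75, strict
#'   inequality).
#' @return A `data.frame` of class `reproducibility_report` with columns
#'   `feature`, `icc`, `pearson_r`, `spearman_rho`, `keep`.
#' @export
agreement_suite <- function(table_a, table_b, threshold = 0.75) {
  if (!setequal(table_a$case_id, table_b$case_id))
    stop("lesion ids do not match between tables")
  table_b <- table_b[match(table_a$case_id, table_b$case_id), ]
  feats <- setdiff(intersect(names(table_a), names(table_b)),
                   c("case_id", "label"))
  if (!setequal(setdiff(names(table_a), c("case_id", "label")), feats))
    stop("feature names do not match between tables")
  rows <- lapply(feats, function(f) {
    a <- table_a[[f]]; b <- table_b[[f]]
    if (any(!is.finite(a)) || any(!is.finite(b)))
      return(data.frame(feature = f, icc = NA_real_, pearson_r = NA_real_,
                        spearman_rho = NA_real_, keep = FALSE,
                        reason = "missing values"))
    if (sd(a) == 0 || sd(b) == 0)
      return(data.frame(feature = f, icc = icc_2_1(cbind(a, b)),
                        pearson_r = NA_real_, spearman_rho = NA_real_,
                        keep = FALSE, reason = "constant feature"))
    icc <- icc_2_1(cbind(a, b))
    data.frame(feature = f, icc = icc,
               pearson_r = cor(a, b),
               spearman_rho = cor(a, b, method = "spearman"),
               keep = is.finite(icc) && icc > threshold,
               reason = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("reproducibility_report", "data.frame")
  out
}

#' Filter reproducible features
#'
#' @param report a `reproducibility_report` (or list of them, in which
#'   case a feature must pass every screen — equivalently the minimum of
#'   its ICCs must pass).
#' @param threshold ICC cutoff; strictly greater-than.
#' @return Character vector of retained feature names, in table order.
#' @export
filter_reproducible <- function(report, threshold = 0.75) {
  if (is.data.frame(report)) report <- list(report)
  if (length(report) == 0L || nrow(report[[1]]) == 0L) return(character(0))
  keep <- Reduce(`&`, lapply(report, function(r)
    is.finite(r$icc) & r$icc > threshold))
  report[[1]]$feature[keep]
}

# ---- mask perturbation (synthetic re-segmentation) ---------------------

shift_mask <- function(mask, ax, by) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  dst[[ax]] <- seq_len(d[ax] - 1) + (if (by > 0) 1L else 0L)
  src[[ax]] <- seq_len(d[ax] - 1) + (if (by > 0) 0L else 1L)
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological erosion/dilation of a mask by one voxel (6-connectivity)
#'
#' Used to emulate observer variability in manual segmentation: a
#' re-segmentation is approximated by growing or shrinking the tumor ROI
#' by one voxel layer.
#'
#' @param mask logical 3D array.
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask) {
  out <- mask
  for (ax in 1:3) for (by in c(-1, 1))
    out <- out & shift_mask(mask, ax, by)
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask) {
  out <- mask
  for (ax in 1:3) for (by in c(-1, 1))
    out <- out | shift_mask(mask, ax, by)
  out
}

#' Re-extract a cohort under a perturbed tumor segmentation
#'
#' @param cohort a `phantom_cohort`.
#' @param config a [feature_config].
#' @param mode `"erode"` or `"dilate"` the tumor mask by one voxel.
#' @return A feature table like [extract_cohort]'s.
#' @export
extract_cohort_perturbed <- function(cohort, config = feature_config(),
                                     mode = c("erode", "dilate")) {
  mode <- match.arg(mode)
  fun <- if (mode == "erode") erode_mask else dilate_mask
  cases <- lapply(cohort$cases, function(cs) {
    m <- fun(cs$masks$tumor)
    if (!any(m)) m <- cs$masks$tumor    # do not erode tiny tumors away
    cs$masks$tumor <- m & !cs$masks$bone
    cs
  })
  extract_cohort(cases, config)
}
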