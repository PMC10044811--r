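#' @title 3D radiomic feature engine
#' @description From-scratch implementation of the 107 standard radiomic
#'   features over seven families (18 first-order, 14 shape, 24 GLCM,
#'   16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) plus the tumor-to-bone distance.
#'   Texture matrices are built in compiled code over the discretized ROI;
#'   feature formulas are evaluated in R on the resulting matrices.
#' @name features
NULL

#' Feature-extraction configuration
#'
#' @param bin_width discretization bin width in NIV units.
#' @param normalize apply fat-referenced NIV normalization before
#'   extraction (requires a reference mask).
#' @param gldm_alpha gray-level similarity tolerance for the dependence
#'   matrix.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(bin_width = 25, normalize = TRUE, gldm_alpha = 0) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  structure(list(bin_width = bin_width, normalize = isTRUE(normalize),
                 gldm_alpha = as.integer(gldm_alpha)),
            class = "feature_config")
}

# log2 with the convention 0 * log2(0) = 0 (inputs are probabilities)
log2p <- function(p) log2(p + (p <= 0))

# ---- first order -------------------------------------------------------

#' First-order (histogram) features
#'
#' @param values numeric vector of (normalized) ROI intensities.
#' @param voxel_volume physical volume of one voxel in mm^3.
#' @param bin_width bin width used for the entropy/uniformity histogram.
#' @return Named numeric vector of the 18 first-order features.
#' @export
first_order_features <- function(values, voxel_volume = 1, bin_width = 25) {
  if (length(values) == 0L) stop("ROI is empty")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  robust <- values[values >= q[1] & values <= q[5]]
  lv <- floor((values - min(values)) / bin_width)
  p <- tabulate(as.integer(lv) + 1L) / n
  p <- p[p > 0]
  c(firstorder_Energy = sum(values^2),
    firstorder_TotalEnergy = voxel_volume * sum(values^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(values),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[5],
    firstorder_Maximum = max(values),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(values) - min(values),
    firstorder_MeanAbsoluteDeviation = mean(abs(values - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      mean(abs(robust - mean(robust))),
    firstorder_RootMeanSquared = sqrt(mean(values^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

# ---- shape -------------------------------------------------------------

# voxels of `mask` with at least one 6-neighbour outside the mask
boundary_voxels <- function(mask) {
  array(cpp_boundary(as.logical(mask), dim(mask)), dim(mask))
}

# smoothed marching-tetrahedra surface: area (mm^2) and volume (mm^3).
# A 3^3 box filter blended with the binary mask (blend = weight of the raw
# mask) rounds off voxel staircase before iso-surfacing at 0.5; thin
# structures that the smoothing erases fall back to the raw binary field.
mesh_area_volume <- function(mask, spacing_mm, blend = 0.1) {
  bb <- mask_bbox(mask)
  mask <- mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
               drop = FALSE]
  d <- dim(mask)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(mask)
  box <- pad
  for (ax in 1:3) {
    dp <- dim(box)
    n <- dp[ax]
    idx <- lapply(dp, seq_len)
    i1 <- idx; i1[[ax]] <- c(1L, seq_len(n - 1))
    i2 <- idx; i2[[ax]] <- c(seq_len(n - 1) + 1L, n)
    box <- (box + box[i1[[1]], i1[[2]], i1[[3]]] +
              box[i2[[1]], i2[[2]], i2[[3]]]) / 3
  }
  field <- blend * pad + (1 - blend) * box
  res <- cpp_mesh(as.numeric(field), dim(field), as.numeric(spacing_mm), 0.5)
  if (res[2] <= 0)
    res <- cpp_mesh(as.numeric(pad), dim(pad), as.numeric(spacing_mm), 0.5)
  list(area = res[1], volume = res[2])
}

#' 3D shape features
#'
#' Mesh-based surface area and volume (marching tetrahedra on a lightly
#' smoothed binary field), principal-axis lengths from the eigenvalues of
#' the voxel-coordinate covariance (axis length `4 * sqrt(lambda)`), and
#' maximum diameters from tumor boundary voxel centres.  If the mask is
#' disconnected, the largest 26-connected component is used.
#'
#' @param mask logical 3D array (tumor ROI).
#' @param spacing_mm per-axis voxel size in mm.
#' @return Named numeric vector of the 14 shape features.
#' @export
shape_features <- function(mask, spacing_mm = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("shape: mask is empty")
  bb <- mask_bbox(mask)   # crop; shape features are translation invariant
  mask <- mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
               drop = FALSE]
  lab <- cpp_label_mask(mask, dim(mask))
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    mask <- array(lab == keep, dim = dim(mask))
  }
  n <- sum(mask)
  if (n < 2L) stop("shape: mask has fewer than 2 voxels; axis features degenerate")
  sp <- as.numeric(spacing_mm)

  mesh <- mesh_area_volume(mask, sp)
  vvol <- n * prod(sp)

  w <- which(mask, arr.ind = TRUE)
  coords <- sweep(w - 1, 2, sp, `*`)
  cv <- stats::cov(coords) * (n - 1) / n
  ev <- sort(pmax(eigen(cv, symmetric = TRUE)$values, 0), decreasing = TRUE)

  bw <- which(boundary_voxels(mask), arr.ind = TRUE)
  bc <- sweep(bw - 1, 2, sp, `*`)
  max3d <- cpp_max_pairwise_dist(bc)
  max2d <- function(plane_axis) {
    best <- 0
    for (g in unique(bw[, plane_axis])) {
      pts <- bc[bw[, plane_axis] == g, , drop = FALSE]
      pts[, plane_axis] <- 0
      if (nrow(pts) > 1) best <- max(best, cpp_max_pairwise_dist(pts))
    }
    best
  }

  sphericity <- (36 * pi * mesh$volume^2)^(1 / 3) / mesh$area
  c(shape_MeshVolume = mesh$volume,
    shape_VoxelVolume = vvol,
    shape_SurfaceArea = mesh$area,
    shape_SurfaceVolumeRatio = mesh$area / mesh$volume,
    shape_Sphericity = sphericity,
    shape_Maximum3DDiameter = max3d,
    shape_Maximum2DDiameterSlice = max2d(3),
    shape_Maximum2DDiameterColumn = max2d(2),
    shape_Maximum2DDiameterRow = max2d(1),
    shape_MajorAxisLength = 4 * sqrt(ev[1]),
    shape_MinorAxisLength = 4 * sqrt(ev[2]),
    shape_LeastAxisLength = 4 * sqrt(ev[3]),
    shape_Elongation = sqrt(ev[2] / ev[1]),
    shape_Flatness = sqrt(ev[3] / ev[1]))
}

# ---- GLCM --------------------------------------------------------------

# weight matrices reused across the 13 directions
glcm_weights <- function(ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  list(ng = ng, i = i, j = j, ij = i * j, dif = abs(i - j),
       dif2 = (i - j)^2, sum = i + j,
       idm = 1 / (1 + (i - j)^2), idmn = 1 / (1 + ((i - j) / ng)^2),
       id = 1 / (1 + abs(i - j)), idn = 1 / (1 + abs(i - j) / ng),
       inv = ifelse(i == j, 0, 1 / pmax((i - j)^2, 1)))
}

glcm_features_one <- function(p, wt = glcm_weights(nrow(p))) {
  ng <- nrow(p)
  i <- wt$i; j <- wt$j
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * p); muy <- sum(j * p)
  sigx <- sqrt(sum((i - mux)^2 * p)); sigy <- sqrt(sum((j - muy)^2 * p))
  # diagonal (difference) and cross-diagonal (sum) probabilities
  kdiff <- 0:(ng - 1)
  pxmy <- as.vector(rowsum(as.vector(p), as.vector(wt$dif)))
  ksum <- 2:(2 * ng)
  pxpy <- as.vector(rowsum(as.vector(p), as.vector(wt$sum)))
  da <- sum(kdiff * pxmy)
  hx <- -sum(log2p(px) * px); hy <- -sum(log2p(py) * py)
  hxy <- -sum(log2p(p) * p)
  pp <- outer(px, py)
  lpp <- log2p(pp)
  hxy1 <- -sum(p * lpp)
  hxy2 <- -sum(pp * lpp)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * p) - mux * muy) / (sigx * sigy) else 1
  mcc <- {
    act <- which(px > 0)
    if (length(act) < 2) 1 else {
      # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)) is similar to B B''
      # with B = diag(px^-1/2) p diag(py^-1/2); use the symmetric form
      bmat <- p[act, act, drop = FALSE] / sqrt(px[act]) /
        rep(sqrt(py[act]), each = length(act))
      lam <- eigen(tcrossprod(bmat), symmetric = TRUE,
                   only.values = TRUE)$values
      sqrt(max(lam[2], 0))
    }
  }
  clus <- wt$sum - mux - muy
  c(glcm_Autocorrelation = sum(wt$ij * p),
    glcm_JointAverage = mux,
    glcm_ClusterProminence = sum(clus^4 * p),
    glcm_ClusterShade = sum(clus^3 * p),
    glcm_ClusterTendency = sum(clus^2 * p),
    glcm_Contrast = sum(wt$dif2 * p),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(log2p(pxmy) * pxmy),
    glcm_DifferenceVariance = sum((kdiff - da)^2 * pxmy),
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = hxy,
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_Idm = sum(p * wt$idm),
    glcm_MCC = mcc,
    glcm_Idmn = sum(p * wt$idmn),
    glcm_Id = sum(p * wt$id),
    glcm_Idn = sum(p * wt$idn),
    glcm_InverseVariance = sum(p * wt$inv),
    glcm_MaximumProbability = max(p),
    glcm_SumAverage = sum(ksum * pxpy),
    glcm_SumEntropy = -sum(log2p(pxpy) * pxpy),
    glcm_SumSquares = sum((i - mux)^2 * p))
}

#' Gray-level co-occurrence features
#'
#' Symmetric co-occurrence at distance 1 over the 13 unique 3D directions;
#' each direction's matrix is normalized separately and the 24 features are
#' averaged over directions with at least one voxel pair.
#'
#' @param glm a [discretize] result (`gray_level_map`).
#' @return Named numeric vector of 24 GLCM features.
#' @export
glcm_features <- function(glm) {
  counts <- cpp_glcm(glm$levels, dim(glm$levels), glm$n_levels)
  wt <- glcm_weights(glm$n_levels)
  vals <- NULL
  for (d in seq_len(13)) {
    m <- counts[, , d, drop = FALSE]
    dim(m) <- c(glm$n_levels, glm$n_levels)
    tot <- sum(m)
    if (tot == 0) next
    f <- glcm_features_one(m / tot, wt)
    vals <- if (is.null(vals)) rbind(f) else rbind(vals, f)
  }
  if (is.null(vals))
    stop("glcm: ROI has no neighbouring voxel pairs; features undefined")
  colMeans(vals)
}

# ---- GLRLM -------------------------------------------------------------

glrlm_features_one <- function(P, np) {
  nr <- sum(P)
  p <- P / nr
  i <- row(P); l <- col(P)
  pg <- rowSums(p); pl <- colSums(p)
  mui <- sum(i * p); mul <- sum(l * p)
  c(glrlm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    glrlm_GrayLevelVariance = sum((i - mui)^2 * p),
    glrlm_HighGrayLevelRunEmphasis = sum(i^2 * p),
    glrlm_LongRunEmphasis = sum(l^2 * p),
    glrlm_LongRunHighGrayLevelEmphasis = sum(i^2 * l^2 * p),
    glrlm_LongRunLowGrayLevelEmphasis = sum(l^2 / i^2 * p),
    glrlm_LowGrayLevelRunEmphasis = sum(p / i^2),
    glrlm_RunEntropy = -sum(log2p(p) * p),
    glrlm_RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    glrlm_RunPercentage = nr / np,
    glrlm_RunVariance = sum((l - mul)^2 * p),
    glrlm_ShortRunEmphasis = sum(p / l^2),
    glrlm_ShortRunHighGrayLevelEmphasis = sum(i^2 / l^2 * p),
    glrlm_ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * l^2)))
}

#' Gray-level run-length features
#'
#' Run lengths per 13 directions, features averaged over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 GLRLM features.
#' @export
glrlm_features <- function(glm) {
  counts <- cpp_glrlm(glm$levels, dim(glm$levels), glm$n_levels)
  maxlen <- dim(counts)[2]
  vals <- NULL
  for (d in seq_len(13)) {
    m <- counts[, , d, drop = FALSE]
    dim(m) <- c(glm$n_levels, maxlen)
    f <- glrlm_features_one(m, glm$n_voxels)
    vals <- if (is.null(vals)) rbind(f) else rbind(vals, f)
  }
  colMeans(vals)
}

# ---- GLSZM -------------------------------------------------------------

glszm_features_from_zones <- function(zones, np, ng) {
  sizes <- sort(unique(zones[, 2]))
  P <- matrix(0, ng, length(sizes))
  for (r in seq_len(nrow(zones)))
    P[zones[r, 1], match(zones[r, 2], sizes)] <-
      P[zones[r, 1], match(zones[r, 2], sizes)] + 1
  nz <- sum(P)
  p <- P / nz
  i <- row(P); s <- matrix(sizes, ng, length(sizes), byrow = TRUE)
  mui <- sum(i * p); mus <- sum(s * p)
  c(glszm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nz^2,
    glszm_GrayLevelVariance = sum((i - mui)^2 * p),
    glszm_HighGrayLevelZoneEmphasis = sum(i^2 * p),
    glszm_LargeAreaEmphasis = sum(s^2 * p),
    glszm_LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2 * p),
    glszm_LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2 * p),
    glszm_LowGrayLevelZoneEmphasis = sum(p / i^2),
    glszm_SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    glszm_SmallAreaEmphasis = sum(p / s^2),
    glszm_SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2 * p),
    glszm_SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * s^2)),
    glszm_ZoneEntropy = -sum(log2p(p) * p),
    glszm_ZonePercentage = nz / np,
    glszm_ZoneVariance = sum((s - mus)^2 * p))
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level; direction-free.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 GLSZM features.
#' @export
glszm_features <- function(glm) {
  zones <- cpp_glszm(glm$levels, dim(glm$levels))
  glszm_features_from_zones(zones, glm$n_voxels, glm$n_levels)
}

# ---- GLDM --------------------------------------------------------------

#' Gray-level dependence features
#'
#' The dependence of a voxel is the number of its 26-neighbours (within the
#' ROI) whose gray level differs by at most `alpha`; the matrix is indexed
#' by gray level and dependence + 1.
#'
#' @inheritParams glcm_features
#' @param alpha gray-level similarity tolerance (default 0).
#' @return Named numeric vector of 14 GLDM features.
#' @export
gldm_features <- function(glm, alpha = 0) {
  P <- cpp_gldm(glm$levels, dim(glm$levels), glm$n_levels,
                as.integer(alpha))
  np <- sum(P)
  p <- P / np
  i <- row(P); j <- col(P)   # j = dependence + 1
  mui <- sum(i * p); muj <- sum(j * p)
  c(gldm_SmallDependenceEmphasis = sum(p / j^2),
    gldm_LargeDependenceEmphasis = sum(j^2 * p),
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / np,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / np,
    gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / np^2,
    gldm_GrayLevelVariance = sum((i - mui)^2 * p),
    gldm_DependenceVariance = sum((j - muj)^2 * p),
    gldm_DependenceEntropy = -sum(log2p(p) * p),
    gldm_LowGrayLevelEmphasis = sum(p / i^2),
    gldm_HighGrayLevelEmphasis = sum(i^2 * p),
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(i^2 / j^2 * p),
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(j^2 / i^2 * p),
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(i^2 * j^2 * p))
}

# ---- NGTDM -------------------------------------------------------------

#' Neighbouring gray-tone difference features
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of the 5 NGTDM features.
#' @export
ngtdm_features <- function(glm) {
  sn <- cpp_ngtdm(glm$levels, dim(glm$levels), glm$n_levels)
  s <- sn[, 1]; n <- sn[, 2]
  nvp <- sum(n)
  p <- n / nvp
  act <- which(p > 0)
  ngp <- length(act)
  lev <- seq_len(glm$n_levels)
  coarse_den <- sum(p * s)
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(lev[act], lev[act], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / nvp
  } else 0
  busy_den <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], `-`)))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  complexity <- if (nvp > 0 && ngp > 0) {
    pi_ <- p[act]; si <- s[act]; li <- lev[act]
    sum(abs(outer(li, li, `-`)) *
          (outer(pi_ * si, rep(1, ngp)) + outer(rep(1, ngp), pi_ * si)) /
          (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))) / nvp
  } else 0
  strength <- if (sum(s) > 0) {
    pi_ <- p[act]; li <- lev[act]
    sum((outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_)) *
          outer(li, li, `-`)^2) / sum(s)
  } else 0
  c(ngtdm_Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

# ---- tumor-to-bone distance -------------------------------------------

#' Tumor-to-bone distance
#'
#' Minimum Euclidean distance in mm between any tumor boundary voxel
#' centre and any bone voxel centre; 0 if the masks touch or overlap; `NA`
#' (feature missing) if the bone mask is empty.
#'
#' @param tumor_mask,bone_mask logical 3D arrays sharing geometry.
#' @param spacing_mm per-axis voxel size in mm.
#' @return Distance in mm (scalar), or `NA_real_` when bone is absent.
#' @export
tumor_to_bone_distance <- function(tumor_mask, bone_mask,
                                   spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(tumor_mask), dim(bone_mask)))
    stop("tumor and bone masks must share geometry")
  if (!any(tumor_mask)) stop("tumor mask is empty")
  if (is.null(bone_mask) || !any(bone_mask)) return(NA_real_)
  if (!is.logical(tumor_mask))
    tumor_mask <- array(as.logical(tumor_mask), dim(tumor_mask))
  bb <- mask_bbox(tumor_mask)
  tcrop <- tumor_mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2],
                      bb[3, 1]:bb[3, 2], drop = FALSE]
  bone_distance_cropped(tcrop, bb[, 1], bone_mask, as.numeric(spacing_mm))
}

# tumor arrives cropped to its bounding box with `off` = global index of
# the local origin; bone is the full-grid mask
bone_distance_cropped <- function(tcrop, off, bone_mask, sp) {
  if (!is.logical(bone_mask))
    bone_mask <- array(as.logical(bone_mask), dim(bone_mask))
  bbB <- mask_bbox(bone_mask)
  hiT <- off + dim(tcrop) - 1L
  if (all(bbB[, 1] <= hiT) && all(bbB[, 2] >= off)) {
    # bounding boxes intersect: check voxel overlap on the intersection
    lo <- pmax(off, bbB[, 1]); hi <- pmin(hiT, bbB[, 2])
    tl <- lo - off + 1L; th <- hi - off + 1L
    sub_t <- tcrop[tl[1]:th[1], tl[2]:th[2], tl[3]:th[3], drop = FALSE]
    sub_b <- bone_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (any(sub_t & sub_b)) return(0)
  }
  bcrop <- bone_mask[bbB[1, 1]:bbB[1, 2], bbB[2, 1]:bbB[2, 2],
                     bbB[3, 1]:bbB[3, 2], drop = FALSE]
  pts <- function(mc, o) {
    w <- which(boundary_voxels(mc), arr.ind = TRUE)
    t((t(w) + (o - 2)) * sp)
  }
  a <- pts(tcrop, off)
  b <- pts(bcrop, bbB[, 1])
  # cheap upper bound from a subsample, then bounding-box pruning
  ub <- cpp_min_dist(a, b[seq(1, nrow(b), by = 29), , drop = FALSE])
  lb2 <- function(p, lo, hi)
    pmax(0, lo[1] - p[, 1], p[, 1] - hi[1])^2 +
    pmax(0, lo[2] - p[, 2], p[, 2] - hi[2])^2 +
    pmax(0, lo[3] - p[, 3], p[, 3] - hi[3])^2
  b <- b[lb2(b, apply(a, 2, min), apply(a, 2, max)) <= ub^2, , drop = FALSE]
  cpp_min_dist(a, b)
}

# ---- full vector -------------------------------------------------------

#' Names of all 108 features
#' @return Character vector: 107 radiomic feature names plus
#'   `tumor_to_bone_distance`.
#' @export
feature_names <- function() {
  tiny <- array(0, c(3, 3, 3)); tiny[2, 2, 2] <- 1
  m <- array(TRUE, c(3, 3, 3))
  gl <- discretize(tiny, m, 1)
  c(names(first_order_features(1:3)),
    names(shape_features(m)),
    names(glcm_features(gl)), names(glrlm_features(gl)),
    names(glszm_features(gl)), names(gldm_features(gl)),
    names(ngtdm_features(gl)),
    "tumor_to_bone_distance")
}

#' Extract the full 108-feature vector for one case
#'
#' Applies NIV normalization (when enabled and a fat-reference mask is
#' available), discretizes the tumor ROI, and evaluates all seven radiomic
#' families plus the tumor-to-bone distance.
#'
#' @param case a `phantom_case`, or a list with elements `volume`
#'   ([image_volume]) and `masks` (list with `tumor`, optionally `bone`,
#'   `ref`).
#' @param config a [feature_config].
#' @return Named numeric vector of length 108.
#' @export
extract_features <- function(case, config = feature_config()) {
  vol <- case$volume
  masks <- case$masks
  if (is.null(masks$tumor) || !any(masks$tumor))
    stop("case has an empty tumor mask")
  sp <- vol$spacing_mm
  if (config$normalize) {
    if (is.null(masks$ref)) stop("normalization enabled but no reference mask")
    if (!any(masks$ref)) stop("reference mask is empty")
    m <- mean(vol$voxels[masks$ref])
    if (!is.finite(m) || m <= 0)
      stop("reference-ROI mean must be strictly positive, got ", format(m))
  } else m <- NULL
  # everything intensity-based lives inside the tumor bounding box
  bb <- mask_bbox(masks$tumor)
  ix <- bb[1, 1]:bb[1, 2]; iy <- bb[2, 1]:bb[2, 2]; iz <- bb[3, 1]:bb[3, 2]
  tcrop <- masks$tumor[ix, iy, iz, drop = FALSE]
  vcrop <- vol$voxels[ix, iy, iz, drop = FALSE]
  if (!is.null(m)) vcrop <- vcrop / m * 1000
  glm <- discretize(vcrop, tcrop, config$bin_width)
  dist <- if (is.null(masks$bone) || !any(masks$bone)) NA_real_ else
    bone_distance_cropped(tcrop, bb[, 1], masks$bone, sp)
  c(first_order_features(vcrop[tcrop], prod(sp), config$bin_width),
    shape_features(tcrop, sp),
    glcm_features(glm), glrlm_features(glm), glszm_features(glm),
    gldm_features(glm, config$gldm_alpha), ngtdm_features(glm),
    tumor_to_bone_distance = dist)
}

#' Extract features for a list of cases into a feature table
#'
#' @param cases list of `phantom_case` objects.
#' @param config a [feature_config].
#' @return A `data.frame` with `case_id`, `label`, and 108 feature columns.
#' @export
extract_cohort <- function(cases, config = feature_config()) {
  rows <- lapply(cases, function(cs) extract_features(cs, config))
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(case_id = vapply(cases, function(cs) cs$case_id, character(1)),
             label = vapply(cases, function(cs) cs$label, character(1)),
             tab, check.names = FALSE)
}
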