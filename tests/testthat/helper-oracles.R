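# Brute-force oracles: every texture family re-derived with naive R loops
# and scalar-summation formulas, independent of the package's compiled
# matrix builders and vectorized formula code.

DIRS13 <- matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
                   1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,
                   0, 1, 1,  0, 1, -1,
                   1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
                 ncol = 3, byrow = TRUE)

N26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
N26 <- N26[rowSums(abs(N26)) > 0, ]

in_grid <- function(i, j, k, d)
  i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3]

# wrap a level array (NA outside ROI) as the package's gray_level_map
make_glm <- function(lv) {
  structure(list(levels = lv, n_levels = max(lv, na.rm = TRUE),
                 bin_width = 1, n_voxels = sum(!is.na(lv))),
            class = "gray_level_map")
}

olog2 <- function(x) if (x > 0) log2(x) else 0

# ---- GLCM --------------------------------------------------------------

oracle_glcm_mats <- function(lv) {
  d <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  lapply(seq_len(13), function(t) {
    m <- matrix(0, ng, ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- lv[i, j, k]
      if (is.na(a)) next
      i2 <- i + DIRS13[t, 1]; j2 <- j + DIRS13[t, 2]; k2 <- k + DIRS13[t, 3]
      if (!in_grid(i2, j2, k2, d)) next
      b <- lv[i2, j2, k2]
      if (is.na(b)) next
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
    m
  })
}

oracle_glcm_features_one <- function(p) {
  ng <- nrow(p)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  pxmy <- numeric(ng)            # k = 0 .. ng-1
  pxpy <- numeric(2 * ng - 1)    # k = 2 .. 2 ng
  ac <- jener <- hxy <- hxy1 <- hxy2 <- maxp <- ss <- 0
  contrast <- idm <- idmn <- idv <- idnv <- invvar <- 0
  cp <- cs <- ct <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + v
    pxpy[i + j - 1] <- pxpy[i + j - 1] + v
    ac <- ac + i * j * v
    jener <- jener + v^2
    hxy <- hxy - v * olog2(v)
    hxy1 <- hxy1 - v * olog2(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * olog2(px[i] * py[j])
    maxp <- max(maxp, v)
    ss <- ss + (i - mux)^2 * v
    contrast <- contrast + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    idmn <- idmn + v / (1 + ((i - j) / ng)^2)
    idv <- idv + v / (1 + abs(i - j))
    idnv <- idnv + v / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + v / (i - j)^2
    cp <- cp + (i + j - mux - muy)^4 * v
    cs <- cs + (i + j - mux - muy)^3 * v
    ct <- ct + (i + j - mux - muy)^2 * v
  }
  da <- sum((0:(ng - 1)) * pxmy)
  dv <- sum(((0:(ng - 1)) - da)^2 * pxmy)
  de <- -sum(sapply(pxmy, function(v) v * olog2(v)))
  se <- -sum(sapply(pxpy, function(v) v * olog2(v)))
  sa <- sum((2:(2 * ng)) * pxpy)
  hx <- -sum(sapply(px, function(v) v * olog2(v)))
  hy <- -sum(sapply(py, function(v) v * olog2(v)))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sigx > 0 && sigy > 0) (ac - mux * muy) / (sigx * sigy) else 1
  act <- which(px > 0)
  mcc <- if (length(act) < 2) 1 else {
    q <- matrix(0, length(act), length(act))
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      s <- 0
      for (kk in seq_along(act))
        s <- s + p[act[ii], act[kk]] * p[act[jj], act[kk]] /
          (px[act[ii]] * py[act[kk]])
      q[ii, jj] <- s
    }
    lam <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(lam[2], 0))
  }
  c(glcm_Autocorrelation = ac, glcm_JointAverage = mux,
    glcm_ClusterProminence = cp, glcm_ClusterShade = cs,
    glcm_ClusterTendency = ct, glcm_Contrast = contrast,
    glcm_Correlation = corr, glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = de, glcm_DifferenceVariance = dv,
    glcm_JointEnergy = jener, glcm_JointEntropy = hxy,
    glcm_Imc1 = imc1, glcm_Imc2 = imc2, glcm_Idm = idm, glcm_MCC = mcc,
    glcm_Idmn = idmn, glcm_Id = idv, glcm_Idn = idnv,
    glcm_InverseVariance = invvar, glcm_MaximumProbability = maxp,
    glcm_SumAverage = sa, glcm_SumEntropy = se, glcm_SumSquares = ss)
}

oracle_glcm_features <- function(lv) {
  mats <- oracle_glcm_mats(lv)
  vals <- t(sapply(Filter(function(m) sum(m) > 0, mats),
                   function(m) oracle_glcm_features_one(m / sum(m))))
  colMeans(vals)
}

# ---- GLRLM -------------------------------------------------------------

# runs collected with rle() over full grid lines, NA breaking runs
oracle_glrlm_mats <- function(lv) {
  d <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  maxlen <- max(d)
  lapply(seq_len(13), function(t) {
    m <- matrix(0, ng, maxlen)
    dd <- DIRS13[t, ]
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      # line start: predecessor out of grid
      if (in_grid(i - dd[1], j - dd[2], k - dd[3], d)) next
      vec <- integer(0)
      ci <- i; cj <- j; ck <- k
      while (in_grid(ci, cj, ck, d)) {
        v <- lv[ci, cj, ck]
        vec <- c(vec, if (is.na(v)) 0L else v)
        ci <- ci + dd[1]; cj <- cj + dd[2]; ck <- ck + dd[3]
      }
      r <- rle(vec)
      for (q in seq_along(r$values))
        if (r$values[q] > 0)
          m[r$values[q], r$lengths[q]] <- m[r$values[q], r$lengths[q]] + 1
    }
    m
  })
}

oracle_glrlm_features_one <- function(P, np) {
  ng <- nrow(P); L <- ncol(P)
  nr <- sum(P)
  out <- setNames(numeric(16),
    c("glrlm_GrayLevelNonUniformity", "glrlm_GrayLevelNonUniformityNormalized",
      "glrlm_GrayLevelVariance", "glrlm_HighGrayLevelRunEmphasis",
      "glrlm_LongRunEmphasis", "glrlm_LongRunHighGrayLevelEmphasis",
      "glrlm_LongRunLowGrayLevelEmphasis", "glrlm_LowGrayLevelRunEmphasis",
      "glrlm_RunEntropy", "glrlm_RunLengthNonUniformity",
      "glrlm_RunLengthNonUniformityNormalized", "glrlm_RunPercentage",
      "glrlm_RunVariance", "glrlm_ShortRunEmphasis",
      "glrlm_ShortRunHighGrayLevelEmphasis",
      "glrlm_ShortRunLowGrayLevelEmphasis"))
  mui <- mul <- 0
  for (i in 1:ng) for (l in 1:L) {
    mui <- mui + i * P[i, l] / nr
    mul <- mul + l * P[i, l] / nr
  }
  for (i in 1:ng) for (l in 1:L) {
    pr <- P[i, l] / nr
    out["glrlm_GrayLevelVariance"] <- out["glrlm_GrayLevelVariance"] +
      (i - mui)^2 * pr
    out["glrlm_HighGrayLevelRunEmphasis"] <-
      out["glrlm_HighGrayLevelRunEmphasis"] + i^2 * pr
    out["glrlm_LongRunEmphasis"] <- out["glrlm_LongRunEmphasis"] + l^2 * pr
    out["glrlm_LongRunHighGrayLevelEmphasis"] <-
      out["glrlm_LongRunHighGrayLevelEmphasis"] + i^2 * l^2 * pr
    out["glrlm_LongRunLowGrayLevelEmphasis"] <-
      out["glrlm_LongRunLowGrayLevelEmphasis"] + l^2 / i^2 * pr
    out["glrlm_LowGrayLevelRunEmphasis"] <-
      out["glrlm_LowGrayLevelRunEmphasis"] + pr / i^2
    out["glrlm_RunEntropy"] <- out["glrlm_RunEntropy"] - pr * olog2(pr)
    out["glrlm_RunVariance"] <- out["glrlm_RunVariance"] + (l - mul)^2 * pr
    out["glrlm_ShortRunEmphasis"] <- out["glrlm_ShortRunEmphasis"] + pr / l^2
    out["glrlm_ShortRunHighGrayLevelEmphasis"] <-
      out["glrlm_ShortRunHighGrayLevelEmphasis"] + i^2 / l^2 * pr
    out["glrlm_ShortRunLowGrayLevelEmphasis"] <-
      out["glrlm_ShortRunLowGrayLevelEmphasis"] + pr / (i^2 * l^2)
  }
  for (i in 1:ng)
    out["glrlm_GrayLevelNonUniformity"] <-
      out["glrlm_GrayLevelNonUniformity"] + sum(P[i, ])^2 / nr
  for (l in 1:L)
    out["glrlm_RunLengthNonUniformity"] <-
      out["glrlm_RunLengthNonUniformity"] + sum(P[, l])^2 / nr
  out["glrlm_GrayLevelNonUniformityNormalized"] <-
    out["glrlm_GrayLevelNonUniformity"] / nr
  out["glrlm_RunLengthNonUniformityNormalized"] <-
    out["glrlm_RunLengthNonUniformity"] / nr
  out["glrlm_RunPercentage"] <- nr / np
  out
}

oracle_glrlm_features <- function(lv) {
  np <- sum(!is.na(lv))
  vals <- t(sapply(oracle_glrlm_mats(lv), oracle_glrlm_features_one, np = np))
  colMeans(vals)
}

# ---- GLSZM -------------------------------------------------------------

oracle_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (seen[i, j, k] || is.na(lv[i, j, k])) next
    lev <- lv[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      c0 <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (q in seq_len(nrow(N26))) {
        n0 <- c0 + as.integer(N26[q, ])
        if (!in_grid(n0[1], n0[2], n0[3], d)) next
        if (seen[n0[1], n0[2], n0[3]]) next
        v <- lv[n0[1], n0[2], n0[3]]
        if (!is.na(v) && v == lev) {
          seen[n0[1], n0[2], n0[3]] <- TRUE
          queue <- c(queue, list(n0))
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lv) {
  zones <- oracle_zones(lv)
  np <- sum(!is.na(lv))
  ng <- max(lv, na.rm = TRUE)
  nz <- nrow(zones)
  mui <- sum(zones[, 1]) / nz
  mus <- sum(zones[, 2]) / nz
  f <- function(w) sum(w) / nz
  levels_tab <- table(factor(zones[, 1], levels = 1:ng))
  sizes_tab <- table(zones[, 2])
  c(glszm_GrayLevelNonUniformity = sum(levels_tab^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(levels_tab^2) / nz^2,
    glszm_GrayLevelVariance = f((zones[, 1] - mui)^2),
    glszm_HighGrayLevelZoneEmphasis = f(zones[, 1]^2),
    glszm_LargeAreaEmphasis = f(zones[, 2]^2),
    glszm_LargeAreaHighGrayLevelEmphasis = f(zones[, 1]^2 * zones[, 2]^2),
    glszm_LargeAreaLowGrayLevelEmphasis = f(zones[, 2]^2 / zones[, 1]^2),
    glszm_LowGrayLevelZoneEmphasis = f(1 / zones[, 1]^2),
    glszm_SizeZoneNonUniformity = sum(sizes_tab^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(sizes_tab^2) / nz^2,
    glszm_SmallAreaEmphasis = f(1 / zones[, 2]^2),
    glszm_SmallAreaHighGrayLevelEmphasis = f(zones[, 1]^2 / zones[, 2]^2),
    glszm_SmallAreaLowGrayLevelEmphasis = f(1 / (zones[, 1]^2 * zones[, 2]^2)),
    glszm_ZoneEntropy = {
      cnt <- table(paste(zones[, 1], zones[, 2]))
      -sum(sapply(cnt / nz, function(v) v * olog2(v)))
    },
    glszm_ZonePercentage = nz / np,
    glszm_ZoneVariance = f((zones[, 2] - mus)^2))
}

# ---- GLDM --------------------------------------------------------------

oracle_gldm_mat <- function(lv, alpha = 0) {
  d <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  m <- matrix(0, ng, 27)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    dep <- 0
    for (q in seq_len(nrow(N26))) {
      i2 <- i + N26[q, 1]; j2 <- j + N26[q, 2]; k2 <- k + N26[q, 3]
      if (!in_grid(i2, j2, k2, d)) next
      b <- lv[i2, j2, k2]
      if (!is.na(b) && abs(b - a) <= alpha) dep <- dep + 1
    }
    m[a, dep + 1] <- m[a, dep + 1] + 1
  }
  m
}

oracle_gldm_features <- function(lv, alpha = 0) {
  P <- oracle_gldm_mat(lv, alpha)
  np <- sum(P)
  ng <- nrow(P)
  out <- setNames(numeric(14),
    c("gldm_SmallDependenceEmphasis", "gldm_LargeDependenceEmphasis",
      "gldm_GrayLevelNonUniformity", "gldm_DependenceNonUniformity",
      "gldm_DependenceNonUniformityNormalized", "gldm_GrayLevelVariance",
      "gldm_DependenceVariance", "gldm_DependenceEntropy",
      "gldm_LowGrayLevelEmphasis", "gldm_HighGrayLevelEmphasis",
      "gldm_SmallDependenceLowGrayLevelEmphasis",
      "gldm_SmallDependenceHighGrayLevelEmphasis",
      "gldm_LargeDependenceLowGrayLevelEmphasis",
      "gldm_LargeDependenceHighGrayLevelEmphasis"))
  mui <- muj <- 0
  for (i in 1:ng) for (j in 1:27) {
    mui <- mui + i * P[i, j] / np
    muj <- muj + j * P[i, j] / np
  }
  for (i in 1:ng) for (j in 1:27) {
    pr <- P[i, j] / np
    out["gldm_SmallDependenceEmphasis"] <-
      out["gldm_SmallDependenceEmphasis"] + pr / j^2
    out["gldm_LargeDependenceEmphasis"] <-
      out["gldm_LargeDependenceEmphasis"] + pr * j^2
    out["gldm_GrayLevelVariance"] <-
      out["gldm_GrayLevelVariance"] + (i - mui)^2 * pr
    out["gldm_DependenceVariance"] <-
      out["gldm_DependenceVariance"] + (j - muj)^2 * pr
    out["gldm_DependenceEntropy"] <-
      out["gldm_DependenceEntropy"] - pr * olog2(pr)
    out["gldm_LowGrayLevelEmphasis"] <-
      out["gldm_LowGrayLevelEmphasis"] + pr / i^2
    out["gldm_HighGrayLevelEmphasis"] <-
      out["gldm_HighGrayLevelEmphasis"] + pr * i^2
    out["gldm_SmallDependenceLowGrayLevelEmphasis"] <-
      out["gldm_SmallDependenceLowGrayLevelEmphasis"] + pr / (i^2 * j^2)
    out["gldm_SmallDependenceHighGrayLevelEmphasis"] <-
      out["gldm_SmallDependenceHighGrayLevelEmphasis"] + pr * i^2 / j^2
    out["gldm_LargeDependenceLowGrayLevelEmphasis"] <-
      out["gldm_LargeDependenceLowGrayLevelEmphasis"] + pr * j^2 / i^2
    out["gldm_LargeDependenceHighGrayLevelEmphasis"] <-
      out["gldm_LargeDependenceHighGrayLevelEmphasis"] + pr * i^2 * j^2
  }
  for (i in 1:ng)
    out["gldm_GrayLevelNonUniformity"] <-
      out["gldm_GrayLevelNonUniformity"] + sum(P[i, ])^2 / np
  for (j in 1:27)
    out["gldm_DependenceNonUniformity"] <-
      out["gldm_DependenceNonUniformity"] + sum(P[, j])^2 / np
  out["gldm_DependenceNonUniformityNormalized"] <-
    out["gldm_DependenceNonUniformity"] / np
  out
}

# ---- NGTDM -------------------------------------------------------------

oracle_ngtdm_features <- function(lv) {
  d <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  s <- n <- numeric(ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (q in seq_len(nrow(N26))) {
      i2 <- i + N26[q, 1]; j2 <- j + N26[q, 2]; k2 <- k + N26[q, 3]
      if (!in_grid(i2, j2, k2, d)) next
      b <- lv[i2, j2, k2]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1
  }
  nvp <- sum(n)
  p <- n / nvp
  act <- which(p > 0)
  ngp <- length(act)
  coarse_den <- sum(p * s)
  contrast <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in act) for (j in act) acc <- acc + p[i] * p[j] * (i - j)^2
    contrast <- acc / (ngp * (ngp - 1)) * sum(s) / nvp
  }
  busy_den <- 0
  for (i in act) for (j in act) busy_den <- busy_den + abs(i * p[i] - j * p[j])
  complexity <- 0
  for (i in act) for (j in act)
    complexity <- complexity +
      abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  complexity <- complexity / nvp
  strength <- 0
  for (i in act) for (j in act)
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  c(ngtdm_Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = if (sum(s) > 0) strength / sum(s) else 0)
}
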