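#' Default class-conditional phantom parameters
#'
#' Benign intramuscular-lipoma phantoms are smaller, more elongated,
#' farther from bone, homogeneous with negatively skewed intensities;
#' malignant ALT/WDLS phantoms are larger, more sphere-like, closer to
#' bone, with bright septa-like sheets adding texture heterogeneity and
#' pulling the histogram skewness toward zero.  Geometry is desk-scale
#' (tumor radii of 6-16 mm inside a 64 mm grid); real lesions are an
#' order of magnitude larger, but the class contrasts are what matter.
#'
#' @param radius_range_mm range of the volume-equivalent tumor radius.
#' @param elongation_range range of the major/minor axis ratio.
#' @param septa_intensity_contrast added raw intensity of septa sheets.
#' @param noise_sd raw-intensity noise standard deviation inside the tumor.
#' @param histogram_skew_target target skewness of the tumor histogram
#'   before septa are added (negative values use a reflected-gamma draw).
#' @param bone_gap_range_mm range of the drawn tumor-to-bone gap.
#' @return A named list of class parameters.
#' @export
phantom_class_params <- function(radius_range_mm, elongation_range,
                                 septa_intensity_contrast, noise_sd,
                                 histogram_skew_target, bone_gap_range_mm) {
  list(radius_range_mm = radius_range_mm,
       elongation_range = elongation_range,
       septa_intensity_contrast = septa_intensity_contrast,
       noise_sd = noise_sd,
       histogram_skew_target = histogram_skew_target,
       bone_gap_range_mm = bone_gap_range_mm)
}

default_benign_params <- function() {
  phantom_class_params(radius_range_mm = c(6, 10),
                       elongation_range = c(1.4, 2.2),
                       septa_intensity_contrast = 0,
                       noise_sd = 40,
                       histogram_skew_target = -1,
                       bone_gap_range_mm = c(12, 20))
}

default_malignant_params <- function() {
  phantom_class_params(radius_range_mm = c(10, 16),
                       elongation_range = c(1.0, 1.3),
                       septa_intensity_contrast = 100,
                       noise_sd = 40,
                       histogram_skew_target = 0,
                       bone_gap_range_mm = c(2, 8))
}

#' Specification of a synthetic phantom cohort
#'
#' The default cohort mirrors the study population: 38 benign
#' intramuscular lipomas and 30 malignant ALTs/WDLSs.
#'
#' @param n_benign,n_malignant case counts (each >= 0, total >= 1).
#' @param grid_shape voxels per axis.
#' @param spacing_mm per-axis voxel size in mm.
#' @param benign_params,malignant_params see [phantom_class_params].
#' @param fat_reference_mean mean raw intensity of the fat-reference ROI.
#' @param seed master RNG seed; per-case substreams are derived from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_benign = 38, n_malignant = 30,
                         grid_shape = c(64, 64, 64),
                         spacing_mm = c(1, 1, 1),
                         benign_params = default_benign_params(),
                         malignant_params = default_malignant_params(),
                         fat_reference_mean = 600,
                         seed = 42) {
  if (n_benign < 0 || n_malignant < 0 || n_benign + n_malignant < 1)
    stop("need at least one case")
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive")
  if (any(grid_shape < 16)) stop("grid too small for phantom geometry")
  for (p in list(benign_params, malignant_params)) {
    ext <- max(p$radius_range_mm) * max(p$elongation_range)^(2 / 3)
    if (2 * ext + max(p$bone_gap_range_mm) + 6 >
        min(grid_shape * spacing_mm))
      stop("tumor radius/gap ranges do not fit inside the grid")
  }
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 benign_params = benign_params,
                 malignant_params = malignant_params,
                 fat_reference_mean = fat_reference_mean,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$n_benign, " benign + ", x$n_malignant,
      " malignant; grid ", paste(x$grid_shape, collapse = "x"),
      ", spacing ", paste(format(x$spacing_mm), collapse = "x"),
      " mm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# random rotation matrix (Haar via QR, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

BONE_SLAB_VOX <- 3L  # slab thickness at the low-x grid face

#' Generate one synthetic phantom case
#'
#' Places an ellipsoidal tumor (random orientation, class-conditional size
#' and elongation) at a class-conditional gap from a flat bone slab at the
#' low-x grid face, draws class-conditional tumor intensities (reflected
#' gamma for negative skew; bright septa sheets for malignant lesions) on
#' a muscle background, and adds a spherical fat-reference ROI.
#'
#' @param spec a [phantom_spec].
#' @param label `"benign"` or `"malignant"`.
#' @param rng_stream integer seed of this case's RNG substream.
#' @param case_id case identifier string.
#' @return An object of class `phantom_case`: `volume` ([image_volume]),
#'   `masks` (list `tumor`, `bone`, `ref`), `label`, `case_id`, and the
#'   drawn geometry in `meta`.
#' @export
generate_case <- function(spec, label = c("benign", "malignant"),
                          rng_stream = spec$seed, case_id = "case") {
  label <- match.arg(label)
  pars <- if (label == "benign") spec$benign_params else spec$malignant_params
  set.seed(as.integer(rng_stream))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  ext_mm <- d * sp

  # ellipsoid semi-axes: volume-equivalent radius r, elongation e
  r <- runif(1, pars$radius_range_mm[1], pars$radius_range_mm[2])
  e <- runif(1, pars$elongation_range[1], pars$elongation_range[2])
  axes <- c(r * e^(2 / 3), r * e^(-1 / 3), r * e^(-1 / 3))
  rot <- random_rotation()
  gap <- runif(1, pars$bone_gap_range_mm[1], pars$bone_gap_range_mm[2])

  # support of the rotated ellipsoid along each axis
  supp <- sqrt(colSums((axes * t(rot))^2))
  bone_face <- (BONE_SLAB_VOX - 1) * sp[1]    # outer bone voxel-centre plane
  centre <- c(bone_face + gap + supp[1], 0, 0)
  ok <- FALSE
  for (try in 1:20) {
    centre[2:3] <- ext_mm[2:3] / 2 + runif(2, -4, 4)
    lo <- centre - supp
    hi <- centre + supp
    if (all(lo >= sp * 0.5) && all(hi <= ext_mm - 1.5 * sp) &&
        hi[1] <= ext_mm[1] - 1.5 * sp[1]) { ok <- TRUE; break }
  }
  if (!ok) stop("phantom geometry error: tumor does not fit in grid")

  # voxelize over the bounding box
  vox_lo <- pmax(floor(lo / sp) + 1L, 1L)
  vox_hi <- pmin(ceiling(hi / sp) + 1L, d)
  tumor <- array(FALSE, d)
  ii <- vox_lo[1]:vox_hi[1]; jj <- vox_lo[2]:vox_hi[2]; kk <- vox_lo[3]:vox_hi[3]
  ni <- length(ii); nj <- length(jj); nk <- length(kk)
  gi <- rep(ii, times = nj * nk)
  gj <- rep(rep(jj, each = ni), times = nk)
  gk <- rep(kk, each = ni * nj)
  pc <- cbind((gi - 1) * sp[1] - centre[1], (gj - 1) * sp[2] - centre[2],
              (gk - 1) * sp[3] - centre[3])
  q <- pc %*% rot
  inside <- (q[, 1] / axes[1])^2 + (q[, 2] / axes[2])^2 +
    (q[, 3] / axes[3])^2 <= 1
  tumor[cbind(gi, gj, gk)[inside, , drop = FALSE]] <- TRUE
  if (!any(tumor)) stop("phantom geometry error: tumor voxelized to empty")

  bone <- array(FALSE, d)
  bone[seq_len(BONE_SLAB_VOX), , ] <- TRUE
  if (any(tumor & bone)) stop("phantom geometry error: tumor overlaps bone")

  # fat-reference ball in the far corner, away from tumor and bone
  ref <- array(FALSE, d)
  ref_r <- 4.5
  ref_c <- ext_mm - c(8, 8, 8)
  ri <- which(abs((seq_len(d[1]) - 1) * sp[1] - ref_c[1]) <= ref_r)
  rj <- which(abs((seq_len(d[2]) - 1) * sp[2] - ref_c[2]) <= ref_r)
  rk <- which(abs((seq_len(d[3]) - 1) * sp[3] - ref_c[3]) <= ref_r)
  rg <- expand.grid(i = ri, j = rj, k = rk)
  rc <- cbind((rg$i - 1) * sp[1], (rg$j - 1) * sp[2], (rg$k - 1) * sp[3])
  rin <- rowSums(sweep(rc, 2, ref_c)^2) <= ref_r^2
  ref[cbind(rg$i, rg$j, rg$k)[rin, , drop = FALSE]] <- TRUE
  ref <- ref & !tumor & !bone
  if (!any(ref)) stop("phantom geometry error: reference ROI is empty")

  # intensities: muscle background, dark bone, bright fat reference
  vox <- array(rnorm(prod(d), 300, 30), d)
  vox[bone] <- rnorm(sum(bone), 150, 20)
  vox[ref] <- rnorm(sum(ref), spec$fat_reference_mean, 25)

  # tumor interior: reflected-gamma draw for negative skewness targets
  nt <- sum(tumor)
  base <- 0.92 * spec$fat_reference_mean
  skw <- pars$histogram_skew_target
  if (skw < 0) {
    shape <- (2 / abs(skw))^2
    draw <- base + pars$noise_sd * sqrt(shape) -
      rgamma(nt, shape = shape, scale = 1) * pars$noise_sd / sqrt(shape)
  } else {
    draw <- rnorm(nt, base, pars$noise_sd)
  }
  vox[tumor] <- draw

  # septa: randomly oriented bright sheets through the tumor
  if (pars$septa_intensity_contrast > 0) {
    w <- which(tumor, arr.ind = TRUE)
    tc <- sweep(w - 1, 2, sp, `*`)
    n_septa <- sample(2:4, 1)
    septum <- rep(FALSE, nrow(tc))
    for (s in seq_len(n_septa)) {
      nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
      p0 <- centre + runif(3, -0.5, 0.5) * r
      septum <- septum | abs(sweep(tc, 2, p0) %*% nrm) < 0.75
    }
    vox[tumor][septum] <- vox[tumor][septum] + pars$septa_intensity_contrast
  }

  structure(list(volume = image_volume(vox, sp),
                 masks = list(tumor = tumor, bone = bone, ref = ref),
                 label = label, case_id = case_id,
                 meta = list(radius_mm = r, elongation = e, gap_mm = gap,
                             centre_mm = centre, axes_mm = axes)),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", x$case_id, " (", x$label, "): tumor ",
      sum(x$masks$tumor), " voxels, drawn gap ",
      round(x$meta$gap_mm, 2), " mm\n", sep = "")
  invisible(x)
}

#' Generate a seeded phantom cohort
#'
#' Per-case RNG substreams are drawn once from the master seed by case
#' index, so any case is reproducible independently of generation order.
#'
#' @param spec a [phantom_spec].
#' @return List of class `phantom_cohort`: `cases` (list of
#'   `phantom_case`), `labels` (data.frame `case_id`, `label`), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_benign + spec$n_malignant
  labels <- c(rep("benign", spec$n_benign),
              rep("malignant", spec$n_malignant))
  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("case_%03d", seq_len(n))
  cases <- vector("list", n)
  for (i in seq_len(n))
    cases[[i]] <- generate_case(spec, labels[i], streams[i], ids[i])
  structure(list(cases = cases,
                 labels = data.frame(case_id = ids, label = labels,
                                     stringsAsFactors = FALSE),
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$cases), " cases (",
      x$spec$n_benign, " benign, ", x$spec$n_malignant, " malignant)\n",
      sep = "")
  invisible(x)
}

# ---- NIfTI round trip --------------------------------------------------

#' Write a phantom case to NIfTI files
#'
#' Writes `<case_id>_img.nii.gz` plus `_tumor`, `_bone`, `_ref` mask
#' volumes with the voxel spacing recorded in the headers.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_case <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- case$volume$spacing_mm
  out <- c(img = file.path(dir, paste0(case$case_id, "_img.nii.gz")),
           tumor = file.path(dir, paste0(case$case_id, "_tumor.nii.gz")),
           bone = file.path(dir, paste0(case$case_id, "_bone.nii.gz")),
           ref = file.path(dir, paste0(case$case_id, "_ref.nii.gz")))
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, sp)
    RNifti::writeNifti(img, path)
  }
  wr(case$volume$voxels, out["img"])
  wr(array(as.integer(case$masks$tumor), dim(case$masks$tumor)), out["tumor"])
  wr(array(as.integer(case$masks$bone), dim(case$masks$bone)), out["bone"])
  wr(array(as.integer(case$masks$ref), dim(case$masks$ref)), out["ref"])
  invisible(out)
}

#' Read a phantom case back from NIfTI files
#'
#' @param dir directory holding the files written by [write_case].
#' @param case_id case identifier.
#' @param label optional class label to attach.
#' @return A `phantom_case`.
#' @export
read_case <- function(dir, case_id, label = "benign") {
  rd <- function(suffix) {
    path <- file.path(dir, paste0(case_id, "_", suffix, ".nii.gz"))
    if (!file.exists(path)) stop("missing file: ", path)
    RNifti::readNifti(path)
  }
  img <- rd("img")
  sp <- RNifti::pixdim(img)[1:3]
  masks <- list()
  for (m in c("tumor", "bone", "ref")) {
    arr <- rd(m)
    if (!identical(dim(arr), dim(img)))
      stop("geometry error: mask '", m, "' grid differs from image")
    msp <- RNifti::pixdim(arr)[1:3]
    if (max(abs(msp - sp)) > 1e-5)
      stop("geometry error: mask '", m, "' spacing differs from image")
    masks[[m]] <- array(as.vector(arr) > 0.5, dim(arr))
  }
  structure(list(volume = image_volume(array(as.vector(img), dim(img)), sp),
                 masks = masks, label = label, case_id = case_id,
                 meta = list()),
            class = "phantom_case")
}

#' Write a cohort with a manifest CSV
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- lapply(cohort$cases, write_case, dir = dir)
  man <- cbind(cohort$labels,
               img = vapply(paths, `[[`, character(1), "img"))
  manifest <- file.path(dir, "manifest.csv")
  write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Simulate a cohort and extract feature tables in one streaming pass
#'
#' Generates each case, extracts its features (optionally also under
#' eroded/dilated tumor masks emulating repeat segmentation), and discards
#' the volume before moving on, so arbitrarily large cohorts fit in
#' memory.  Case RNG substreams match [generate_cohort] exactly.
#'
#' @param spec a [phantom_spec].
#' @param config a [feature_config].
#' @param sessions subset of `c("orig", "erode", "dilate")`.
#' @return Named list of feature tables (one per session).
#' @export
simulate_feature_tables <- function(spec, config = feature_config(),
                                    sessions = "orig") {
  stopifnot(inherits(spec, "phantom_spec"),
            all(sessions %in% c("orig", "erode", "dilate")))
  n <- spec$n_benign + spec$n_malignant
  labels <- c(rep("benign", spec$n_benign),
              rep("malignant", spec$n_malignant))
  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("case_%03d", seq_len(n))
  rows <- lapply(sessions, function(s) vector("list", n))
  names(rows) <- sessions
  for (i in seq_len(n)) {
    cs <- generate_case(spec, labels[i], streams[i], ids[i])
    for (s in sessions) {
      csi <- cs
      if (s != "orig") {
        fun <- if (s == "erode") erode_mask else dilate_mask
        m <- fun(cs$masks$tumor)
        if (!any(m)) m <- cs$masks$tumor
        csi$masks$tumor <- m & !cs$masks$bone
      }
      rows[[s]][[i]] <- extract_features(csi, config)
    }
  }
  lapply(rows, function(rr)
    data.frame(case_id = ids, label = labels,
               as.data.frame(do.call(rbind, rr)), check.names = FALSE))
}
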