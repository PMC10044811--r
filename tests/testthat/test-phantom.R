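test_that("case generation is deterministic and seed-sensitive", {
  spec <- small_spec()
  a <- generate_case(spec, "malignant", rng_stream = 13, "x")
  b <- generate_case(spec, "malignant", rng_stream = 13, "x")
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$masks, b$masks)
  c_ <- generate_case(spec, "malignant", rng_stream = 14, "x")
  expect_false(identical(a$volume$voxels, c_$volume$voxels))
})

test_that("masks are mutually consistent and the gap echoes its draw", {
  spec <- small_spec()
  for (stream in c(3, 4, 5)) {
    for (label in c("benign", "malignant")) {
      cs <- generate_case(spec, label, rng_stream = stream, "x")
      expect_true(any(cs$masks$tumor))
      expect_true(any(cs$masks$ref))
      expect_true(any(cs$masks$bone))
      expect_false(any(cs$masks$tumor & cs$masks$bone))
      expect_false(any(cs$masks$tumor & cs$masks$ref))
      rng <- if (label == "benign") spec$benign_params$bone_gap_range_mm
             else spec$malignant_params$bone_gap_range_mm
      expect_gte(cs$meta$gap_mm, rng[1])
      expect_lte(cs$meta$gap_mm, rng[2])
      realized <- tumor_to_bone_distance(cs$masks$tumor, cs$masks$bone,
                                         spec$spacing_mm)
      expect_lt(abs(realized - cs$meta$gap_mm), max(spec$spacing_mm) + 0.5)
    }
  }
})

test_that("cohorts have the requested composition", {
  spec <- phantom_spec(n_benign = 38, n_malignant = 30)
  expect_equal(spec$n_benign + spec$n_malignant, 68L)
  coh <- generate_cohort(small_spec(n_benign = 3, n_malignant = 2))
  expect_length(coh$cases, 5L)
  expect_equal(sum(coh$labels$label == "benign"), 3L)
  one <- generate_cohort(small_spec(n_benign = 1, n_malignant = 0))
  expect_length(one$cases, 1L)
  expect_equal(one$cases[[1]]$label, "benign")
  s1 <- generate_cohort(small_spec(n_benign = 1, n_malignant = 1, seed = 1))
  s2 <- generate_cohort(small_spec(n_benign = 1, n_malignant = 1, seed = 2))
  expect_false(identical(s1$cases[[1]]$volume$voxels,
                         s2$cases[[1]]$volume$voxels))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(n_benign = 0, n_malignant = 0), "at least one")
  expect_error(phantom_spec(spacing_mm = c(1, -1, 1)), "positive")
  expect_error(phantom_spec(grid_shape = c(32, 32, 32)), "fit inside")
})

test_that("NIfTI round trip preserves voxels, masks and anisotropic spacing", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  spec$spacing_mm <- c(1, 1, 2.5)
  cs <- generate_case(spec, "malignant", rng_stream = 21, "rt1")
  write_case(cs, dir)
  back <- read_case(dir, "rt1", label = "malignant")
  expect_equal(back$volume$spacing_mm, c(1, 1, 2.5), tolerance = 1e-5)
  expect_equal(back$volume$voxels, cs$volume$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$masks$tumor, cs$masks$tumor)
  fv1 <- extract_features(cs)
  fv2 <- extract_features(back)
  expect_equal(fv1, fv2, tolerance = 1e-6)
})

test_that("reading mismatched geometries fails loudly", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  cs <- generate_case(spec, "benign", rng_stream = 22, "rt2")
  write_case(cs, dir)
  # overwrite one mask with a different grid
  bad <- RNifti::asNifti(array(0L, c(10, 10, 10)), pixdim = c(1, 1, 1))
  RNifti::writeNifti(bad, file.path(dir, "rt2_bone.nii.gz"))
  expect_error(read_case(dir, "rt2"), "geometry")
  expect_error(read_case(dir, "missing_case"), "missing file")
})

test_that("planted class effects point the documented way (50 + 50, seed 42)", {
  tab <- cached("directions_table",
                simulate_feature_tables(
                  phantom_spec(n_benign = 50, n_malignant = 50,
                               seed = 42))$orig)
  mb <- colMeans(tab[tab$label == "benign", -(1:2)])
  mm <- colMeans(tab[tab$label == "malignant", -(1:2)])
  expect_gt(mm["shape_Sphericity"], mb["shape_Sphericity"])
  expect_gt(mm["shape_MajorAxisLength"], mb["shape_MajorAxisLength"])
  expect_gt(mb["tumor_to_bone_distance"], mm["tumor_to_bone_distance"])
  expect_lt(mb["firstorder_Skewness"], mm["firstorder_Skewness"])
  expect_lt(mb["firstorder_Skewness"], -0.5)   # clearly negative skew
  expect_gt(mb["shape_SurfaceVolumeRatio"], mm["shape_SurfaceVolumeRatio"])
})
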