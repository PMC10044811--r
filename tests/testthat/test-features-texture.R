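# Every texture family must agree with the brute-force oracle (naive loop
# enumeration + scalar formula evaluation) on all three fixtures.

expect_rel_equal <- function(got, want, tol = 1e-9) {
  expect_equal(names(got), names(want))
  denom <- pmax(abs(want), 1e-12)
  expect_lt(max(abs(got - want) / denom), tol)
}

test_that("GLCM features match the brute-force oracle on all fixtures", {
  for (lv in texture_fixtures()) {
    glm <- make_glm(lv)
    expect_rel_equal(glcm_features(glm), oracle_glcm_features(lv))
  }
})

test_that("GLRLM features match the brute-force oracle on all fixtures", {
  for (lv in texture_fixtures()) {
    glm <- make_glm(lv)
    expect_rel_equal(glrlm_features(glm), oracle_glrlm_features(lv))
  }
})

test_that("GLSZM features match the brute-force oracle on all fixtures", {
  for (lv in texture_fixtures()) {
    glm <- make_glm(lv)
    expect_rel_equal(glszm_features(glm), oracle_glszm_features(lv))
  }
})

test_that("GLDM features match the brute-force oracle on all fixtures", {
  for (lv in texture_fixtures()) {
    glm <- make_glm(lv)
    expect_rel_equal(gldm_features(glm), oracle_gldm_features(lv))
  }
})

test_that("NGTDM features match the brute-force oracle on all fixtures", {
  for (lv in texture_fixtures()) {
    glm <- make_glm(lv)
    expect_rel_equal(ngtdm_features(glm), oracle_ngtdm_features(lv))
  }
})

test_that("constant and degenerate ROIs take their defined limits", {
  lv <- array(1L, c(3, 3, 3))
  glm <- make_glm(lv)
  g <- glcm_features(glm)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_Correlation"]), 1)
  expect_equal(unname(g["glcm_MCC"]), 1)
  expect_equal(unname(ngtdm_features(glm)["ngtdm_Contrast"]), 0)
  # constant ROI of V voxels: single zone, SmallAreaEmphasis = 1/V^2
  sz <- glszm_features(glm)
  expect_equal(unname(sz["glszm_SmallAreaEmphasis"]), 1 / 27^2)
  expect_equal(unname(sz["glszm_ZonePercentage"]), 1 / 27)
  # single voxel: no neighbour pairs
  one <- array(NA_integer_, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_error(glcm_features(make_glm(one)), "no neighbouring voxel pairs")
  d <- gldm_features(make_glm(one))
  expect_equal(unname(d["gldm_LargeDependenceEmphasis"]), 1)  # j = 0 + 1
})

test_that("runs and dependences follow their definitions on line fixtures", {
  # constant 1xN line: one run of length N per direction that sees it
  lv <- array(NA_integer_, c(7, 3, 3))
  lv[1:7, 2, 2] <- 2L
  counts <- liporad:::cpp_glrlm(lv, dim(lv), 2L)
  expect_equal(counts[2, 7, 1], 1)       # x direction: single run of 7
  expect_equal(sum(counts[, , 1]), 1)
  expect_equal(counts[2, 1, 2], 7)       # y direction: 7 runs of length 1
  g <- glrlm_features(make_glm(lv))
  # single-run matrix in direction 1: LRHGLE = i^2 l^2 = 4 * 49
  m <- matrix(0, 2, 7); m[2, 7] <- 1
  expect_equal(unname(oracle_glrlm_features_one(m, 7)
                      ["glrlm_LongRunHighGrayLevelEmphasis"]), 4 * 49)
  # alternating levels: all runs have length 1 in every direction
  lv2 <- array(NA_integer_, c(6, 1, 1))
  lv2[, 1, 1] <- rep(c(1L, 2L), 3)
  counts2 <- liporad:::cpp_glrlm(lv2, dim(lv2), 2L)
  expect_true(all(counts2[, -1, ] == 0))
  # constant 3x3x3 ROI: centre voxel has dependence 26
  lv3 <- array(1L, c(3, 3, 3))
  dm <- liporad:::cpp_gldm(lv3, dim(lv3), 1L, 0L)
  expect_equal(dm[1, 27], 1)   # exactly one voxel with 26 dependent neighbours
  expect_equal(sum(dm), 27)
})

test_that("two disjoint equal-level blobs give the expected zone histogram", {
  lv <- array(NA_integer_, c(6, 3, 3))
  lv[1:2, 1:2, 1:2] <- 1L          # 8-voxel zone
  lv[6, 3, 3] <- 1L                # isolated voxel, same level
  zones <- liporad:::cpp_glszm(lv, dim(lv))
  expect_equal(sort(zones[, 2]), c(1, 8))
  expect_rel_equal(glszm_features(make_glm(lv)), oracle_glszm_features(lv))
})

test_that("GLCM features are invariant to ROI translation and Imc2 is bounded", {
  set.seed(31)
  base <- array(NA_integer_, c(8, 8, 8))
  base[2:5, 2:5, 2:5] <- sample(1:3, 64, replace = TRUE)
  shifted <- array(NA_integer_, c(8, 8, 8))
  shifted[4:7, 3:6, 3:6] <- base[2:5, 2:5, 2:5]
  f1 <- glcm_features(make_glm(base))
  f2 <- glcm_features(make_glm(shifted))
  expect_equal(f1, f2, tolerance = 1e-12)
  for (lv in texture_fixtures()) {
    v <- glcm_features(make_glm(lv))["glcm_Imc2"]
    expect_gte(unname(v), 0)
    expect_lte(unname(v), 1)
  }
})

test_that("feature families have the documented sizes and prefixes", {
  lv <- texture_fixtures()$ball
  glm <- make_glm(lv)
  fams <- list(glcm = glcm_features(glm), glrlm = glrlm_features(glm),
               glszm = glszm_features(glm), gldm = gldm_features(glm),
               ngtdm = ngtdm_features(glm))
  sizes <- c(glcm = 24L, glrlm = 16L, glszm = 16L, gldm = 14L, ngtdm = 5L)
  for (fam in names(fams)) {
    expect_length(fams[[fam]], sizes[[fam]])
    expect_true(all(startsWith(names(fams[[fam]]), paste0(fam, "_"))))
  }
})
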