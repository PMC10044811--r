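# Shared fixtures.  Texture fixtures are <= 5x5x5 level arrays (NA = not
# in ROI); phantom-based tables are built once per session and cached.

texture_fixtures <- function() {
  f1 <- array(NA_integer_, c(3, 3, 1))
  f1[, , 1] <- matrix(c(1L, 2L, 2L, 1L, 1L, 2L, 2L, 2L, 1L), 3, 3)
  set.seed(101)
  f2 <- array(sample(1:3, 4 * 4 * 2, replace = TRUE), c(4, 4, 2))
  f2[sample(length(f2), 7)] <- NA_integer_   # ragged ROI
  set.seed(202)
  f3 <- array(sample(1:4, 125, replace = TRUE), c(5, 5, 5))
  ctr <- 3
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 > 6) f3[i, j, k] <- NA
  list(flat = f1, ragged = f2, ball = f3)
}

digital_sphere <- function(r, n = 2 * r + 5) {
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  array((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2 + (idx[, 3] - ctr)^2 <= r^2,
        c(n, n, n))
}

digital_ellipsoid <- function(a, b, c_, n = 2 * max(a, b, c_) + 5) {
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  array(((idx[, 1] - ctr) / a)^2 + ((idx[, 2] - ctr) / b)^2 +
          ((idx[, 3] - ctr) / c_)^2 <= 1, c(n, n, n))
}

# compact phantom population for fast end-to-end tests
small_spec <- function(n_benign = 12, n_malignant = 12, seed = 5) {
  phantom_spec(
    n_benign = n_benign, n_malignant = n_malignant,
    grid_shape = c(44, 44, 44),
    benign_params = phantom_class_params(
      radius_range_mm = c(5, 7), elongation_range = c(1.4, 1.9),
      septa_intensity_contrast = 0, noise_sd = 40,
      histogram_skew_target = -1, bone_gap_range_mm = c(9, 15)),
    malignant_params = phantom_class_params(
      radius_range_mm = c(7, 10), elongation_range = c(1.0, 1.3),
      septa_intensity_contrast = 100, noise_sd = 40,
      histogram_skew_target = 0, bone_gap_range_mm = c(2, 6)),
    seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-spec cohort feature table (38 benign + 30 malignant, seed 42)
default_table <- function()
  cached("default_table",
         simulate_feature_tables(phantom_spec(seed = 42))$orig)

# small cohort: original + eroded + dilated tables
small_tables <- function()
  cached("small_tables",
         simulate_feature_tables(small_spec(),
                                 sessions = c("orig", "erode", "dilate")))
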