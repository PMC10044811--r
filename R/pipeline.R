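#' Pipeline configuration
#'
#' Collects the knobs of the full analysis: the phantom specification,
#' discretization bin width, ICC reproducibility threshold,
#' learning/testing split, and the classification threshold.
#'
#' @param spec a [phantom_spec].
#' @param bin_width discretization bin width in NIV units.
#' @param normalize apply NIV normalization before extraction.
#' @param icc_threshold ICC(2,1) reproducibility cutoff.
#' @param ratio learning-set proportion.
#' @param folds CV folds.
#' @param seed seed of the split/CV stage (the cohort uses `spec$seed`).
#' @param threshold classification probability threshold.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = phantom_spec(), bin_width = 25,
                            normalize = TRUE, icc_threshold = 0.75,
                            ratio = 0.7, folds = 10, seed = 1,
                            threshold = 0.5) {
  structure(list(spec = spec, bin_width = bin_width, normalize = normalize,
                 icc_threshold = icc_threshold, ratio = ratio,
                 folds = folds, seed = seed, threshold = threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror [pipeline_config] and [phantom_spec]; unknown
#' keys raise an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("phantom", "bin_width", "normalize", "icc_threshold", "ratio",
             "folds", "seed", "threshold")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  spec_args <- y$phantom %||% list()
  spec <- do.call(phantom_spec, spec_args)
  args <- y[setdiff(names(y), "phantom")]
  do.call(pipeline_config, c(list(spec = spec), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' simulate -> extract -> reproducibility screen -> train -> evaluate.
#' Intra-observer variability is emulated by re-extracting under a
#' one-voxel eroded tumor mask, inter-observer by a one-voxel dilated
#' mask; a feature must pass the ICC screen in both to be retained.
#'
#' @param config a [pipeline_config].
#' @param output_dir optional directory; when given, feature tables
#'   (CSV), the reproducibility report (CSV), the model (JSON), the
#'   evaluation report (JSON) and a run manifest are written there.
#' @return A list of class `pipeline_bundle` with elements `features`,
#'   `features_intra`, `features_inter`, `reproducibility`, `retained`,
#'   `model`, `evaluation`, `group_tests`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  fc <- feature_config(bin_width = config$bin_width,
                       normalize = config$normalize)
  cohort <- generate_cohort(config$spec)
  features <- extract_cohort(cohort$cases, fc)
  features_intra <- extract_cohort_perturbed(cohort, fc, "erode")
  features_inter <- extract_cohort_perturbed(cohort, fc, "dilate")

  rep_intra <- agreement_suite(features, features_intra,
                               config$icc_threshold)
  rep_inter <- agreement_suite(features, features_inter,
                               config$icc_threshold)
  retained <- filter_reproducible(list(rep_intra, rep_inter),
                                  config$icc_threshold)
  if (length(retained) == 0L)
    stop("training aborted: no feature passed the ICC screen at threshold ",
         config$icc_threshold)

  tab <- features[, c("case_id", "label", retained)]
  model <- cv_lasso_logistic(tab, ratio = config$ratio,
                             folds = config$folds, seed = config$seed,
                             threshold = config$threshold)
  test_ids <- model$plan$testing_ids
  scores <- predict(model)
  test_labels <- features$label[match(test_ids, features$case_id)]
  evaluation <- confusion_metrics(test_labels, scores, config$threshold)
  group_tests <- group_feature_tests(tab)

  rep_joint <- data.frame(feature = rep_intra$feature,
                          icc_intra = rep_intra$icc,
                          icc_inter = rep_inter$icc,
                          r = rep_intra$pearson_r,
                          rho = rep_intra$spearman_rho,
                          keep = rep_intra$feature %in% retained)

  bundle <- structure(list(features = features,
                           features_intra = features_intra,
                           features_inter = features_inter,
                           reproducibility = rep_joint,
                           retained = retained,
                           model = model, evaluation = evaluation,
                           group_tests = group_tests, config = config),
                      class = "pipeline_bundle")
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(bundle$features, file.path(dir, "features.csv"),
            row.names = FALSE)
  write.csv(bundle$reproducibility, file.path(dir, "reproducibility.csv"),
            row.names = FALSE)
  m <- bundle$model
  jsonlite::write_json(
    list(lambda = m$lambda_min,
         intercept = m$intercept,
         coefficients = as.list(m$coefficients[m$coefficients != 0]),
         centre = as.list(m$centre[m$selected]),
         scale = as.list(m$scale[m$selected]),
         threshold = m$threshold,
         learning_ids = m$plan$learning_ids,
         testing_ids = m$plan$testing_ids),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  ev <- bundle$evaluation
  jsonlite::write_json(
    list(auc = ev$auc$auc, auc_ci = ev$auc$ci,
         sensitivity = unname(ev$sensitivity), specificity = unname(ev$specificity),
         accuracy = unname(ev$accuracy), counts = as.list(ev$counts)),
    file.path(dir, "evaluation.json"), digits = NA, auto_unbox = TRUE)
  cfg <- bundle$config
  yaml::write_yaml(list(bin_width = cfg$bin_width,
                        icc_threshold = cfg$icc_threshold,
                        ratio = cfg$ratio, folds = cfg$folds,
                        seed = cfg$seed, threshold = cfg$threshold,
                        phantom_seed = cfg$spec$seed,
                        n_benign = cfg$spec$n_benign,
                        n_malignant = cfg$spec$n_malignant),
                   file.path(dir, "config.yaml"))
  manifest <- data.frame(
    file = c("features.csv", "reproducibility.csv", "model.json",
             "evaluation.json", "config.yaml"),
    md5 = unname(tools::md5sum(file.path(dir, c(
      "features.csv", "reproducibility.csv", "model.json",
      "evaluation.json", "config.yaml")))))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Human-readable pipeline summary
#'
#' @param bundle a `pipeline_bundle`.
#' @param readers optional named list of binary reader call vectors over
#'   the testing lesions, for kappa / DeLong comparison rows.
#' @return Invisibly, the summary lines (character vector).
#' @export
pipeline_report <- function(bundle, readers = NULL) {
  if (!inherits(bundle, "pipeline_bundle"))
    stop("`bundle` must be a pipeline_bundle")
  for (el in c("reproducibility", "model", "evaluation"))
    if (is.null(bundle[[el]])) stop("bundle is missing element '", el, "'")
  ev <- bundle$evaluation
  ln <- c(
    sprintf("Cohort: %d lesions (%d benign, %d malignant)",
            nrow(bundle$features), sum(bundle$features$label == "benign"),
            sum(bundle$features$label == "malignant")),
    sprintf("Reproducible features (ICC > %.2f in both screens): %d of %d",
            bundle$config$icc_threshold, length(bundle$retained),
            nrow(bundle$reproducibility)),
    sprintf("Chosen lambda: %.4g (log = %.2f); selected features: %d",
            bundle$model$lambda_min, log(bundle$model$lambda_min),
            length(bundle$model$selected)),
    sprintf("Testing set: AUC %.2f (95%% CI %.2f-%.2f)", ev$auc$auc,
            ev$auc$ci[1], ev$auc$ci[2]),
    sprintf("  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%",
            100 * ev$sensitivity[1], 100 * ev$specificity[1],
            100 * ev$accuracy[1]))
  if (!is.null(readers)) {
    test_ids <- bundle$model$plan$testing_ids
    labels <- bundle$features$label[match(test_ids,
                                          bundle$features$case_id)]
    scores <- predict(bundle$model)
    for (nm in names(readers)) {
      r <- readers[[nm]]
      dl <- delong_test(labels, scores, as.numeric(r == "malignant"))
      ln <- c(ln, sprintf("  vs %s: DeLong p = %.3f", nm, dl$p))
    }
    if (length(readers) == 2) {
      kp <- cohen_kappa(readers[[1]], readers[[2]])
      ln <- c(ln, sprintf("Reader agreement kappa: %.2f (95%% CI %.2f-%.2f)",
                          kp$kappa, kp$ci[1], kp$ci[2]))
    }
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
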