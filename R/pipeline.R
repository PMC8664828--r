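#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end run: phantom cohort
#' settings, the feature-extraction configuration, LASSO settings and
#' evaluation settings. Round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_subjects Cohort size (default 66).
#' @param prevalence Bone-positive fraction (default 30/66).
#' @param subgroup_split Split of positives among BMB-/PET+, BMB+/PET-,
#'   BMB+/PET+ (default 4:14:12).
#' @param phantom A [phantom_params()] (cohort-level disease effects use
#'   its lesion and diffuse-multiplier settings).
#' @param extraction An [extraction_config()].
#' @param model `"refit"` to fit the LASSO signature on the cohort, or
#'   `"published"` to apply the frozen published model.
#' @param n_folds CV folds for the LASSO.
#' @param fwer,n_tests Family-wise error rate and test count for the
#'   Bonferroni threshold reported with the per-feature group comparisons.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 66L, prevalence = 30 / 66,
                            subgroup_split = c(4, 14, 12),
                            phantom = phantom_params(n_focal_lesions = 3L,
                                                     diffuse_sd_multiplier = 2),
                            extraction = extraction_config(),
                            model = c("refit", "published"),
                            n_folds = 10L, fwer = 0.05, n_tests = 26L) {
  model <- match.arg(model)
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 subgroup_split = subgroup_split, phantom = phantom,
                 extraction = extraction, model = model,
                 n_folds = as.integer(n_folds), fwer = fwer,
                 n_tests = as.integer(n_tests)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- x$phantom
  ex <- x$extraction
  pipeline_config(
    n_subjects = x$n_subjects, prevalence = x$prevalence,
    subgroup_split = x$subgroup_split,
    phantom = do.call(phantom_params, ph[setdiff(names(ph), "bin_width")]),
    extraction = do.call(extraction_config,
                         ex[setdiff(names(ex), character())]),
    model = x$model, n_folds = x$n_folds, fwer = x$fwer, n_tests = x$n_tests)
}

# Feature-vs-label group comparison table (Mann-Whitney per feature, with
# the Bonferroni threshold attached as an attribute).
feature_group_tests <- function(features, labels, fwer = 0.05, n_tests = NULL) {
  nm <- intersect(radiomic_feature_names(), colnames(features))
  labels <- as_binary_labels(labels)
  rows <- lapply(nm, function(f) {
    v <- features[[f]]
    ok <- is.finite(v)
    if (sum(ok & labels == 1L) == 0 || sum(ok & labels == 0L) == 0)
      return(data.frame(feature = f, mean_neg = NA, mean_pos = NA, p = NA))
    mw <- mann_whitney(v[ok & labels == 1L], v[ok & labels == 0L])
    data.frame(feature = f,
               mean_neg = mean(v[ok & labels == 0L]),
               mean_pos = mean(v[ok & labels == 1L]),
               p = mw$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- bonferroni_alpha(n_tests %||% length(nm), fwer)
  out
}

# Spearman correlations of model features vs biomarkers (Table-4-style
# layout: one row per biomarker, rho and p per feature).
biomarker_correlations <- function(features, truth, model_features) {
  bio <- c(haemoglobin_g_dl = "haemoglobin_g_dl", wbc_g_l = "wbc_g_l",
           platelets_g_l = "platelets_g_l", ldh_ui_l = "ldh_ui_l")
  rows <- lapply(names(bio), function(b) {
    row <- data.frame(biomarker = b)
    for (f in model_features) {
      sp <- spearman(truth[[bio[[b]]]], features[[f]])
      row[[paste0(f, "_rho")]] <- sp$rho
      row[[paste0(f, "_p")]] <- sp$p
    }
    row
  })
  do.call(rbind, rows)
}

#' Run the end-to-end pipeline on a phantom cohort
#'
#' Simulates a seeded cohort, extracts the 26 features per subject, builds
#' (or applies) the prediction-score model, and evaluates diagnostic
#' performance: ROC/AUC with CI for the biopsy, the visual PET read, the
#' skewness rule and the prediction score; pairwise DeLong comparisons;
#' confusion metrics at the model cut-off; per-feature group comparisons
#' with the Bonferroni threshold; and biomarker correlations.
#'
#' Deterministic for a fixed `(config, seed)`: re-running writes
#' byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param seed Master seed for the cohort and the fold assignment.
#' @param out_dir Optional output directory; when given, writes
#'   `features.csv`, `truth.csv`, `model.json`, `evaluation.json` and
#'   `correlations.csv` there (volumes are not persisted by default).
#' @param write_volumes Also write per-subject NIfTI volumes under
#'   `out_dir/volumes` (requires `out_dir`).
#' @return List with `truth`, `features`, `model`, `scores`, `evaluation`,
#'   `group_tests` and `correlations`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL, write_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- generate_truth_table(config$n_subjects, config$prevalence,
                                config$subgroup_split, seed)
  if (write_volumes) {
    if (is.null(out_dir)) stop("`write_volumes` requires `out_dir`")
    generate_cohort(config$n_subjects, config$prevalence, config$phantom,
                    config$subgroup_split, seed,
                    out_dir = file.path(out_dir, "volumes"))
  }
  features <- extract_features_cohort(truth, config$phantom, seed,
                                      config$extraction)
  labels <- as.integer(truth$bone_status == "positive")

  model <- if (config$model == "published") published_model()
           else fit_lasso(features[radiomic_feature_names()], labels,
                          n_folds = config$n_folds, seed = seed)
  scores <- pred_score(model, features)
  predicted <- classify(scores, model$cutoff)

  bmb_score <- as.integer(truth$bmb == "+")
  visual_score <- as.integer(truth$pet_visual == "+")
  skew_score <- features$SUVskewness
  evals <- list(bmb = diagnostic_eval(bmb_score, labels),
                visual_pet = diagnostic_eval(visual_score, labels),
                skewness = diagnostic_eval(skew_score, labels),
                pred_score = diagnostic_eval(scores, labels))
  score_sets <- list(bmb = bmb_score, visual_pet = visual_score,
                     skewness = skew_score, pred_score = scores)
  pairs <- utils::combn(names(score_sets), 2)
  delong <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dt <- delong_test(score_sets[[a]], score_sets[[b]], labels)
    data.frame(test_a = a, test_b = b, auc_a = dt$auc_a, auc_b = dt$auc_b,
               z = dt$z, p = dt$p)
  })
  delong <- do.call(rbind, delong)

  cm <- confusion_metrics(tp = sum(predicted == "positive" & labels == 1L),
                          fp = sum(predicted == "positive" & labels == 0L),
                          fn = sum(predicted == "negative" & labels == 1L),
                          tn = sum(predicted == "negative" & labels == 0L))
  group_tests <- feature_group_tests(features, labels, config$fwer,
                                     config$n_tests)
  model_features <- names(model$coefficients)
  correlations <- if (length(model_features))
    biomarker_correlations(features, truth, model_features) else NULL

  evaluation <- list(
    n_subjects = config$n_subjects,
    n_positive = sum(labels), n_negative = sum(labels == 0L),
    model = list(provenance = model$provenance, intercept = model$intercept,
                 coefficients = as.list(model$coefficients),
                 cutoff = model$cutoff),
    auc = lapply(evals, function(e)
      list(auc = e$auc, se = e$auc_se, ci95 = e$ci95)),
    delong = delong,
    confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                     sensitivity = cm$sensitivity, specificity = cm$specificity,
                     ppv = cm$ppv, npv = cm$npv, accuracy = cm$accuracy),
    bonferroni_alpha = attr(group_tests, "alpha"),
    n_significant_features = sum(group_tests$p < attr(group_tests, "alpha"),
                                 na.rm = TRUE),
    seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    write_model_json(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(evaluation, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(correlations))
      utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
  }

  list(truth = truth, features = features, model = model, scores = scores,
       evaluation = evaluation, group_tests = group_tests,
       correlations = correlations)
}
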