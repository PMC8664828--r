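#' Composite gold-standard bone status
#'
#' Combines bone-marrow biopsy and visual PET reads: a subject is
#' bone-negative only when both are negative; any positive read makes the
#' subject bone-positive.
#'
#' @param bmb,pet_visual Character vectors of `"+"` / `"-"` statuses
#'   (vectorized; recycled to a common length).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
composite_gold_label <- function(bmb, pet_visual) {
  chk <- function(x, what) {
    x <- as.character(x)
    if (any(is.na(x)) || !all(x %in% c("+", "-")))
      stop("`", what, "` must be '+' or '-' with no missing values")
    x
  }
  bmb <- chk(bmb, "bmb"); pet_visual <- chk(pet_visual, "pet_visual")
  ifelse(bmb == "+" | pet_visual == "+", "positive", "negative")
}

#' Prediction-score model
#'
#' A linear score over named radiomic features with a decision cut-off:
#' `score = intercept + sum(coefficients * features)`, classified positive
#' when strictly above the cut-off.
#'
#' @param intercept Model intercept.
#' @param coefficients Named numeric vector of feature coefficients.
#' @param cutoff Decision cut-off on the score scale.
#' @param provenance `"published"` or `"refit"`.
#' @param ... Extra fields (selection path, seed, ...) stored alongside.
#' @return A `pred_score_model` object.
#' @export
pred_score_model <- function(intercept, coefficients, cutoff = NA_real_,
                             provenance = c("refit", "published"), ...) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(coefficients) && is.null(names(coefficients)))
    stop("`coefficients` must be named by feature")
  structure(list(intercept = intercept, coefficients = coefficients,
                 cutoff = cutoff, provenance = provenance, ...),
            class = "pred_score_model")
}

#' @export
print.pred_score_model <- function(x, ...) {
  cat("<pred_score_model> (", x$provenance, ")\n  score = ",
      format(x$intercept), sep = "")
  for (nm in names(x$coefficients))
    cat(sprintf(" %+g * %s", x$coefficients[[nm]], nm))
  cat("\n  cut-off: score >", format(x$cutoff), "=> positive\n")
  invisible(x)
}

#' The frozen published prediction-score model
#'
#' The published four-feature linear signature for bone marrow involvement:
#' intercept -8.134, coefficients 0.927 (GLCM variance), 10.272 (GLCM
#' correlation), 0.076 (GLCM joint entropy) and -0.003 (NGLDM busyness),
#' with the published decision cut-off of -0.190.
#'
#' @return A [pred_score_model()] with provenance `"published"`.
#' @export
published_model <- function() {
  pred_score_model(
    intercept = -8.134,
    coefficients = c(variance_GLCM = 0.927, correlation_GLCM = 10.272,
                     joint_entropy_GLCM = 0.076, busyness_NGLDM = -0.003),
    cutoff = -0.190, provenance = "published")
}

#' The published skewness cut-off rule
#'
#' Univariate rule on the SUV-histogram skewness: positive when skewness is
#' strictly above 1.20.
#'
#' @return List with `feature`, `cutoff` and `comparator`.
#' @export
skewness_rule <- function() {
  list(feature = "SUVskewness", cutoff = 1.20, comparator = ">")
}

#' Fit the LASSO radiomic signature
#'
#' Selects features by L1-penalized logistic regression with stratified
#' k-fold cross-validation (binomial deviance loss, penalty at the minimum
#' mean CV loss), then — by default — refits an unpenalized logistic model on
#' the selected features so the reported coefficients are on the original
#' feature scale. The decision cut-off is the Youden-optimal threshold of
#' the refit scores on the training cohort.
#'
#' Features are standardized internally for the penalized path (glmnet
#' `standardize = TRUE`) and reported back on the raw scale. Constant
#' columns are dropped with a warning before fitting.
#'
#' @param features Data.frame or matrix of feature columns (typically the 26
#'   of [radiomic_feature_names()]).
#' @param labels Binary outcome (0/1, logical, or `"positive"`/`"negative"`).
#' @param n_folds Number of CV folds (default 10).
#' @param lambda Optional penalty grid passed to glmnet.
#' @param seed Seed for the stratified fold assignment.
#' @param refit Refit an unpenalized logistic model on the selected set
#'   (default); otherwise the penalized coefficients at the chosen lambda
#'   are reported.
#' @param rule Penalty choice: `"min"` (minimum mean CV deviance, the
#'   default — denser selections) or `"1se"` (the one-standard-error rule —
#'   sparser, with tighter false-selection control on null data).
#' @return A [pred_score_model()] with provenance `"refit"`, carrying
#'   `selection` (selected feature names), `lambda_min`, `n_folds`, `seed`
#'   and `cv` (per-lambda mean CV deviance summary).
#' @export
fit_lasso <- function(features, labels, n_folds = 10L, lambda = NULL,
                      seed = 1L, refit = TRUE, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- labels
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "positive")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (nrow(x) <= n_folds) stop("need more subjects than folds")

  const <- apply(x, 2, function(col) stats::sd(col) == 0 || anyNA(col))
  if (any(const)) {
    warning("dropping constant or incomplete feature column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }

  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })

  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             foldid = foldid, lambda = lambda,
                             type.measure = "deviance", standardize = TRUE)
  s_lambda <- if (rule == "min") "lambda.min" else "lambda.1se"
  beta <- as.matrix(stats::coef(cvfit, s = s_lambda))
  selected <- rownames(beta)[-1][beta[-1, 1] != 0]

  if (refit && length(selected)) {
    df <- data.frame(y = y, x[, selected, drop = FALSE], check.names = FALSE)
    fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", selected),
                                                collapse = " + ")))
    g <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
    intercept <- unname(stats::coef(g)[1])
    coefs <- stats::coef(g)[-1]
    names(coefs) <- selected
  } else {
    intercept <- beta[1, 1]
    coefs <- beta[-1, 1][beta[-1, 1] != 0]
  }

  model <- pred_score_model(intercept, coefs, provenance = "refit",
                            selection = selected,
                            lambda_min = cvfit[[s_lambda]], rule = rule,
                            n_folds = n_folds, seed = seed,
                            cv = data.frame(lambda = cvfit$lambda,
                                            mean_deviance = cvfit$cvm))
  scores <- pred_score(model, as.data.frame(x))
  if (length(unique(scores)) > 1L) {
    yj <- youden_cutoff(scores, y)
    model$cutoff <- yj$cutoff
    model$youden_j <- yj$j
  }
  model
}

#' Compute the prediction score
#'
#' `intercept + sum(coefficients * features)` for each row; no clipping.
#' Every model feature must be present and non-missing — a degenerate
#' (flagged NA) feature is a hard error naming the feature.
#'
#' @param model A [pred_score_model()].
#' @param features One-row-or-more data.frame (or named vector) containing
#'   at least the model's features.
#' @return Numeric score vector.
#' @export
pred_score <- function(model, features) {
  stopifnot(inherits(model, "pred_score_model"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- as.data.frame(as.list(features))
  need <- names(model$coefficients)
  missing_ft <- setdiff(need, colnames(features))
  if (length(missing_ft))
    stop("feature(s) missing from input: ", paste(missing_ft, collapse = ", "))
  xm <- as.matrix(features[, need, drop = FALSE])
  bad <- colnames(xm)[colSums(!is.finite(xm)) > 0]
  if (length(bad))
    stop("feature(s) with missing/degenerate values: ", paste(bad, collapse = ", "))
  as.numeric(model$intercept + xm %*% model$coefficients[need])
}

#' Classify a score against a cut-off
#'
#' Strictly-greater comparison: `score > cutoff` is positive, anything at or
#' below the cut-off is negative.
#'
#' @param score Numeric score(s); must be finite.
#' @param cutoff Decision cut-off, or a [pred_score_model()] whose cut-off
#'   is used.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify <- function(score, cutoff) {
  if (inherits(cutoff, "pred_score_model")) cutoff <- cutoff$cutoff
  if (any(!is.finite(score))) stop("scores must be finite")
  if (!is.finite(cutoff)) stop("cut-off must be finite")
  ifelse(score > cutoff, "positive", "negative")
}

#' Write / read a prediction-score model as JSON
#'
#' Lossless round-trip of the model's intercept, coefficients, cut-off,
#' provenance and selection through a JSON file.
#'
#' @param model A [pred_score_model()].
#' @param path JSON file path.
#' @return `path` (write) or a [pred_score_model()] (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "pred_score_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         cutoff = model$cutoff, provenance = model$provenance,
         selection = model$selection, lambda_min = model$lambda_min,
         seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pred_score_model(intercept = x$intercept,
                   coefficients = unlist(x$coefficients),
                   cutoff = x$cutoff %||% NA_real_,
                   provenance = x$provenance,
                   selection = x$selection, lambda_min = x$lambda_min,
                   seed = x$seed)
}
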