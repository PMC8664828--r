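#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' accuracy as percentages. A metric with a zero denominator is undefined
#' and returned as NA (an explicit sentinel), never silently 0.
#'
#' @param tp,fp,fn,tn Non-negative counts; their total must be positive.
#' @return A `confusion_metrics` list with the counts and the five
#'   percentage metrics.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn),
    accuracy = pct(tp + tn, sum(counts))),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    cat(sprintf("  %-11s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.1f%%", x[[m]])))
  invisible(x)
}

# Normalize labels to 0/1 integers; requires both classes.
as_binary_labels <- function(labels, require_both = TRUE) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "positive")
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1 or positive/negative)")
  if (require_both && length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}

#' Area under the empirical ROC curve
#'
#' Midrank (Mann-Whitney) estimator: `P(score_pos > score_neg) + 0.5 *
#' P(tie)`, identical to the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels Binary labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  r <- rank(scores)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC operating points at thresholds "score > t" for t in
# (-Inf, midpoints of adjacent distinct scores, Inf).
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  sens <- vapply(thr, function(t) sum(scores > t & labels == 1L) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores <= t & labels == 0L) / n_neg, 0)
  data.frame(threshold = thr, fpr = 1 - spec, sensitivity = sens,
             specificity = spec)
}

#' Youden-optimal decision cut-off
#'
#' Scans thresholds at the midpoints of adjacent distinct scores (plus
#' infinite endpoints) with the strict rule `score > cutoff => positive`,
#' and returns the cut-off maximizing `J = sensitivity + specificity - 1`.
#' Ties in J are broken in favour of the higher specificity (the higher
#' cut-off, lowest false-positive burden).
#'
#' @inheritParams auc
#' @return List with `cutoff`, `j`, `sensitivity` and `specificity` (the
#'   latter two as fractions).
#' @export
youden_cutoff <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  rc <- rc[is.finite(rc$threshold) | rc$threshold == -Inf, ]
  j <- rc$sensitivity + rc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(rc$specificity[best])]
  list(cutoff = rc$threshold[pick], j = j[pick],
       sensitivity = rc$sensitivity[pick], specificity = rc$specificity[pick])
}

# DeLong placement values of one score vector: V10 (per positive), V01 (per
# negative).
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong comparison of two correlated AUCs
#'
#' Nonparametric comparison of two ROC AUCs measured on the same subjects,
#' using the structural-component (placement-value) estimator of the AUC
#' covariance matrix, a normal two-sided p-value for the difference, and
#' per-curve standard errors with normal 95% confidence intervals clipped to
#' `[0, 1]`.
#'
#' @param scores_a,scores_b Paired score vectors on identical subjects.
#' @param labels Binary labels shared by both scores.
#' @return List with `auc_a`, `auc_b`, `se_a`, `se_b`, `ci_a`, `ci_b`,
#'   `var_diff`, `z` and `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  labels <- as_binary_labels(labels)
  if (length(labels) != length(scores_a))
    stop("labels must match the score vectors in length")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(var_diff)
  ci <- function(a, se) pmin(1, pmax(0, a + c(-1, 1) * stats::qnorm(0.975) * se))
  list(auc_a = pa$auc, auc_b = pb$auc,
       se_a = sqrt(S[1, 1]), se_b = sqrt(S[2, 2]),
       ci_a = ci(pa$auc, sqrt(S[1, 1])), ci_b = ci(pb$auc, sqrt(S[2, 2])),
       var_diff = var_diff, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Full diagnostic evaluation of one score
#'
#' ROC points, midrank AUC with DeLong standard error and normal 95% CI, the
#' Youden-optimal cut-off and the confusion metrics at that cut-off.
#'
#' @inheritParams auc
#' @return A `diagnostic_eval` list.
#' @export
diagnostic_eval <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pl <- delong_placements(scores, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  se <- sqrt(stats::var(pl$v10) / m + stats::var(pl$v01) / n)
  yj <- youden_cutoff(scores, labels)
  pred_pos <- scores > yj$cutoff
  cm <- confusion_metrics(tp = sum(pred_pos & labels == 1L),
                          fp = sum(pred_pos & labels == 0L),
                          fn = sum(!pred_pos & labels == 1L),
                          tn = sum(!pred_pos & labels == 0L))
  structure(list(roc_points = roc_curve(scores, labels),
                 auc = pl$auc, auc_se = se,
                 ci95 = pmin(1, pmax(0, pl$auc + c(-1, 1) * stats::qnorm(0.975) * se)),
                 optimal_cutoff = yj$cutoff, youden_j = yj$j,
                 confusion = cm),
            class = "diagnostic_eval")
}

#' Mann-Whitney rank-sum test
#'
#' Midrank U statistic. For combined sample sizes of at most 12 the
#' two-sided p-value is exact, from complete enumeration of all group
#' assignments of the pooled midranks (`p = P(|U - mu| >= |U_obs - mu|)`);
#' larger samples use the tie-corrected normal approximation without
#' continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `u` (U statistic for `x`), `p` and `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  mu <- m * n / 2
  if (N <= 12L) {
    combos <- utils::combn(N, m)
    us <- apply(combos, 2, u_of)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) { p <- 1; method <- "normal" }
    else {
      z <- (u_obs - mu) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
      method <- "normal"
    }
  }
  list(u = u_obs, p = min(p, 1), method = method)
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided p by hypergeometric tail summation over tables at least as
#' extreme (probability no larger than the observed table).
#'
#' @param a,b,c,d Non-negative cell counts, row-wise.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("table is empty")
  stats::fisher.test(matrix(counts, 2, byrow = TRUE))$p.value
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t approximation on `n - 2` degrees of freedom. A constant input vector
#' leaves the correlation undefined (NA, with a warning).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, finite values.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Bonferroni-corrected per-test significance level
#'
#' @param m Number of tests (>= 1).
#' @param fwer Family-wise error rate in (0, 1).
#' @return `fwer / m`.
#' @export
bonferroni_alpha <- function(m, fwer = 0.05) {
  if (m < 1) stop("`m` must be at least 1")
  if (!(fwer > 0 && fwer < 1)) stop("`fwer` must be in (0, 1)")
  fwer / m
}
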