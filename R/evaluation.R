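# From-scratch statistical toolkit for method-comparison studies:
# Pearson and Spearman correlation, the Spearman-to-Pearson conversion,
# ROC curves with trapezoidal AUC, and the rank-based vs parametric
# two-group test pair. stats::cor / wilcox.test / t.test are used only as
# independent cross-checks in the test suite, never here.

#' Pearson and Spearman correlation
#'
#' `pearson_cor()` computes the sample Pearson correlation
#' \deqn{r = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
#'  {\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}}.}
#' `spearman_cor()` applies the same formula to mid-ranks (average ranks for
#' ties), giving Spearman's rank correlation. Pearson measures *linear*
#' association and is sensitive to outliers and nonlinearity; Spearman
#' measures *monotone* association and is invariant under strictly
#' increasing transformations of either variable — the property that makes
#' strictly monotone surrogate indices interchangeable in rank-based
#' analyses.
#'
#' @param x,y numeric vectors of equal length, at least 3, no missing values.
#' @return an object of class `"icor"`: a list with `coefficient` (in
#'   \eqn{[-1, 1]}), `method` and `n`.
#' @examples
#' pearson_cor(1:3, c(1, 4, 9))$coefficient   # 0.9897...
#' spearman_cor(1:3, c(1, 4, 9))$coefficient  # exactly 1
#' @export
pearson_cor <- function(x, y) {
  check_paired(x, y)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("undefined correlation: a series is constant (zero denominator)",
         call. = FALSE)
  }
  r <- sum(dx * dy) / (sqrt(sxx) * sqrt(syy))
  structure(list(coefficient = min(1, max(-1, r)),
                 method = "pearson", n = length(x)),
            class = "icor")
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  check_paired(x, y)
  res <- pearson_cor(rank(x, ties.method = "average"),
                     rank(y, ties.method = "average"))
  res$method <- "spearman"
  res
}

check_paired <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("invalid input: x and y must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("invalid input: correlation requires n >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("invalid input: missing or non-finite values", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.icor <- function(x, ...) {
  cat(sprintf("%s correlation: %.6f (n = %d)\n",
              x$method, x$coefficient, x$n))
  invisible(x)
}

#' Convert a Spearman correlation to a Pearson correlation
#'
#' The conversion \eqn{r = 2 \sin(\rho \pi / 6)} used in correlational
#' meta-analysis. It assumes bivariate normality; insulin sensitivity
#' measures are typically skewed, so converted values should be read with
#' caution. The map is odd, strictly increasing, and fixes \eqn{-1, 0, 1}.
#'
#' @param rho Spearman correlation(s) in \eqn{[-1, 1]}.
#' @return Pearson-scale correlation(s) in \eqn{[-1, 1]}.
#' @examples
#' spearman_to_pearson(c(-1, 0, 0.5, 1))
#' @export
spearman_to_pearson <- function(rho) {
  check_finite(rho, "rho")
  if (any(abs(rho) > 1)) {
    stop("domain error: |rho| must be <= 1", call. = FALSE)
  }
  2 * sin(rho * pi / 6)
}

# ---- ROC --------------------------------------------------------------------

#' ROC curve and trapezoidal AUC
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' label (here: insulin resistant as defined by the clamp). The score is
#' first oriented so that larger oriented values call the positive class:
#' for sensitivity-type indices such as QUICKI pass
#' `orientation = "lower_is_positive"`, which negates the score. All
#' distinct score values are swept from most to least extreme; at each
#' threshold the true positive rate is the fraction of positives called
#' positive and the false positive rate the fraction of negatives called
#' positive. Tied scores move as a block, so the curve has one vertex per
#' distinct value, and the AUC is the trapezoidal area — which equals the
#' tie-corrected probability that a random positive outranks a random
#' negative (see [auc_probability_oracle()]).
#'
#' Because the curve depends on the score only through its ranks, any two
#' scores related by a strictly increasing function have identical ROC
#' curves — the reason HOMA-IR, FIRI and (orientation-reversed) QUICKI can
#' never be distinguished by ROC analysis.
#'
#' @param scores numeric vector of index values.
#' @param labels logical vector, `TRUE` = positive class (insulin resistant).
#' @param orientation `"higher_is_positive"` (resistance-type indices) or
#'   `"lower_is_positive"` (sensitivity-type indices).
#' @return object of class `"roc_curve"`: list with `points` (data frame of
#'   `fpr`, `tpr` from (0,0) to (1,1)), `thresholds` (oriented-score
#'   thresholds, one per interior vertex), `orientation`, `auc`, and class
#'   counts `n_pos`, `n_neg`.
#' @examples
#' rc <- roc_curve(c(3, 1, 4, 2), c(TRUE, FALSE, TRUE, FALSE))
#' rc$auc
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_is_positive",
                                      "lower_is_positive")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(scores) || !is.logical(labels) ||
      length(scores) != length(labels)) {
    stop("invalid input: scores numeric and labels logical, equal length",
         call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || any(!is.finite(scores))) {
    stop("invalid input: missing or non-finite values", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("degenerate labels: both classes must be non-empty", call. = FALSE)
  }
  s <- if (orientation == "lower_is_positive") -scores else scores
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  lab <- labels[o]
  # block boundaries: last position of each distinct oriented value
  last <- which(s != c(s[-1L], NA)) # NA comparison at end is FALSE -> add n
  last <- c(last, length(s))
  last <- unique(last)
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  pts <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, thresholds = s[last],
                 orientation = orientation, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d vertices, AUC = %.4f\n",
              x$n_pos, x$n_neg, nrow(x$points), x$auc))
  invisible(x)
}

#' Pairwise-probability AUC oracle
#'
#' Brute-force AUC as the probability that a random positive-class score
#' exceeds a random negative-class score, with ties counting one half:
#' \eqn{(\mathrm{wins} + 0.5\,\mathrm{ties}) / (n_+ n_-)}. Exact by
#' enumeration of all positive-negative pairs; serves as the independent
#' oracle for the trapezoidal AUC of [roc_curve()].
#'
#' @param scores_pos,scores_neg scores of the positive / negative class.
#' @return AUC in \eqn{[0, 1]}.
#' @examples
#' auc_probability_oracle(2, 1)  # 1
#' auc_probability_oracle(1, 1)  # 0.5
#' @export
auc_probability_oracle <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("degenerate labels: both classes must be non-empty", call. = FALSE)
  }
  cmp <- outer(scores_pos, scores_neg, function(p, q) {
    (p > q) + 0.5 * (p == q)
  })
  sum(cmp) / (length(scores_pos) * length(scores_neg))
}

#' Classify insulin resistance from the clamp measure
#'
#' Insulin resistance is defined from the clamp glucose infusion rate
#' normalized per kg lean body mass as \eqn{M_{LBM} < 4.7} mg/(kg·min);
#' the inequality is strict, so a subject exactly at the cutoff is not
#' resistant.
#'
#' @param m_lbm clamp measure, mg/(kg·min), strictly positive.
#' @param cutoff resistance threshold, default 4.7 mg/(kg·min).
#' @return logical vector, `TRUE` = insulin resistant.
#' @examples
#' classify_resistant(c(4.69, 4.7, 100))
#' @export
classify_resistant <- function(m_lbm, cutoff = 4.7) {
  check_positive(m_lbm, "m_lbm")
  check_positive(cutoff, "cutoff")
  m_lbm < cutoff
}

# ---- two-group tests --------------------------------------------------------

#' Rank-based and parametric two-group tests, side by side
#'
#' Runs the Mann-Whitney rank-sum test (normal approximation with tie and
#' continuity correction, two-sided) and the Welch two-sample t-test on the
#' same pair of groups. Because the Mann-Whitney test depends on the data
#' only through ranks, it gives identical results for any two scores related
#' by a strictly increasing transformation — e.g. HOMA-IR vs FIRI, or
#' HOMA-IR vs negated QUICKI — whereas the t-test generally does not.
#'
#' The Mann-Whitney statistic is \eqn{U = R_a - n_a(n_a+1)/2} with \eqn{R_a}
#' the rank sum of the first group (mid-ranks for ties); its null variance
#' carries the standard tie correction, and the two-sided p-value uses a
#' 0.5 continuity correction.
#'
#' @param values_a,values_b numeric vectors, each of length at least 2.
#' @return list with elements `mann_whitney` and `t_test`, each a list with
#'   `method`, `statistic`, `p_value`, `n_a`, `n_b` (the t-test adds `df`).
#' @examples
#' g <- group_tests(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' g$mann_whitney$p_value
#' g$t_test$p_value
#' @export
group_tests <- function(values_a, values_b) {
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      length(values_a) < 2L || length(values_b) < 2L) {
    stop("invalid input: each group needs at least 2 numeric values",
         call. = FALSE)
  }
  if (anyNA(values_a) || anyNA(values_b)) {
    stop("invalid input: missing values", call. = FALSE)
  }
  na <- length(values_a)
  nb <- length(values_b)
  n <- na + nb

  # Mann-Whitney, normal approximation with tie + continuity correction
  r <- rank(c(values_a, values_b), ties.method = "average")
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(values_a, values_b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- na * nb / 2
  if (sigma2 <= 0) {
    mw_p <- 1
    z <- 0
  } else {
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    mw_p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  mw <- list(method = "mann_whitney", statistic = u, p_value = mw_p,
             n_a = na, n_b = nb)

  # Welch t-test
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    stop("degenerate data: zero variance in both groups, t-test undefined",
         call. = FALSE)
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(values_a) - mean(values_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tt <- list(method = "t_test", statistic = tstat,
             p_value = 2 * stats::pt(-abs(tstat), df),
             df = df, n_a = na, n_b = nb)

  list(mann_whitney = mw, t_test = tt)
}
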