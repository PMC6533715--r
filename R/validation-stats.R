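#' Pearson correlation with domain checks
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, with nonzero
#'   variance.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort_domain("need two vectors of equal length >= 3")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    abort_domain("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    abort_domain("zero variance input")
  stats::cor(x, y)
}

#' Steiger's Z test for two dependent overlapping correlations
#'
#' Tests whether two correlations sharing a variable differ: r_jk versus
#' r_jh, with r_kh the correlation between the non-shared variables. Both
#' correlations are Fisher z-transformed; their asymptotic covariance uses
#' the back-transformed mean correlation (Steiger's recommendation):
#' with rbar = tanh((z_jk + z_jh)/2),
#' psi = r_kh (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_kh^2) / 2,
#' c = psi / (1 - rbar^2)^2, and
#' Z = (z_jk - z_jh) sqrt((n - 3) / (2 - 2c)).
#'
#' @param r_jk,r_jh,r_kh Sample correlations, all strictly inside (-1, 1);
#'   the three must form a positive semi-definite correlation matrix.
#' @param n Sample size (> 3).
#' @return A one-row tibble of class `steiger_result`: `z`, `p` (two-sided),
#'   `r_jk`, `r_jh`, `r_kh`, `n`.
#' @examples
#' steiger_z(0.81, -0.50, -0.74, 194) # CT metric vs score and vs FEV1
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(abs(rs) >= 1)) abort_domain("correlations must lie inside (-1, 1)")
  if (!is_number(n) || n <= 3) abort_domain("`n` must exceed 3")
  cm <- matrix(c(1, r_jk, r_jh,
                 r_jk, 1, r_kh,
                 r_jh, r_kh, 1), 3L, 3L)
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    abort_domain("correlations do not form a positive semidefinite matrix")
  z1 <- atanh(r_jk)
  z2 <- atanh(r_jh)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  cov_z <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_z))
  out <- tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)),
                        r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n)
  class(out) <- c("steiger_result", class(tibble::tibble()))
  out
}

#' Bootstrap version of the dependent-correlation comparison
#'
#' A resampling reading of the "robust" dependent-correlation test: subjects
#' are resampled with replacement, the difference r_jk - r_jh is recomputed
#' per resample, and the two-sided p-value is taken from the bootstrap
#' z-score of the observed difference.
#'
#' @param j,k,h Raw data vectors for the shared variable `j` and the two
#'   compared variables.
#' @param n_boot Number of resamples (default 2000).
#' @param seed Optional seed.
#' @return A one-row tibble: `diff` (observed r_jk - r_jh), `z`, `p`,
#'   `n_boot`.
#' @export
steiger_z_boot <- function(j, k, h, n_boot = 2000L, seed = NULL) {
  n <- length(j)
  if (length(k) != n || length(h) != n || n < 4L)
    abort_domain("need three equal-length vectors with n >= 4")
  obs <- stats::cor(j, k) - stats::cor(j, h)
  diffs <- with_seed_(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, replace = TRUE)
    stats::cor(j[idx], k[idx]) - stats::cor(j[idx], h[idx])
  }, numeric(1)))
  se <- stats::sd(diffs)
  z <- obs / se
  tibble::tibble(diff = obs, z = z, p = 2 * stats::pnorm(-abs(z)),
                 n_boot = n_boot)
}

group_summaries <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("mean", "sd", "n")
    if (!all(need %in% names(groups)))
      abort_domain("summary input needs columns mean, sd, n")
    out <- tibble::tibble(mean = groups$mean, sd = groups$sd, n = groups$n)
  } else if (is.list(groups)) {
    out <- tibble::tibble(
      mean = unname(vapply(groups, mean, numeric(1))),
      sd = unname(vapply(groups, stats::sd, numeric(1))),
      n = unname(vapply(groups, length, integer(1)))
    )
  } else {
    abort_domain("`groups` must be a list of vectors or a summary data frame")
  }
  if (nrow(out) < 2L) abort_domain("need at least 2 groups")
  if (any(out$n < 2) || any(out$sd <= 0) || anyNA(out))
    abort_domain("each group needs n >= 2 and sd > 0")
  out
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F* with Welch-Satterthwaite denominator degrees of freedom. The
#' statistic depends on the data only through per-group (mean, sd, n), so
#' published summary tables can be tested directly.
#'
#' @param groups Either a list of numeric vectors (raw data) or a data frame
#'   with columns `mean`, `sd`, `n` (one row per group).
#' @return A one-row tibble of class `welch_anova_result`: `f_star`, `df1`,
#'   `df2`, `p`.
#' @examples
#' welch_anova(data.frame(mean = c(1.1, 3.1, 6.8),
#'                        sd = c(1.5, 2.6, 2.5),
#'                        n = c(57, 58, 79)))
#' @export
welch_anova <- function(groups) {
  s <- group_summaries(groups)
  k <- nrow(s)
  w <- s$n / s$sd^2
  w_tot <- sum(w)
  m_w <- sum(w * s$mean) / w_tot
  num <- sum(w * (s$mean - m_w)^2) / (k - 1)
  lambda <- sum((1 - w / w_tot)^2 / (s$n - 1))
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f_star <- num / den
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  out <- tibble::tibble(f_star = f_star, df1 = df1, df2 = df2,
                        p = stats::pf(f_star, df1, df2, lower.tail = FALSE))
  class(out) <- c("welch_anova_result", class(tibble::tibble()))
  out
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' All pairwise mean comparisons without assuming equal variances: each pair
#' uses the Welch standard error and degrees of freedom, and the p-value
#' comes from the studentized range distribution with the total number of
#' groups, q = |t| * sqrt(2).
#'
#' @param groups A named list of numeric vectors (raw data per group), or a
#'   summary data frame with columns `group`, `mean`, `sd`, `n`.
#' @return A tibble with one row per pair: `group1`, `group2`, `mean_diff`,
#'   `se`, `t`, `q`, `df`, `p`.
#' @export
games_howell <- function(groups) {
  if (is.data.frame(groups)) {
    s <- group_summaries(groups)
    s$group <- if ("group" %in% names(groups)) as.character(groups$group)
               else paste0("G", seq_len(nrow(s)))
  } else {
    s <- group_summaries(groups)
    s$group <- if (!is.null(names(groups))) names(groups)
               else paste0("G", seq_len(nrow(s)))
  }
  k <- nrow(s)
  pairs <- utils::combn(k, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1L, pi]; j <- pairs[2L, pi]
    vi <- s$sd[i]^2 / s$n[i]
    vj <- s$sd[j]^2 / s$n[j]
    se <- sqrt(vi + vj)
    t_stat <- (s$mean[i] - s$mean[j]) / se
    df <- (vi + vj)^2 / (vi^2 / (s$n[i] - 1) + vj^2 / (s$n[j] - 1))
    q <- abs(t_stat) * sqrt(2)
    tibble::tibble(group1 = s$group[i], group2 = s$group[j],
                   mean_diff = s$mean[i] - s$mean[j], se = se, t = t_stat,
                   q = q, df = df,
                   p = stats::ptukey(q, nmeans = k, df = df,
                                     lower.tail = FALSE))
  })
}

#' Univariate logistic regression of a binary outcome on a score
#'
#' Maximum-likelihood fit of Pr(Y = 1 | X = x) = plogis(a + b x) by
#' iteratively reweighted least squares (Newton scoring, via `stats::glm`).
#' Quasi-complete separation is detected and flagged; the monotone predicted
#' probabilities of a separated fit are still usable for ranking/ROC work.
#'
#' @param x Numeric score vector.
#' @param y Binary outcome (logical, 0/1, or two-level factor); both classes
#'   must be present.
#' @return An object of class `logistic_fit`: list with `intercept`, `slope`,
#'   `converged`, `n_iter`, `separation`, and the underlying `glm` object.
#' @export
fit_logistic <- function(x, y) {
  y <- as_binary(y)
  if (length(unique(y)) < 2L) abort_domain("both outcome classes required")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(list(
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L]),
    converged = fit$converged,
    n_iter = fit$iter,
    separation = sep_warn,
    model = fit
  ), class = "logistic_fit")
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) abort_domain("`y` must be binary")
  as.integer(y)
}

#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  stats::plogis(object$intercept + object$slope * newdata)
}

#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, n_iter = x$n_iter,
                 separation = x$separation)
}

# empirical ROC of scores against binary labels; returns the full step curve
roc_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  scores <- scores[ord]
  # collapse threshold ties so the curve steps once per distinct score
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(scores, fromLast = TRUE)
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  tibble::tibble(
    threshold = c(Inf, scores[last]),
    sensitivity = c(0, tp[last] / n_pos),
    specificity = c(1, 1 - fp[last] / n_neg)
  )
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
}

#' Cross-validated logistic ROC analysis
#'
#' Stratified k-fold cross-validation of the univariate logistic classifier:
#' within each fold the model is fitted on the remaining folds and held-out
#' probabilities are predicted. The pooled held-out probabilities define the
#' reported ROC curve and AUC (trapezoid rule, which on the pooled step curve
#' equals the Mann-Whitney statistic); per-fold AUCs and a vertically
#' fold-averaged ROC over a common false-positive-rate grid are also
#' returned.
#'
#' @param x Numeric score vector.
#' @param y Binary outcome; each class must have at least `k_folds` members.
#' @param k_folds Number of folds (default 10).
#' @param seed Optional integer seed controlling fold assignment.
#' @param fpr_grid Grid for the fold-averaged curve (default 0 to 1 by 0.01).
#' @return An object of class `roc_result`: list with `roc` (pooled tibble of
#'   threshold/sensitivity/specificity), `auc`, `fold_aucs`, `mean_fold_auc`,
#'   `averaged_roc` (tibble fpr/tpr), `predictions` (tibble x, y, prob,
#'   fold), `k_folds`.
#' @export
cv_roc <- function(x, y, k_folds = 10L, seed = NULL,
                   fpr_grid = seq(0, 1, by = 0.01)) {
  y <- as_binary(y)
  n <- length(x)
  if (length(y) != n) abort_domain("`x` and `y` lengths differ")
  counts <- table(y)
  if (length(counts) < 2L || any(counts < k_folds))
    abort_domain("each class needs at least `k_folds` members")
  fold <- integer(n)
  with_seed_(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  prob <- numeric(n)
  for (f in seq_len(k_folds)) {
    test <- fold == f
    fit <- fit_logistic(x[!test], y[!test])
    prob[test] <- predict(fit, x[test])
  }
  pooled <- roc_points(prob, y)
  auc <- trapezoid_auc(1 - pooled$specificity, pooled$sensitivity)
  fold_aucs <- vapply(seq_len(k_folds), function(f) {
    pts <- roc_points(prob[fold == f], y[fold == f])
    trapezoid_auc(1 - pts$specificity, pts$sensitivity)
  }, numeric(1))
  tpr_mat <- vapply(seq_len(k_folds), function(f) {
    pts <- roc_points(prob[fold == f], y[fold == f])
    stats::approx(1 - pts$specificity, pts$sensitivity, xout = fpr_grid,
                  ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  structure(list(
    roc = pooled,
    auc = auc,
    fold_aucs = fold_aucs,
    mean_fold_auc = mean(fold_aucs),
    averaged_roc = tibble::tibble(fpr = fpr_grid,
                                  tpr = rowMeans(tpr_mat)),
    predictions = tibble::tibble(x = x, y = y, prob = prob, fold = fold),
    k_folds = k_folds
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Cross-validated ROC (%d folds): pooled AUC %.3f, mean fold AUC %.3f\n",
              x$k_folds, x$auc, x$mean_fold_auc))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  bt <- best_threshold(x)
  tibble::tibble(auc = x$auc, mean_fold_auc = x$mean_fold_auc,
                 k_folds = x$k_folds, best_threshold = bt$threshold,
                 sensitivity = bt$sensitivity, specificity = bt$specificity)
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$roc

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$averaged_roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Fold-averaged ROC (AUC %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Operating point maximizing Youden's J
#'
#' Scans the ROC thresholds for the point maximizing
#' sensitivity + specificity - 1; ties are broken toward the higher
#' specificity.
#'
#' @param roc A `roc_result` from [cv_roc()], or a tibble with columns
#'   `threshold`, `sensitivity`, `specificity`.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
best_threshold <- function(roc) {
  pts <- if (inherits(roc, "roc_result")) roc$roc else tibble::as_tibble(roc)
  if (nrow(pts) == 0L) abort_domain("empty ROC")
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(pts$specificity[best])]
  tibble::tibble(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 youden_j = j[best])
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction. All expected cell counts must be positive.
#'
#' @param table A contingency table (matrix of counts).
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort_domain("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort_domain("zero marginal in contingency table")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected <= 0)) abort_domain("expected counts must be positive")
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p = unname(res$p.value))
}
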