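#' Regional parenchymal pattern profile
#'
#' One subject's texture-quantified lung composition: for each of six lung
#' regions (left/right crossed with upper/middle/lower zones), the fractions
#' of lung volume assigned to the ordered severity classes Normal (grade 0),
#' Mild LAA (1), Moderate LAA (2), Severe LAA (3), plus a relative region
#' volume weight. Per-region fractions must sum to 1 and weights to 1.
#'
#' Columns for other texture classes (e.g. `ground_glass`, `reticular`,
#' `honeycombing`) may be present; if any are nonzero the four ordered LAA
#' fractions are renormalized over their own sum with a warning, since only
#' the ordered axis enters the dissimilarity.
#'
#' @param data A data frame with columns `region`, `normal`, `mild_laa`,
#'   `moderate_laa`, `severe_laa`, `volume_weight`.
#' @return A tibble of class `pattern_profile`.
#' @export
pattern_profile <- function(data) {
  need <- c("region", "normal", "mild_laa", "moderate_laa", "severe_laa",
            "volume_weight")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    abort_malformed(paste("profile needs columns:",
                          paste(need, collapse = ", ")))
  out <- tibble::as_tibble(data)
  extra <- intersect(c("ground_glass", "reticular", "honeycombing"),
                     names(out))
  if (length(extra) > 0L && any(unlist(out[extra]) > 0)) {
    rlang::warn(paste("nonzero non-LAA pattern fractions present;",
                      "renormalizing over the ordered LAA classes"))
  }
  frac <- as.matrix(out[c("normal", "mild_laa", "moderate_laa", "severe_laa")])
  if (any(frac < 0)) abort_malformed("pattern fractions must be non-negative")
  rs <- rowSums(frac)
  if (any(rs <= 0)) abort_malformed("each region needs positive LAA mass")
  if (any(abs(rs - 1) > 1e-9)) frac <- frac / rs
  out$normal <- frac[, 1L]; out$mild_laa <- frac[, 2L]
  out$moderate_laa <- frac[, 3L]; out$severe_laa <- frac[, 4L]
  w <- out$volume_weight
  if (any(w < 0) || sum(w) <= 0)
    abort_malformed("volume weights must be non-negative with positive sum")
  out$volume_weight <- w / sum(w)
  out <- out[c(need, setdiff(names(out), need))]
  class(out) <- c("pattern_profile", class(tibble::tibble()))
  out
}

profile_cdf <- function(p) {
  frac <- as.matrix(p[c("normal", "mild_laa", "moderate_laa", "severe_laa")])
  t(apply(frac, 1L, cumsum))   # rows: regions; cols: CDF at grades 0..3
}

#' SILA dissimilarity between two pattern profiles
#'
#' The Scale Indicative of Lung parenchyma Abnormality: an ordinal
#' earth-mover distance between the ordered-class distributions, aggregated
#' over regions. Per region r, D_r = sum over grades k = 0..2 of
#' |CDF_p(k) - CDF_q(k)| (the cost of moving pattern mass along the ordered
#' severity axis with unit ground distance); SILA is the volume-weighted sum
#' of the regional distances, using the average of the two subjects'
#' (shared) region weights.
#'
#' @param p,q [pattern_profile()] objects with matching regions.
#' @return A non-negative dissimilarity; 0 iff the ordered marginals coincide
#'   in every region. Maximum 3 per region (all mass moved from Normal to
#'   Severe LAA).
#' @export
sila <- function(p, q) {
  if (!inherits(p, "pattern_profile")) p <- pattern_profile(p)
  if (!inherits(q, "pattern_profile")) q <- pattern_profile(q)
  if (nrow(p) != nrow(q) || !all(p$region == q$region))
    abort_domain("profiles must cover the same regions in the same order")
  cp <- profile_cdf(p)
  cq <- profile_cdf(q)
  d_r <- rowSums(abs(cp[, 1:3, drop = FALSE] - cq[, 1:3, drop = FALSE]))
  w <- (p$volume_weight + q$volume_weight) / 2
  w <- w / sum(w)
  sum(w * d_r)
}

#' Pairwise SILA dissimilarity matrix
#'
#' @param profiles A list of [pattern_profile()] objects (>= 2), or the
#'   `profile` list-column of a cohort tibble.
#' @return A symmetric matrix with zero diagonal; entry `[i, j]` is
#'   `sila(profiles[[i]], profiles[[j]])`.
#' @export
sila_matrix <- function(profiles) {
  n <- length(profiles)
  if (n < 2L) abort_domain("need at least 2 profiles")
  profiles <- purrr::map(profiles, function(p)
    if (inherits(p, "pattern_profile")) p else pattern_profile(p))
  cdfs <- purrr::map(profiles, profile_cdf)
  ws <- purrr::map(profiles, "volume_weight")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d_r <- rowSums(abs(cdfs[[i]][, 1:3, drop = FALSE] -
                         cdfs[[j]][, 1:3, drop = FALSE]))
      w <- (ws[[i]] + ws[[j]]) / 2
      d[i, j] <- d[j, i] <- sum(w / sum(w) * d_r)
    }
  }
  d
}

#' Affinity propagation clustering of a dissimilarity matrix
#'
#' Frey-Dueck exemplar-based clustering by responsibility/availability
#' message passing on the similarity matrix s = -dissimilarity, with the
#' diagonal set to the preference. The number of clusters emerges from the
#' preference; the default (the median off-diagonal similarity) favours a
#' moderate number of clusters.
#'
#' @param dissim Square symmetric non-negative dissimilarity matrix.
#' @param preference Diagonal self-similarity; default median off-diagonal
#'   similarity.
#' @param damping Message damping factor in \[0.5, 1).
#' @param max_iter Iteration cap (default 500).
#' @param stable_iters Declare convergence after this many iterations with an
#'   unchanged exemplar set (default 50).
#' @return An object of class `ap_result`: list with `labels` (exemplar index
#'   per subject; exemplars label themselves), `exemplars` (sorted indices),
#'   `n_iter`, `converged`, `preference`.
#' @export
affinity_propagation <- function(dissim, preference = NULL, damping = 0.7,
                                 max_iter = 500L, stable_iters = 50L) {
  dissim <- as.matrix(dissim)
  n <- nrow(dissim)
  if (n != ncol(dissim)) abort_domain("dissimilarity matrix must be square")
  if (max(abs(dissim - t(dissim))) > 1e-8)
    abort_domain("dissimilarity matrix must be symmetric")
  if (damping < 0.5 || damping >= 1)
    abort_domain("`damping` must lie in [0.5, 1)")
  if (n == 1L)
    return(structure(list(labels = 1L, exemplars = 1L, n_iter = 0L,
                          converged = TRUE, preference = 0),
                     class = "ap_result"))
  s <- -dissim
  if (is.null(preference))
    preference <- stats::median(s[row(s) != col(s)])
  diag(s) <- preference

  r <- matrix(0, n, n)
  a <- matrix(0, n, n)
  last_ex <- integer(0)
  stable <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # responsibilities
    as_mat <- a + s
    max1_idx <- max.col(as_mat, ties.method = "first")
    max1 <- as_mat[cbind(seq_len(n), max1_idx)]
    as2 <- as_mat
    as2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- apply(as2, 1L, max)
    rep_max <- matrix(max1, n, n)
    rep_max[cbind(seq_len(n), max1_idx)] <- max2
    r <- damping * r + (1 - damping) * (s - rep_max)
    # availabilities
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    cs <- rep(colSums(rp), each = n)
    a_new <- matrix(cs, n, n) - rp
    d_a <- diag(a_new)
    a_new <- pmin(a_new, 0)
    diag(a_new) <- d_a
    a <- damping * a + (1 - damping) * a_new

    ex <- which(diag(a) + diag(r) > 0)
    if (identical(ex, last_ex) && length(ex) > 0L) {
      stable <- stable + 1L
      if (stable >= stable_iters) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
      last_ex <- ex
    }
  }
  ex <- which(diag(a) + diag(r) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(a) + diag(r))
  labels <- ex[max.col(s[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  # final exemplar refinement: within each cluster pick the member with the
  # highest total similarity to the cluster, then reassign
  for (pass in 1:2) {
    new_ex <- sort(unique(vapply(unique(labels), function(k) {
      members <- which(labels == k)
      members[which.max(colSums(s[members, members, drop = FALSE]))]
    }, integer(1))))
    labels <- new_ex[max.col(s[, new_ex, drop = FALSE], ties.method = "first")]
    labels[new_ex] <- new_ex
    ex <- new_ex
  }
  structure(list(labels = labels, exemplars = ex, n_iter = iter,
                 converged = converged, preference = preference),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("Affinity propagation: %d clusters, %d iterations (%s)\n",
              length(x$exemplars), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ap_result <- function(x, ...) {
  cl <- match(x$labels, x$exemplars)
  tibble::tibble(subject = seq_along(x$labels), cluster = cl,
                 exemplar = x$labels,
                 is_exemplar = seq_along(x$labels) %in% x$exemplars)
}

#' @exportS3Method generics::glance
glance.ap_result <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$exemplars), n_iter = x$n_iter,
                 converged = x$converged, preference = x$preference)
}

#' Read / write pattern profile CSV files
#'
#' One row per subject-region with columns `id` (optional for a single
#' subject), `region`, `normal`, `mild_laa`, `moderate_laa`, `severe_laa`,
#' `volume_weight`.
#'
#' @param path CSV path.
#' @return A named list of [pattern_profile()] objects (by `id`), or a single
#'   profile when no `id` column is present.
#' @export
read_pattern_profiles <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"id" %in% names(df)) return(pattern_profile(df))
  split(df, df$id) |>
    purrr::map(function(d) pattern_profile(dplyr::select(d, -"id")))
}
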