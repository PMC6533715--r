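# shared fixtures, all built in code

# triangle curve: linear rise to PEF = 8 L/s at 0.8 L, linear fall to 0 at 4.8 L
triangle_curve <- function(n = 61) {
  v <- seq(0, 4.8, length.out = n)
  q <- ifelse(v <= 0.8, 8 * v / 0.8, 8 * (4.8 - v) / 4)
  mefv_curve(tibble::tibble(volume_l = v, flow_l_s = q))
}

# curve from explicit shape parameters with fixed scale
param_curve <- function(theta_p, theta_d, u_star, w, noise_sd = 0,
                        seed = NULL, n_samples = 200L,
                        pef = 7, fvc = 3.5, rise_fraction = 0.05) {
  params <- structure(list(
    severity = NA_real_, theta_p = theta_p, theta_d = theta_d,
    u_star = u_star, w = w, pef_l_s = pef, fvc_l = fvc,
    rise_fraction = rise_fraction), class = "phenotype_params")
  generate_curve(params, noise_sd = noise_sd, n_samples = n_samples,
                 seed = seed)
}

# single-region profile from explicit ordered-class fractions
one_region_profile <- function(fr) {
  pattern_profile(tibble::tibble(
    region = "R1", normal = fr[1], mild_laa = fr[2],
    moderate_laa = fr[3], severe_laa = fr[4], volume_weight = 1))
}

random_profile <- function(seed) {
  withr::with_seed(seed, {
    fr <- matrix(stats::rexp(24), 6, 4)
    fr <- fr / rowSums(fr)
    pattern_profile(tibble::tibble(
      region = paste0("R", 1:6),
      normal = fr[, 1], mild_laa = fr[, 2],
      moderate_laa = fr[, 3], severe_laa = fr[, 4],
      volume_weight = rep(1 / 6, 6)))
  })
}

# independent ordinal-EMD oracle: quantile coupling on discretized atoms
emd_oracle <- function(p_fr, q_fr, atoms = 20000L) {
  pos_p <- rep(0:3, round(p_fr * atoms))
  pos_q <- rep(0:3, round(q_fr * atoms))
  m <- min(length(pos_p), length(pos_q))
  mean(abs(sort(pos_p)[seq_len(m)] - sort(pos_q)[seq_len(m)]))
}

# exhaustive k-medoid partition oracle for small dissimilarity matrices
medoid_oracle <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  best <- NULL
  best_cost <- Inf
  for (i in seq_len(ncol(combs))) {
    med <- combs[, i]
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best_cost) {
      best_cost <- cost
      best <- med
    }
  }
  assign <- best[apply(d[, best, drop = FALSE], 1, which.min)]
  list(medoids = best, labels = assign, cost = best_cost)
}

# one default-size cohort shared across test files (generated once per run)
.fixture_env <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(cohort_spec(seed = 1))
  .fixture_env$cohort
}
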