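#' Map a latent emphysema severity to curve phenotype parameters
#'
#' One latent severity s in \[0, 1\] drives every synthetic modality. The
#' curve-shape map is linear: theta_p = 1.8 - 1.5 s, theta_d = 1.8 + 1.6 s,
#' u_star = 0.6, w = 0.25 - 0.18 s. At s = 0 the limb is a pure scoop
#' (uniform exponent 1.8, no kink); at s = 1 it is flat at high volume
#' (theta_p = 0.3) and collapses abruptly below the transition
#' (theta_d = 3.4, w = 0.07). Absolute scale is drawn independently of shape:
#' PEF ~ logNormal(log 7, 0.15) L/s and FVC ~ logNormal(log 3.5, 0.15) L,
#' plausible adult COPD ranges that the shape-only score ignores by design.
#'
#' @param s Severity in \[0, 1\].
#' @param seed Optional integer seed for the PEF/FVC draws.
#' @param rise_fraction Fraction of FVC on the ascending limb (default 0.05).
#' @return A list of class `phenotype_params`: `severity`, `theta_p`,
#'   `theta_d`, `u_star`, `w`, `pef_l_s`, `fvc_l`, `rise_fraction`.
#' @export
severity_to_params <- function(s, seed = NULL, rise_fraction = 0.05) {
  if (!is_number(s) || s < 0 || s > 1)
    abort_domain("severity `s` must be a single value in [0, 1]")
  if (!is_number(rise_fraction) || rise_fraction <= 0 || rise_fraction > 0.2)
    abort_domain("`rise_fraction` must be in (0, 0.2]")
  draws <- with_seed_(seed, c(stats::rlnorm(1, log(7), 0.15),
                              stats::rlnorm(1, log(3.5), 0.15)))
  structure(list(
    severity = s,
    theta_p = 1.8 - 1.5 * s,
    theta_d = 1.8 + 1.6 * s,
    u_star = 0.6,
    w = 0.25 - 0.18 * s,
    pef_l_s = draws[1L],
    fvc_l = draws[2L],
    rise_fraction = rise_fraction
  ), class = "phenotype_params")
}

# the true ESI implied by a severity under the default score calibration
severity_to_esi <- function(s, delta_ref = 3.5) {
  10 * clamp(3.1 * s / delta_ref, 0, 1)
}

# inverse of severity_to_esi on its linear range, clamped into [0, 1]
esi_to_severity <- function(esi, delta_ref = 3.5) {
  clamp(esi * delta_ref / 31, 0, 1)
}

#' Generate a synthetic MEFV curve from phenotype parameters
#'
#' The forward model of the curve the score is designed to read: a linear
#' flow rise over `rise_fraction * FVC`, then the two-regime descending limb
#' Q = PEF * q(u) of [biomech_flow()] evaluated on the volume grid. Gaussian
#' flow noise with sd `noise_sd * PEF` is added and clipped below at zero;
#' the first, peak and final samples are left noise-free so the trace always
#' starts at zero flow, attains its nominal peak, and ends fully expired.
#'
#' @param params A `phenotype_params` from [severity_to_params()].
#' @param noise_sd Flow noise, as a fraction of PEF (default 0).
#' @param n_samples Number of samples (>= 30, default 200).
#' @param seed Optional integer seed.
#' @return An [mefv_curve()].
#' @export
generate_curve <- function(params, noise_sd = 0, n_samples = 200L,
                           seed = NULL) {
  if (!inherits(params, "phenotype_params"))
    abort_domain("`params` must come from severity_to_params()")
  if (!is_number(n_samples) || n_samples < 30)
    abort_domain("`n_samples` must be >= 30")
  if (!is_number(noise_sd) || noise_sd < 0)
    abort_domain("`noise_sd` must be a non-negative number")
  fvc <- params$fvc_l
  pef <- params$pef_l_s
  vp <- params$rise_fraction * fvc
  v <- sort(unique(c(seq(0, fvc, length.out = as.integer(n_samples) - 1L),
                     vp)))
  flow <- numeric(length(v))
  asc <- v <= vp
  flow[asc] <- pef * v[asc] / vp
  u <- (fvc - v[!asc]) / (fvc - vp)
  flow[!asc] <- pef * biomech_flow(u, params$theta_p, params$theta_d,
                                   params$u_star, params$w)
  if (noise_sd > 0) {
    eps <- with_seed_(seed, stats::rnorm(length(v), 0, noise_sd * pef))
    keep <- c(1L, which(v == vp)[1L], length(v))
    eps[keep] <- 0
    flow <- pmax(flow + eps, 0)
  }
  mefv_curve(tibble::tibble(volume_l = v, flow_l_s = flow))
}

#' Shift an MEFV curve onto the plethysmographic (thoracic) volume axis
#'
#' During forced expiration the alveolar pressure compresses the thoracic gas
#' (Boyle's law), so the thoracic volume signal runs ahead of the volume
#' expired at the mouth. The compressed volume at effort pressure p is
#' dV = TGV * p / (P_B + p) with barometric pressure P_B = 101.3 kPa; the
#' effort profile used is p(u) = palv * sin(pi * min(1, (1 - u)/0.6)), which
#' peaks over high-to-mid lung volumes and vanishes at both ends of the blow.
#' The expired-volume coordinate of each sample is reduced by dV(u) to recover
#' the thoracic-volume trace; flow is unchanged. The resulting curve descends
#' more steeply at high volumes — the flattening seen on the expired-volume
#' axis in severe emphysema is a gas-compression artefact that the thoracic
#' axis removes.
#'
#' @param curve An [mefv_curve()].
#' @param tgv_l Thoracic gas volume (L, > 0).
#' @param palv_kpa Peak alveolar effort pressure (kPa, >= 0); 0 returns the
#'   input unchanged.
#' @return An [mefv_curve()] on the plethysmographic volume axis.
#' @export
apply_gas_compression <- function(curve, tgv_l, palv_kpa) {
  if (!is_number(tgv_l) || tgv_l <= 0) abort_domain("`tgv_l` must be > 0")
  if (!is_number(palv_kpa) || palv_kpa < 0)
    abort_domain("`palv_kpa` must be >= 0")
  if (palv_kpa == 0) return(curve)
  p_b <- 101.3
  v <- curve$volume_l
  q <- curve$flow_l_s
  n <- length(v)
  peak <- which.max(q)
  fvc_v <- v[n]
  u <- rep(1, n)
  u[peak:n] <- (fvc_v - v[peak:n]) / (fvc_v - v[peak])
  p <- palv_kpa * sin(pi * pmin(1, (1 - u) / 0.6))
  dv <- tgv_l * p / (p_b + p)
  v2 <- v - dv
  # keep the volume axis monotone; extreme effort/TGV combinations could fold it
  if (any(diff(v2) < 0))
    abort_domain("compression shift folds the volume axis; reduce palv_kpa")
  mefv_curve(tibble::tibble(volume_l = v2, flow_l_s = q), validate = FALSE)
}

#' Cohort specification for the synthetic three-group study
#'
#' Defaults reproduce the three-group structure used throughout the package's
#' validation battery: group sizes 57/58/79 and per-group ESI score summaries
#' (mean, SD) of 1.1 (1.5), 3.1 (2.6), 6.8 (2.5) for no / moderate / severe
#' emphysema.
#'
#' @param n_ne,n_me,n_se Group sizes (>= 0).
#' @param esi_group_means,esi_group_sds Per-group target ESI Gaussians.
#' @param noise_sd Flow noise as fraction of PEF (default 0.02).
#' @param seed Integer seed (default 1).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ne = 57L, n_me = 58L, n_se = 79L,
                        esi_group_means = c(1.1, 3.1, 6.8),
                        esi_group_sds = c(1.5, 2.6, 2.5),
                        noise_sd = 0.02, seed = 1L) {
  if (any(c(n_ne, n_me, n_se) < 0)) abort_domain("group sizes must be >= 0")
  if (any(esi_group_sds <= 0)) abort_domain("group SDs must be > 0")
  structure(list(n_ne = as.integer(n_ne), n_me = as.integer(n_me),
                 n_se = as.integer(n_se),
                 esi_group_means = esi_group_means,
                 esi_group_sds = esi_group_sds,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# group-consistent %LAA-950insp ranges (NE < 6 <= ME < 14 <= SE)
laa_group_ranges <- list(NE = c(1, 5.5), ME = c(6.5, 13.5), SE = c(14.5, 35))

#' Generate a seeded synthetic COPD cohort
#'
#' For each group, target ESI scores are drawn from the group's Gaussian
#' (clipped to \[0, 10\]) and inverted through the score calibration to a
#' latent severity s; s then drives every modality: the MEFV curve via
#' [severity_to_params()] and [generate_curve()], CT target fractions
#' (%LAA-950insp drawn uniformly within the group's class-consistent range
#' and coupled monotonically to s by rank; %pLDA a severity-increasing share
#' of %LAA; %fLDA increasing in s; %LAA-856exp = %pLDA + %fLDA), and a
#' regional parenchymal pattern profile whose ordered-class weights shift
#' toward severe LAA with s (discretized Beta(1 + 4s, 5 - 4s)). Each record's
#' CT emphysema class is its group label by construction. Every curve is
#' scored with [score_curve()].
#'
#' @param spec A [cohort_spec()].
#' @param n_grid Limb resampling grid for scoring (default 100).
#' @return A tibble with one row per subject: `id`, `group` (factor NE/ME/SE),
#'   `severity`, `esi_true`, `esi_fit`, `single_phase`, `fev1`, `fvc`,
#'   `fev1_fvc`, `pef`, `laa950_insp`, `laa856_exp`, `plda`, `flda`, and
#'   list-columns `curve` ([mefv_curve()]) and `profile`
#'   ([pattern_profile()]).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_ne = 10, n_me = 10, n_se = 10))
#' cor(cohort$severity, cohort$esi_fit, method = "spearman")
#' }
#' @export
generate_cohort <- function(spec = cohort_spec(), n_grid = 100L) {
  if (!inherits(spec, "cohort_spec")) abort_domain("`spec` must be a cohort_spec")
  groups <- c("NE", "ME", "SE")
  sizes <- c(spec$n_ne, spec$n_me, spec$n_se)
  with_seed_(spec$seed, {
    recs <- purrr::pmap(
      list(groups, sizes, spec$esi_group_means, spec$esi_group_sds),
      function(g, n, mu, sigma) {
        if (n == 0L) return(NULL)
        esi_target <- clamp(stats::rnorm(n, mu, sigma), 0, 10)
        s <- esi_to_severity(esi_target)
        rng <- laa_group_ranges[[g]]
        laa <- sort(stats::runif(n, rng[1L], rng[2L]))[rank(s,
                                                            ties.method = "first")]
        plda <- laa * (0.70 + 0.20 * s)
        flda <- clamp(18 + 30 * s + stats::rnorm(n, 0, 3), 2, 95 - plda)
        tibble::tibble(group = g, severity = s, laa950_insp = laa,
                       plda = plda, flda = flda,
                       laa856_exp = plda + flda)
      })
    cohort <- dplyr::bind_rows(recs)
    n_tot <- nrow(cohort)
    cohort$id <- sprintf("S%03d", seq_len(n_tot))
    cohort$esi_true <- severity_to_esi(cohort$severity)
    curve_seeds <- sample.int(.Machine$integer.max, n_tot)
    prof_seeds <- sample.int(.Machine$integer.max, n_tot)
    cohort$curve <- purrr::map(seq_len(n_tot), function(i) {
      params <- severity_to_params(cohort$severity[i], seed = curve_seeds[i])
      generate_curve(params, noise_sd = spec$noise_sd, seed = curve_seeds[i])
    })
    cohort$profile <- purrr::map(seq_len(n_tot), function(i) {
      severity_profile(cohort$severity[i], seed = prof_seeds[i])
    })
    scored <- purrr::map(cohort$curve, score_curve, n_grid = n_grid)
    cohort$esi_fit <- purrr::map_dbl(scored, "esi")
    cohort$single_phase <- purrr::map_lgl(scored, ~ .x$fit$single_phase)
    spiro <- dplyr::bind_rows(purrr::map(scored, "spirometry"))
    cohort$fev1 <- spiro$fev1
    cohort$fvc <- spiro$fvc
    cohort$fev1_fvc <- spiro$fev1_fvc_ratio
    cohort$pef <- spiro$pef
    cohort$group <- factor(cohort$group, levels = groups)
    dplyr::select(cohort, "id", "group", "severity", "esi_true", "esi_fit",
                  "single_phase", "fev1", "fvc", "fev1_fvc", "pef",
                  "laa950_insp", "laa856_exp", "plda", "flda",
                  "curve", "profile")
  })
}

# regional ordered-class profile implied by a severity (used by the cohort)
severity_profile <- function(s, seed = NULL) {
  with_seed_(seed, {
    regions <- c("L_upper", "L_middle", "L_lower",
                 "R_upper", "R_middle", "R_lower")
    s_r <- clamp(s + stats::rnorm(6, 0, 0.05), 0, 1)
    w <- stats::runif(6, 0.8, 1.2)
    w <- w / sum(w)
    breaks <- c(0, 0.25, 0.5, 0.75, 1)
    fr <- t(vapply(s_r, function(si) {
      a <- 1 + 4 * si
      b <- 5 - 4 * si
      diff(stats::pbeta(breaks, a, b))
    }, numeric(4)))
    pattern_profile(tibble::tibble(
      region = regions,
      normal = fr[, 1L], mild_laa = fr[, 2L],
      moderate_laa = fr[, 3L], severe_laa = fr[, 4L],
      volume_weight = w))
  })
}

#' Write a cohort table to CSV
#'
#' Writes the scalar columns of a [generate_cohort()] tibble (list-columns
#' are dropped); optionally writes each subject's curve and profile as CSV
#' files under `dir`.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path for the table.
#' @param curve_dir,profile_dir Optional directories for per-subject files.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, curve_dir = NULL, profile_dir = NULL) {
  tab <- dplyr::select(cohort, -dplyr::any_of(c("curve", "profile")))
  readr::write_csv(tab, path)
  if (!is.null(curve_dir)) {
    dir.create(curve_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk2(cohort$curve, cohort$id, function(cv, id)
      write_mefv_curve(cv, file.path(curve_dir, paste0(id, ".csv"))))
  }
  if (!is.null(profile_dir)) {
    dir.create(profile_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk2(cohort$profile, cohort$id, function(pr, id)
      readr::write_csv(tibble::as_tibble(unclass(pr)),
                       file.path(profile_dir, paste0(id, ".csv"))))
  }
  invisible(path)
}

#' Simulate per-group ESI scores from summary Gaussians
#'
#' Draws one synthetic score per subject from untruncated group Gaussians —
#' the sampling model used to benchmark the score's classification
#' performance from published group summaries alone (no curves involved).
#'
#' @param n Integer vector of group sizes.
#' @param means,sds Group means and standard deviations (same length as `n`).
#' @param labels Optional group labels (default `G1..Gk`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `esi` and `group` (factor in the order
#'   given).
#' @export
simulate_group_scores <- function(n, means, sds, labels = NULL, seed = NULL) {
  k <- length(n)
  if (length(means) != k || length(sds) != k)
    abort_domain("`n`, `means`, `sds` must have equal length")
  if (any(sds <= 0)) abort_domain("`sds` must be positive")
  if (is.null(labels)) labels <- paste0("G", seq_len(k))
  esi <- with_seed_(seed,
    unlist(purrr::pmap(list(n, means, sds), function(ni, mu, sigma)
      stats::rnorm(ni, mu, sigma))))
  tibble::tibble(esi = esi,
                 group = factor(rep(labels, times = n), levels = labels))
}
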