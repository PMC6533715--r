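test_that("descending limb: identity for triangles, boundary cases, analytics", {
  # linear descent maps to q(u) = u
  limb <- extract_descending_limb(triangle_curve())
  expect_lt(max(abs(limb$q - limb$u)), 1e-9)
  expect_equal(limb$q[1], 1, tolerance = 1e-9)
  expect_lte(limb$q[nrow(limb)], 0.05)
  expect_true(all(diff(limb$u) < 0))

  # flow maximum at the first sample: limb covers the whole curve
  v <- seq(0, 3, length.out = 40)
  first_peak <- mefv_curve(tibble::tibble(
    volume_l = v, flow_l_s = 6 * (1 - v / 3)^1.5), validate = FALSE)
  lb <- extract_descending_limb(first_peak)
  expect_equal(range(lb$u), c(0, 1))

  # flow maximum at the last sample: no descending limb
  rising <- mefv_curve(tibble::tibble(volume_l = v,
                                      flow_l_s = seq(0.1, 5, length.out = 40)),
                       validate = FALSE)
  expect_error(extract_descending_limb(rising),
               class = "esitools_degenerate_curve")

  # sampled generator curve matches the analytic shape on the grid
  curve <- param_curve(0.3, 3.0, 0.6, 0.05, n_samples = 400)
  lb2 <- extract_descending_limb(curve, n_grid = 100)
  expect_lt(max(abs(lb2$q - biomech_flow(lb2$u, 0.3, 3.0, 0.6, 0.05))), 1e-3)
})

test_that("noise-free fits recover generating parameters within 5%", {
  curve <- param_curve(0.3, 3.0, 0.6, 0.05, n_samples = 400)
  fit <- fit_biomech_model(extract_descending_limb(curve))
  expect_false(fit$single_phase)
  expect_lt(abs(fit$theta_p - 0.3) / 0.3, 0.05)
  expect_lt(abs(fit$theta_d - 3.0) / 3.0, 0.05)
  expect_lt(abs(fit$u_star - 0.6) / 0.6, 0.05)
  expect_lt(abs(fit$w - 0.05) / 0.05, 0.05)

  # identity limb collapses to the single-phase model with unit exponent
  fit1 <- fit_biomech_model(extract_descending_limb(triangle_curve()))
  expect_true(fit1$single_phase)
  expect_equal(fit1$theta_p, 1, tolerance = 1e-3)
  expect_equal(fit1$theta_p, fit1$theta_d)
  expect_true(is.na(fit1$u_star) && is.na(fit1$w))
})

test_that("noisy fits keep median exponent errors within 0.15", {
  errs <- vapply(1:100, function(i) {
    curve <- param_curve(0.3, 3.0, 0.6, 0.05, noise_sd = 0.02, seed = i)
    fit <- fit_biomech_model(extract_descending_limb(curve))
    c(abs(fit$theta_p - 0.3), abs(fit$theta_d - 3.0))
  }, numeric(2))
  expect_lte(stats::median(errs[1, ]), 0.15)
  expect_lte(stats::median(errs[2, ]), 0.15)
})

test_that("score mapping: zero for single phase, linear contrast, clamped", {
  single <- structure(list(theta_p = 1, theta_d = 1, single_phase = TRUE),
                      class = "biomech_fit")
  expect_identical(compute_esi(single), 0)

  two <- structure(list(theta_p = 0.3, theta_d = 3.0, single_phase = FALSE),
                   class = "biomech_fit")
  expect_equal(compute_esi(two), 10 * 2.7 / 3.5, tolerance = 1e-12)

  sat <- structure(list(theta_p = 0.0, theta_d = 4.0, single_phase = FALSE),
                   class = "biomech_fit")
  expect_identical(compute_esi(sat), 10)
})

test_that("score separates archetypes and ignores axis scales", {
  severe <- generate_curve(severity_to_params(0.85, seed = 1), noise_sd = 0,
                           seed = 1)
  mild <- generate_curve(severity_to_params(0.05, seed = 2), noise_sd = 0,
                         seed = 2)
  expect_gt(score_curve(severe)$esi, 5)
  expect_lt(score_curve(mild)$esi, 5)

  # Q -> 2Q, V -> 0.5V leaves the score untouched
  rescaled <- mefv_curve(tibble::tibble(volume_l = 0.5 * severe$volume_l,
                                        flow_l_s = 2 * severe$flow_l_s))
  expect_lt(abs(score_curve(rescaled)$esi - score_curve(severe)$esi), 1e-6)

  # general affine volume change and flow scaling; rounding in the rescaled
  # samples perturbs the interpolated limb at the last ulp, so the bound is
  # looser than for the exactly representable halving/doubling above
  shifted <- mefv_curve(tibble::tibble(volume_l = 1.7 * severe$volume_l,
                                       flow_l_s = 0.3 * severe$flow_l_s))
  expect_lt(abs(score_curve(shifted)$esi - score_curve(severe)$esi), 1e-4)
})

test_that("score stays in [0, 10] on fuzzed monotone-descending limbs", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(60:150, 1)
      v <- sort(runif(n, 0, 5))
      v <- c(0, v - min(v))[1:n]
      pef <- runif(1, 3, 10)
      # random monotone descending flow after a short rise
      drop <- sort(runif(n - 5, 0, 1), decreasing = TRUE)
      q <- c(seq(0, pef, length.out = 5), pef * drop * 0.96)[1:n]
      q[n] <- 0
      curve <- mefv_curve(tibble::tibble(volume_l = v, flow_l_s = q),
                          validate = FALSE)
      esi <- score_curve(curve)$esi
      expect_gte(esi, 0)
      expect_lte(esi, 10)
    }
  })
})

test_that("score is monotone in the distal and anti-monotone in the proximal exponent", {
  grid_tp <- seq(0.1, 3, length.out = 7)
  grid_td <- seq(0.1, 4.5, length.out = 7)
  for (tp in grid_tp) {
    esis <- vapply(grid_td, function(td) compute_esi(
      structure(list(theta_p = tp, theta_d = td, single_phase = FALSE),
                class = "biomech_fit")), numeric(1))
    expect_true(all(diff(esis) >= 0))
  }
  for (td in grid_td) {
    esis <- vapply(grid_tp, function(tp) compute_esi(
      structure(list(theta_p = tp, theta_d = td, single_phase = FALSE),
                class = "biomech_fit")), numeric(1))
    expect_true(all(diff(esis) <= 0))
  }
})

test_that("scoring is deterministic and the JSON report carries all keys", {
  curve <- generate_curve(severity_to_params(0.5, seed = 9), noise_sd = 0.02,
                          seed = 9)
  r1 <- score_curve(curve)
  r2 <- score_curve(curve)
  expect_identical(r1, r2)

  path <- file.path(withr::local_tempdir(), "report.json")
  write_esi_report(r1, path)
  rep <- jsonlite::read_json(path)
  expect_true(all(c("esi", "theta_p", "theta_d", "u_star", "w", "sse",
                    "single_phase", "fev1", "fvc", "pef") %in% names(rep)))
  expect_equal(rep$esi, r1$esi, tolerance = 1e-12)
})

test_that("tidiers summarise fits as tibbles", {
  res <- score_curve(triangle_curve())
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("theta_p", "theta_d") %in% td$term))
  gl <- generics::glance(res)
  expect_named(gl, c("esi", "sse", "single_phase", "sse_single", "n_points",
                     "converged", "fev1", "fvc", "pef", "fev1_fvc_ratio"))
})
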