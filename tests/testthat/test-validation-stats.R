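test_that("pearson_r: collinear cases, checks, Monte-Carlo calibration", {
  x <- seq_len(50)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 50)), class = "esitools_domain_error")
  expect_error(pearson_r(1:2, 1:2), class = "esitools_domain_error")

  withr::with_seed(13, {
    n <- 1e4
    z <- rnorm(n)
    y <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
    expect_equal(pearson_r(z, y), 0.8, tolerance = 0.025)
  })
})

test_that("Steiger's Z: null identity, published inputs, degenerate matrix", {
  res <- steiger_z(0.5, 0.5, 0.2, 100)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  # correlations of a CT emphysema metric with the score vs with FEV1
  res2 <- steiger_z(0.81, -0.50, -0.74, 194)
  expect_lt(res2$p, 0.001)
  expect_gt(res2$z, 0)

  expect_error(steiger_z(0.9, -0.9, 0.9, 100),
               class = "esitools_domain_error")
  expect_error(steiger_z(1, 0.5, 0.2, 100), class = "esitools_domain_error")
})

test_that("Steiger's Z holds its nominal type-I error under the null", {
  # null: r_jk = r_jh by construction of the population covariance
  sigma <- matrix(c(1, 0.5, 0.5,
                    0.5, 1, 0.3,
                    0.5, 0.3, 1), 3, 3)
  ch <- chol(sigma)
  rejections <- withr::with_seed(29, {
    vapply(seq_len(2000), function(b) {
      x <- matrix(rnorm(200 * 3), 200, 3) %*% ch
      r <- stats::cor(x)
      steiger_z(r[1, 2], r[1, 3], r[2, 3], 200)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("bootstrap correlation comparison agrees in direction with the Z test", {
  withr::with_seed(41, {
    n <- 150
    j <- rnorm(n)
    k <- 0.8 * j + 0.6 * rnorm(n)
    h <- 0.2 * j + 0.98 * rnorm(n)
    bt <- steiger_z_boot(j, k, h, n_boot = 500, seed = 2)
    zt <- steiger_z(cor(j, k), cor(j, h), cor(k, h), n)
    expect_gt(bt$diff, 0)
    expect_lt(bt$p, 0.05)
    expect_lt(zt$p, 0.05)
  })
})

test_that("Welch ANOVA: degenerate equality, printed summaries, cross-check", {
  eq <- welch_anova(data.frame(mean = c(2, 2), sd = c(1, 1), n = c(20, 20)))
  expect_equal(eq$f_star, 0)
  expect_equal(eq$p, 1)

  # the three-group score summaries separate decisively
  tab4 <- welch_anova(data.frame(mean = c(1.1, 3.1, 6.8),
                                 sd = c(1.5, 2.6, 2.5),
                                 n = c(57, 58, 79)))
  expect_lt(tab4$p, 0.001)

  # agreement with stats::oneway.test on raw data
  withr::with_seed(55, {
    for (rep in 1:100) {
      g <- lapply(1:3, function(i) rnorm(sample(5:30, 1), mean = runif(1, 0, 3),
                                         sd = runif(1, 0.5, 2)))
      mine <- welch_anova(g)
      ref <- stats::oneway.test(y ~ f,
                                data = data.frame(y = unlist(g),
                                                  f = factor(rep(seq_along(g),
                                                                 lengths(g)))),
                                var.equal = FALSE)
      expect_equal(mine$f_star, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(mine$df2, unname(ref$parameter[2]), tolerance = 1e-8)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Welch ANOVA holds its nominal type-I error under the null", {
  rejections <- withr::with_seed(77, {
    vapply(seq_len(2000), function(b) {
      g <- lapply(c(15, 25, 40), function(n) rnorm(n, 0, runif(1, 0.5, 2)))
      welch_anova(g)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("Games-Howell matches an independent reference and behaves", {
  # frozen oracle: pingouin 0.6.1 pairwise_gameshowell on this exact data
  g <- list(a = c(2.9, 3.8, 2.5, 4.5, 3.1, 3.9, 2.7, 3.4),
            b = c(4.1, 5.2, 4.8, 5.9, 4.4, 5.1, 4.7),
            c = c(6.3, 7.1, 6.8, 7.9, 6.1, 7.4, 6.6, 7.2, 6.9))
  gh <- games_howell(g)
  expect_equal(gh$mean_diff, c(-1.5357143, -3.5722222, -2.0365079),
               tolerance = 1e-6)
  expect_equal(gh$df, c(12.999847, 13.591829, 12.670215), tolerance = 1e-4)
  oracle_p <- c(1.139394e-03, 4.723598e-08, 2.803711e-05)
  expect_true(all(abs(gh$p - oracle_p) < 1e-4))
  expect_true(all(abs(log10(gh$p) - log10(oracle_p)) < 0.05))

  # identical groups: all p = 1
  same <- games_howell(list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4)))
  expect_equal(same$p, 1, tolerance = 1e-6)

  # p decreases monotonically as the mean separation grows
  ps <- vapply(c(0.5, 1, 2, 4), function(delta)
    games_howell(data.frame(mean = c(0, delta), sd = c(1, 1),
                            n = c(20, 20)))$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("logistic fit: symmetry, score equations, monotonicity, separation", {
  x <- rep(c(-1, 1), each = 50)
  y <- rep(c(0, 1, 0, 1), c(15, 35, 35, 15))  # symmetric design
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$intercept), 1e-6)

  # maximum likelihood: score equations vanish at the estimate
  withr::with_seed(91, {
    x2 <- rnorm(200)
    y2 <- rbinom(200, 1, plogis(-0.5 + 1.2 * x2))
    f2 <- fit_logistic(x2, y2)
    p_hat <- plogis(f2$intercept + f2$slope * x2)
    expect_lt(abs(sum(y2 - p_hat)), 1e-6)
    expect_lt(abs(sum((y2 - p_hat) * x2)), 1e-6)
  })

  # monotone predictions with positive slope
  expect_true(all(diff(predict(fit, seq(-3, 3, by = 0.5))) > 0) == (fit$slope > 0))

  sep <- fit_logistic(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separation)
  expect_true(all(diff(predict(sep, 1:12)) >= 0))

  expect_error(fit_logistic(1:5, rep(1, 5)), class = "esitools_domain_error")
})

test_that("cross-validated ROC: separation, rank identity, null calibration", {
  withr::with_seed(101, {
    x <- c(rnorm(50, 0), rnorm(50, 10))
    y <- rep(c(0, 1), each = 50)
    roc <- cv_roc(x, y, k_folds = 10, seed = 1)
    expect_equal(roc$auc, 1)
    expect_equal(roc$fold_aucs, rep(1, 10))

    # pooled AUC equals the Mann-Whitney statistic on held-out scores
    x2 <- c(rnorm(60, 0, 1), rnorm(60, 1, 1))
    y2 <- rep(c(0, 1), each = 60)
    roc2 <- cv_roc(x2, y2, k_folds = 10, seed = 2)
    pr <- roc2$predictions
    pos <- pr$prob[pr$y == 1]
    neg <- pr$prob[pr$y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc2$auc, mean(cmp), tolerance = 1e-9)

    expect_error(cv_roc(rnorm(20), rep(c(0, 1), c(15, 5)), k_folds = 10),
                 class = "esitools_domain_error")
  })

  # permuted labels: mean AUC centred on 0.5 (held-out CV carries a small
  # pessimistic bias that shrinks with n; 200 subjects keeps it within band)
  aucs <- withr::with_seed(111, {
    vapply(seq_len(500), function(b) {
      x <- rnorm(200)
      y <- sample(rep(c(0, 1), each = 100))
      cv_roc(x, y, k_folds = 10, seed = b)$auc
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("fold assignment is stratified and seed-stable", {
  x <- rnorm(80)
  y <- rep(c(0, 1), c(30, 50))
  r1 <- cv_roc(x, y, k_folds = 10, seed = 5)
  r2 <- cv_roc(x, y, k_folds = 10, seed = 5)
  expect_identical(r1$predictions, r2$predictions)
  folds <- r1$predictions$fold
  expect_true(all(table(folds, y)[, "1"] == 5))
  expect_true(all(table(folds, y)[, "0"] == 3))
})

test_that("ROC agrees with an independent implementation on pooled scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(121, {
    x <- c(rnorm(70, 0, 1), rnorm(50, 1.2, 1))
    y <- rep(c(0, 1), c(70, 50))
    roc <- cv_roc(x, y, k_folds = 10, seed = 3)
    ref <- pROC::auc(pROC::roc(roc$predictions$y, roc$predictions$prob,
                               quiet = TRUE))
    expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-9)
  })
})

test_that("best operating point maximizes Youden's J with spec-favouring ties", {
  roc_tbl <- tibble::tibble(
    threshold = c(Inf, 0.9, 0.7, 0.5, 0.3, 0.1),
    sensitivity = c(0, 0.4, 0.72, 0.8, 0.9, 1),
    specificity = c(1, 0.95, 0.85, 0.75, 0.5, 0))
  bt <- best_threshold(roc_tbl)
  j <- roc_tbl$sensitivity + roc_tbl$specificity - 1
  expect_equal(bt$youden_j, max(j))
  expect_equal(bt$threshold, roc_tbl$threshold[which.max(j)])

  # tie broken toward higher specificity
  tie <- tibble::tibble(threshold = c(0.6, 0.4),
                        sensitivity = c(0.6, 0.8),
                        specificity = c(0.9, 0.7))
  expect_equal(best_threshold(tie)$specificity, 0.9)

  withr::with_seed(131, {
    x <- c(rnorm(40), rnorm(40, 1))
    y <- rep(c(0, 1), each = 40)
    roc <- cv_roc(x, y, seed = 4)
    bt2 <- best_threshold(roc)
    expect_gte(bt2$threshold, 0)
    expect_lte(bt2$threshold, 1)
  })
})

test_that("chi-squared: closed forms and manual-formula cross-check", {
  d <- chi_squared(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(d$statistic, 20)
  expect_equal(d$df, 1)

  ind <- chi_squared(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p, 1)

  withr::with_seed(141, {
    for (rep in 1:20) {
      tab <- matrix(rpois(9, 20) + 1, 3, 3)
      mine <- chi_squared(tab)
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- sum((tab - e)^2 / e)
      expect_equal(mine$statistic, stat, tolerance = 1e-8)
      expect_equal(mine$p, stats::pchisq(stat, 4, lower.tail = FALSE),
                   tolerance = 1e-8)
    }
  })

  expect_error(chi_squared(matrix(c(0, 0, 3, 4), 2, 2)),
               class = "esitools_domain_error")
})
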