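test_that("ratio estimate and delta-method SE follow the closed form", {
  r <- mr_ratio(0.2, 0.01, 0.03, 0.01)
  expect_equal(r$estimate, 0.15)
  r0 <- mr_ratio(0.2, 0.01, 0, 0.01)
  expect_equal(r0$estimate, 0)
  r_se <- mr_ratio(0.1, 0.01, 0.02, 0.01)
  expect_equal(r_se$se, 0.1) # |sy / bx|
  r2nd <- mr_ratio(0.1, 0.01, 0.02, 0.01, order = 2)
  expect_equal(r2nd$se, sqrt(0.01^2 / 0.1^2 + 0.02^2 * 0.01^2 / 0.1^4))
  expect_error(mr_ratio(0, 0.01, 0.1, 0.01), "undefined")
})

test_that("IVW reproduces the hand-arithmetic closed form", {
  h <- make_harmonized(bx = c(0.1, 0.2), sx = 0.01,
                       by = c(0.015, 0.030), sy = 0.01)
  fit <- mr_ivw(h, mode = "fixed")
  expect_equal(fit$estimate, 0.0075 / 0.05, tolerance = 1e-12)
  expect_equal(fit$se, sqrt(1 / 500), tolerance = 1e-12)
  # exact fit: Q = 0, fixed and random SEs coincide
  expect_equal(fit$q_stat, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(h)$se, fit$se)
  # all-null outcome
  h0 <- make_harmonized(bx = c(0.1, 0.2), sx = 0.01, by = 0, sy = 0.01)
  expect_equal(mr_ivw(h0)$estimate, 0)
})

test_that("IVW with two variants equals the weight-averaged ratio closed form", {
  h <- make_harmonized(bx = c(0.12, 0.3), sx = 0.01,
                       by = c(0.02, 0.07), sy = c(0.011, 0.02))
  theta_j <- h$beta_outcome / h$beta_exposure
  w_j <- h$beta_exposure^2 / h$se_outcome^2
  expect_equal(mr_ivw(h, mode = "fixed")$estimate,
               sum(w_j * theta_j) / sum(w_j), tolerance = 1e-12)
})

test_that("single-variant IVW falls back to the ratio with a warning", {
  h <- make_harmonized(0.1, 0.01, 0.02, 0.01)
  expect_warning(fit <- mr_ivw(h), "ratio")
  expect_equal(fit$estimate, 0.2)
})

test_that("Egger recovers an exact affine relation and its orientation invariance", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- make_harmonized(bx, 0.005, 0.02 + 0.1 * bx, 0.01)
  fit <- mr_egger(h)
  expect_equal(fit$estimate[fit$method == "egger"], 0.1, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$method == "egger_intercept"], 0.02,
               tolerance = 1e-10)
  # negating one variant's pair is undone by the orientation step
  h2 <- h
  h2$beta_exposure[2] <- -h2$beta_exposure[2]
  h2$beta_outcome[2] <- -h2$beta_outcome[2]
  fit2 <- mr_egger(h2)
  expect_equal(fit2$estimate, fit$estimate, tolerance = 1e-12)
  expect_equal(fit2$se, fit$se, tolerance = 1e-12)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("weighted median interpolation matches the hand-evaluated rule", {
  # equal weights, ratios {0.1, 0.2, 0.9}: cumulative centered weights hit
  # 0.5 exactly at the middle ratio
  h <- make_harmonized(bx = c(0.1, 0.1, 0.1), sx = 0.001,
                       by = c(0.01, 0.02, 0.09), sy = 0.01)
  fit <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(fit$estimate, 0.2, tolerance = 1e-12)
  # degenerate: identical ratios give that ratio with a tiny bootstrap se
  hc <- make_harmonized(bx = c(0.1, 0.2, 0.4), sx = 1e-6,
                        by = c(0.015, 0.030, 0.060), sy = 1e-6)
  fitc <- mr_weighted_median(hc, n_boot = 100, seed = 2)
  expect_equal(fitc$estimate, 0.15, tolerance = 1e-4)
  expect_lt(fitc$se, 1e-3)
})

test_that("weighted median bootstrap is reproducible under a seed", {
  h <- make_harmonized(bx = runif(6, 0.05, 0.2), sx = 0.01,
                       by = rnorm(6, 0.02, 0.005), sy = 0.01)
  f1 <- mr_weighted_median(h, n_boot = 200, seed = 99)
  f2 <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(f1$se, f2$se)
})

test_that("weighted mode finds the dominant cluster and smooths toward the center", {
  h <- make_harmonized(bx = rep(0.1, 7), sx = 0.002,
                       by = c(rep(0.015, 5), 0.09, 0.091), sy = 0.004)
  fit <- mr_weighted_mode(h, n_boot = 50, seed = 3)
  expect_equal(fit$estimate, 0.15, tolerance = 0.02)
  # zero-noise single cluster is returned exactly
  hc <- make_harmonized(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                        by = c(0.015, 0.030, 0.060), sy = 0.01)
  expect_equal(mr_weighted_mode(hc, n_boot = 10, seed = 1)$estimate, 0.15)
  # enormous bandwidth behaves like a central-value estimator
  fit_wide <- mr_weighted_mode(h, phi = 100, n_boot = 10, seed = 1)
  med <- mr_weighted_median(h, n_boot = 10, seed = 1)
  expect_lt(abs(fit_wide$estimate - med$estimate), 0.25)
})

test_that("maximum likelihood matches IVW in the exact-sx limit and exact fit", {
  h <- make_harmonized(bx = c(0.1, 0.2, 0.35), sx = 1e-8,
                       by = c(0.021, 0.039, 0.071), sy = 0.01)
  ml <- mr_max_likelihood(h)
  ivw <- mr_ivw(h, mode = "fixed")
  expect_equal(ml$estimate, ivw$estimate, tolerance = 1e-6)
  expect_equal(ml$se, ivw$se, tolerance = 1e-4)
  # exact-fit data recovers theta exactly
  hexact <- make_harmonized(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                            by = c(0.015, 0.030, 0.045), sy = 0.01)
  expect_equal(mr_max_likelihood(hexact)$estimate, 0.15, tolerance = 1e-8)
})

test_that("maximum likelihood is approximately unbiased on simulated data", {
  set.seed(17)
  ests <- replicate(60, {
    k <- 50
    gamma <- runif(k, 0.03, 0.1)
    sx <- rep(0.005, k)
    sy <- rep(0.005, k)
    h <- make_harmonized(rnorm(k, gamma, sx), sx,
                         rnorm(k, 0.15 * gamma, sy), sy)
    mr_max_likelihood(h)$estimate
  })
  expect_lt(abs(mean(ests) - 0.15), 3 * sd(ests) / sqrt(length(ests)) + 0.005)
})

test_that("MVMR reduces to univariable IVW and honors orthogonality", {
  set.seed(5)
  k <- 12
  bx1 <- runif(k, 0.05, 0.2)
  sy <- rep(0.01, k)
  by <- 0.15 * bx1 + rnorm(k, 0, 0.01)
  d <- tibble::tibble(beta_x1 = bx1, beta_x2 = 0, beta_outcome = by,
                      se_outcome = sy)
  expect_warning(fit <- mr_mvmr(d, c("beta_x1", "beta_x2")), "All-zero")
  h <- make_harmonized(bx1, 0.001, by, sy)
  expect_equal(fit$estimate[fit$exposure == "beta_x1"],
               mr_ivw(h, mode = "fixed")$estimate, tolerance = 1e-12)
  expect_true(is.na(fit$estimate[fit$exposure == "beta_x2"]))

  # orthogonal exposure vectors (equal weights): adjusted = univariable
  bxa <- c(rep(0.2, 6), rep(0, 6))
  bxb <- c(rep(0, 6), rep(0.3, 6))
  by2 <- 0.1 * bxa + 0.4 * bxb
  d2 <- tibble::tibble(beta_a = bxa, beta_b = bxb,
                       beta_outcome = by2, se_outcome = 0.01)
  fit2 <- mr_mvmr(d2, c("beta_a", "beta_b"))
  expect_equal(fit2$estimate, c(0.1, 0.4), tolerance = 1e-10)

  # duplicated exposure column is a collinearity error naming the column
  d3 <- tibble::tibble(beta_a = bxa, beta_dup = bxa,
                       beta_outcome = by2, se_outcome = 0.01)
  expect_error(mr_mvmr(d3, c("beta_a", "beta_dup")), "beta_dup")
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(23)
  k <- 15
  h <- make_harmonized(runif(k, 0.05, 0.2), 0.005,
                       rnorm(k, 0.02, 0.01), 0.01)
  fits <- function(d) {
    c(
      ivw = mr_ivw(d)$estimate,
      egger = mr_egger(d)$estimate[1],
      wm = mr_weighted_median(d, n_boot = 10, seed = 1)$estimate,
      ml = mr_max_likelihood(d)$estimate
    )
  }
  base <- fits(h)
  # scaling all exposure betas by c rescales every estimate by 1/c
  h_scaled <- dplyr::mutate(h, beta_exposure = 2 * .data$beta_exposure,
                            se_exposure = 2 * .data$se_exposure)
  expect_equal(fits(h_scaled), base / 2, tolerance = 1e-6)
  # negating all outcome betas negates every estimate
  h_neg <- dplyr::mutate(h, beta_outcome = -.data$beta_outcome)
  expect_equal(fits(h_neg), -base, tolerance = 1e-6)
})

test_that("weighted median stays consistent below 50% invalid weight where IVW breaks", {
  set.seed(41)
  reps <- 60
  wm_est <- numeric(reps)
  ivw_est <- numeric(reps)
  for (r in seq_len(reps)) {
    k <- 30
    invalid <- seq_len(9) # 30% by count and (equal weights) by weight
    gamma <- runif(k, 0.08, 0.12)
    alpha <- numeric(k)
    alpha[invalid] <- 0.05
    sx <- rep(0.002, k)
    sy <- rep(0.002, k)
    h <- make_harmonized(rnorm(k, gamma, sx), sx,
                         rnorm(k, 0.15 * gamma + alpha, sy), sy)
    wm_est[r] <- mr_weighted_median(h, n_boot = 10, seed = r)$estimate
    ivw_est[r] <- mr_ivw(h)$estimate
  }
  expect_lt(abs(mean(wm_est) - 0.15), 0.02)
  expect_gt(abs(mean(ivw_est) - 0.15), 0.05)
})

test_that("binary outcomes are reported as odds ratios alongside log-odds", {
  h <- make_harmonized(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                       by = c(0.015, 0.030, 0.045), sy = 0.01)
  out <- mr_all(h, methods = c("ivw", "egger"), outcome_type = "binary",
                n_boot = 10, seed = 1)
  ivw <- out[out$method == "ivw_mre", ]
  expect_equal(ivw$or, exp(ivw$estimate))
  expect_equal(ivw$or_ci_lower, exp(ivw$ci_lower))
  expect_true(is.na(out$or[out$method == "egger_intercept"]))
})
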