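test_that("Wald ratio and its delta-method SE are exact", {
  wr <- wald_ratio(0.1, 0.05, 0.01)
  expect_equal(wr$theta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(0.1, 0, 0.01)$theta, 0)
  wr2 <- wald_ratio(-0.2, 0.05, 0.02)
  expect_equal(wr2$theta, -0.25)
  expect_equal(wr2$se, 0.1)
  expect_error(wald_ratio(0, 0.05, 0.01), "degenerate")
})

test_that("IVW reduces to the Wald ratio and to symmetric means in degenerate cases", {
  # identical ratios with equal weights: the common value
  h <- hset_theta_w(theta = c(0.37, 0.37), w = c(2, 2))
  expect_equal(mr_ivw(h)$beta, 0.37)
  # equal weights: the arithmetic mean
  h2 <- hset_theta_w(theta = c(0.2, 0.4), w = c(1, 1))
  expect_equal(mr_ivw(h2)$beta, 0.3)
  expect_error(mr_ivw(hset_theta_w(0.1, 1)), "at least 2")
})

test_that("IVW matches the hand-computed weighted mean and fixed-effect SE", {
  h <- hset_theta_w(theta = c(0.1, 0.3, 0.5), w = c(4, 1, 1))
  est <- mr_ivw(h, "fixed")
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 6^(-1 / 2))
  expect_equal(est$or, exp(0.2))
  expect_equal(est$ci_low, 0.2 - 1.96 * 6^(-1 / 2))
})

test_that("IVW closed form equals the zero-intercept weighted regression", {
  for (seed in 1:50) {
    set.seed(seed)
    J <- sample(3:20, 1)
    be <- rnorm(J, 0.1, 0.05)
    be[be == 0] <- 0.01
    bo <- rnorm(J, 0.03, 0.02)
    so <- runif(J, 0.005, 0.05)
    h <- hset_from(be, bo, so)
    # independent oracle: weighted least squares through the origin
    slope <- sum(bo * be / so^2) / sum(be^2 / so^2)
    expect_equal(mr_ivw(h, "fixed")$beta, slope, tolerance = 1e-12)
    expect_equal(mr_ivw(h, "multiplicative_random")$beta, slope,
                 tolerance = 1e-12)
  }
})

test_that("multiplicative random effects never shrink below the fixed SE", {
  set.seed(4)
  h <- hset_from(rnorm(10, 0.1, 0.02), rnorm(10, 0, 0.05),
                 runif(10, 0.005, 0.02))
  expect_gte(mr_ivw(h, "multiplicative_random")$se, mr_ivw(h, "fixed")$se)
  # homogeneous data: the floor makes the two models coincide
  h0 <- hset_theta_w(rep(0.2, 6), rep(1, 6))
  expect_equal(mr_ivw(h0, "multiplicative_random")$se, mr_ivw(h0, "fixed")$se)
})

test_that("Egger recovers exact linear structure", {
  be <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- hset_from(be, 0.02 + 0.5 * be, rep(0.01, 5))
  fit <- mr_egger(h)
  expect_equal(fit$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept$intercept, 0.02, tolerance = 1e-10)
  # pure proportionality: zero intercept
  h2 <- hset_from(be, 0.3 * be, rep(0.01, 5))
  fit2 <- mr_egger(h2)
  expect_equal(fit2$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit2$intercept$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(hset_from(be[1:2], be[1:2], c(0.01, 0.01))),
               "at least 3")
})

test_that("Egger equals an independent generalized-least-squares oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    J <- sample(4:25, 1)
    be <- abs(rnorm(J, 0.1, 0.05)) + 0.01
    bo <- 0.05 + 0.3 * be + rnorm(J, 0, 0.02)
    so <- runif(J, 0.005, 0.05)
    h <- hset_from(be, bo, so)
    fit <- mr_egger(h)
    # oracle: closed-form GLS normal equations, solved directly
    X <- cbind(1, be)
    W <- diag(1 / so^2)
    coefs <- solve(t(X) %*% W %*% X, t(X) %*% W %*% bo)
    expect_equal(fit$intercept$intercept, unname(coefs[1]), tolerance = 1e-10)
    expect_equal(fit$slope$beta, unname(coefs[2]), tolerance = 1e-10)
    # oracle SEs under the floored multiplicative overdispersion convention
    resid <- bo - X %*% coefs
    sigma2 <- sum(resid^2 / so^2) / (J - 2)
    cov_u <- solve(t(X) %*% W %*% X)
    se <- unname(sqrt(diag(cov_u)) * max(1, sqrt(sigma2)))
    expect_equal(fit$intercept$se, se[1], tolerance = 1e-10)
    expect_equal(fit$slope$se, se[2], tolerance = 1e-10)
  }
})

test_that("Egger is invariant to per-SNP allele relabeling by construction", {
  set.seed(12)
  be <- rnorm(8, 0.1, 0.05)
  bo <- 0.02 + 0.4 * be + rnorm(8, 0, 0.01)
  h <- hset_from(be, bo, rep(0.01, 8))
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  h2 <- hset_from(be * flip, bo * flip, rep(0.01, 8))
  f1 <- mr_egger(h)
  f2 <- mr_egger(h2)
  expect_equal(f1$slope$beta, f2$slope$beta, tolerance = 1e-12)
  expect_equal(f1$intercept$intercept, f2$intercept$intercept,
               tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative weight at 50%", {
  h <- hset_theta_w(theta = c(1, 2, 3), w = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta, 2)
  # a gross outlier with 25% of the weight cannot move the estimate outside
  # the valid cluster; hand-interpolated value is 0.15
  h2 <- hset_theta_w(theta = c(0, 0.1, 0.2, 5), w = c(1, 1, 1, 1))
  est <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.15)
  expect_gt(est$beta, 0.1)
  expect_lt(est$beta, 0.2)
  # a single ratio carrying > 50% of the weight pins the estimate near it,
  # up to the interpolation step toward the next order statistic
  h3 <- hset_theta_w(theta = c(0.1, 0.9, 1.1), w = c(50, 1, 1))
  est3 <- mr_weighted_median(h3, n_boot = 100, seed = 1)$beta
  # hand interpolation: cumulative midweights (25, 50.5, 51.5)/52
  expect_equal(est3, 0.1 + 0.8 * (0.5 - 25 / 52) / (50.5 / 52 - 25 / 52))
  expect_lt(abs(est3 - 0.1), 0.05)
})

test_that("weighted median bootstrap SE is seeded and reproducible", {
  set.seed(7)
  h <- hset_from(rnorm(8, 0.1, 0.03), rnorm(8, 0.03, 0.02),
                 runif(8, 0.005, 0.02))
  e1 <- mr_weighted_median(h, n_boot = 300, seed = 42)
  e2 <- mr_weighted_median(h, n_boot = 300, seed = 42)
  expect_identical(e1, e2)
  expect_gt(e1$se, 0)
  expect_error(mr_weighted_median(h, n_boot = 50), "n_boot")
})

test_that("mode estimators find the dominant cluster", {
  h <- hset_theta_w(theta = c(0.3, 0.3, 0.3, 9), w = rep(1, 4))
  expect_equal(mr_mode(h, n_boot = 100, seed = 1)$beta, 0.3)
  # degenerate bandwidth: all ratios identical
  h2 <- hset_theta_w(theta = rep(0.7, 4), w = rep(1, 4))
  expect_equal(mr_mode(h2, n_boot = 100, seed = 1)$beta, 0.7)
})

test_that("weighting can move the mode between clusters", {
  theta <- c(rep(0.1, 6), rep(0.8, 3))
  w <- c(rep(1, 6), rep(10, 3))
  h <- hset_theta_w(theta, w)
  simple <- mr_mode(h, weighted = FALSE, n_boot = 100, seed = 1)
  weighted <- mr_mode(h, weighted = TRUE, n_boot = 100, seed = 1)
  expect_lt(abs(simple$beta - 0.1), 0.1)
  expect_lt(abs(weighted$beta - 0.8), 0.1)
  # independent oracle: brute-force kernel density on a fine grid
  brute_mode <- function(th, wts, phi = 1) {
    J <- length(th)
    wn <- wts / sum(wts)
    m <- sum(wn * th)
    sd_ <- sqrt(sum(wn * (th - m)^2))
    h_bw <- phi * 0.9 * sd_ * J^(-0.2)  # sd < iqr/1.349 for these clusters
    grid <- th
    dens <- sapply(grid, function(g) sum(wn * dnorm(g, th, h_bw)))
    mean(grid[dens >= max(dens) - 1e-12])
  }
  expect_equal(weighted$beta, brute_mode(theta, w), tolerance = 1e-10)
})

test_that("all estimators are invariant to jointly negating any pair", {
  set.seed(99)
  be <- rnorm(10, 0.12, 0.04)
  bo <- 0.25 * be + rnorm(10, 0, 0.01)
  so <- runif(10, 0.005, 0.02)
  flip <- sample(c(-1, 1), 10, replace = TRUE)
  h1 <- hset_from(be, bo, so)
  h2 <- hset_from(be * flip, bo * flip, so)
  expect_equal(mr_ivw(h1)$beta, mr_ivw(h2)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h1, 100, 5)$beta,
               mr_weighted_median(h2, 100, 5)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(h1, TRUE, 1, 100, 5)$beta,
               mr_mode(h2, TRUE, 1, 100, 5)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h1)$slope$beta, mr_egger(h2)$slope$beta,
               tolerance = 1e-12)
})

test_that("the five-method table has the standard order and OR columns", {
  set.seed(2)
  be <- abs(rnorm(10, 0.15, 0.04))
  theta <- log(0.92)
  h <- hset_from(be, theta * be, rep(0.004, 10))
  tab <- run_all_methods(h, mr_config(n_boot = 100, seed = 1))
  expect_identical(tab$method, c("egger", "weighted_median", "ivw",
                                 "simple_mode", "weighted_mode"))
  # noiseless proportional data: every method returns exactly theta
  expect_equal(tab$beta, rep(theta, 5), tolerance = 1e-10)
  expect_equal(tab$or, rep(0.92, 5), tolerance = 1e-10)
  expect_equal(tab$or_low, exp(tab$ci_low))
  expect_true(all(tab$ci_low < tab$beta & tab$beta < tab$ci_high))
})

test_that("method gating: 2 pairs give IVW only, 1 pair gives the Wald ratio", {
  h2 <- hset_theta_w(c(0.1, 0.3), c(1, 1))
  tab <- run_all_methods(h2, mr_config(n_boot = 100))
  expect_identical(tab$method, "ivw")
  h1 <- harmonized_set(0.1, 0.01, 0.05, 0.01)
  tab1 <- run_all_methods(h1, mr_config(n_boot = 100))
  expect_identical(tab1$method, "wald")
  expect_equal(tab1$beta, 0.5)
})

test_that("the estimator table is deterministic for a fixed seed", {
  sim <- simulate_pair(sim_config(n_snps = 8, seed = 13, theta = 0.2))
  iv <- select_instruments(sim$exposure)
  h <- harmonize_datasets(iv, sim$outcome)
  t1 <- run_all_methods(h, mr_config(n_boot = 200, seed = 77))
  t2 <- run_all_methods(h, mr_config(n_boot = 200, seed = 77))
  expect_identical(t1, t2)
})
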