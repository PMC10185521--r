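test_that("Cochran's Q is zero for homogeneous ratios and exact on a hand case", {
  h <- hset_theta_w(rep(0.4, 5), rep(2, 5))
  q <- cochran_q(h, "ivw")
  expect_equal(q$q, 0)
  expect_equal(q$i2, 0)
  expect_equal(q$pval, 1)
  expect_identical(q$df, 4)
  # two ratios 0 and 1 with equal weight 2: Q about the mean 0.5 is 1
  h2 <- hset_theta_w(c(0, 1), c(2, 2))
  q2 <- cochran_q(h2, "ivw")
  expect_equal(q2$q, 1)
  expect_identical(q2$df, 1)
  expect_equal(q2$pval, pchisq(1, 1, lower.tail = FALSE))
})

test_that("Q computed about the weighted mean equals the regression-residual route", {
  for (seed in 1:20) {
    set.seed(seed)
    J <- sample(3:15, 1)
    be <- rnorm(J, 0.1, 0.04)
    be[be == 0] <- 0.05
    bo <- rnorm(J, 0.02, 0.03)
    so <- runif(J, 0.005, 0.05)
    h <- hset_from(be, bo, so)
    q <- cochran_q(h, "ivw")$q
    # independent route: residuals of the zero-intercept weighted fit
    slope <- sum(bo * be / so^2) / sum(be^2 / so^2)
    q_reg <- sum((bo - slope * be)^2 / so^2)
    expect_equal(q, q_reg, tolerance = 1e-10)
  }
})

test_that("Q doubles when every pair is duplicated and I2 stays in [0,1)", {
  set.seed(5)
  be <- rnorm(8, 0.1, 0.03)
  bo <- rnorm(8, 0.02, 0.02)
  so <- runif(8, 0.005, 0.02)
  q1 <- cochran_q(hset_from(be, bo, so), "ivw")
  q2 <- cochran_q(hset_from(rep(be, 2), rep(bo, 2), rep(so, 2)), "ivw")
  expect_equal(q2$q, 2 * q1$q, tolerance = 1e-10)
  for (q in list(q1, q2)) {
    expect_gte(q$i2, 0)
    expect_lt(q$i2, 1)
  }
})

test_that("Egger-reference Q uses the Egger fit and J-2 degrees of freedom", {
  set.seed(6)
  be <- abs(rnorm(6, 0.12, 0.03))
  bo <- 0.01 + 0.3 * be + rnorm(6, 0, 0.01)
  so <- rep(0.01, 6)
  h <- hset_from(be, bo, so)
  q <- cochran_q(h, "egger")
  expect_identical(q$df, 4)
  fit <- mr_egger(h)
  q_manual <- sum((bo - fit$intercept$intercept - fit$slope$beta * be)^2 / so^2)
  expect_equal(q$q, q_manual, tolerance = 1e-10)
  expect_error(cochran_q(hset_from(be[1:2], bo[1:2], so[1:2]), "egger"),
               "egger")
})

test_that("Q p-values are calibrated under a homogeneous null", {
  cfg <- sim_config(n_snps = 10, theta = 0.1, seed = 2024)
  batch <- simulate_null_batch(cfg, n_reps = 300, methods = "ivw")
  rej <- mean(batch$q_pval < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Egger intercept test: null behavior, power, and df bookkeeping", {
  # noiseless balanced data: intercept exactly zero
  be <- c(0.05, 0.1, 0.2, 0.4)
  h0 <- hset_from(be, 0.3 * be, rep(0.01, 4))
  t0 <- egger_intercept_test(h0)
  expect_lt(abs(t0$intercept), 1e-12)
  expect_gt(t0$pval, 0.99)
  # directional pleiotropy with tight SEs is detected in most replicates
  set.seed(31)
  hits <- 0L
  n_reps <- 40L
  for (r in seq_len(n_reps)) {
    bx <- abs(rnorm(20, 0.15, 0.08)) + 0.02
    by <- 0.1 + 0.3 * bx + rnorm(20, 0, 0.05)
    h <- hset_from(bx, by, rep(0.004, 20))
    if (egger_intercept_test(h)$pval < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_reps, 0.8)
  # minimal J = 3 case uses df = 1
  h3 <- hset_from(c(0.1, 0.2, 0.3), c(0.05, 0.08, 0.1), rep(0.01, 3))
  fit3 <- mr_egger(h3)
  t_stat <- fit3$intercept$intercept / fit3$intercept$se
  expect_equal(fit3$intercept$pval, 2 * pt(-abs(t_stat), df = 1))
})

test_that("MR-PRESSO is deterministic and respects the add-one p-value floor", {
  sim <- simulate_pair(sim_config(n_snps = 8, seed = 17, theta = 0.1))
  iv <- select_instruments(sim$exposure)
  h <- harmonize_datasets(iv, sim$outcome)
  p1 <- mr_presso(h, n_sim = 300, seed = 9)
  p2 <- mr_presso(h, n_sim = 300, seed = 9)
  expect_identical(p1, p2)
  expect_gte(p1$global_pval, 1 / 301)
  expect_true(all(p1$per_snp_pvals >= 1 / 301))
  expect_error(mr_presso(h, n_sim = 50), "n_sim")
  expect_error(
    mr_presso(hset_from(c(0.1, 0.2, 0.3), c(0, 0, 0), rep(0.01, 3))),
    "at least 4")
})

test_that("a clean synthetic set shows no outliers; an injected one is flagged", {
  sim <- simulate_pair(sim_config(n_snps = 15, seed = 55, theta = 0.1))
  iv <- select_instruments(sim$exposure)
  h <- harmonize_datasets(iv, sim$outcome)
  clean <- mr_presso(h, n_sim = 500, seed = 3)
  expect_gt(clean$global_pval, 0.05)
  expect_identical(clean$outlier_snp_ids, character(0))
  # shift one SNP's outcome effect by 10 of its standard errors
  h_out <- h
  h_out$pairs$beta_out[4] <- h_out$pairs$beta_out[4] +
    10 * h_out$pairs$se_out[4]
  hit <- mr_presso(h_out, n_sim = 500, seed = 3)
  expect_true(h_out$pairs$snp_id[4] %in% hit$outlier_snp_ids)
  expect_lt(hit$global_pval, 0.05)
})

test_that("small n_sim relative to the Bonferroni level warns", {
  sim <- simulate_pair(sim_config(n_snps = 10, seed = 19, theta = 0))
  iv <- select_instruments(sim$exposure)
  h <- harmonize_datasets(iv, sim$outcome)
  expect_warning(mr_presso(h, n_sim = 100, seed = 1), "resolve")
})

test_that("leave-one-out produces J rows of J-1 estimates", {
  sim <- simulate_pair(sim_config(n_snps = 6, seed = 23, theta = 0.15))
  iv <- select_instruments(sim$exposure)
  h <- harmonize_datasets(iv, sim$outcome)
  loo <- leave_one_out(h)
  J <- nrow(h$pairs)
  expect_identical(nrow(loo$rows), J)
  expect_setequal(loo$rows$omitted_snp_id, h$pairs$snp_id)
  # each row equals the IVW estimate on the complementary pairs
  for (j in seq_len(J)) {
    expect_equal(loo$rows$beta[j], mr_ivw(h$pairs[-j, ])$beta,
                 tolerance = 1e-12)
  }
})

test_that("homogeneous noiseless sets have no influential SNPs", {
  be <- seq(0.05, 0.3, length.out = 5)
  h <- hset_from(be, 0.2 * be, rep(0.01, 5))
  loo <- leave_one_out(h)
  expect_equal(loo$rows$beta, rep(0.2, 5), tolerance = 1e-12)
  expect_false(any(loo$rows$influential))
  expect_error(leave_one_out(hset_from(be[1:2], be[1:2], c(0.01, 0.01))),
               "at least 3")
})

test_that("a dominant-weight outlier moves its leave-one-out row the most", {
  theta <- c(rep(0.2, 6), 1.5)
  w <- c(rep(1, 6), 20)
  h <- hset_theta_w(theta, w)
  loo <- leave_one_out(h)
  shift <- abs(loo$rows$beta - loo$full_estimate$beta)
  expect_identical(which.max(shift), 7L)
})

test_that("the sensitivity suite gates components by instrument count", {
  h2 <- hset_theta_w(c(0.1, 0.2), c(1, 1))
  s2 <- sensitivity_suite(h2, mr_config(presso_n_sim = 200))
  expect_false(is.null(s2$q_ivw))
  expect_null(s2$egger_intercept)
  expect_null(s2$presso)
  h5 <- hset_theta_w(seq(0.1, 0.5, 0.1), rep(1, 5))
  s5 <- suppressWarnings(sensitivity_suite(h5, mr_config(presso_n_sim = 200)))
  expect_false(is.null(s5$q_egger))
  expect_false(is.null(s5$presso))
  expect_false(is.null(s5$loo))
})
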