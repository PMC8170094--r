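kBT300 <- 0.0019872 * 300

test_that("exponential estimator handles degenerate and Gaussian work", {
  expect_equal(fep_exp_estimator(rep(2.5, 10)), 2.5)
  expect_equal(fep_exp_estimator(0), 0)

  # Gaussian work: dG = mu - sigma^2 / (2 kBT)
  withr::local_seed(91)
  n <- 1e5
  w <- rnorm(n, 2.0, 1.0)
  dg_expected <- 2.0 - 1.0 / (2 * kBT300)
  # 3 SE via nonparametric bootstrap of the estimator
  boot <- replicate(60, {
    fep_exp_estimator(w[sample.int(n, n, replace = TRUE)])
  })
  expect_lt(abs(fep_exp_estimator(w) - dg_expected), 3 * sd(boot))

  # no overflow deep into the exponential tail
  expect_equal(fep_exp_estimator(c(-400, -400)), -400)
  expect_error(fep_exp_estimator(numeric(0)), "no work samples")
})

test_that("BAR solves the self-consistency condition", {
  # symmetric degenerate case pins the estimate exactly
  est <- fep_bar_estimator(rep(3, 20), rep(-3, 20))
  expect_equal(est$delta_g_kcal_mol, 3, tolerance = 1e-7)

  # Crooks-consistent Gaussian pair recovers the construction truth
  f <- sim_fep_windows(1.1611, sigma_w_kcal_mol = 1, n_per_window = 2e4,
                       seed = 92)
  fw <- f$work_kcal_mol[f$direction == "forward"]
  bw <- f$work_kcal_mol[f$direction == "backward"]
  est2 <- fep_bar_estimator(fw, bw)
  expect_lt(abs(est2$delta_g_kcal_mol - 1.1611), 3 * est2$se_kcal_mol)

  # zero-work window contributes exactly zero
  est0 <- fep_bar_estimator(rep(0, 5), rep(0, 5))
  expect_equal(est0$delta_g_kcal_mol, 0, tolerance = 1e-8)
})

test_that("BAR lies between the two exponential estimates", {
  # Per sample, finite-n noise can move BAR slightly past the bracket, so
  # the check allows the combined estimator uncertainty; the systematic
  # (expectation) ordering is asserted separately on a fixed configuration.
  withr::local_seed(92001)
  for (s in 1:100) {
    f <- sim_fep_windows(runif(1, -3, 3), sigma_w_kcal_mol = runif(1, 0.5, 2),
                         n_per_window = 1000, seed = 9200 + s)
    fw <- f$work_kcal_mol[f$direction == "forward"]
    bw <- f$work_kcal_mol[f$direction == "backward"]
    est <- fep_bar_estimator(fw, bw)
    margin <- 3 * (est$se_kcal_mol +
                     max(redoxleak:::fep_exp_se(fw),
                         redoxleak:::fep_exp_se(bw)))
    lo <- min(fep_exp_estimator(fw), -fep_exp_estimator(bw))
    hi <- max(fep_exp_estimator(fw), -fep_exp_estimator(bw))
    expect_gte(est$delta_g_kcal_mol, lo - margin)
    expect_lte(est$delta_g_kcal_mol, hi + margin)
  }

  # expectation ordering: the forward exponential estimate is biased low,
  # the negated backward one biased high, and BAR sits in between
  bar <- lo <- hi <- numeric(150)
  for (s in 1:150) {
    f <- sim_fep_windows(1, sigma_w_kcal_mol = 2, n_per_window = 400,
                         seed = 60000 + s)
    fw <- f$work_kcal_mol[f$direction == "forward"]
    bw <- f$work_kcal_mol[f$direction == "backward"]
    bar[s] <- fep_bar_estimator(fw, bw)$delta_g_kcal_mol
    lo[s] <- min(fep_exp_estimator(fw), -fep_exp_estimator(bw))
    hi[s] <- max(fep_exp_estimator(fw), -fep_exp_estimator(bw))
  }
  expect_lt(mean(lo), mean(bar))
  expect_lt(mean(bar), mean(hi))
})

test_that("BAR variance does not exceed the exponential estimators'", {
  worse <- 0
  for (s in 1:20) {
    f <- sim_fep_windows(1.5, sigma_w_kcal_mol = 1, n_per_window = 2000,
                         seed = 9300 + s)
    fw <- f$work_kcal_mol[f$direction == "forward"]
    bw <- f$work_kcal_mol[f$direction == "backward"]
    bar_se <- fep_bar_estimator(fw, bw)$se_kcal_mol
    exp_se <- min(redoxleak:::fep_exp_se(fw), redoxleak:::fep_exp_se(bw))
    if (bar_se > exp_se * 1.05) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("window estimates accumulate into transformation totals", {
  f <- sim_fep_windows(c(1, -2, 0.5), sigma_w_kcal_mol = 0, n_per_window = 3,
                       seed = 94)
  acc <- fep_accumulate(f, method = "bar")
  expect_equal(acc$total_delta_g_kcal_mol, -0.5, tolerance = 1e-7)
  expect_equal(acc$windows$delta_delta_g_kcal_mol, c(1, -2, 0.5),
               tolerance = 1e-7)

  # noisy 16-window transformation recovers the summed truth
  truths <- seq(-2, 1, length.out = 16)
  f2 <- sim_fep_windows(truths, sigma_w_kcal_mol = 0.8, n_per_window = 2000,
                        seed = 95)
  acc2 <- fep_accumulate(f2, method = "bar")
  expect_lt(abs(acc2$total_delta_g_kcal_mol - sum(truths)),
            3 * acc2$se_kcal_mol)
})

test_that("hysteresis is the absolute sum of directional exponential totals", {
  # construct a single window whose forward and backward exponential
  # estimates disagree by design: forward work all 5.0, backward all -4.2
  f <- tibble::tibble(
    leg = "FEP1", model = "I",
    direction = rep(c("forward", "backward"), each = 3),
    window_index = 1, lambda_from = c(rep(0, 3), rep(1, 3)),
    lambda_to = c(rep(1, 3), rep(0, 3)),
    work_kcal_mol = c(rep(5, 3), rep(-4.2, 3)))
  acc <- fep_accumulate(f, method = "exp_forward")
  expect_equal(acc$hysteresis_kcal_mol, 0.8, tolerance = 1e-10)
})

test_that("accumulate refuses mixed transformations", {
  f1 <- sim_fep_windows(1, n_per_window = 2, seed = 96, leg = "FEP1")
  f2 <- sim_fep_windows(1, n_per_window = 2, seed = 96, leg = "FEP2")
  expect_error(fep_accumulate(dplyr::bind_rows(f1, f2)), "one transformation")
})

test_that("legs combine additively with quadrature uncertainties", {
  f1 <- sim_fep_windows(rep(30 / 8, 8), sigma_w_kcal_mol = 0.5,
                        n_per_window = 500, seed = 97, leg = "FEP1")
  f2 <- sim_fep_windows(rep(-51.6 / 8, 8), sigma_w_kcal_mol = 0.5,
                        n_per_window = 500, seed = 98, leg = "FEP2")
  e1 <- fep_accumulate(f1)
  e2 <- fep_accumulate(f2)
  comb <- combine_fep_legs(e1, e2)
  expect_equal(comb$delta_g0_kcal_mol,
               e1$total_delta_g_kcal_mol + e2$total_delta_g_kcal_mol)
  expect_lt(abs(comb$delta_g0_kcal_mol - (-21.6)), 3 * comb$se_kcal_mol)
  expect_equal(comb$se_kcal_mol,
               sqrt(e1$se_kcal_mol^2 + e2$se_kcal_mol^2))

  # commutative
  ba <- combine_fep_legs(e2, e1)
  expect_equal(ba$delta_g0_kcal_mol, comb$delta_g0_kcal_mol)

  # degenerate zero legs
  z <- fep_accumulate(sim_fep_windows(0, sigma_w_kcal_mol = 0,
                                      n_per_window = 2, seed = 99))
  expect_equal(combine_fep_legs(z, z)$delta_g0_kcal_mol, 0, tolerance = 1e-9)

  e2$model <- "II"
  expect_error(combine_fep_legs(e1, e2), "different reaction models")
})

test_that("estimate objects expose tidy, glance and autoplot", {
  f <- sim_fep_windows(rep(-1, 4), sigma_w_kcal_mol = 0.5, n_per_window = 100,
                       seed = 100)
  acc <- fep_accumulate(f)
  expect_equal(nrow(tidy(acc)), 4)
  gl <- glance(acc)
  expect_equal(gl$n_windows, 4)
  expect_true(is.finite(gl$hysteresis_kcal_mol))
  expect_s3_class(autoplot(acc), "ggplot")
})
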