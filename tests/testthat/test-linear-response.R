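eval_parabola_for_test <- function(p, x) p$a * (x - p$vertex)^2 + p$offset

test_that("gap computation is elementwise product minus reactant", {
  expect_equal(gap_from_energies(10, 30), -20)
  expect_equal(gap_from_energies(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(gap_from_energies(c(3, 3), c(3, 3)), c(0, 0))
  expect_error(gap_from_energies(1:3, 1:2), "equal length")
})

test_that("gap summaries report mean, sample sd and skewness", {
  tbl <- tibble::tibble(state = "reactant", delta_u_kcal_mol = c(-1, 1))
  s <- summarize_gaps(tbl)
  expect_equal(s$mean_kcal_mol, 0)
  expect_equal(s$sd_kcal_mol, sqrt(2))

  sym <- tibble::tibble(state = "reactant",
                        delta_u_kcal_mol = c(-2, -1, 0, 1, 2))
  expect_equal(summarize_gaps(sym)$skewness, 0)

  withr::local_seed(81)
  n <- 1e5
  big <- tibble::tibble(state = "product", delta_u_kcal_mol = rnorm(n))
  expect_lt(abs(summarize_gaps(big)$skewness), 3 * sqrt(6 / n))

  expect_error(summarize_gaps(tbl[1, ]), "at least 2")
  skewed <- tibble::tibble(state = "product",
                           delta_u_kcal_mol = rexp(500))
  expect_warning(summarize_gaps(skewed), "skewed")
})

test_that("paired state energies are converted to gaps on the fly", {
  tbl <- tibble::tibble(state = "reactant",
                        u_product_kcal_mol = c(10, 12),
                        u_reactant_kcal_mol = c(30, 30))
  s <- summarize_gaps(tbl)
  expect_equal(s$mean_kcal_mol, -19)
})

test_that("empirical free-energy curve matches the Gaussian closed form", {
  withr::local_seed(82)
  mu <- 5; sigma <- 3; n <- 1e5
  x <- rnorm(n, mu, sigma)
  kBT <- 0.0019872 * 300
  cu <- empirical_free_energy_curve(x, temperature_K = 300)
  central <- abs(cu$delta_u_kcal_mol - mu) < 2 * sigma
  expected <- kBT * (cu$delta_u_kcal_mol[central] - mu)^2 / (2 * sigma^2)
  expected <- expected - min(expected)
  expect_lt(max(abs(cu$g_kcal_mol[central] - expected)), 0.5)

  # duplicating every sample leaves the curve unchanged (fixed binning)
  cu1 <- empirical_free_energy_curve(x, bins = 40)
  cu2 <- empirical_free_energy_curve(rep(x, 2), bins = 40)
  expect_equal(cu1$g_kcal_mol, cu2$g_kcal_mol, tolerance = 1e-12)

  expect_error(empirical_free_energy_curve(rep(1, 100)), "identical")
  expect_error(empirical_free_energy_curve(rnorm(10)), ">= 50")
})

test_that("parabola curvature is kBT over twice the variance", {
  p <- parabola_from_summary(63.87, 10, temperature_K = 300)
  expect_equal(p$a, 0.59616 / 200)
  expect_equal(p$vertex, 63.87)
  expect_equal(p$offset, 0)
  expect_error(parabola_from_summary(0, 0), "> 0")
  # curvature vanishes in the wide-distribution limit
  expect_lt(parabola_from_summary(0, 1e6)$a, 1e-12)
})

test_that("alignment extracts driving force and reorganization energies", {
  r <- parabola_from_summary(63.87, 10, 300)
  p <- parabola_from_summary(-103.87, 10, 300)
  d <- align_and_extract(r, p)
  # reference values quoted at printed precision (sigma = 10 corresponds to
  # lambda = 100 / (2 kBT) = 83.8702...)
  expect_equal(d$delta_g0_kcal_mol, -20, tolerance = 1e-5)
  expect_equal(d$lambda_p_kcal_mol, 83.87, tolerance = 1e-5)
  expect_equal(d$lambda_r_kcal_mol, 83.87, tolerance = 1e-5)

  # aligned curves agree at gap zero for arbitrary inputs
  r2 <- parabola_from_summary(40, 7, 300)
  p2 <- parabola_from_summary(-90, 12, 300)
  d2 <- align_and_extract(r2, p2)
  g_r <- d2$parabolas$reactant
  g_p <- d2$parabolas$product
  expect_equal(g_r$a * g_r$vertex^2 + g_r$offset,
               g_p$a * g_p$vertex^2 + g_p$offset)

  expect_warning(align_and_extract(r, r), "coincide")
})

test_that("product vertex at gap zero means |driving force| = |reorganization|", {
  # equal-variance case constructed so the product minimum sits at zero:
  # the aligned curves then intersect at the product equilibrium and the
  # extracted driving force and product reorganization energy coincide in
  # magnitude
  kBT <- 0.59616
  lam <- 30
  sigma <- sqrt(2 * lam * kBT)
  r <- parabola_from_summary(2 * lam, sigma, 300)
  p <- parabola_from_summary(0, sigma, 300)
  d <- align_and_extract(r, p)
  expect_equal(d$lambda_p_kcal_mol, abs(d$delta_g0_kcal_mol))
  # intersection at the product vertex: both curves equal there
  expect_equal(eval_parabola_for_test(d$parabolas$reactant, 0),
               eval_parabola_for_test(d$parabolas$product, 0))
})

test_that("full linear response recovers generator ground truth", {
  n <- 1e5
  gaps <- sim_gap_samples(-20, 83.87, n_samples = n, seed = 83)
  d <- full_linear_response(gaps)
  # 3 SE of the geometric estimator itself via bootstrap
  kBT <- 0.0019872 * 300
  r_samp <- gaps$delta_u_kcal_mol[gaps$state == "reactant"]
  p_samp <- gaps$delta_u_kcal_mol[gaps$state == "product"]
  boot <- withr::with_seed(830, replicate(100, {
    i <- sample.int(n, n, replace = TRUE)
    r <- r_samp[i]; p <- p_samp[i]
    kBT / (2 * var(r)) * mean(r)^2 - kBT / (2 * var(p)) * mean(p)^2
  }))
  expect_lt(abs(d$delta_g0_kcal_mol - (-20)), 3 * sd(boot))
  expect_lt(abs(d$lambda_p_kcal_mol - 83.87), 1)

  # unequal curvature: both reorganization energies positive but different
  gaps2 <- sim_gap_samples(-20, 83.87, n_samples = 2e4, sigma_ratio = 1.2,
                           seed = 84)
  d2 <- full_linear_response(gaps2)
  expect_gt(d2$lambda_p_kcal_mol, 0)
  expect_gt(d2$lambda_r_kcal_mol, 0)
  expect_gt(abs(d2$lambda_r_kcal_mol / d2$lambda_p_kcal_mol - 1), 0.1)

  # swapping states with a coordinate reflection negates the driving force
  swapped <- dplyr::mutate(
    gaps,
    state = ifelse(.data$state == "reactant", "product", "reactant"),
    delta_u_kcal_mol = -.data$delta_u_kcal_mol)
  d3 <- full_linear_response(swapped)
  expect_equal(d3$delta_g0_kcal_mol, -d$delta_g0_kcal_mol, tolerance = 1e-10)
})

test_that("parabola and empirical curve agree over the sampled range", {
  gaps <- sim_gap_samples(-20, 83.87, n_samples = 1e5, seed = 85)
  d <- full_linear_response(gaps)
  for (st in c("reactant", "product")) {
    cu <- d$curves[[st]]
    pb <- d$parabolas[[st]]
    s <- d$summaries[d$summaries$state == st, ]
    central <- abs(cu$delta_u_kcal_mol - s$mean_kcal_mol) < 2 * s$sd_kcal_mol
    diff <- cu$g_kcal_mol[central] -
      (pb$a * (cu$delta_u_kcal_mol[central] - pb$vertex)^2 + pb$offset)
    expect_lt(max(abs(diff - mean(diff))), 0.5)
  }
})

test_that("diagram accessors and plot builders work", {
  gaps <- sim_gap_samples(-20, 83.87, n_samples = 5000, seed = 86)
  d <- full_linear_response(gaps)
  gl <- glance(d)
  expect_named(gl, c("delta_g0_kcal_mol", "lambda_p_kcal_mol",
                     "lambda_r_kcal_mol"))
  td <- tidy(d)
  expect_setequal(td$state, c("reactant", "product"))
  expect_s3_class(autoplot(d), "ggplot")
})
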