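# Threshold estimation and polychoric / polyserial / mixed correlations.

test_that("thresholds invert cumulative normal proportions", {
  expect_equal(estimate_thresholds(c(50, 50)), 0)
  expect_equal(estimate_thresholds(c(50, 25, 25)), c(0, qnorm(0.75)))
  expect_equal(estimate_thresholds(c(50, 25, 25))[2], 0.6745, tolerance = 1e-4)
  expect_error(estimate_thresholds(c(100)), "2 categories")
  expect_error(estimate_thresholds(c(1, 0, 99)), "collapse")
  expect_error(estimate_thresholds(c(0, 10, 90)), "Empty category")
})

test_that("an independence table gives zero polychoric correlation", {
  rows <- c(0.5, 0.3, 0.2)
  cols <- c(0.6, 0.3, 0.1)
  tab <- outer(rows, cols) * 1000
  expect_lt(abs(polychoric(tab)$rho), 1e-4)
})

test_that("polychoric recovers the generating latent correlation", {
  withr::with_seed(42, {
    n <- 1e5
    z1 <- rnorm(n)
    z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
    y1 <- (z1 > -0.5) + (z1 > 0.5)
    y2 <- (z2 > -0.5) + (z2 > 0.5)
    est <- polychoric(y1, y2)
    expect_equal(est$rho, 0.5, tolerance = 0.01)
    # exchanging the variables leaves the estimate unchanged
    est_t <- polychoric(y2, y1)
    expect_equal(est$rho, est_t$rho, tolerance = 1e-6)
  })
})

test_that("polychoric is consistent: errors shrink within asymptotic bands", {
  withr::with_seed(7, {
    for (n in c(1e3, 1e4, 1e5)) {
      z1 <- rnorm(n)
      z2 <- 0.4 * z1 + sqrt(1 - 0.16) * rnorm(n)
      y1 <- (z1 > -0.3) + (z1 > 0.8)
      y2 <- (z2 > -0.6) + (z2 > 0.6)
      est <- polychoric(y1, y2)
      expect_lt(abs(est$rho - 0.4), 4 * est$se)
    }
  })
})

test_that("the influence-function variance matches replicate variance", {
  reps <- vapply(1:500, function(s) {
    withr::with_seed(s, {
      z1 <- rnorm(2000)
      z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(2000)
      polychoric((z1 > -0.4) + (z1 > 0.6), (z2 > -0.4) + (z2 > 0.6))$rho
    })
  }, 0)
  withr::with_seed(999, {
    z1 <- rnorm(2000)
    z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(2000)
    est <- polychoric((z1 > -0.4) + (z1 > 0.6), (z2 > -0.4) + (z2 > 0.6))
  })
  expect_gt(est$avar / var(reps), 0.8)
  expect_lt(est$avar / var(reps), 1.25)
})

test_that("polyserial recovers latent correlations that Pearson attenuates", {
  withr::with_seed(11, {
    n <- 5e4
    x <- rnorm(n)
    ystar <- 0.3 * x + sqrt(1 - 0.09) * rnorm(n)
    y <- (ystar > -0.5) + (ystar > 0.5)
    est <- polyserial(x, y)
    expect_equal(est$rho, 0.3, tolerance = 0.02)
    expect_lt(cor(x, y), est$rho)  # discretization attenuates Pearson
    # independent variables give a near-zero estimate
    est0 <- polyserial(rnorm(n), y)
    expect_lt(abs(est0$rho), 0.02)
  })
  expect_error(polyserial(rep(1, 100), rep(0:1, 50)), "constant")
})

test_that("mixed_cor dispatches estimators by variable type", {
  withr::with_seed(3, {
    n <- 500
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n),
      o1 = sample(0:2, n, replace = TRUE), o2 = sample(0:2, n, replace = TRUE)
    )
    # covariates only: plain Pearson
    mc0 <- mixed_cor(d, items = character(0), covariates = c("x1", "x2"))
    expect_equal(mc0$R["x1", "x2"], cor(d$x1, d$x2), tolerance = 1e-10)
    expect_equal(unname(mc0$types["x1", "x2"]), "pearson")

    mc <- mixed_cor(d, items = c("o1", "o2"), covariates = c("x1", "x2"))
    expect_equal(unname(mc$types["o1", "o2"]), "polychoric")
    expect_equal(unname(mc$types["o1", "x1"]), "polyserial")
    expect_equal(unname(mc$types["x1", "x2"]), "pearson")
    expect_true(isSymmetric(mc$R))
    expect_true(all(eigen(mc$R, symmetric = TRUE, only.values = TRUE)$values > 0))

    # permuting variable order permutes the matrix consistently
    mc_p <- mixed_cor(d, items = c("o2", "o1"), covariates = c("x2", "x1"))
    expect_equal(mc_p$R[rownames(mc$R), colnames(mc$R)], mc$R, tolerance = 1e-10)

    expect_error(mixed_cor(d, items = c("o1", "o2"), covariates = "x1",
                           min_n = n + 1), "minimum pairwise n")
  })
})

test_that("synthetic-cohort moment matrices are PSD without repair", {
  repaired <- vapply(1:20, function(s) {
    cfg <- sim_config(n_families = 1000, n_variants = 30, seed = 300 + s)
    sim <- simulate_cohort(cfg)
    co <- sim$cohort
    co$prs <- co$prs_true
    mc <- mixed_cor(co, items = cfg$loading_plan$item,
                    covariates = c("prs", "sex", "age"), compute_if = FALSE)
    mc$repaired
  }, TRUE)
  expect_lte(mean(repaired), 0.05)
})
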