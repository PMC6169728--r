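# Model specification, DWLS fitting, robust inference, fit indices, and the
# scaled difference test.

covs9 <- c("prs", "sex", "age", paste0("pc", 1:6))

test_that("free-parameter enumeration matches hand counts", {
  m2 <- gf_model(list(f1 = c("a", "b", "c"), f2 = c("d", "e", "f")),
                 general = FALSE)
  expect_equal(count_free_parameters(m2)$n_free, 7)   # 6 loadings + 1 correlation
  m2g <- gf_model(list(f1 = c("a", "b", "c"), f2 = c("d", "e", "f")),
                  general = TRUE)
  expect_equal(count_free_parameters(m2g)$n_free, 13) # + 6 general loadings

  # one factor, 3 items: 3 moments - 3 loadings = just-identified
  m1 <- gf_model(list(f = c("a", "b", "c")), general = FALSE)
  expect_equal(count_free_parameters(m1)$df, 0)

  expect_error(gf_model(list(f1 = c("a", "b"), f2 = c("b", "c"))),
               "more than one")
  expect_error(count_free_parameters(
    gf_model(list(f = c("a", "b")), general = FALSE)
  ), "under-identified")
})

test_that("df bookkeeping reproduces the published questionnaire designs", {
  mc_ <- count_free_parameters(gf_model(atac_design(), FALSE, covs9))
  mg_ <- count_free_parameters(gf_model(atac_design(), TRUE, covs9))
  expect_equal(mc_$df, 2287)
  expect_equal(mg_$df, 2216)
  expect_equal(mg_$n_free - mc_$n_free, 71)
})

test_that("exactly structured matrices are recovered with zero discrepancy", {
  # one factor, loadings 0.6: off-diagonals 0.36
  items1 <- c("a", "b", "c")
  R1 <- matrix(0.36, 3, 3); diag(R1) <- 1
  dimnames(R1) <- list(items1, items1)
  f1 <- fit_gsem(fake_mc(R1, items1), gf_model(list(f = items1), FALSE))
  expect_equal(unname(f1$par$estimate[f1$par$type == "loading_s"]),
               rep(0.6, 3), tolerance = 1e-5)
  expect_lt(f1$F_min, 1e-10)

  # two factors, loadings 0.6, factor correlation 0.5: exact recovery
  items2 <- c("a1", "a2", "a3", "b1", "b2", "b3")
  L <- matrix(0, 6, 2); L[1:3, 1] <- 0.6; L[4:6, 2] <- 0.6
  R2 <- L %*% matrix(c(1, 0.5, 0.5, 1), 2) %*% t(L); diag(R2) <- 1
  dimnames(R2) <- list(items2, items2)
  mod2 <- gf_model(list(fa = items2[1:3], fb = items2[4:6]), FALSE)
  f2 <- fit_gsem(fake_mc(R2, items2), mod2)
  expect_equal(unname(f2$par$estimate[f2$par$type == "factor_cor"]), 0.5,
               tolerance = 1e-5)
  expect_lt(f2$chisq_scaled, 1e-6)
  expect_equal(f2$cfi, 1)
  expect_equal(f2$rmsea, 0)

  # sign indeterminacy: an all-negative solution is flipped to positive
  f1n <- fit_gsem(fake_mc(R1, items1), gf_model(list(f = items1), FALSE),
                  control = list(maxiter = 400))
  expect_true(all(f1n$par$estimate[f1n$par$type == "loading_s"] > 0))
})

test_that("fixing general loadings at zero reproduces the correlated-factors fit", {
  cfg <- small_config(seed = 21)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fmap <- config_factor_map(cfg)
  mc <- mixed_cor(co, cfg$loading_plan$item, c("prs", "sex"))
  fit_c <- fit_gsem(mc, gf_model(fmap, FALSE, c("prs", "sex")))
  items <- cfg$loading_plan$item
  fx <- c(
    setNames(rep(0, length(items)), paste0("lambda_g[", items, "]")),
    setNames(rep(0, 2), paste0("beta[g,", c("prs", "sex"), "]"))
  )
  fit_g0 <- fit_gsem(mc, gf_model(fmap, TRUE, c("prs", "sex")), fixed = fx)
  expect_equal(fit_g0$F_min, fit_c$F_min, tolerance = 1e-8)
  expect_equal(count_free_parameters(gf_model(fmap, TRUE, c("prs", "sex")),
                                     fixed = fx)$df,
               count_free_parameters(gf_model(fmap, FALSE, c("prs", "sex")))$df)
})

test_that("the discrepancy is invariant to item and factor reordering", {
  cfg <- small_config(seed = 22)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fmap <- config_factor_map(cfg)
  mc <- mixed_cor(co, cfg$loading_plan$item, "prs")
  f_a <- fit_gsem(mc, gf_model(fmap, FALSE, "prs"))
  fmap_r <- rev(lapply(fmap, rev))
  f_b <- fit_gsem(mc, gf_model(fmap_r, FALSE, "prs"))
  expect_equal(f_a$F_min, f_b$F_min, tolerance = 1e-6)
  expect_equal(f_a$chisq_scaled, f_b$chisq_scaled, tolerance = 1e-4)
})

test_that("standardized betas are invariant to covariate rescaling", {
  cfg <- small_config(seed = 23)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fmap <- config_factor_map(cfg)
  f1 <- fit_gsem(co, gf_model(fmap, FALSE, c("prs", "sex")))
  co2 <- co; co2$prs <- co2$prs * 2
  f2 <- fit_gsem(co2, gf_model(fmap, FALSE, c("prs", "sex")))
  b1 <- latent_regressions(f1); b2 <- latent_regressions(f2)
  expect_equal(b1$beta, b2$beta, tolerance = 1e-6)
  expect_equal(b1$r2_pct, b1$beta^2 * 100)  # R^2 = beta^2 exactly
})

test_that("collinear covariates are rejected", {
  cfg <- small_config(seed = 24)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  co$prs_copy <- co$prs
  expect_error(
    fit_gsem(co, gf_model(config_factor_map(cfg), FALSE, c("prs", "prs_copy"))),
    "Collinear"
  )
})

test_that("sandwich and naive standard errors coincide under singleton clusters", {
  cfg <- small_config(seed = 25)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fmap <- config_factor_map(cfg)
  fit <- fit_gsem(co, gf_model(fmap, FALSE, "prs"), clusters = co$family_id)
  expect_warning(fit_ind <- sandwich_se(fit, seq_len(nrow(co))), "singleton")
  naive <- sqrt(diag(fit$vcov_naive))
  ratio <- fit_ind$par$se[fit_ind$par$free] / naive
  expect_true(all(ratio > 0.9 & ratio < 1.1))
  expect_error(sandwich_se(fit, co$family_id[-1]), "length")
  expect_error(sandwich_se(fit, c(co$family_id[-1], NA)), "cluster")
})

test_that("duplicating every family leaves sandwich SEs nearly unchanged", {
  cfg <- small_config(seed = 26)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fmap <- config_factor_map(cfg)
  fit <- fit_gsem(co, gf_model(fmap, FALSE, "prs"), clusters = co$family_id)
  co2 <- dplyr::bind_rows(co, co)
  fit2 <- fit_gsem(co2, gf_model(fmap, FALSE, "prs"), clusters = co2$family_id)
  b1 <- latent_regressions(fit); b2 <- latent_regressions(fit2)
  expect_equal(b2$beta, b1$beta, tolerance = 1e-3)
  # duplication doubles the raw chi-square scale but not the clustered SEs
  expect_gt(fit2$chisq / fit$chisq, 1.6)
  expect_true(all(b2$se / b1$se > 0.9 & b2$se / b1$se < 1.1))
  # naive SEs, by contrast, shrink by about 1/sqrt(2)
  n2 <- sqrt(diag(fit2$vcov_naive)) / sqrt(diag(fit$vcov_naive))
  expect_lt(median(n2), 0.8)
})

test_that("RMSEA confidence limits match a brute-force noncentrality search", {
  brute_ncp <- function(T_stat, df, target) {
    f <- function(l) pchisq(T_stat, df, ncp = l) - target
    if (f(0) < target - 1) return(0)
    grid <- seq(0, T_stat * 3 + 20, by = 0.05)
    v <- vapply(grid, f, 0)
    if (all(v < 0)) return(0)
    k <- which(v < 0)[1]
    if (is.na(k) || k == 1) return(0)
    uniroot(f, c(grid[k - 1], grid[k]))$root
  }
  for (case in list(c(120, 80, 1000), c(35, 40, 500), c(300, 115, 4000))) {
    T_ <- case[1]; df_ <- case[2]; n_ <- case[3]
    ci <- genfactor:::rmsea_ci(T_, df_, n_)
    lo <- sqrt(brute_ncp(T_, df_, 0.95) / (n_ * df_))
    hi <- sqrt(brute_ncp(T_, df_, 0.05) / (n_ * df_))
    expect_equal(ci[1], lo, tolerance = 1e-4)
    expect_equal(ci[2], hi, tolerance = 1e-4)
  }
})

test_that("the nested difference test rejects degenerate comparisons", {
  cfg <- small_config(seed = 27)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fmap <- config_factor_map(cfg)
  mc <- mixed_cor(co, cfg$loading_plan$item, "prs")
  fit_c <- fit_gsem(mc, gf_model(fmap, FALSE, "prs"))
  fit_g <- fit_gsem(mc, gf_model(fmap, TRUE, "prs"))
  expect_error(nested_difference_test(fit_c, fit_c), "delta df = 0")
  dt <- nested_difference_test(fit_c, fit_g)
  expect_equal(dt$delta_df, length(cfg$loading_plan$item) + 1)
  expect_gte(dt$p_value, 0)
  expect_lte(dt$p_value, 1)
  # swapped direction: full model's parameters are not a subset
  expect_error(nested_difference_test(fit_g, fit_c), "not a subset")
})

test_that("the difference test is calibrated for a regular (interior) nesting", {
  # Fixing one regression path at its true interior value of zero is a
  # regular nesting (unlike removing the whole general factor, which puts
  # the restricted model on a boundary): the scaled difference test should
  # reject at the nominal rate.
  lp <- default_loading_plan(3)
  fmap <- split(lp$item, lp$factor)[unique(lp$factor)]
  fx <- c("beta[g,prs]" = 0)
  p_vals <- vapply(1:100, function(s) {
    cfg <- sim_config(n_families = 600, n_variants = 50, gamma_gp = 0,
                      gamma_hi = 0, loading_plan = lp,
                      covariate_effects = list(), seed = 70000 + s)
    sim <- simulate_cohort(cfg)
    co <- sim$cohort
    co$prs <- co$prs_true
    mc <- suppressWarnings(mixed_cor(co, lp$item, "prs"))
    mod <- gf_model(fmap, TRUE, "prs")
    f_r <- suppressWarnings(fit_gsem(mc, mod, clusters = co$family_id, fixed = fx))
    f_f <- suppressWarnings(fit_gsem(mc, mod, clusters = co$family_id))
    suppressWarnings(nested_difference_test(f_r, f_f))$p_value
  }, 0)
  n_rej <- sum(p_vals < 0.05)
  expect_gte(n_rej, qbinom(0.025, 100, 0.05))
  expect_lte(n_rej, qbinom(0.975, 100, 0.05))
})

test_that("tidiers and autoplot return well-formed objects", {
  cfg <- small_config(seed = 28)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort; co$prs <- co$prs_true
  fit <- fit_gsem(co, gf_model(config_factor_map(cfg), TRUE, "prs"),
                  clusters = co$family_id)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), nrow(fit$model$par))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
  mc <- mixed_cor(co, cfg$loading_plan$item[1:8], "prs")
  expect_s3_class(autoplot(mc), "ggplot")
})
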