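# The synthetic twin-cohort generator: validation, determinism, and the
# statistical structure it promises.

test_that("configuration validation rejects bad fields by name", {
  expect_error(sim_config(causal_fraction = NaN), "causal_fraction")
  expect_error(sim_config(mz_fraction = 1.4), "mz_fraction")
  expect_error(sim_config(n_eff_discovery = -10), "n_eff_discovery")
  lp <- default_loading_plan()
  lp$lambda_g[3] <- 0.9
  lp$lambda_s[3] <- 0.9
  expect_error(sim_config(loading_plan = lp), "communality")
  tp <- tibble::tibble(item = default_loading_plan()$item, tau1 = 1, tau2 = 0.5)
  expect_error(sim_config(threshold_plan = tp), "strictly increasing")
})

test_that("every generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$cohort, b$cohort)
  expect_identical(rlang::hash(a$cohort), rlang::hash(b$cohort))
})

test_that("null discovery GWAS yields standard-normal z and ~5% significance", {
  cfg <- sim_config(n_variants = 10000, causal_fraction = 0, n_families = 2, seed = 2)
  ss <- simulate_discovery_sumstats(cfg)
  expect_true(all(ss$beta_true == 0))
  frac <- mean(ss$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000) + 1e-9)
  expect_lt(abs(mean(ss$z)), 0.05)
  expect_lt(abs(sd(ss$z) - 1), 0.05)
})

test_that("significant fraction matches closed-form power at genome-wide alpha", {
  # standardized effect chosen so two-sided power at alpha = 5e-8 is 0.5
  zcrit <- qnorm(1 - 2.5e-8)
  b <- zcrit / sqrt(50000)
  cfg <- sim_config(n_variants = 1000, n_eff_discovery = 50000,
                    n_families = 2, seed = 4)
  ss <- simulate_discovery_sumstats(cfg, beta_std = rep(b, 1000))
  frac <- mean(ss$p_value < 5e-8)
  expect_lt(abs(frac - 0.5), 1.96 * sqrt(0.25 / 1000))
})

test_that("MZ pairs share genotypes; DZ pairs share about half", {
  cfg <- sim_config(n_families = 2000, n_variants = 300, mz_fraction = 0.3, seed = 6)
  ss <- simulate_discovery_sumstats(cfg)
  panel <- simulate_twin_genotypes(cfg, ss)
  sm <- panel$samples
  expect_equal(sum(sm$zygosity == "MZ") / 2, 600)   # deterministic allocation
  expect_equal(sum(sm$zygosity == "DZ") / 2, 1400)
  mz1 <- panel$dosage[sm$zygosity == "MZ" & sm$member == 1, ]
  mz2 <- panel$dosage[sm$zygosity == "MZ" & sm$member == 2, ]
  expect_true(all(mz1 == mz2))
  dz1 <- panel$dosage[sm$zygosity == "DZ" & sm$member == 1, ]
  dz2 <- panel$dosage[sm$zygosity == "DZ" & sm$member == 2, ]
  # per-variant correlation of co-twin dosages across DZ families
  rv <- vapply(seq_len(ncol(dz1)), function(j) cor(dz1[, j], dz2[, j]), 0)
  expect_lt(abs(mean(rv) - 0.5), 0.05)
  # population allele frequency reproduces the generating frequency
  phat <- colMeans(panel$dosage) / 2
  expect_lt(max(abs(phat - ss$allele_freq)), 0.02)
})

test_that("item category frequencies match threshold-implied normal orthants", {
  lp <- tibble::tibble(
    item = c("a_1", "a_2", "b_1", "b_2"), factor = c("a", "a", "b", "b"),
    lambda_g = c(0.6, 0.6, 0, 0), lambda_s = c(0.5, 0.5, 0.6, 0.4)
  )
  tp <- tibble::tibble(item = lp$item, tau1 = -0.5, tau2 = 0.5)
  cfg <- sim_config(
    n_families = 5000, n_variants = 10, gamma_gp = 0, gamma_hi = 0,
    loading_plan = lp, threshold_plan = tp, covariate_effects = list(),
    seed = 8
  )
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  # a_1 x a_2 cross-table vs bivariate-normal cell probabilities at the
  # implied latent correlation 0.6^2 + 0.5^2 (orthogonal GP and specifics)
  rho <- 0.6^2 + 0.5^2
  tab <- table(factor(co$a_1, 0:2), factor(co$a_2, 0:2)) / nrow(co)
  expected <- ordinal_cell_probs(c(-0.5, 0.5), c(-0.5, 0.5), rho)
  expect_lt(max(abs(as.matrix(tab) - expected)), 0.02)
  # univariate margins
  expect_lt(max(abs(as.numeric(table(co$b_1)) / nrow(co) -
                      c(pnorm(-0.5), pnorm(0.5) - pnorm(-0.5), 1 - pnorm(0.5)))),
            0.02)
})

test_that("zero general loadings leave cross-scale items uncorrelated", {
  lp <- default_loading_plan()
  lp$lambda_g <- 0
  cfg <- sim_config(n_families = 2000, n_variants = 10, gamma_gp = 0,
                    gamma_hi = 0, covariate_effects = list(),
                    loading_plan = lp, seed = 12)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  cross <- polychoric(co$ia_1, co$dep_1)$rho
  expect_lt(abs(cross), 0.05)
})

test_that("communality violations are rejected naming the item", {
  lp <- default_loading_plan()
  lp$lambda_g[5] <- 0.95
  lp$lambda_s[5] <- 0.5
  expect_error(sim_config(loading_plan = lp), lp$item[5])
})

test_that("zero exclusion prevalence means exclusions remove nobody", {
  cfg <- small_config(seed = 3, exclusion_prevalence = 0)
  sim <- simulate_cohort(cfg)
  out <- apply_exclusions(sim$cohort)
  expect_equal(nrow(out), nrow(sim$cohort))
  expect_true(all(attr(out, "removals")$n == 0))
})

test_that("truth record round-trips losslessly through JSON", {
  sim <- simulate_cohort(small_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$loading_plan, sim$truth$loading_plan)
  expect_equal(back$gamma_gp, sim$truth$gamma_gp)
  expect_equal(back$variant_effects$beta_true, sim$truth$variant_effects$beta_true)
})
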