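# PRS construction: standardization, QC filtering, clumping, scoring,
# MZ imputation.

test_that("standardized betas follow the z / sqrt(2p(1-p)(n+z^2)) conversion", {
  expect_equal(standardize_beta(0, 1e4, 0.3), 0)
  expect_equal(standardize_beta(-2.5, 1e4, 0.3),
               -standardize_beta(2.5, 1e4, 0.3))
  # direct arithmetic: z = 5, p = 0.5, n = 50000 -> 5 / sqrt(0.5 * 50025)
  expect_equal(standardize_beta(5, 50000, 0.5), 5 / sqrt(0.5 * 50025),
               tolerance = 1e-12)
  expect_equal(standardize_beta(5, 50000, 0.5), 0.031615, tolerance = 1e-4)
  expect_error(standardize_beta(1, 50000, 0, variant_id = "rs1"), "rs1")
  expect_error(standardize_beta(1, -3, 0.2, variant_id = "rs9"), "rs9")
})

test_that("variant filtering applies MAF, INFO, and allele-type rules", {
  empty <- filter_variants(tibble::tibble(
    variant_id = character(0), allele_freq = numeric(0), info = numeric(0),
    is_indel = logical(0), is_multiallelic = logical(0), is_ambiguous = logical(0)
  ))
  expect_equal(nrow(empty), 0)
  expect_true(all(attr(empty, "removals")$n == 0))

  toy <- tibble::tibble(
    variant_id = paste0("v", 1:6),
    allele_freq = c(0.3, 0.2, 0.4, 0.97, 0.25, 0.45),
    info = c(0.95, 0.99, 0.5, 0.9, 0.92, 0.97),
    is_indel = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_multiallelic = FALSE,
    is_ambiguous = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  out <- filter_variants(toy)
  # one indel, one A/T-ambiguous, one INFO 0.5, one MAF 0.03 -> v1, v6 remain
  # of the three clean records plus the high-frequency one is dropped
  expect_equal(out$variant_id, c("v1", "v6"))
  tal <- attr(out, "removals")
  expect_equal(tal$n[tal$reason == "indel"], 1L)
  expect_equal(tal$n[tal$reason == "ambiguous"], 1L)
  expect_equal(tal$n[tal$reason == "info"], 1L)
  expect_equal(tal$n[tal$reason == "maf"], 1L)

  # allele_freq 0.97 -> MAF 0.03 < 0.05, excluded at the default threshold
  one <- toy[4, ]
  expect_equal(nrow(filter_variants(one)), 0)
  expect_equal(nrow(filter_variants(one, maf_min = 0.01)), 1)
})

test_that("greedy clumping follows the smallest-p index / window / r2 rule", {
  rec <- tibble::tibble(
    variant_id = c("A", "B", "C"),
    chromosome = c(1, 1, 1),
    position = c(1e6, 1e6 + 1e5, 1e6 + 1.5e6),
    p_value = c(1e-8, 1e-4, 1e-3)
  )
  ld <- tibble::tibble(var_a = "A", var_b = "B", r2 = 0.25)
  out <- clump_variants(rec, ld, r2_max = 0.1, window_kb = 1000)
  expect_setequal(out$variant_id, c("A", "C"))
  expect_equal(attr(out, "clumps")$member, "B")

  single <- clump_variants(rec[1, ], ld)
  expect_equal(single$variant_id, "A")
})

test_that("clumping on a panel errors for variants absent from the LD source", {
  sim <- simulate_cohort(small_config(seed = 2))
  rec <- sim$sumstats[1:5, ]
  rec$variant_id[3] <- "not_there"
  expect_error(clump_variants(rec, sim$panel), "not_there")
})

test_that("scoring implements no-mean-imputation average-per-allele semantics", {
  cfg <- sim_config(n_families = 3, n_variants = 2, seed = 1)
  ss <- simulate_discovery_sumstats(cfg)
  panel <- simulate_twin_genotypes(cfg, ss)
  panel$dosage[1, ] <- c(2, 1)
  eff <- tibble::tibble(variant_id = ss$variant_id,
                        beta_std = c(0.1, -0.2), p_value = c(0.01, 0.01))
  out <- score_prs(panel, eff, thresholds = 1)
  # (2 * 0.1 + 1 * -0.2) / (2 * 2) = 0
  expect_equal(out$raw[out$sample_id == panel$samples$sample_id[1]], 0)

  # a missing genotype shrinks that sample's denominator only
  panel$dosage[2, 2] <- NA
  out2 <- score_prs(panel, eff, thresholds = 1)
  expect_equal(out2$n_used[2], 1L)
  expect_equal(out2$n_used[1], 2L)
  expect_equal(out2$raw[2], panel$dosage[2, 1] * 0.1 / 2)

  # zero effects give zero scores
  eff0 <- eff
  eff0$beta_std <- 0
  expect_true(all(score_prs(panel, eff0, thresholds = 1)$raw == 0))

  # linearity: scaling all betas by c scales raw scores by c
  eff3 <- eff
  eff3$beta_std <- eff$beta_std * 3
  expect_equal(score_prs(panel, eff3, thresholds = 1)$raw, out2$raw * 3)
})

test_that("threshold sets are nested and empty thresholds yield NA", {
  sim <- simulate_cohort(small_config(seed = 4))
  eff <- add_standardized_beta(sim$sumstats)
  out <- score_prs(sim$panel, eff, thresholds = c(1e-12, 1e-3, 0.1, 1))
  wide <- tidyr::pivot_wider(out, id_cols = "sample_id",
                             names_from = "threshold", values_from = "n_used")
  counts <- apply(wide[, -1], 1, function(x) all(diff(x) >= 0))
  expect_true(all(counts))
  n_at <- vapply(c(1e-3, 0.1, 1),
                 function(t) sum(eff$p_value <= t), 0)
  expect_true(all(diff(n_at) > 0))
  if (all(eff$p_value > 1e-12)) {
    expect_true(all(is.na(out$raw[out$threshold == 1e-12])))
  }
})

test_that("MZ imputation copies dosages verbatim and propagates to scores", {
  sim <- simulate_cohort(small_config(seed = 6))
  panel <- sim$panel
  expect_identical(impute_mz_genotypes(panel, tibble::tibble()), panel)

  src <- panel$samples$sample_id[1]
  p2 <- impute_mz_genotypes(panel, tibble::tibble(sample_id = "new_twin",
                                                  co_twin = src))
  expect_equal(unname(p2$dosage["new_twin", ]), unname(panel$dosage[src, ]))
  expect_equal(p2$samples$imputed_from[p2$samples$sample_id == "new_twin"], src)

  eff <- add_standardized_beta(sim$sumstats)
  sc <- score_prs(p2, eff, thresholds = 0.5)
  expect_equal(sc$raw[sc$sample_id == "new_twin"], sc$raw[sc$sample_id == src])

  expect_error(
    impute_mz_genotypes(panel, tibble::tibble(sample_id = "x", co_twin = "ghost")),
    "ghost"
  )
})

test_that("null discovery statistics give calibrated phenotype associations", {
  # with causal_fraction = 0, regressing an independent phenotype on the PRS
  # rejects at the nominal 5% rate
  rej <- vapply(1:200, function(s) {
    cfg <- sim_config(n_families = 150, n_variants = 80, causal_fraction = 0,
                      seed = 5000 + s)
    ss <- simulate_discovery_sumstats(cfg)
    panel <- simulate_twin_genotypes(cfg, ss)
    prs <- score_prs(panel, add_standardized_beta(ss), thresholds = 1)
    y <- withr::with_seed(s, rnorm(nrow(panel$samples)))
    summary(lm(y ~ prs$std))$coefficients[2, 4] < 0.05
  }, TRUE)
  expect_gte(sum(rej), qbinom(0.005, 200, 0.05))
  expect_lte(sum(rej), qbinom(0.995, 200, 0.05))
})
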