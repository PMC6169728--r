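# Synthetic twin-cohort generator: discovery GWAS summary statistics, twin
# genotypes under Mendelian transmission, and graded 0/1/2 item responses from
# a bifactor latent structure with a causal polygenic score.

NUCS <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate discovery GWAS summary statistics
#'
#' Generates per-variant z-scores as
#' \eqn{z = \sqrt{n_{eff}} \, b \sqrt{2p(1-p)} + \epsilon}, \eqn{\epsilon \sim N(0,1)},
#' where `b` is the per-allele true effect (zero for non-causal variants) and
#' `p` the effect-allele frequency. Standardized true effects of causal
#' variants are drawn so their squared sum equals `heritability_target`.
#' Configured fractions of variants are flagged as indels, strand-ambiguous
#' (A/T or C/G), or poorly imputed, to exercise downstream QC filters.
#'
#' @param config A [sim_config()].
#' @param beta_std Optional numeric vector (length `n_variants`) of
#'   standardized true effects, overriding the random draw (used for
#'   closed-form power checks).
#' @return A tibble of summary-statistic records: `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `z`, `p_value`,
#'   `allele_freq`, `n_eff`, `info`, flag columns, and the generating
#'   `beta_true` (per-allele truth; dropped by [write_sumstats()]).
#' @export
simulate_discovery_sumstats <- function(config, beta_std = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants
  withr::with_seed(config$seed, {
    # positions: contiguous chromosome chunks with irregular spacing
    chrom <- sort(rep_len(seq_len(22L), m))
    position <- integer(m)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      position[idx] <- cumsum(as.integer(runif(length(idx), 5e4, 4e5))) + 1e6L
    }
    if (config$ld_block_size > 1L) {
      block <- (seq_len(m) - 1L) %/% config$ld_block_size
      pblock <- runif(max(block) + 1L, 0.05, 0.5)
      freq <- pblock[block + 1L]
    } else {
      freq <- runif(m, 0.01, 0.5)
    }
    n_causal <- round(config$causal_fraction * m)
    bstd <- numeric(m)
    if (!is.null(beta_std)) {
      stopifnot(length(beta_std) == m)
      bstd <- beta_std
    } else if (n_causal > 0) {
      causal <- sample.int(m, n_causal)
      bstd[causal] <- rnorm(n_causal, 0, sqrt(config$heritability_target / n_causal))
    }
    beta_true <- bstd / sqrt(2 * freq * (1 - freq))
    z <- sqrt(config$n_eff_discovery) * bstd + rnorm(m)

    is_indel <- seq_len(m) %in% sample.int(m, round(config$indel_fraction * m))
    is_ambiguous <- seq_len(m) %in% sample.int(m, round(config$ambiguous_fraction * m))
    low_info <- seq_len(m) %in% sample.int(m, round(config$low_info_fraction * m))
    info <- ifelse(low_info, runif(m, 0.3, 0.8), runif(m, 0.9, 1.0))

    ea <- sample(NUCS, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(NUCS, c(a, COMPLEMENT[[a]])), 1L), "")
    oa[is_ambiguous] <- COMPLEMENT[ea[is_ambiguous]]
    oa[is_indel] <- paste0(ea[is_indel], "A")

    tibble(
      variant_id = sprintf("v%05d", seq_len(m)),
      chromosome = chrom,
      position = position,
      effect_allele = unname(ea),
      other_allele = unname(oa),
      z = z,
      p_value = 2 * pnorm(-abs(z)),
      allele_freq = freq,
      n_eff = config$n_eff_discovery,
      info = info,
      is_indel = is_indel,
      is_multiallelic = FALSE,
      is_ambiguous = is_ambiguous,
      beta_true = beta_true
    )
  })
}

#' Simulate twin genotypes by Mendelian transmission
#'
#' Draws parental haplotypes per variant from the effect-allele frequency and
#' transmits one allele per parent to each child. Monozygotic pairs receive
#' identical dosage vectors; dizygotic co-twins draw independent
#' transmissions, sharing each parental allele with probability 1/2. MZ/DZ
#' allocation is deterministic: the first `round(mz_fraction * n_families)`
#' families are MZ. An optional exchangeable within-block haplotype
#' correlation (see [sim_config()]) provides toy LD for clumping exercises.
#'
#' @param config A [sim_config()].
#' @param variants Tibble of variant metadata carrying at least `variant_id`
#'   and `allele_freq` (typically the output of
#'   [simulate_discovery_sumstats()]).
#' @return An object of class `genotype_panel`: list with `samples` (tibble:
#'   `sample_id`, `family_id`, `zygosity`, `member`, `imputed_from`),
#'   `variants`, and `dosage` (samples x variants matrix with entries 0..2;
#'   `NA` marks missing genotypes).
#' @export
simulate_twin_genotypes <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  variants <- as_tibble(variants)
  if (!all(c("variant_id", "allele_freq") %in% names(variants))) {
    abort("variants must carry variant_id and allele_freq columns.")
  }
  nf <- config$n_families
  m <- nrow(variants)
  p <- variants$allele_freq
  withr::with_seed(config$seed + 1L, {
    draw_hap <- function() {
      if (config$ld_block_size > 1L) {
        block <- (seq_len(m) - 1L) %/% config$ld_block_size
        nb <- max(block) + 1L
        pb <- p[!duplicated(block)]
        core <- matrix(rbinom(nf * nb, 1L, rep(pb, each = nf)), nf, nb)
        w <- sqrt(config$ld_r2)
        copy <- matrix(rbinom(nf * m, 1L, w), nf, m)
        indep <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
        copy * core[, block + 1L, drop = FALSE] + (1L - copy) * indep
      } else {
        matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
      }
    }
    M1 <- draw_hap(); M2 <- draw_hap(); F1 <- draw_hap(); F2 <- draw_hap()
    pick <- function() matrix(rbinom(nf * m, 1L, 0.5), nf, m)
    child_from <- function(S, T_) S * M1 + (1L - S) * M2 + T_ * F1 + (1L - T_) * F2
    child1 <- child_from(pick(), pick())
    child2 <- child_from(pick(), pick())
    n_mz <- round(config$mz_fraction * nf)
    if (n_mz > 0) child2[seq_len(n_mz), ] <- child1[seq_len(n_mz), , drop = FALSE]

    family_id <- sprintf("fam%05d", seq_len(nf))
    zyg <- c(rep("MZ", n_mz), rep("DZ", nf - n_mz))
    # family-major order: fam1 twin1, fam1 twin2, fam2 twin1, ...
    dosage <- matrix(0L, 2L * nf, m)
    dosage[seq(1L, 2L * nf, by = 2L), ] <- child1
    dosage[seq(2L, 2L * nf, by = 2L), ] <- child2
    sample_id <- paste0(rep(family_id, each = 2L), "_", rep(1:2, nf))
    rownames(dosage) <- sample_id
    colnames(dosage) <- variants$variant_id
    structure(
      list(
        samples = tibble(
          sample_id = sample_id,
          family_id = rep(family_id, each = 2L),
          zygosity = rep(zyg, each = 2L),
          member = rep(1:2, nf),
          imputed_from = NA_character_
        ),
        variants = variants,
        dosage = dosage
      ),
      class = "genotype_panel"
    )
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " variants (", sum(is.na(x$dosage)), " missing dosages)\n", sep = "")
  invisible(x)
}

# standardized covariate value used in the factor equations
std_covariates <- function(cov_df) {
  cbind(
    sex = (cov_df$sex - 0.5) / 0.5,
    age = (cov_df$age - 10.5) / 1.5,
    pc1 = cov_df$pc1, pc2 = cov_df$pc2, pc3 = cov_df$pc3,
    pc4 = cov_df$pc4, pc5 = cov_df$pc5, pc6 = cov_df$pc6
  )
}

#' Simulate graded item responses from a bifactor latent structure
#'
#' Builds, for each child, a general psychopathology factor
#' `GP = gamma_gp * PRS + covariate effects + family-shared residual +
#' individual residual` (total variance 1), analogous specific factors with
#' residuals orthogonal to GP, and latent item responses
#' `y* = lambda_g GP + lambda_s S + e` with unit total variance. Observed
#' items count the thresholds exceeded (0/1/2). Covariates (sex, age, six
#' PCs) are generated here; PCs and age are family-shared, sex is shared for
#' MZ pairs only.
#'
#' @param panel A `genotype_panel` whose `variants` carry `beta_true`.
#' @param config A [sim_config()].
#' @return A list with `cohort` (one row per child: ids, zygosity,
#'   covariates, standardized true polygenic score `prs_true`, item
#'   responses, per-dimension endorsed-symptom counts) and `truth` (a
#'   `truth_record` with every generating parameter).
#' @export
simulate_item_responses <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (!"beta_true" %in% names(panel$variants)) {
    abort("panel$variants must carry beta_true (generating per-allele effects).")
  }
  lp <- config$loading_plan
  tp <- config$threshold_plan[match(lp$item, config$threshold_plan$item), ]
  comm <- lp$lambda_g^2 + lp$lambda_s^2
  if (any(comm > 1 + 1e-12)) {
    abort(paste0("Item '", lp$item[which.max(comm)], "' has communality > 1."))
  }
  samples <- panel$samples
  n <- nrow(samples)
  nf <- length(unique(samples$family_id))
  fam_idx <- match(samples$family_id, unique(samples$family_id))

  g_raw <- as.numeric(panel$dosage %*% panel$variants$beta_true)
  prs_true <- if (sd(g_raw) > 0) as.numeric(scale(g_raw)) else g_raw * 0

  withr::with_seed(config$seed + 2L, {
    # covariates
    sex_fam <- rbinom(nf, 1L, 0.5)
    sex <- sex_fam[fam_idx]
    dz <- samples$zygosity == "DZ" & samples$member == 2L
    sex[dz] <- rbinom(sum(dz), 1L, 0.5)
    age_fam <- sample(c(9L, 12L), nf, replace = TRUE)
    pcs <- matrix(rnorm(nf * 6L), nf, 6L)
    cov_df <- tibble(
      sex = sex, age = age_fam[fam_idx],
      pc1 = pcs[fam_idx, 1], pc2 = pcs[fam_idx, 2], pc3 = pcs[fam_idx, 3],
      pc4 = pcs[fam_idx, 4], pc5 = pcs[fam_idx, 5], pc6 = pcs[fam_idx, 6]
    )
    X <- std_covariates(cov_df)

    factors <- unique(lp$factor)
    gamma_of <- function(f) {
      if (f == "gp") config$gamma_gp else if (f == "hi") config$gamma_hi else 0
    }
    cov_eff <- function(f) {
      ce <- config$covariate_effects[[f]] %||% numeric(0)
      out <- setNames(numeric(ncol(X)), colnames(X))
      out[names(ce)] <- ce
      out
    }
    make_factor <- function(f) {
      g <- gamma_of(f)
      ce <- cov_eff(f)
      expl <- g^2 + sum(ce^2) + config$family_share
      if (expl >= 1) {
        abort(paste0("Factor '", f, "': explained variance share ", round(expl, 3),
                     " >= 1; reduce effects or family_share."))
      }
      fam_res <- rnorm(nf)[fam_idx] * sqrt(config$family_share)
      g * prs_true + as.numeric(X %*% ce) + fam_res + rnorm(n) * sqrt(1 - expl)
    }
    GP <- make_factor("gp")
    S <- vapply(factors, make_factor, numeric(n))
    cov_gs <- vapply(factors, function(f) {
      gamma_of("gp") * gamma_of(f) + sum(cov_eff("gp") * cov_eff(f))
    }, 0)

    items <- matrix(NA_integer_, n, nrow(lp))
    colnames(items) <- lp$item
    for (r in seq_len(nrow(lp))) {
      f <- lp$factor[r]
      v <- lp$lambda_g[r]^2 + lp$lambda_s[r]^2 +
        2 * lp$lambda_g[r] * lp$lambda_s[r] * cov_gs[[f]]
      if (v > 1) {
        abort(paste0("Item '", lp$item[r], "': implied latent-response variance > 1."))
      }
      ystar <- lp$lambda_g[r] * GP + lp$lambda_s[r] * S[, f] + rnorm(n) * sqrt(1 - v)
      items[, r] <- (ystar > tp$tau1[r]) + (ystar > tp$tau2[r])
    }

    count_dim <- function(scale) {
      cols <- lp$item[lp$factor == scale]
      if (!length(cols)) return(rep(0L, n))
      as.integer(rowSums(items[, cols, drop = FALSE] >= 1L))
    }
    cohort <- dplyr::bind_cols(
      samples[, c("sample_id", "family_id", "zygosity")],
      cov_df,
      tibble(prs_true = prs_true),
      as_tibble(items),
      tibble(dsm_ia_count = count_dim("ia"), dsm_hi_count = count_dim("hi"))
    ) %>% rename(child_id = "sample_id")

    truth <- structure(
      list(
        loading_plan = lp, threshold_plan = tp,
        gamma_gp = config$gamma_gp, gamma_hi = config$gamma_hi,
        covariate_effects = config$covariate_effects,
        family_share = config$family_share,
        factor_cov_gp = cov_gs,
        variant_effects = panel$variants[, c("variant_id", "allele_freq", "beta_true")],
        seed = config$seed
      ),
      class = "truth_record"
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a complete synthetic twin cohort
#'
#' One call produces every input the analysis pipeline needs: discovery
#' summary statistics, a twin genotype panel, a phenotype table with
#' covariates, item responses, exclusion-condition flags and an ADHD case
#' flag consistent with the endorsed-symptom counts, plus the ground-truth
#' record for parameter-recovery checks. Fully deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort_sim`: list with `cohort`, `panel`,
#'   `sumstats`, `truth`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 200, n_variants = 50))
#' dplyr::count(sim$cohort, zygosity)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sumstats <- simulate_discovery_sumstats(config)
  panel <- simulate_twin_genotypes(config, sumstats)
  resp <- simulate_item_responses(panel, config)
  cohort <- resp$cohort
  n <- nrow(cohort)
  withr::with_seed(config$seed + 3L, {
    prev <- config$exclusion_prevalence
    cohort$excl_cerebral_palsy <- rbinom(n, 1L, prev) == 1L
    cohort$excl_down_syndrome <- rbinom(n, 1L, prev) == 1L
    cohort$excl_brain_injury <- rbinom(n, 1L, prev) == 1L
    cohort$excl_chromosomal <- rbinom(n, 1L, prev) == 1L
    p_icd <- stats::plogis(config$icd_intercept +
                             config$icd_slope * (cohort$dsm_ia_count + cohort$dsm_hi_count))
    cohort$adhd_icd <- rbinom(n, 1L, p_icd) == 1L
  })
  cohort$adhd_dx <- cohort$adhd_icd |
    cohort$dsm_ia_count >= config$adhd_symptom_cutoff |
    cohort$dsm_hi_count >= config$adhd_symptom_cutoff
  structure(
    list(cohort = cohort, panel = panel, sumstats = sumstats, truth = resp$truth),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> ", nrow(x$cohort), " children in ",
      length(unique(x$cohort$family_id)), " families; ",
      ncol(x$panel$dosage), " variants; ",
      nrow(x$truth$loading_plan), " items\n", sep = "")
  invisible(x)
}
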