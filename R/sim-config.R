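# Simulation configuration for the synthetic twin cohort.

#' Default measurement design for the synthetic cohort
#'
#' A compact four-scale design (inattention, hyperactivity/impulsivity,
#' oppositional-defiant, depressive symptoms; four 0/1/2 items each) whose
#' generating loadings resemble published bifactor loadings of parent-rated
#' childhood symptoms: general loadings strongest for neurodevelopmental
#' items, weakest for internalizing items, with non-trivial specific loadings
#' throughout.
#'
#' @param n_items Items per scale (default 4).
#' @return A tibble with columns `item`, `factor`, `lambda_g`, `lambda_s`.
#' @export
default_loading_plan <- function(n_items = 4L) {
  # loadings vary within scale (general decreasing, specific increasing):
  # besides realism, non-proportional lambda_g : lambda_s within each scale
  # keeps the bifactor-with-correlated-specifics structure identified
  gen_range <- list(ia = c(0.80, 0.58), hi = c(0.65, 0.45),
                    odd = c(0.55, 0.40), dep = c(0.45, 0.28))
  spec_range <- list(ia = c(0.20, 0.55), hi = c(0.42, 0.62),
                     odd = c(0.50, 0.65), dep = c(0.55, 0.72))
  purrr::map_dfr(names(gen_range), function(sc) {
    tibble(
      item = paste0(sc, "_", seq_len(n_items)),
      factor = sc,
      lambda_g = seq(gen_range[[sc]][1], gen_range[[sc]][2], length.out = n_items),
      lambda_s = seq(spec_range[[sc]][1], spec_range[[sc]][2], length.out = n_items)
    )
  })
}

#' Simulation configuration for a synthetic twin cohort
#'
#' Bundles the generating parameters for the discovery GWAS, the twin
#' genotypes, and the graded item responses. Defaults define the reference
#' study conditions used throughout the package's calibration and recovery
#' checks: a polygenic score that loads on a general psychopathology factor
#' (standardized effect `gamma_gp`) and on the specific
#' hyperactivity/impulsivity factor (`gamma_hi`), orthogonal specific factors,
#' family-shared environmental clustering, and 0/1/2 items produced by
#' thresholding latent normal responses.
#'
#' @param n_variants Number of discovery variants.
#' @param causal_fraction Fraction of variants with non-zero effects.
#' @param heritability_target Variance of the standardized true score
#'   attributable to the causal variants (SNP-heritability analogue, 0.22 as
#'   for clinical ADHD).
#' @param n_eff_discovery Effective discovery sample size (51,000 mirrors a
#'   20k-case / 35k-control case-control GWAS).
#' @param n_families Number of twin pairs.
#' @param mz_fraction Fraction of pairs that are monozygotic (allocation is
#'   deterministic: `round(mz_fraction * n_families)` MZ pairs).
#' @param gamma_gp Standardized effect of the true polygenic score on the
#'   general factor.
#' @param gamma_hi Standardized effect on the specific
#'   hyperactivity/impulsivity factor (applied when a factor named `"hi"`
#'   exists in the loading plan).
#' @param loading_plan Tibble with `item`, `factor`, `lambda_g`, `lambda_s`;
#'   see [default_loading_plan()].
#' @param threshold_plan Tibble with `item`, `tau1`, `tau2` (strictly
#'   increasing latent-response cutpoints). Default `(0.8, 1.8)` for all
#'   items, i.e. roughly 79/18/3% category prevalences, as seen for rare-ish
#'   parent-endorsed symptoms.
#' @param covariate_effects Named list: factor -> named numeric vector of
#'   standardized covariate effects (covariates `sex`, `age`, `pc1`..`pc6`).
#'   Default: sex effect 0.15 and age effect -0.05 on the general factor.
#' @param family_share Variance share of each latent factor due to a
#'   family-shared residual (environmental twin clustering), default 0.2.
#' @param indel_fraction,ambiguous_fraction,low_info_fraction Fractions of
#'   discovery variants flagged as indels, strand-ambiguous (A/T or C/G), or
#'   poorly imputed (INFO < 0.8), to exercise the QC filters.
#' @param exclusion_prevalence Per-condition prevalence of the four exclusion
#'   flags (cerebral palsy, Down syndrome, brain injury, chromosomal
#'   abnormality).
#' @param adhd_symptom_cutoff Endorsed-symptom count (per ADHD dimension) at
#'   or above which a child meets the symptom-based ADHD case definition.
#' @param icd_intercept,icd_slope Logistic coefficients linking the total
#'   endorsed ADHD symptom count to the probability of a register (ICD-like)
#'   ADHD diagnosis flag.
#' @param ld_block_size Variants per exchangeable-LD block (1 = independent
#'   variants; larger values give within-block haplotype correlation, only
#'   intended to exercise clumping).
#' @param ld_r2 Target within-block haplotype r-squared when
#'   `ld_block_size > 1`.
#' @param seed Integer seed; every generator is deterministic given the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_variants = 500L,
                       causal_fraction = 0.2,
                       heritability_target = 0.22,
                       n_eff_discovery = 51000,
                       n_families = 2000L,
                       mz_fraction = 1 / 3,
                       gamma_gp = 0.10,
                       gamma_hi = 0.07,
                       loading_plan = default_loading_plan(),
                       threshold_plan = NULL,
                       covariate_effects = list(gp = c(sex = 0.15, age = -0.05)),
                       family_share = 0.2,
                       indel_fraction = 0.02,
                       ambiguous_fraction = 0.05,
                       low_info_fraction = 0.05,
                       exclusion_prevalence = 0.002,
                       adhd_symptom_cutoff = 8L,
                       icd_intercept = -7,
                       icd_slope = 0.45,
                       ld_block_size = 1L,
                       ld_r2 = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_variants = as.integer(n_variants), causal_fraction = causal_fraction,
    heritability_target = heritability_target, n_eff_discovery = n_eff_discovery,
    n_families = as.integer(n_families), mz_fraction = mz_fraction,
    gamma_gp = gamma_gp, gamma_hi = gamma_hi,
    loading_plan = as_tibble(loading_plan),
    threshold_plan = threshold_plan,
    covariate_effects = covariate_effects, family_share = family_share,
    indel_fraction = indel_fraction, ambiguous_fraction = ambiguous_fraction,
    low_info_fraction = low_info_fraction,
    exclusion_prevalence = exclusion_prevalence,
    adhd_symptom_cutoff = as.integer(adhd_symptom_cutoff),
    icd_intercept = icd_intercept, icd_slope = icd_slope,
    ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
    seed = as.integer(seed)
  )
  if (is.null(cfg$threshold_plan)) {
    cfg$threshold_plan <- tibble(item = cfg$loading_plan$item, tau1 = 0.8, tau2 = 1.8)
  } else {
    cfg$threshold_plan <- as_tibble(threshold_plan)
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num_fields <- c(
    "causal_fraction", "heritability_target", "n_eff_discovery", "mz_fraction",
    "gamma_gp", "gamma_hi", "family_share", "indel_fraction",
    "ambiguous_fraction", "low_info_fraction", "exclusion_prevalence",
    "icd_intercept", "icd_slope", "ld_r2"
  )
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]])) {
      abort(paste0("Configuration field '", f, "' must be a finite number."))
    }
  }
  props <- c(
    "causal_fraction", "heritability_target", "mz_fraction", "family_share",
    "indel_fraction", "ambiguous_fraction", "low_info_fraction",
    "exclusion_prevalence"
  )
  for (f in props) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("Configuration field '", f, "' must be a proportion in [0, 1]."))
    }
  }
  if (cfg$n_variants < 1L) abort("Configuration field 'n_variants' must be >= 1.")
  if (cfg$n_families < 1L) abort("Configuration field 'n_families' must be >= 1.")
  if (cfg$n_eff_discovery <= 0) abort("Configuration field 'n_eff_discovery' must be positive.")

  lp <- cfg$loading_plan
  if (!all(c("item", "factor", "lambda_g", "lambda_s") %in% names(lp))) {
    abort("loading_plan needs columns item, factor, lambda_g, lambda_s.")
  }
  if (anyDuplicated(lp$item)) {
    abort("loading_plan assigns an item to more than one specific factor.")
  }
  comm <- lp$lambda_g^2 + lp$lambda_s^2
  if (any(comm > 1 + 1e-12)) {
    abort(paste0("Item '", lp$item[which.max(comm)],
                 "' has communality lambda_g^2 + lambda_s^2 > 1."))
  }
  tp <- cfg$threshold_plan
  if (!all(c("item", "tau1", "tau2") %in% names(tp))) {
    abort("threshold_plan needs columns item, tau1, tau2.")
  }
  if (!setequal(tp$item, lp$item)) {
    abort("threshold_plan must cover exactly the items of loading_plan.")
  }
  if (any(!is.finite(tp$tau1)) || any(!is.finite(tp$tau2)) || any(tp$tau2 <= tp$tau1)) {
    abort("Thresholds must be finite and strictly increasing per item (field 'threshold_plan').")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_families, " twin pairs (",
      round(x$mz_fraction * 100), "% MZ), ", x$n_variants, " variants, ",
      nrow(x$loading_plan), " items on ",
      length(unique(x$loading_plan$factor)), " scales\n", sep = "")
  cat("  gamma_gp = ", x$gamma_gp, ", gamma_hi = ", x$gamma_hi,
      ", h2 = ", x$heritability_target, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
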