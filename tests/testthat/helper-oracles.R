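# Independent reference implementations and shared fixtures, built in code.

# Brute-force clumping reference: repeated full scans over a data frame,
# sharing no code with clump_variants().
ref_clump <- function(records, ld_lookup, r2_max, window_kb) {
  rec <- as.data.frame(records)
  lookup_r2 <- function(a, b) {
    hit <- (ld_lookup$var_a == a & ld_lookup$var_b == b) |
      (ld_lookup$var_a == b & ld_lookup$var_b == a)
    if (any(hit)) ld_lookup$r2[which(hit)[1]] else 0
  }
  remaining <- rec
  index_ids <- character(0)
  while (nrow(remaining) > 0) {
    o <- order(remaining$p_value, remaining$chromosome,
               remaining$position, remaining$variant_id)
    idx <- remaining[o[1], ]
    index_ids <- c(index_ids, idx$variant_id)
    keep <- rep(TRUE, nrow(remaining))
    for (k in seq_len(nrow(remaining))) {
      r <- remaining[k, ]
      if (r$variant_id == idx$variant_id) {
        keep[k] <- FALSE
      } else if (r$chromosome == idx$chromosome &&
                 abs(r$position - idx$position) <= window_kb * 1000 &&
                 lookup_r2(r$variant_id, idx$variant_id) > r2_max) {
        keep[k] <- FALSE
      }
    }
    remaining <- remaining[keep, , drop = FALSE]
  }
  index_ids
}

# random small clumping instances (records + LD lookup) for equivalence checks
random_clump_instance <- function(n, seed) {
  withr::with_seed(seed, {
    rec <- tibble::tibble(
      variant_id = paste0("s", seq_len(n)),
      chromosome = sample(1:2, n, replace = TRUE),
      position = sample.int(3e6, n),
      p_value = signif(runif(n), 3)
    )
    if (n >= 2 && runif(1) < 0.3) {
      # inject p-value ties to exercise deterministic tie-breaking
      rec$p_value[2] <- rec$p_value[1]
    }
    if (n >= 2) {
      pr <- t(utils::combn(rec$variant_id, 2))
      ld <- tibble::tibble(
        var_a = pr[, 1], var_b = pr[, 2],
        r2 = round(runif(nrow(pr)), 2)
      )
      ld <- ld[runif(nrow(ld)) < 0.8, , drop = FALSE]  # unlisted pairs -> r2 0
    } else {
      ld <- tibble::tibble(var_a = character(0), var_b = character(0),
                           r2 = numeric(0))
    }
    list(records = rec, ld = ld)
  })
}

# Brute-force polychoric: grid search of the two-step likelihood over rho,
# with rectangle probabilities from mvtnorm (TVPACK), independent of the
# package's quadrature.
grid_polychoric <- function(tab, step = 1e-3) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  # TVPACK handles semi-infinite orthants only, so build rectangle
  # probabilities from CDF values by inclusion-exclusion (bounds clamped
  # far into the tails where the CDF is 0/1 to machine precision)
  clamp <- function(x) pmin(pmax(x, -8.5), 8.5)
  tau1 <- clamp(c(-Inf, qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n), Inf))
  tau2 <- clamp(c(-Inf, qnorm(cumsum(colSums(tab))[-ncol(tab)] / n), Inf))
  cellp <- function(rho) {
    S <- matrix(c(1, rho, rho, 1), 2)
    cdf <- outer(seq_along(tau1), seq_along(tau2), Vectorize(function(a, b) {
      mvtnorm::pmvnorm(upper = c(tau1[a], tau2[b]), corr = S,
                       algorithm = mvtnorm::TVPACK())[1]
    }))
    k1 <- length(tau1); k2 <- length(tau2)
    cdf[-1, -1, drop = FALSE] - cdf[-k1, -1, drop = FALSE] -
      cdf[-1, -k2, drop = FALSE] + cdf[-k1, -k2, drop = FALSE]
  }
  grid <- seq(-0.99, 0.99, by = step)
  ll <- vapply(grid, function(r) sum(tab * log(pmax(cellp(r), 1e-12))), 0)
  grid[which.max(ll)]
}

# fixed battery of 3x3 tables with n = 60 (includes zero cells and skewed
# margins) for the grid-search equivalence check
polychoric_table_battery <- function() {
  withr::with_seed(20260928, {
    rhos <- c(-0.7, -0.3, 0, 0.25, 0.5, 0.8)
    lapply(rhos, function(r) {
      z1 <- rnorm(60)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(60)
      y1 <- (z1 > -0.4) + (z1 > 0.9)
      y2 <- (z2 > -0.6) + (z2 > 0.7)
      table(factor(y1, 0:2), factor(y2, 0:2))
    })
  })
}

# small synthetic-cohort configuration used across tests
small_config <- function(seed = 1, ...) {
  sim_config(n_families = 400, n_variants = 60, seed = seed, ...)
}

# factor map of a config's loading plan, in design order
config_factor_map <- function(cfg) {
  split(cfg$loading_plan$item, cfg$loading_plan$factor)[unique(cfg$loading_plan$factor)]
}

# exact mixed_cor stand-in built from a known correlation matrix (for
# closed-form recovery tests): tiny symmetric influence noise, unit weights
fake_mc <- function(R, items, covariates = character(), n = 1000) {
  vars <- c(items, covariates)
  stopifnot(all(vars %in% rownames(R)))
  R <- R[vars, vars]
  p <- length(items)
  q <- length(covariates)
  a <- character(0); b <- character(0)
  for (i in seq_along(vars)[-length(vars)]) {
    for (j in (i + 1):length(vars)) {
      if (i > p && j > p) next
      a <- c(a, vars[i]); b <- c(b, vars[j])
    }
  }
  K <- length(a)
  withr::with_seed(1, Psi <- matrix(rnorm(n * K) * 1e-3, n, K))
  structure(
    list(
      R = R, types = NULL, avar = NULL,
      pairs = tibble::tibble(a = a, b = b, type = "polychoric",
                             n_pair = n, est = R[cbind(a, b)], avar = 1 / n),
      Psi = Psi, thresholds = list(), n = n,
      items = items, covariates = covariates, repaired = FALSE
    ),
    class = "mixed_cor"
  )
}
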