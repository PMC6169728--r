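# Polychoric / polyserial correlation estimation.
#
# Two-step estimators: thresholds from the univariate margins (normal-quantile
# inversion), then the correlation by maximizing the bivariate-normal
# likelihood with thresholds held fixed. Uncertainty comes from per-observation
# influence functions that propagate threshold-estimation error through the
# correlation estimating equation; these same influence functions are what the
# family-cluster sandwich aggregates later, so they are stored alongside the
# correlation matrix.

#' Thresholds of an ordinal item on the standard-normal scale
#'
#' Inverts cumulative category proportions: \eqn{\tau_k = \Phi^{-1}(F_k)}.
#' A three-category item (coded 0/1/2) yields two strictly increasing
#' cutpoints.
#'
#' @param counts Non-negative category counts in category order (a named or
#'   unnamed vector, or a 1-way `table`).
#' @return Numeric vector of `length(counts) - 1` thresholds.
#' @examples
#' estimate_thresholds(c(50, 50))        # 0
#' estimate_thresholds(c(50, 25, 25))    # 0, 0.674
#' @export
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) {
    abort("At least 2 categories are required to estimate thresholds.")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("Category counts must be finite and non-negative.")
  }
  if (any(counts == 0)) {
    abort(paste0(
      "Empty category (position ", which(counts == 0)[1], ") with ",
      length(counts), "-category coding declared: collapse adjacent ",
      "categories or exclude the item."
    ))
  }
  p <- cumsum(counts) / sum(counts)
  qnorm(p[-length(p)])
}

# -- polychoric ---------------------------------------------------------------

# Core fit from a two-way contingency table of category counts.
# Returns rho, asymptotic variance, thresholds, and the per-cell influence
# function of the two-step estimator (threshold propagation included).
polychoric_fit <- function(tab, nodes = 24L, compute_if = TRUE) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    abort("Degenerate margin: every category of both variables needs at least one observation.")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("Both variables need at least 2 observed categories.")
  }
  tau1 <- qnorm(cumsum(rs)[-length(rs)] / n)
  tau2 <- qnorm(cumsum(cs)[-length(cs)] / n)

  nll <- function(rho) {
    -sum(tab * log(pmax(ordinal_cell_probs(tau1, tau2, rho, nodes = nodes), 1e-12)))
  }
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  if (abs(rho) > 0.998) {
    warn("Polychoric correlation at the boundary; clipped to +/-0.999.")
    rho <- sign(rho) * 0.999
  }

  out <- list(rho = rho, tau1 = tau1, tau2 = tau2, n = n)
  if (!compute_if) {
    return(out)
  }

  p_hat <- tab / n
  # per-cell score u_ab = d log pi_ab / d rho at the optimum
  score_cells <- function(r, t1 = tau1, t2 = tau2) {
    pi_c <- pmax(ordinal_cell_probs(t1, t2, r, nodes = nodes), 1e-12)
    ordinal_cell_dprobs(t1, t2, r) / pi_c
  }
  u <- score_cells(rho)
  eps <- 1e-4
  mean_score <- function(r, t1 = tau1, t2 = tau2) sum(p_hat * score_cells(r, t1, t2))
  H <- (mean_score(rho + eps) - mean_score(rho - eps)) / (2 * eps)

  # threshold propagation: J[t] = d mean-score / d tau_t, paired with the
  # influence of each observation on the marginal threshold estimate
  if_cell <- u
  for (a0 in seq_along(tau1)) {
    t1p <- tau1; t1p[a0] <- t1p[a0] + eps
    t1m <- tau1; t1m[a0] <- t1m[a0] - eps
    J <- (mean_score(rho, t1 = t1p) - mean_score(rho, t1 = t1m)) / (2 * eps)
    Fa <- sum(rs[seq_len(a0)]) / n
    if_tau <- (as.numeric(seq_along(rs) <= a0) - Fa) / dnorm(tau1[a0])  # by row
    if_cell <- if_cell + J * matrix(if_tau, nrow = nrow(tab), ncol = ncol(tab))
  }
  for (b0 in seq_along(tau2)) {
    t2p <- tau2; t2p[b0] <- t2p[b0] + eps
    t2m <- tau2; t2m[b0] <- t2m[b0] - eps
    J <- (mean_score(rho, t2 = t2p) - mean_score(rho, t2 = t2m)) / (2 * eps)
    Fb <- sum(cs[seq_len(b0)]) / n
    if_tau <- (as.numeric(seq_along(cs) <= b0) - Fb) / dnorm(tau2[b0])  # by col
    if_cell <- if_cell + J * matrix(if_tau, nrow = nrow(tab), ncol = ncol(tab), byrow = TRUE)
  }
  if_cell <- -if_cell / H
  out$if_cell <- if_cell
  out$avar <- sum(p_hat * if_cell^2) / n
  out
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood under the bivariate-normal latent-response
#' model: thresholds are fixed at the margin-implied normal quantiles and the
#' correlation maximizes the orthant likelihood. The asymptotic variance is
#' influence-function based and accounts for threshold estimation.
#'
#' @param x Either a two-way contingency `table`/matrix of counts, or a vector
#'   of ordinal responses.
#' @param y A second ordinal vector when `x` is a vector; ignored otherwise.
#' @param nodes Gauss-Legendre nodes for rectangle probabilities.
#' @return A list with elements `rho`, `se`, `avar`, `thresholds` (list of two
#'   numeric vectors), and `n`.
#' @examples
#' tab <- matrix(c(20, 10, 5, 10, 20, 10, 5, 10, 20), 3, 3)
#' polychoric(tab)$rho
#' @export
polychoric <- function(x, y = NULL, nodes = 24L) {
  if (is.table(x) || is.matrix(x)) {
    tab <- as.matrix(x)
  } else {
    if (is.null(y)) abort("Supply either a contingency table or two ordinal vectors.")
    ok <- complete.cases(x, y)
    tab <- table(x[ok], y[ok])
  }
  fit <- polychoric_fit(tab, nodes = nodes)
  list(
    rho = fit$rho, se = sqrt(fit$avar), avar = fit$avar,
    thresholds = list(fit$tau1, fit$tau2), n = fit$n
  )
}

# -- polyserial ---------------------------------------------------------------

# Core fit: x continuous (standardized internally), y ordinal (integer codes
# 1..K). Maximum likelihood under bivariate normality with thresholds fixed
# from the ordinal margin; the continuous margin drops out of the score, so
# the estimator is the ordinal-probit regression of y on standardized x and
# remains consistent for cor(x, y*) whenever y* | x is normal and linear in x.
polyserial_fit <- function(x, y_idx, k, compute_if = TRUE) {
  n <- length(x)
  sdx <- sd(x)
  if (!is.finite(sdx) || sdx < .Machine$double.eps) {
    abort("Continuous variable is constant; polyserial correlation undefined.")
  }
  xs <- (x - mean(x)) / sdx
  counts <- tabulate(y_idx, nbins = k)
  if (any(counts == 0)) {
    abort("Degenerate ordinal margin in polyserial estimation.")
  }
  tau <- qnorm(cumsum(counts)[-k] / n)

  loglik_i <- function(rho, tau_loc = tau, x_use = xs) {
    s <- sqrt(1 - rho^2)
    te <- c(-Inf, tau_loc, Inf)
    up <- (te[y_idx + 1L] - rho * x_use) / s
    lo <- (te[y_idx] - rho * x_use) / s
    log(pmax(pnorm(up) - pnorm(lo), 1e-12))
  }
  opt <- optimize(function(r) -sum(loglik_i(r)), interval = c(-0.995, 0.995), tol = 1e-7)
  rho <- opt$minimum

  out <- list(rho = rho, tau = tau, n = n)
  if (!compute_if) {
    return(out)
  }
  eps <- 1e-4
  lp <- loglik_i(rho + eps)
  lm_ <- loglik_i(rho - eps)
  l0 <- loglik_i(rho)
  u <- (lp - lm_) / (2 * eps)
  H <- (mean(lp) - 2 * mean(l0) + mean(lm_)) / eps^2
  score_at <- function(tau_loc = tau, x_use = xs) {
    (mean(loglik_i(rho + eps, tau_loc, x_use)) -
       mean(loglik_i(rho - eps, tau_loc, x_use))) / (2 * eps)
  }
  if_obs <- u
  for (t in seq_along(tau)) {
    taup <- tau; taup[t] <- taup[t] + eps
    taum <- tau; taum[t] <- taum[t] - eps
    J <- (score_at(taup) - score_at(taum)) / (2 * eps)
    Ft <- sum(counts[seq_len(t)]) / n
    if_tau <- (as.numeric(y_idx <= t) - Ft) / dnorm(tau[t])
    if_obs <- if_obs + J * if_tau
  }
  # propagation of the covariate's estimated mean and SD (on the
  # standardized scale x has mean 0, SD 1, so the influences are x and
  # (x^2 - 1) / 2)
  J_mu <- (score_at(x_use = xs - eps) - score_at(x_use = xs + eps)) / (2 * eps)
  J_sd <- (score_at(x_use = xs / (1 + eps)) - score_at(x_use = xs / (1 - eps))) / (2 * eps)
  if_obs <- if_obs + J_mu * xs + J_sd * (xs^2 - 1) / 2
  if_obs <- -if_obs / H
  out$if_obs <- if_obs
  out$avar <- mean(if_obs^2) / n
  out
}

#' Polyserial correlation of an ordinal and a continuous variable
#'
#' @param x Continuous vector (standardized internally).
#' @param y Ordinal vector (any ordered coding; categories taken from the
#'   observed values).
#' @return A list with `rho`, `se`, `avar`, `thresholds`, `n`.
#' @export
polyserial <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  lev <- sort(unique(y))
  if (length(lev) < 2) abort("Ordinal variable has fewer than 2 observed categories.")
  y_idx <- match(y, lev)
  fit <- polyserial_fit(x, y_idx, length(lev))
  list(rho = fit$rho, se = sqrt(fit$avar), avar = fit$avar, thresholds = fit$tau, n = fit$n)
}

# Pearson correlation with its per-observation influence function.
pearson_fit <- function(x, y) {
  n <- length(x)
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  r <- sum(xs * ys) / (n - 1)
  if_obs <- xs * ys - r / 2 * (xs^2 + ys^2)
  list(rho = r, if_obs = if_obs, avar = mean(if_obs^2) / n, n = n)
}

# -- mixed correlation matrix -------------------------------------------------

#' Mixed polychoric / polyserial / Pearson correlation matrix
#'
#' Assembles the sample-moment input for ordinal-indicator SEM: polychoric
#' correlations between ordinal items, polyserial correlations between items
#' and continuous covariates, and Pearson correlations among covariates.
#' Estimation is pairwise-complete with a minimum-n guard. Per-moment
#' asymptotic variances (the DWLS weights) and per-observation influence
#' functions (for cluster-robust inference) are returned alongside the matrix.
#' The covariate-covariate block is treated as fixed sample moments and
#' carries no influence columns.
#'
#' @param data A data frame.
#' @param items Character vector of ordinal item columns (e.g. 0/1/2 coded).
#' @param covariates Character vector of continuous covariate columns
#'   (PRS, sex, age, principal components, ...).
#' @param min_n Minimum pairwise-complete observations per pair (default 50).
#' @param sparse_warn Warn when any item category has fewer endorsements than
#'   this (default 5); such items are candidates for collapse or exclusion.
#' @param compute_if Keep the n x K influence matrix (needed for sandwich
#'   standard errors). Set `FALSE` to save memory.
#' @param nodes Gauss-Legendre nodes for polychoric likelihood evaluations.
#' @return An object of class `mixed_cor`: list with the correlation matrix
#'   `R` (items first, then covariates), `types` and `avar` matrices, a
#'   `pairs` tibble indexing the modelled moments (covariate-covariate pairs
#'   excluded), the influence matrix `Psi` (n x nrow(pairs)), per-item
#'   `thresholds`, and a `repaired` flag set when an eigenvalue floor was
#'   applied to restore positive semi-definiteness.
#' @export
mixed_cor <- function(data, items, covariates = character(), min_n = 50,
                      sparse_warn = 5, compute_if = TRUE, nodes = 24L) {
  vars <- c(items, covariates)
  if (length(vars) < 2) abort("At least 2 variables are required.")
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("Variables absent from data: ", paste(missing_vars, collapse = ", ")))
  }
  n <- nrow(data)
  v <- length(vars)
  is_item <- vars %in% items

  # per-item category codings from the observed values
  levels_list <- list()
  thresholds <- list()
  for (it in items) {
    val <- data[[it]]
    lev <- sort(unique(val[!is.na(val)]))
    if (length(lev) < 2) abort(paste0("Item '", it, "' has fewer than 2 observed categories."))
    cnt <- tabulate(match(val, lev), nbins = length(lev))
    if (any(cnt < sparse_warn)) {
      warn(paste0("Item '", it, "' has a category with fewer than ", sparse_warn,
                  " endorsements; consider collapsing categories or excluding the item."))
    }
    levels_list[[it]] <- lev
    thresholds[[it]] <- qnorm(cumsum(cnt)[-length(cnt)] / sum(cnt))
  }

  R <- diag(1, v)
  dimnames(R) <- list(vars, vars)
  types <- matrix(NA_character_, v, v, dimnames = dimnames(R))
  avar <- matrix(NA_real_, v, v, dimnames = dimnames(R))

  pair_a <- character(0); pair_b <- character(0)
  pair_type <- character(0); pair_n <- integer(0)
  psi_cols <- list()
  low_n_pairs <- character(0)

  for (i in seq_len(v - 1)) {
    for (j in (i + 1):v) {
      vi <- vars[i]; vj <- vars[j]
      xi <- data[[vi]]; xj <- data[[vj]]
      ok <- !is.na(xi) & !is.na(xj)
      np <- sum(ok)
      modelled <- is_item[i] || is_item[j]
      if (np < min_n) {
        low_n_pairs <- c(low_n_pairs, paste0(vi, ":", vj, " (n=", np, ")"))
        next
      }
      psi <- numeric(n)
      if (is_item[i] && is_item[j]) {
        ii <- match(xi[ok], levels_list[[vi]])
        jj <- match(xj[ok], levels_list[[vj]])
        k1 <- length(levels_list[[vi]]); k2 <- length(levels_list[[vj]])
        tab <- matrix(tabulate(ii + k1 * (jj - 1L), nbins = k1 * k2), k1, k2)
        fit <- polychoric_fit(tab, nodes = nodes, compute_if = compute_if)
        rho <- fit$rho
        if (compute_if) {
          psi[ok] <- (n / np) * fit$if_cell[cbind(ii, jj)]
          avar[i, j] <- avar[j, i] <- fit$avar
        }
        ty <- "polychoric"
      } else if (xor(is_item[i], is_item[j])) {
        if (is_item[i]) {
          yv <- vi; xv <- vj
        } else {
          yv <- vj; xv <- vi
        }
        y_idx <- match(data[[yv]][ok], levels_list[[yv]])
        xc <- data[[xv]][ok]
        if (sd(xc) < .Machine$double.eps) {
          abort(paste0("Covariate '", xv, "' is constant; polyserial correlation undefined."))
        }
        fit <- polyserial_fit(xc, y_idx, length(levels_list[[yv]]), compute_if = compute_if)
        rho <- fit$rho
        if (compute_if) {
          psi[ok] <- (n / np) * fit$if_obs
          avar[i, j] <- avar[j, i] <- fit$avar
        }
        ty <- "polyserial"
      } else {
        fit <- pearson_fit(xi[ok], xj[ok])
        rho <- fit$rho
        if (compute_if) {
          psi[ok] <- (n / np) * fit$if_obs
        }
        avar[i, j] <- avar[j, i] <- fit$avar
        ty <- "pearson"
      }
      R[i, j] <- R[j, i] <- rho
      types[i, j] <- types[j, i] <- ty
      if (modelled) {
        pair_a <- c(pair_a, vi); pair_b <- c(pair_b, vj)
        pair_type <- c(pair_type, ty); pair_n <- c(pair_n, np)
        psi_cols[[length(psi_cols) + 1L]] <- psi
      }
    }
  }
  if (length(low_n_pairs)) {
    abort(paste0("Pairs below the minimum pairwise n of ", min_n, ": ",
                 paste(low_n_pairs, collapse = "; ")))
  }

  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    R2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R2))
    R <- R2 / tcrossprod(d)
    dimnames(R) <- list(vars, vars)
    repaired <- TRUE
    inform(paste0("Correlation matrix repaired to positive semi-definite ",
                  "(eigenvalue floor 1e-6; smallest eigenvalue was ",
                  signif(min(ev$values), 3), ")."))
  }

  structure(
    list(
      R = R, types = types, avar = avar,
      pairs = tibble(
        a = pair_a, b = pair_b, type = pair_type, n_pair = pair_n,
        est = R[cbind(pair_a, pair_b)], avar = avar[cbind(pair_a, pair_b)]
      ),
      Psi = if (compute_if && length(psi_cols)) do.call(cbind, psi_cols) else NULL,
      thresholds = thresholds, n = n, items = items, covariates = covariates,
      repaired = repaired
    ),
    class = "mixed_cor"
  )
}

#' @export
print.mixed_cor <- function(x, ...) {
  cat("<mixed_cor> ", length(x$items), " items + ", length(x$covariates),
      " covariates, n = ", x$n, "\n", sep = "")
  cat("  moments: ", nrow(x$pairs), " (",
      sum(x$pairs$type == "polychoric"), " polychoric, ",
      sum(x$pairs$type == "polyserial"), " polyserial, ",
      sum(x$pairs$type == "pearson"), " pearson)\n", sep = "")
  if (x$repaired) cat("  note: PSD repair applied\n")
  invisible(x)
}

#' Tidy a mixed correlation matrix
#'
#' @param x A `mixed_cor` object.
#' @param ... Unused.
#' @return A tibble with one row per modelled moment: variable pair, estimator
#'   type, correlation, asymptotic variance, pairwise n.
#' @export
tidy.mixed_cor <- function(x, ...) {
  x$pairs
}
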