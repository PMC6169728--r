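# Bivariate-normal rectangle probabilities for ordinal models.
#
# The polychoric likelihood needs many cheap evaluations of standard
# bivariate-normal CDF values at threshold grids, vectorized over the grid for
# a scalar correlation. We use the single-integral identity
#   Phi2(h, k; rho) = Phi(h) Phi(k) +
#     (1 / 2 pi) int_0^rho exp(-(h^2 - 2 r h k + k^2) / (2 (1 - r^2))) /
#                          sqrt(1 - r^2) dr
# evaluated by Gauss-Legendre quadrature (nodes from pracma).

.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n = 32L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}

#' Standard bivariate normal CDF
#'
#' \eqn{P(Z_1 \le h, Z_2 \le k)} for standard normal margins with correlation
#' `rho`. Vectorized over `h` and `k` (recycled to common length); `rho` is a
#' scalar. Infinite limits are handled exactly.
#'
#' @param h,k Upper limits (may be `Inf`/`-Inf`).
#' @param rho Correlation in (-1, 1).
#' @param nodes Number of Gauss-Legendre nodes for the correlation integral.
#' @return Numeric vector of probabilities.
#' @export
pbvn <- function(h, k, rho, nodes = 32L) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) < 1)
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn)
  k <- rep_len(k, nn)
  out <- pnorm(h) * pnorm(k)
  if (rho != 0) {
    fin <- is.finite(h) & is.finite(k)
    if (any(fin)) {
      gl <- gl_nodes(nodes)
      r <- gl$x * rho          # nodes mapped to [0, rho]
      wts <- gl$w * rho
      omr2 <- 1 - r * r
      hf <- h[fin]
      kf <- k[fin]
      # integrand matrix: length(r) x sum(fin)
      num <- outer(-2 * r, hf * kf) +
        matrix(hf^2 + kf^2, nrow = length(r), ncol = length(hf), byrow = TRUE)
      integ <- exp(-num / (2 * omr2)) / sqrt(omr2)
      out[fin] <- out[fin] + as.vector(t(wts) %*% integ) / (2 * pi)
    }
    # limits at +/-Inf with the other finite reduce to the univariate case,
    # already handled by pnorm() above (pnorm(Inf) = 1, pnorm(-Inf) = 0).
  }
  pmin(pmax(out, 0), 1)
}

#' Standard bivariate normal density
#'
#' Density at `(h, k)` for standard margins with correlation `rho`; returns 0
#' when either coordinate is infinite. Vectorized over `h`, `k`.
#'
#' @inheritParams pbvn
#' @return Numeric vector of densities.
#' @export
dbvn <- function(h, k, rho) {
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn)
  k <- rep_len(k, nn)
  out <- numeric(nn)
  fin <- is.finite(h) & is.finite(k)
  if (any(fin)) {
    omr2 <- 1 - rho * rho
    q <- (h[fin]^2 - 2 * rho * h[fin] * k[fin] + k[fin]^2) / (2 * omr2)
    out[fin] <- exp(-q) / (2 * pi * sqrt(omr2))
  }
  out
}

#' Cell probabilities of two thresholded standard normals
#'
#' Probabilities of the \eqn{K_1 \times K_2} cross-classification obtained by
#' cutting a standard bivariate normal with correlation `rho` at thresholds
#' `tau1` and `tau2` (the model behind a polychoric contingency table).
#'
#' @param tau1,tau2 Strictly increasing threshold vectors (length K - 1).
#' @inheritParams pbvn
#' @return A matrix of cell probabilities summing to 1.
#' @export
ordinal_cell_probs <- function(tau1, tau2, rho, nodes = 32L) {
  c1 <- c(-Inf, tau1, Inf)
  c2 <- c(-Inf, tau2, Inf)
  k1 <- length(c1)
  k2 <- length(c2)
  grid_h <- rep(c1, times = k2)
  grid_k <- rep(c2, each = k1)
  cdf <- matrix(pbvn(grid_h, grid_k, rho, nodes = nodes), nrow = k1, ncol = k2)
  cells <- cdf[-1, -1, drop = FALSE] - cdf[-k1, -1, drop = FALSE] -
    cdf[-1, -k2, drop = FALSE] + cdf[-k1, -k2, drop = FALSE]
  pmax(cells, 0)
}

# d(cell probabilities)/d(rho) via the corner-density identity
# dPhi2(h, k; rho)/drho = phi2(h, k; rho).
ordinal_cell_dprobs <- function(tau1, tau2, rho) {
  c1 <- c(-Inf, tau1, Inf)
  c2 <- c(-Inf, tau2, Inf)
  k1 <- length(c1)
  k2 <- length(c2)
  grid_h <- rep(c1, times = k2)
  grid_k <- rep(c2, each = k1)
  dd <- matrix(dbvn(grid_h, grid_k, rho), nrow = k1, ncol = k2)
  dd[-1, -1, drop = FALSE] - dd[-k1, -1, drop = FALSE] -
    dd[-1, -k2, drop = FALSE] + dd[-k1, -k2, drop = FALSE]
}
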