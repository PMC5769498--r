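#' Gauss-Hermite quadrature for expectations under N(0, 1)
#'
#' Nodes and weights such that `sum(w * f(z))` approximates
#' `E[f(Z)]` for `Z ~ N(0, 1)` (probabilists' convention; weights sum to 1).
#' Computed by the Golub-Welsch eigenvalue method on the Jacobi matrix of the
#' physicists' Hermite polynomials, then rescaled.
#'
#' @param n quadrature order (>= 2).
#' @return list with numeric vectors `z` (nodes) and `w` (weights).
#' @examples
#' gh <- gauss_hermite(30)
#' sum(gh$w)                 # 1
#' sum(gh$w * gh$z^2)        # Var of N(0,1) = 1
#' @export
gauss_hermite <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("quadrature order must be an integer >= 2")
  n <- as.integer(n)
  # Jacobi matrix for physicists' Hermite: off-diagonal sqrt(i/2)
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2   # normalized so weights sum to 1 (total mass sqrt(pi)/sqrt(pi))
  ord <- order(x)
  list(z = sqrt(2) * x[ord], w = w[ord])
}

#' Effective sample size of an MCMC chain
#'
#' Geyer initial-monotone positive sequence estimator on the empirical
#' autocorrelations. Returns `length(x)` for constant chains.
#'
#' @param x numeric vector of draws.
#' @return effective sample size (scalar).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  max_lag <- min(n - 2L, 2000L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}; keep while positive and nonincreasing
  m <- floor(length(rho) / 2)
  if (m < 1L) return(n)
  gam <- rho[2 * seq_len(m) - 1] + rho[2 * seq_len(m)]
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1] - 1L)]
  if (length(gam) > 1L) gam <- cummin(gam)
  denom <- 1 + 2 * sum(gam)
  if (denom <= 0) return(n)
  min(n, n / denom)
}

#' Nearest-rank empirical percentile
#'
#' The p-th percentile is the ceiling(p*n)-th order statistic (no
#' interpolation), fixed for reproducibility.
#'
#' @param x numeric vector (nonempty).
#' @param probs probabilities in (0, 1].
#' @return numeric vector of percentiles.
#' @export
nearest_rank_percentile <- function(x, probs) {
  if (!length(x)) stop("empty input")
  xs <- sort(x)
  k <- pmax(1L, ceiling(probs * length(xs)))
  xs[k]
}

# internal: stop with a message naming the offending field/row
fail_field <- function(field, row = NULL, msg = "invalid value") {
  where <- if (is.null(row)) field else sprintf("%s (row %s)", field, row)
  stop(sprintf("%s: %s", where, msg), call. = FALSE)
}
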