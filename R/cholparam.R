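#' Cholesky-regression parametrization of a precision matrix
#'
#' The Gaussian model \eqn{Z \sim N(0, \Omega^{-1})} with
#' \eqn{\Omega = LL'} (\eqn{L} lower triangular) is equivalent to the
#' sequence of regressions \eqn{Z_d = \sum_{k>d} \beta_{kd} Z_k +
#' \varepsilon_d}, \eqn{\varepsilon_d \sim N(0, \sigma_d^2)}, with
#' \eqn{\beta_{kd} = -l_{kd}/l_{dd}} and residual precision
#' \eqn{\phi_d = 1/\sigma_d^2 = l_{dd}^2}. These helpers map between the
#' regression parameters and the precision matrix; the reconstruction
#' \eqn{\omega_{kd} = \sum_{m \le d} l_{km} l_{dm}} is positive definite by
#' construction for any finite coefficients and positive precisions.
#'
#' @param beta \code{p x p} matrix holding \eqn{\beta_{kd}} in its strictly
#'   lower triangle (entry \code{[k, d]} for \code{k > d}); the rest is
#'   ignored.
#' @param phi length-\code{p} vector of positive residual precisions.
#' @return \code{chol_to_precision}: the \code{p x p} SPD precision matrix.
#' @export
#' @examples
#' Om <- diag(3) + 0.4
#' pr <- precision_to_chol(Om)
#' max(abs(chol_to_precision(pr$beta, pr$phi) - Om))
chol_to_precision <- function(beta, phi) {
  p <- length(phi)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("'phi' must be positive and finite", call. = FALSE)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(p, p))) stop("'beta' must be a p x p matrix", call. = FALSE)
  L <- matrix(0, p, p)
  diag(L) <- sqrt(phi)
  low <- lower.tri(L)
  L[low] <- -beta[low] * rep(sqrt(phi), each = p)[low]
  tcrossprod(L)
}

#' @rdname chol_to_precision
#' @param Omega a symmetric positive definite matrix.
#' @return \code{precision_to_chol}: a list with \code{beta}, \code{phi} and
#'   the lower factor \code{L}; round trip through
#'   \code{chol_to_precision} is the identity.
#' @export
precision_to_chol <- function(Omega) {
  Omega <- as.matrix(Omega)
  U <- tryCatch(chol(Omega), error = function(e)
    stop("'Omega' is not symmetric positive definite", call. = FALSE))
  L <- t(U)                       # Omega = L %*% t(L)
  p <- ncol(L)
  phi <- diag(L)^2
  beta <- matrix(0, p, p)
  low <- lower.tri(beta)
  beta[low] <- -(L / rep(diag(L), each = p))[low]
  list(beta = beta, phi = phi, L = L)
}

#' Probability that a precision entry is nonzero under row-sparse factors
#'
#' If the rows of the Cholesky factor \eqn{L} have independent Bernoulli
#' supports with row-\eqn{k} inclusion probability \eqn{\rho_k}, then
#' \eqn{P(\omega_{kd} \neq 0) = 1 - (1 - \rho_k \rho_d)^{\min(k, d)}}:
#' the entry is a sum of \eqn{\min(k,d)} products, each nonzero only when
#' both factors are active.
#'
#' @param rho_k,rho_d row inclusion probabilities in \eqn{[0,1]}.
#' @param k,d row/column indices (positive integers); vectorized.
#' @return Probability (or vector of probabilities) in \eqn{[0,1]}.
#' @export
edge_probability <- function(rho_k, rho_d, k, d) {
  if (any(rho_k < 0 | rho_k > 1) || any(rho_d < 0 | rho_d > 1))
    stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
  if (any(k < 1) || any(d < 1)) stop("indices must be positive", call. = FALSE)
  1 - (1 - rho_k * rho_d)^pmin(k, d)
}

#' Row-wise sparsity plan for the Cholesky factor
#'
#' The row inclusion probabilities \eqn{\rho_k = c/(p\sqrt{k})} keep the
#' implied probability of a nonzero precision entry,
#' \eqn{1 - (1 - \rho_k\rho_d)^{\min(k,d)}}, essentially constant across
#' rows (for \eqn{k \sim d} it tends to \eqn{1 - \exp\{-c^2/p^2\}} as the
#' row index grows), which gives the weak order invariance the row
#' regressions need. Values are capped at 1 for very small \eqn{p} with
#' large \eqn{c}.
#'
#' @param p dimension.
#' @param c_sparsity global sparsity constant; the tuned grid in the fitting
#'   functions covers \code{c(0.1, 1, 10)}.
#' @return A list with \code{c_sparsity} and the length-\code{p} vector
#'   \code{rho}.
#' @export
sparsity_plan <- function(p, c_sparsity = 1) {
  if (p < 1) stop("'p' must be positive", call. = FALSE)
  if (c_sparsity <= 0) stop("'c_sparsity' must be positive", call. = FALSE)
  rho <- pmin(1, c_sparsity / (p * sqrt(seq_len(p))))
  list(c_sparsity = c_sparsity, rho = rho)
}
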