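#' Posterior estimation of the monotone marginal transformations
#'
#' Runs the Gibbs scheme over the B-spline coefficients \eqn{\theta_d}, the
#' free means \eqn{\mu}, and a conjugate Wishart working model for the
#' precision matrix of the transformed variables:
#' \itemize{
#'   \item \eqn{\theta_d \mid \mu, \Omega, rest}: truncated-normal full
#'     conditional in the reduced coordinates, sampled by one exact-HMC
#'     trajectory per scan;
#'   \item \eqn{\mu \mid \theta, \Omega \sim N(\bar Y, (n\Omega)^{-1})}
#'     (flat prior on each mean);
#'   \item \eqn{\Omega \mid \theta, \mu \sim W_p(n + df, (I + S)^{-1})}
#'     with \eqn{S = (Y-\mu)'(Y-\mu)}; this Wishart working model is used
#'     only inside this stage to propagate dependence between columns while
#'     the transformations are learned. The sparse engines afterwards see
#'     only the plug-in matrix \code{Z}.
#' }
#' Posterior means \eqn{\hat\theta_d} and \eqn{\hat\mu_d} give the plug-in
#' transformed data \eqn{Z_{id} = \sum_j \hat\theta_{jd} B_j(X_{id}) -
#' \hat\mu_d}. Monotonicity and the linear identification constraints are
#' preserved by averaging because both regions are convex.
#'
#' @param X \code{n x p} data matrix with entries in \eqn{[0,1]} (min-max
#'   rescale raw data first; see [minmax_rescale()]).
#' @param nu,tau,osq prior constants of [transform_prior()].
#' @param J fixed number of basis functions for all columns, or \code{NULL}
#'   to pick per column by [select_basis_dim()] over \code{J_grid}.
#' @param J_grid candidate basis dimensions when \code{J} is \code{NULL}.
#' @param n_iter,burn_in total Gibbs scans and discarded scans.
#' @param wishart_df prior degrees of freedom of the Wishart working model.
#' @param store_draws how many (thinned) coefficient draws to retain for
#'   diagnostics.
#' @param seed integer seed; the run is fully reproducible from it.
#' @return An object of class \code{npn_transform}: list with
#'   \code{theta_hat} (per-column posterior-mean coefficients),
#'   \code{mu_hat}, the plug-in matrix \code{Z}, the initialization matrix
#'   \code{Z_init} (used by the sparsity tuning stage), per-column
#'   \code{basis}/\code{prior} objects, retained \code{theta_draws}, and
#'   \code{J}.
#' @export
fit_transforms <- function(X, nu = 1, tau = 1, osq = 1,
                           J = NULL, J_grid = 5:12,
                           n_iter = 15000, burn_in = 5000,
                           wishart_df = 3, store_draws = 50, seed = 1) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("'X' contains non-finite values", call. = FALSE)
  if (any(X < 0) || any(X > 1))
    stop("'X' must be rescaled into [0, 1] before transform estimation", call. = FALSE)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)

  cols <- vector("list", p)
  for (d in seq_len(p)) {
    Jd <- as.integer(if (is.null(J)) select_basis_dim(X[, d], J_grid, nu, tau, osq) else J)
    basis <- spline_basis(Jd)
    prior <- transform_prior(basis, nu, tau, osq)
    B <- basis_eval(basis, X[, d])
    G <- B %*% prior$Tmap
    theta0 <- init_spline_coef(X[, d], basis, prior)
    cols[[d]] <- list(
      J = Jd, basis = basis, prior = prior, B = B, G = G,
      y0 = drop(B %*% prior$t0), GtG = crossprod(G),
      Gamma_inv = chol2inv(chol(prior$Gamma_bar)),
      theta_bar = reduce_coef(prior, theta0))
    cols[[d]]$prior_rhs <- drop(cols[[d]]$Gamma_inv %*% prior$xi_bar)
  }

  Y <- vapply(seq_len(p), function(d)
    cols[[d]]$y0 + drop(cols[[d]]$G %*% cols[[d]]$theta_bar), numeric(n))
  mu <- colMeans(Y)
  Z_init <- sweep(Y, 2L, mu)
  Sg <- stats::cov(Y)
  Omega <- chol2inv(chol(Sg + 1e-6 * mean(diag(Sg)) * diag(p)))

  keep <- n_iter - burn_in
  thin_at <- if (store_draws > 0) unique(round(seq(burn_in + 1, n_iter, length.out = min(store_draws, keep)))) else integer(0)
  theta_sum <- lapply(cols, function(cl) numeric(cl$J))
  theta_draws <- if (store_draws > 0) lapply(cols, function(cl) matrix(NA_real_, length(thin_at), cl$J)) else NULL
  mu_sum <- numeric(p)
  draw_row <- 0L

  Yc <- sweep(Y, 2L, mu)
  for (it in seq_len(n_iter)) {
    for (d in seq_len(p)) {
      cl <- cols[[d]]
      odd <- Omega[d, d]
      # r_i = sum_{k != d} omega_dk (Y_ik - mu_k)
      r <- drop(Yc %*% Omega[, d]) - odd * Yc[, d]
      P <- odd * cl$GtG + cl$Gamma_inv
      rhs <- odd * drop(crossprod(cl$G, mu[d] - cl$y0)) - drop(crossprod(cl$G, r)) + cl$prior_rhs
      Rp <- chol(P)
      mvec <- backsolve(Rp, backsolve(Rp, rhs, transpose = TRUE))
      # whiten: theta_bar = mvec + A u, A = Rp^{-1}
      u <- drop(Rp %*% (cl$theta_bar - mvec))
      FA <- t(backsolve(Rp, t(cl$prior$F_bar), transpose = TRUE))  # F_bar %*% Rp^{-1}
      gA <- cl$prior$g_bar + drop(cl$prior$F_bar %*% mvec)
      u <- hmc_trajectory(u, FA, gA, pi / 2)
      cl$theta_bar <- mvec + backsolve(Rp, u)
      cols[[d]] <- cl
      Y[, d] <- cl$y0 + drop(cl$G %*% cl$theta_bar)
      Yc[, d] <- Y[, d] - mu[d]
    }
    mu <- colMeans(Y) + backsolve(chol(n * Omega), stats::rnorm(p))
    Yc <- sweep(Y, 2L, mu)
    Omega <- drop(stats::rWishart(1, n + wishart_df,
                                  chol2inv(chol(diag(p) + crossprod(Yc)))))
    if (it > burn_in) {
      for (d in seq_len(p))
        theta_sum[[d]] <- theta_sum[[d]] + complete_coef(cols[[d]]$prior, cols[[d]]$theta_bar)
      mu_sum <- mu_sum + mu
      if (store_draws > 0 && it %in% thin_at) {
        draw_row <- draw_row + 1L
        for (d in seq_len(p))
          theta_draws[[d]][draw_row, ] <- complete_coef(cols[[d]]$prior, cols[[d]]$theta_bar)
      }
    }
  }

  theta_hat <- lapply(theta_sum, function(s) s / keep)
  mu_hat <- mu_sum / keep
  Z <- vapply(seq_len(p), function(d)
    drop(cols[[d]]$B %*% theta_hat[[d]]) - mu_hat[d], numeric(n))
  colnames(Z) <- colnames(X)

  structure(list(theta_hat = theta_hat, mu_hat = mu_hat, Z = Z,
                 Z_init = Z_init, J = vapply(cols, `[[`, integer(1), "J"),
                 basis = lapply(cols, `[[`, "basis"),
                 prior = lapply(cols, `[[`, "prior"),
                 theta_draws = theta_draws,
                 n_iter = n_iter, burn_in = burn_in, seed = seed),
            class = "npn_transform")
}

#' Evaluate an estimated transformation on new points
#'
#' @param object an \code{npn_transform} fit.
#' @param d column index of the transformation.
#' @param x points in \eqn{[0,1]}.
#' @return \eqn{\hat f_d(x) - \hat\mu_d}, the centered transformed values.
#' @export
predict_transform <- function(object, d, x) {
  drop(basis_eval(object$basis[[d]], x) %*% object$theta_hat[[d]]) - object$mu_hat[d]
}

#' @export
print.npn_transform <- function(x, ...) {
  cat(sprintf("Nonparanormal transform fit: n = %d, p = %d, J = %s\n",
              nrow(x$Z), ncol(x$Z), paste(range(x$J), collapse = "-")))
  invisible(x)
}

#' Min-max rescale columns into [0, 1]
#'
#' @param X numeric matrix.
#' @return Matrix of the same shape with each column affinely mapped so its
#'   minimum is 0 and maximum is 1.
#' @export
minmax_rescale <- function(X) {
  X <- as.matrix(X)
  apply(X, 2L, function(x) {
    r <- range(x)
    if (r[1] == r[2]) stop("constant column cannot be rescaled", call. = FALSE)
    (x - r[1]) / (r[2] - r[1])
  })
}
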