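#' @title Gibbs samplers for the Cholesky regressions
#' @description
#' Both samplers work on the row regressions \eqn{Z_d = Z_{k>d}\beta_{k>d} +
#' \varepsilon_d} of the transformed data and rebuild a positive definite
#' precision matrix from every draw via [chol_to_precision()]. The horseshoe
#' sampler places the global-local hierarchy
#' \eqn{\beta_{kd} \sim N(0, \sigma_d^2 b_{kd} c^2 \lambda_d^2 / (p^2 k))},
#' \eqn{\lambda_d^2 \mid a_d \sim IG(1/2, 1/a_d)}, \eqn{a_d \sim IG(1/2,1)},
#' \eqn{b_{kd} \mid h_{kd} \sim IG(1/2, 1/h_{kd})},
#' \eqn{h_{kd} \sim IG(1/2, 1)} on the coefficients (so \eqn{\lambda_d} and
#' \eqn{b_{kd}} are half-Cauchy) with the row-index scaling that keeps the
#' sparsity of \eqn{\Omega} stable across rows. The Bernoulli-Gaussian
#' sampler uses the spike-and-slab likelihood of the VB engine and samples
#' the inclusion indicators sitewise from their exact full conditionals.
#' All scale draws are inverse-gamma conjugate updates; no thinning is
#' applied.
#' @name mcmcfit
NULL

rinvgamma1 <- function(shape, scale) {
  # clamped to keep downstream precisions finite when tiny shapes (prior-only
  # runs) produce astronomically large or small draws
  pmin(pmax(1 / stats::rgamma(length(scale), shape, rate = scale), 1e-300), 1e300)
}

# structural support of Omega implied by an active-set matrix of L:
# U binary lower-triangular with unit diagonal
support_from_indicators <- function(U) {
  (tcrossprod(U) > 0)
}

#' Horseshoe Gibbs sampler for the sparse precision matrix
#'
#' @param Z \code{n x p} matrix of transformed data.
#' @param c_sparsity sparsity constant \eqn{c}; candidates
#'   \code{c(0.1, 1, 10)} are compared by BIC in [bic_select()].
#' @param n_iter,burn_in total and discarded iterations (defaults 15000 and
#'   5000, i.e. 10000 retained draws).
#' @param A,B inverse-gamma hyperparameters of \eqn{\sigma_d^2}.
#' @param seed integer seed.
#' @param ref_partial optional \code{p x p} matrix of reference partial
#'   correlations (from [wishart_partial_corr()]); when supplied, every
#'   retained draw is thresholded by the 0-1-loss rule and the per-entry
#'   indicator frequencies are accumulated in \code{edge_freq}.
#' @param store_draws number of (thinned) retained \eqn{\Omega} draws to
#'   keep in the output (0 stores none; summaries are always accumulated).
#' @param store_latents keep per-iteration traces of the column-1 latents
#'   (for sampler validation).
#' @param fix_scales,sigma_fixed validation switches: freeze all local and
#'   global scales at 1, and optionally freeze \eqn{\sigma_d^2} at a given
#'   value, reducing the \eqn{\beta} update to the conjugate Bayesian linear
#'   model.
#' @return An object of class \code{npn_chain}: \code{omega_mean},
#'   \code{edge_freq} (or \code{NULL}), optional \code{draws} (array
#'   \code{p x p x store_draws}), optional latent traces, and bookkeeping.
#' @export
gibbs_horseshoe <- function(Z, c_sparsity = 1, n_iter = 15000, burn_in = 5000,
                            A = 0.01, B = 0.01, seed = 1, ref_partial = NULL,
                            store_draws = 0, store_latents = FALSE,
                            fix_scales = FALSE, sigma_fixed = NULL) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("'Z' contains non-finite values", call. = FALSE)
  n <- nrow(Z); p <- ncol(Z)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'", call. = FALSE)
  set.seed(seed)

  X <- lapply(seq_len(p - 1L), function(d) Z[, (d + 1L):p, drop = FALSE])
  XtX <- lapply(X, crossprod)
  Xty <- lapply(seq_len(p - 1L), function(d) drop(crossprod(X[[d]], Z[, d])))
  ztz <- colSums(Z^2)
  kidx <- lapply(seq_len(p - 1L), function(d) (d + 1L):p)  # row index k of each beta

  beta <- lapply(seq_len(p - 1L), function(d) numeric(p - d))
  sig2 <- rep(1, p)
  lam2 <- rep(1, p - 1L)
  a_aux <- rep(1, p - 1L)
  b_loc <- lapply(seq_len(p - 1L), function(d) rep(1, p - d))
  h_aux <- lapply(seq_len(p - 1L), function(d) rep(1, p - d))

  keep <- n_iter - burn_in
  om_sum <- matrix(0, p, p)
  ind_sum <- if (!is.null(ref_partial)) matrix(0, p, p) else NULL
  thin_at <- if (store_draws > 0)
    unique(round(seq(burn_in + 1, n_iter, length.out = min(store_draws, keep)))) else integer(0)
  draws <- if (store_draws > 0) array(NA_real_, c(p, p, length(thin_at))) else NULL
  trace <- if (store_latents)
    list(lambda_sq = numeric(n_iter), inv_a = numeric(n_iter),
         inv_h1 = numeric(n_iter),
         beta1 = matrix(NA_real_, n_iter, p - 1L)) else NULL
  draw_i <- 0L
  Bm <- matrix(0, p, p)

  for (it in seq_len(n_iter)) {
    for (d in seq_len(p - 1L)) {
      m <- p - d
      k <- kidx[[d]]
      # prior variance of beta_kd is sig2 * v_k with v_k = b c^2 lam^2/(p^2 k)
      v <- if (fix_scales) rep(c_sparsity^2 / p^2, m) else
        pmin(pmax(b_loc[[d]] * c_sparsity^2 * lam2[d] / (p^2 * k), 1e-290), 1e290)
      Q <- XtX[[d]] + diag(1 / v, m)
      Rq <- chol(Q)
      mean_b <- backsolve(Rq, backsolve(Rq, Xty[[d]], transpose = TRUE))
      beta[[d]] <- mean_b + sqrt(sig2[d]) * backsolve(Rq, stats::rnorm(m))
      resid2 <- ztz[d] - 2 * sum(beta[[d]] * Xty[[d]]) +
        drop(crossprod(beta[[d]], XtX[[d]] %*% beta[[d]]))
      prior_quad <- sum(beta[[d]]^2 / v)
      if (is.null(sigma_fixed)) {
        sig2[d] <- rinvgamma1(A + n / 2 + m / 2,
                              B + max(resid2, 0) / 2 + prior_quad / 2)
      } else sig2[d] <- sigma_fixed
      if (!fix_scales) {
        sc <- beta[[d]]^2 * p^2 * k / (2 * sig2[d] * c_sparsity^2)
        lam2[d] <- rinvgamma1((m + 1) / 2, 1 / a_aux[d] + sum(sc / b_loc[[d]]))
        a_aux[d] <- rinvgamma1(1, 1 + 1 / lam2[d])
        b_loc[[d]] <- rinvgamma1(1, 1 / h_aux[[d]] + sc / lam2[d])
        h_aux[[d]] <- rinvgamma1(1, 1 + 1 / b_loc[[d]])
      }
    }
    sig2[p] <- if (is.null(sigma_fixed))
      rinvgamma1(A + n / 2, B + ztz[p] / 2) else sigma_fixed

    if (store_latents) {
      trace$lambda_sq[it] <- lam2[1]
      trace$inv_a[it] <- 1 / a_aux[1]
      trace$inv_h1[it] <- 1 / h_aux[[1]][1]
      trace$beta1[it, ] <- beta[[1]]
    }
    if (it > burn_in) {
      for (d in seq_len(p - 1L)) Bm[(d + 1L):p, d] <- beta[[d]]
      Om <- chol_to_precision(Bm, 1 / sig2)
      om_sum <- om_sum + Om
      if (!is.null(ref_partial)) {
        e <- partial_corr(Om)
        ind_sum <- ind_sum + threshold_partial(e, ref_partial)
      }
      if (store_draws > 0 && it %in% thin_at) {
        draw_i <- draw_i + 1L
        draws[, , draw_i] <- Om
      }
    }
  }

  structure(list(prior = "horseshoe", omega_mean = om_sum / keep,
                 edge_freq = if (!is.null(ind_sum)) ind_sum / keep else NULL,
                 draws = draws, trace = trace, c_sparsity = c_sparsity,
                 n_iter = n_iter, burn_in = burn_in, n = n, p = p, seed = seed),
            class = "npn_chain")
}

#' Bernoulli-Gaussian Gibbs sampler for the sparse precision matrix
#'
#' Spike-and-slab chain on \eqn{(\beta, \upsilon, \sigma^2)}: the
#' coefficients of the active columns are drawn from their conjugate normal
#' conditional (all \eqn{\beta} keep the \eqn{N(0, g^2)} prior; inactive
#' coefficients are refreshed from it), each indicator from its Bernoulli
#' full conditional given the rest, and \eqn{\sigma_d^2} from its
#' inverse-gamma conditional. The indicator probabilities receive the same
#' floating-point guards as the VB engine. Edge support per draw comes from
#' the indicator matrix through the Cholesky support algebra, and the
#' accumulated frequencies feed the median probability model.
#'
#' @inheritParams gibbs_horseshoe
#' @param rho prior inclusion probabilities \eqn{\rho^*_{kd}} (formats of
#'   [vb_fit()]), normally the tuned values from [vb_tune()].
#' @param gsq slab variance \eqn{g^2} (default 10).
#' @param upsilon_init optional initial 0/1 indicators (per-column list),
#'   normally \code{vb_tune(...)$upsilon_init}.
#' @return An \code{npn_chain} with \code{omega_mean}, \code{edge_freq},
#'   optional stored draws, and \code{upsilon_freq} (per-entry inclusion
#'   frequencies of the indicators themselves).
#' @export
gibbs_bg <- function(Z, rho, gsq = 10, A = 0.01, B = 0.01,
                     n_iter = 15000, burn_in = 5000, seed = 1,
                     upsilon_init = NULL, store_draws = 0,
                     store_latents = FALSE) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("'Z' contains non-finite values", call. = FALSE)
  n <- nrow(Z); p <- ncol(Z)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'", call. = FALSE)
  set.seed(seed)
  rho <- vb_expand_rho(rho, p)

  X <- lapply(seq_len(p - 1L), function(d) Z[, (d + 1L):p, drop = FALSE])
  XtX <- lapply(X, crossprod)
  Xty <- lapply(seq_len(p - 1L), function(d) drop(crossprod(X[[d]], Z[, d])))
  ztz <- colSums(Z^2)

  beta <- lapply(seq_len(p - 1L), function(d) numeric(p - d))
  ups <- if (is.null(upsilon_init))
    lapply(rho, function(r) as.integer(r > 0.5)) else
    lapply(upsilon_init, function(u) as.integer(u))
  sig2 <- rep(1, p)

  keep <- n_iter - burn_in
  om_sum <- matrix(0, p, p)
  ind_sum <- matrix(0, p, p)
  ups_sum <- matrix(0, p, p)
  thin_at <- if (store_draws > 0)
    unique(round(seq(burn_in + 1, n_iter, length.out = min(store_draws, keep)))) else integer(0)
  draws <- if (store_draws > 0) array(NA_real_, c(p, p, length(thin_at))) else NULL
  trace <- if (store_latents)
    list(beta1 = matrix(NA_real_, n_iter, p - 1L), sig2_1 = numeric(n_iter)) else NULL
  draw_i <- 0L
  Bm <- matrix(0, p, p)
  Um <- diag(1L, p)

  for (it in seq_len(n_iter)) {
    for (d in seq_len(p - 1L)) {
      m <- p - d
      u <- ups[[d]]
      act <- which(u == 1L)
      b <- stats::rnorm(m, 0, sqrt(gsq))      # prior refresh (inactive entries)
      if (length(act)) {
        Q <- XtX[[d]][act, act, drop = FALSE] / sig2[d] + diag(1 / gsq, length(act))
        Rq <- chol(Q)
        mb <- backsolve(Rq, backsolve(Rq, Xty[[d]][act] / sig2[d], transpose = TRUE))
        b[act] <- mb + backsolve(Rq, stats::rnorm(length(act)))
      }
      # sitewise indicator updates given beta
      fit_act <- if (length(act)) drop(X[[d]][, act, drop = FALSE] %*% b[act]) else numeric(n)
      r0 <- Z[, d] - fit_act
      for (k in seq_len(m)) {
        rk <- if (u[k] == 1L) r0 + b[k] * X[[d]][, k] else r0  # residual with k off
        eta <- log(rho[[d]][k]) - log1p(-rho[[d]][k]) +
          (2 * b[k] * sum(X[[d]][, k] * rk) - b[k]^2 * XtX[[d]][k, k]) / (2 * sig2[d])
        if (rho[[d]][k] == 0) eta <- -Inf
        if (rho[[d]][k] == 1) eta <- Inf
        wk <- expit_guard(eta)
        new_u <- stats::rbinom(1L, 1L, wk)
        if (new_u != u[k]) {
          r0 <- if (new_u == 1L) rk - b[k] * X[[d]][, k] else rk
          u[k] <- new_u
        }
      }
      ups[[d]] <- u
      beta[[d]] <- b
      resid2 <- sum(r0^2)
      sig2[d] <- rinvgamma1(A + n / 2, B + resid2 / 2)
    }
    sig2[p] <- rinvgamma1(A + n / 2, B + ztz[p] / 2)

    if (store_latents) {
      trace$beta1[it, ] <- beta[[1]]
      trace$sig2_1[it] <- sig2[1]
    }
    if (it > burn_in) {
      for (d in seq_len(p - 1L)) {
        Bm[(d + 1L):p, d] <- beta[[d]] * ups[[d]]
        Um[(d + 1L):p, d] <- ups[[d]]
      }
      Om <- chol_to_precision(Bm, 1 / sig2)
      om_sum <- om_sum + Om
      ind_sum <- ind_sum + support_from_indicators(Um)
      ups_sum <- ups_sum + Um
      if (store_draws > 0 && it %in% thin_at) {
        draw_i <- draw_i + 1L
        draws[, , draw_i] <- Om
      }
    }
  }

  structure(list(prior = "bg", omega_mean = om_sum / keep,
                 edge_freq = ind_sum / keep, upsilon_freq = ups_sum / keep,
                 draws = draws, trace = trace, n_iter = n_iter,
                 burn_in = burn_in, n = n, p = p, seed = seed),
            class = "npn_chain")
}

#' @export
print.npn_chain <- function(x, ...) {
  cat(sprintf("%s chain: p = %d, n = %d, %d retained draws\n",
              x$prior, x$p, x$n, x$n_iter - x$burn_in))
  invisible(x)
}
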