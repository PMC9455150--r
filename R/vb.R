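#' @title Mean-field variational Bayes for the Bernoulli-Gaussian Cholesky
#'   regressions
#'
#' @description
#' The transformed data \eqn{Z} (\code{n x p}) follow the row regressions
#' \eqn{Z_d = Z_{k>d}(\Upsilon_d \circ \beta_d) + \varepsilon_d} with
#' \eqn{\beta_{kd} \sim N(0, g^2)}, inclusion indicators
#' \eqn{\upsilon_{kd} \sim Ber(\rho^*_{kd})} and
#' \eqn{\sigma_d^2 \sim IG(A, B)}. The variational family factorizes as
#' \eqn{q(\beta_d) = N(\alpha_d, \Sigma_d)},
#' \eqn{q(\sigma_d^2) = IG(A + n/2, s_d)} and
#' \eqn{q(\upsilon_{kd}) = Ber(w_{kd})}; coordinate ascent on the evidence
#' lower bound gives closed-form updates. With \eqn{W_d = diag(w)},
#' \eqn{\Omega_d = ww' + W_d(I - W_d)} (the second-moment matrix of the
#' indicators) and \eqn{\tau_d = E_q[1/\sigma_d^2]}:
#' \deqn{\Sigma_d = \{\tau_d (Z_{k>d}'Z_{k>d} \circ \Omega_d) + g^{-2}I\}^{-1},
#'   \quad \alpha_d = \tau_d \Sigma_d W_d Z_{k>d}' Z_d,}
#' the inclusion scores are updated sitewise from the ELBO stationarity
#' condition, and \eqn{s_d = B + E_q\|Z_d - Z_{k>d}\Upsilon\beta\|^2/2},
#' \eqn{\tau_d = (2A + n)/(2 s_d)}. Within each column the scan ends with
#' \eqn{(s_d, \tau_d)} so that the simplified closed-form lower bound
#' returned by [vb_elbo()] equals the exact ELBO of the returned state.
#'
#' @name vbfit
NULL

vb_hyper <- function(gsq = 10, A = 0.01, B = 0.01, tau0 = 1000, tol = 1e-6,
                     max_sweeps = 1000) {
  stopifnot(gsq > 0, A > 0, B > 0, tau0 > 0, tol > 0)
  list(gsq = gsq, A = A, B = B, tau0 = tau0, tol = tol, max_sweeps = max_sweeps)
}

# rho given as a single number, a p-vector (recycled down columns by row
# index k), or a list of length p-1 with the per-column vectors over
# k = (d+1):p.
vb_expand_rho <- function(rho, p) {
  if (is.list(rho)) {
    stopifnot(length(rho) == p - 1L)
    out <- rho
  } else if (length(rho) == 1L) {
    out <- lapply(seq_len(p - 1L), function(d) rep(rho, p - d))
  } else if (length(rho) == p) {
    out <- lapply(seq_len(p - 1L), function(d) rho[(d + 1L):p])
  } else stop("'rho' must be scalar, length p, or a list of length p-1", call. = FALSE)
  bad <- vapply(out, function(r) any(r < 0 | r > 1 | !is.finite(r)), logical(1))
  if (any(bad)) stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
  out
}

vb_design <- function(Z) {
  p <- ncol(Z)
  lapply(seq_len(p - 1L), function(d) {
    Xd <- Z[, (d + 1L):p, drop = FALSE]
    list(XtX = crossprod(Xd), Xty = drop(crossprod(Xd, Z[, d])),
         ztz = sum(Z[, d]^2))
  })
}

vb_init <- function(Z, rho, hyper, w_init = NULL) {
  n <- nrow(Z); p <- ncol(Z)
  rho <- vb_expand_rho(rho, p)
  if (!is.null(w_init)) w_init <- vb_expand_rho(w_init, p)
  state <- list(
    n = n, p = p, hyper = hyper, rho = rho,
    alpha = lapply(seq_len(p - 1L), function(d) numeric(p - d)),
    Sigma = lapply(seq_len(p - 1L), function(d) diag(hyper$gsq, p - d)),
    w = if (is.null(w_init)) lapply(rho, function(r) rep(0.5, length(r))) else w_init,
    s = rep(hyper$B + 1, p),
    tau = rep(hyper$tau0, p),
    elbo_trace = numeric(0))
  class(state) <- "npn_vb"
  state
}

# guarded expit per the numerical rule: exact 0 below the double epsilon,
# exact 1 on overflow of exp(eta)
expit_guard <- function(eta) {
  w <- 1 / (1 + exp(-eta))
  w[eta < log(2^-52)] <- 0
  w[eta > 709.7827] <- 1
  w
}

#' One coordinate-ascent sweep of the variational updates
#'
#' @param Z \code{n x p} matrix of transformed data.
#' @param state a VB state from [vb_fit()] internals (class \code{npn_vb}).
#' @param design precomputed cross-products (internal; recomputed if
#'   \code{NULL}).
#' @param update_w logical; the sparsity tuning stage freezes the inclusion
#'   probabilities.
#' @return The updated state.
#' @export
vb_sweep <- function(Z, state, design = NULL, update_w = TRUE) {
  if (any(!is.finite(Z))) stop("'Z' contains non-finite values", call. = FALSE)
  if (is.null(design)) design <- vb_design(Z)
  n <- state$n; p <- state$p
  hy <- state$hyper
  a_post <- hy$A + n / 2
  for (d in seq_len(p - 1L)) {
    ds <- design[[d]]
    w <- state$w[[d]]; rho <- state$rho[[d]]
    tau <- state$tau[d]
    m <- p - d
    Om <- tcrossprod(w) + diag(w * (1 - w), m)
    Sig <- chol2inv(chol(tau * (ds$XtX * Om) + diag(1 / hy$gsq, m)))
    alpha <- tau * drop(Sig %*% (w * ds$Xty))
    if (update_w) {
      # sitewise stationarity update of q(upsilon_kd)
      M2 <- tcrossprod(alpha) + Sig            # E[beta beta']
      for (k in seq_len(m)) {
        lin <- ds$XtX[k, ] * M2[k, ]
        eta <- log(rho[k]) - log1p(-rho[k]) -
          (tau / 2) * M2[k, k] * ds$XtX[k, k] +
          tau * (alpha[k] * ds$Xty[k] - (sum(w * lin) - w[k] * lin[k]))
        if (rho[k] == 0) eta <- -Inf
        if (rho[k] == 1) eta <- Inf
        w[k] <- expit_guard(eta)
      }
    }
    Om <- tcrossprod(w) + diag(w * (1 - w), m)
    quad <- ds$ztz - 2 * sum(w * alpha * ds$Xty) +
      sum((ds$XtX * Om) * (tcrossprod(alpha) + Sig))
    s <- hy$B + quad / 2
    state$alpha[[d]] <- alpha
    state$Sigma[[d]] <- Sig
    state$w[[d]] <- w
    state$s[d] <- s
    state$tau[d] <- a_post / s
  }
  state$s[p] <- hy$B + sum(Z[, p]^2) / 2
  state$tau[p] <- a_post / state$s[p]
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form variational lower bound
#'
#' Evaluates the simplified ELBO of the Bernoulli-Gaussian regressions. The
#' expression is exact (equals \eqn{E_q[\log p(Z,\kappa) - \log q(\kappa)]})
#' whenever \eqn{s_d} and \eqn{\tau_d} are consistent with the current
#' \eqn{(\alpha_d, \Sigma_d, w_d)}, which [vb_sweep()] guarantees by
#' updating them last. Terms \eqn{0\log 0} from inclusion probabilities that
#' are exactly 0 or 1 are taken as 0.
#'
#' @inheritParams vb_sweep
#' @param restricted if \code{TRUE}, drop the terms of the last column
#'   (\eqn{Z_p}, \eqn{\sigma_p^2}); used by the sparsity tuning stage, which
#'   compares bounds that only involve the \eqn{p-1} regressions.
#' @return The scalar lower bound.
#' @export
vb_elbo <- function(Z, state, restricted = FALSE) {
  n <- state$n; p <- state$p
  hy <- state$hyper
  a_post <- hy$A + n / 2
  bern <- function(w, rho) {
    t1 <- ifelse(w > 0, w * (log(rho) - log(w)), 0)
    t2 <- ifelse(w < 1, (1 - w) * (log1p(-rho) - log1p(-w)), 0)
    sum(t1 + t2)
  }
  n_cols <- if (restricted) p - 1L else p
  const <- n_cols * (-n / 2 * log(2 * pi) + hy$A * log(hy$B) - lgamma(hy$A) +
                       lgamma(a_post))
  v <- const - a_post * sum(log(state$s[seq_len(n_cols)]))
  for (d in seq_len(p - 1L)) {
    m <- p - d
    Sig <- state$Sigma[[d]]; alpha <- state$alpha[[d]]
    v <- v + m / 2 - (m / 2) * log(hy$gsq) +
      determinant(Sig, logarithm = TRUE)$modulus / 2 -
      (sum(alpha^2) + sum(diag(Sig))) / (2 * hy$gsq) +
      bern(state$w[[d]], state$rho[[d]])
  }
  as.numeric(v)
}

#' Fit the variational approximation
#'
#' Iterates [vb_sweep()] until the lower bound changes by less than
#' \code{tol} (default \eqn{10^{-6}}) or \code{max_sweeps} is hit (with a
#' warning). The trace of bound values is stored in the returned state; an
#' ascent violation beyond numerical tolerance aborts, since it signals a
#' derivation bug rather than a data problem.
#'
#' @param Z \code{n x p} matrix of transformed data.
#' @param rho prior inclusion probabilities \eqn{\rho^*_{kd}}; scalar,
#'   length-\code{p} vector indexed by row, or per-column list. Usually the
#'   output of [vb_tune()].
#' @param gsq,A,B,tau0,tol,max_sweeps hyperparameters: slab variance
#'   (default 10), inverse-gamma shape/scale (0.01), initial precision mean
#'   (1000), stopping threshold (1e-6).
#' @param w_init optional initial inclusion probabilities (same formats as
#'   \code{rho}).
#' @param update_w internal switch used by the tuning stage.
#' @return Converged state of class \code{npn_vb}, with \code{elbo_trace}.
#' @export
vb_fit <- function(Z, rho, gsq = 10, A = 0.01, B = 0.01, tau0 = 1000,
                   tol = 1e-6, max_sweeps = 1000, w_init = NULL,
                   update_w = TRUE) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("'Z' contains non-finite values", call. = FALSE)
  if (ncol(Z) < 2L) stop("need at least two columns", call. = FALSE)
  hyper <- vb_hyper(gsq, A, B, tau0, tol, max_sweeps)
  design <- vb_design(Z)
  state <- vb_init(Z, rho, hyper, w_init)
  prev <- -Inf
  for (sw in seq_len(max_sweeps)) {
    state <- vb_sweep(Z, state, design, update_w = update_w)
    cur <- vb_elbo(Z, state)
    state$elbo_trace <- c(state$elbo_trace, cur)
    if (cur < prev - 1e-8 * max(1, abs(prev)))
      stop(sprintf("variational lower bound decreased (%.10g -> %.10g)", prev, cur),
           call. = FALSE)
    if (is.finite(prev) && abs(cur - prev) < tol) return(state)
    prev <- cur
  }
  warning("variational Bayes did not converge within 'max_sweeps'; returning last state")
  state
}

#' Tune the sparsity hyperparameters of the variational fit
#'
#' Two-stage procedure. Stage 1 fits the variational approximation with the
#' fixed plan \eqn{\rho^*_k = expit(-0.5 n)/(p\sqrt k)} to obtain inclusion
#' probabilities \eqn{w} (numerically 0/1). Stage 2 holds \eqn{w} fixed,
#' refits the remaining factors, and evaluates the lower bound restricted to
#' the first \eqn{p-1} regressions on the grid
#' \eqn{\rho^*_{kd} = expit(\iota_j)\, c_j/(p\sqrt k)}, with \eqn{c_j} on an
#' equally spaced grid of 50 points in \eqn{[0.1, 10]} and \eqn{\iota_j} on
#' an equally spaced grid of 50 points in \eqn{[-15, 5]}. Grids are paired
#' by \eqn{j} by default; \code{product = TRUE} scans the full Cartesian
#' product. With \eqn{w} fixed, only the Bernoulli cross-entropy term of the
#' bound varies over the grid, so the scan is cheap.
#'
#' @param Z matrix used for tuning (the initialization-stage transformed
#'   data \eqn{Z_{init} = Y_{init} - \mu_{init}} in the full pipeline).
#' @param grid_len number of grid points (50).
#' @param product scan the full \code{grid_len^2} product instead of paired
#'   values.
#' @param ... hyperparameters passed to [vb_fit()].
#' @return List with \code{rho} (selected per-column inclusion
#'   probabilities), \code{w} (stage-1 inclusion probabilities),
#'   \code{upsilon_init} (0/1 rounding of \code{w}, the MCMC initializer),
#'   \code{iota}, \code{c} (selected grid values) and the grid table
#'   \code{grid}.
#' @export
vb_tune <- function(Z, grid_len = 50, product = FALSE, ...) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (grid_len < 1) stop("empty tuning grid", call. = FALSE)
  rho_fixed <- lapply(seq_len(p - 1L), function(d) {
    k <- (d + 1L):p
    pmin(1, stats::plogis(-0.5 * n) / (p * sqrt(k)))
  })
  stage1 <- vb_fit(Z, rho_fixed, ...)
  w <- stage1$w
  # refit the non-indicator factors once with w frozen (they do not depend
  # on rho), then score the Bernoulli term over the grid
  stage2 <- vb_fit(Z, rho_fixed, w_init = w, update_w = FALSE, ...)
  cs <- seq(0.1, 10, length.out = grid_len)
  iotas <- seq(-15, 5, length.out = grid_len)
  pairs <- if (product) expand.grid(iota = iotas, c = cs) else
    data.frame(iota = iotas, c = cs)
  score <- function(iota, cj) {
    st <- stage2
    st$rho <- lapply(seq_len(p - 1L), function(d) {
      k <- (d + 1L):p
      pmin(1, stats::plogis(iota) * cj / (p * sqrt(k)))
    })
    vb_elbo(Z, st, restricted = TRUE)
  }
  pairs$vlb <- mapply(score, pairs$iota, pairs$c)
  best <- which.max(pairs$vlb)
  rho_sel <- lapply(seq_len(p - 1L), function(d) {
    k <- (d + 1L):p
    pmin(1, stats::plogis(pairs$iota[best]) * pairs$c[best] / (p * sqrt(k)))
  })
  list(rho = rho_sel, w = w,
       upsilon_init = lapply(w, function(x) as.integer(x > 0.5)),
       iota = pairs$iota[best], c = pairs$c[best], grid = pairs)
}

#' Posterior summaries from the variational distribution
#'
#' Draws \code{n_draws} independent samples of \eqn{(\beta, \upsilon,
#' \sigma^2)} from the variational distribution, reconstructs the precision
#' matrix of each draw from the effective coefficients
#' \eqn{\beta \circ \upsilon} via [chol_to_precision()], and averages them
#' for the Bayes estimate \eqn{\hat\Omega}. The support of each draw's
#' \eqn{\omega_{kd}} follows from the indicator draw through the Cholesky
#' support algebra (\eqn{\omega_{kd} \neq 0} iff some \eqn{m \le \min(k,d)}
#' has both factor entries active); the median probability model keeps an
#' edge when its support frequency exceeds one half (strictly).
#'
#' @param state converged state from [vb_fit()].
#' @param n_draws number of variational draws (default 500).
#' @param seed integer seed.
#' @return List with \code{omega} (\eqn{\hat\Omega}), \code{edges} (binary
#'   edge matrix) and \code{edge_freq} (per-entry support frequencies).
#' @export
vb_precision <- function(state, n_draws = 500, seed = 1) {
  set.seed(seed)
  p <- state$p
  hy <- state$hyper
  a_post <- hy$A + state$n / 2
  chol_S <- lapply(state$Sigma, chol)
  om_sum <- matrix(0, p, p)
  ind_sum <- matrix(0, p, p)
  beta <- matrix(0, p, p)
  for (t in seq_len(n_draws)) {
    U <- diag(1L, p)
    for (d in seq_len(p - 1L)) {
      m <- p - d
      bd <- state$alpha[[d]] + drop(crossprod(chol_S[[d]], stats::rnorm(m)))
      ud <- stats::rbinom(m, 1L, state$w[[d]])
      beta[(d + 1L):p, d] <- bd * ud
      U[(d + 1L):p, d] <- ud
    }
    phi <- stats::rgamma(p, shape = a_post, rate = state$s)
    om_sum <- om_sum + chol_to_precision(beta, phi)
    ind_sum <- ind_sum + (tcrossprod(U) > 0)
  }
  freq <- ind_sum / n_draws
  edges <- (freq > 0.5)
  diag(edges) <- FALSE
  storage.mode(edges) <- "integer"
  list(omega = om_sum / n_draws, edges = edges, edge_freq = freq)
}

#' @export
print.npn_vb <- function(x, ...) {
  cat(sprintf("VB state: p = %d, n = %d, %d sweeps, VLB = %.6g\n",
              x$p, x$n, length(x$elbo_trace),
              if (length(x$elbo_trace)) utils::tail(x$elbo_trace, 1) else NA))
  invisible(x)
}
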