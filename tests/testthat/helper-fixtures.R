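# Shared fixtures and independent oracles used across the suite.

# random SPD matrix with controlled conditioning
rand_spd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(0.5, p)
}

# small Gaussian regression-structured data set for the sparse engines
toy_Z <- function(n, p, seed = 1, Omega = NULL) {
  set.seed(seed)
  if (is.null(Omega)) Omega <- sim_precision("circle", max(p, 3))[1:p, 1:p, drop = FALSE]
  Omega <- Omega + diag(0.1, p)    # keep small principal blocks SPD
  t(backsolve(chol(Omega), matrix(rnorm(n * p), p, n)))
}

# Monte-Carlo estimate of the exact ELBO E_q[log p(Z, kappa) - log q(kappa)]
# for the Bernoulli-Gaussian regressions; independent of vb_elbo()'s
# closed form.
mc_elbo <- function(Z, state, n_mc = 1e5, seed = 99) {
  set.seed(seed)
  n <- state$n; p <- state$p
  hy <- state$hyper
  a <- hy$A + n / 2
  dinvg <- function(x, sh, sc) sh * log(sc) - lgamma(sh) - (sh + 1) * log(x) - sc / x
  comps <- matrix(0, n_mc, p)
  for (d in seq_len(p - 1L)) {
    m <- p - d
    X <- Z[, (d + 1L):p, drop = FALSE]
    ch <- chol(state$Sigma[[d]])
    w <- pmin(pmax(state$w[[d]], 1e-300), 1 - 1e-15)
    rho <- pmin(pmax(state$rho[[d]], 1e-300), 1 - 1e-15)
    bet <- matrix(rnorm(n_mc * m), n_mc) %*% ch +
      matrix(state$alpha[[d]], n_mc, m, byrow = TRUE)
    ups <- matrix(rbinom(n_mc * m, 1, rep(state$w[[d]], each = n_mc)), n_mc, m)
    sg2 <- 1 / rgamma(n_mc, a, rate = state$s[d])
    fit <- tcrossprod(bet * ups, X)
    rss <- rowSums((matrix(Z[, d], n_mc, n, byrow = TRUE) - fit)^2)
    lp <- -n / 2 * log(2 * pi * sg2) - rss / (2 * sg2) +
      rowSums(dnorm(bet, 0, sqrt(hy$gsq), log = TRUE)) +
      rowSums(ups * matrix(log(rho), n_mc, m, byrow = TRUE) +
                (1 - ups) * matrix(log1p(-rho), n_mc, m, byrow = TRUE)) +
      dinvg(sg2, hy$A, hy$B)
    ctr <- bet - matrix(state$alpha[[d]], n_mc, m, byrow = TRUE)
    mah <- colSums(forwardsolve(t(ch), t(ctr))^2)
    lq <- -m / 2 * log(2 * pi) - sum(log(diag(ch))) - mah / 2 +
      rowSums(ups * matrix(log(w), n_mc, m, byrow = TRUE) +
                (1 - ups) * matrix(log1p(-w), n_mc, m, byrow = TRUE)) +
      dinvg(sg2, a, state$s[d])
    comps[, d] <- lp - lq
  }
  sg2 <- 1 / rgamma(n_mc, a, rate = state$s[p])
  comps[, p] <- -n / 2 * log(2 * pi * sg2) - sum(Z[, p]^2) / (2 * sg2) +
    dinvg(sg2, hy$A, hy$B) - dinvg(sg2, a, state$s[p])
  tot <- rowSums(comps)
  list(est = mean(tot), se = sd(tot) / sqrt(n_mc))
}

# rejection sampler oracle for truncated normals
rtmvn_reject <- function(n_keep, mean, cov, F, g, max_tries = 5e6) {
  p <- length(mean)
  R <- chol(cov)
  out <- matrix(NA_real_, 0, p)
  tries <- 0
  while (nrow(out) < n_keep && tries < max_tries) {
    block <- matrix(rnorm(1e4 * p), ncol = p) %*% R +
      matrix(mean, 1e4, p, byrow = TRUE)
    ok <- block %*% t(F) + matrix(g, 1e4, nrow(F), byrow = TRUE) > 0
    out <- rbind(out, block[rowSums(ok) == nrow(F), , drop = FALSE])
    tries <- tries + 1e4
  }
  out[seq_len(min(n_keep, nrow(out))), , drop = FALSE]
}

# batch-means standard error for an autocorrelated chain
batch_se <- function(x, n_batch = 40) {
  b <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  sd(means) / sqrt(n_batch)
}

# exact marginal likelihood p(Z_d | upsilon) for the Bernoulli-Gaussian
# regression, integrating beta (analytically) and sigma^2 (quadrature)
bg_marginal <- function(zd, X, act, gsq, A, B) {
  n <- length(zd)
  XA <- X[, act, drop = FALSE]
  loglik_sig <- function(lsig2) {
    s2 <- exp(lsig2)
    C <- s2 * diag(n)
    if (length(act)) C <- C + gsq * tcrossprod(XA)
    ch <- chol(C)
    -sum(log(diag(ch))) - n / 2 * log(2 * pi) -
      0.5 * sum(backsolve(ch, zd, transpose = TRUE)^2) +
      A * log(B) - lgamma(A) - A * lsig2 - B / s2  # IG prior in log sigma^2 coords
  }
  ls <- seq(-12, 8, length.out = 400)
  vals <- vapply(ls, loglik_sig, numeric(1))
  mx <- max(vals)
  mx + log(sum(exp(vals - mx)) * (ls[2] - ls[1]))
}
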