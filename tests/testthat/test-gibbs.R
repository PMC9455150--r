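test_that("horseshoe beta update matches the conjugate closed form when scales are frozen", {
  set.seed(51)
  n <- 40; p <- 3
  Z <- toy_Z(n, p, seed = 51)
  cc <- 2; s2 <- 0.8
  ch <- gibbs_horseshoe(Z, c_sparsity = cc, n_iter = 4000, burn_in = 500,
                        seed = 5, fix_scales = TRUE, sigma_fixed = s2,
                        store_latents = TRUE)
  # closed form: beta | sigma^2 ~ N((X'X + diag(p^2/c^2))^{-1} X'z, ...)
  X <- Z[, 2:3]
  Q <- crossprod(X) + diag(p^2 / cc^2, 2)
  mean_th <- solve(Q, crossprod(X, Z[, 1]))
  cov_th <- s2 * solve(Q)
  b1 <- ch$trace$beta1[501:4000, ]
  for (j in 1:2) {
    expect_lt(abs(mean(b1[, j]) - mean_th[j]), 3 * batch_se(b1[, j]))
    expect_lt(abs(var(b1[, j]) - cov_th[j, j]),
              3 * batch_se((b1[, j] - mean(b1[, j]))^2) + 0.02 * cov_th[j, j])
  }
})

test_that("prior-only horseshoe chain reproduces the prior latent moments", {
  # n = 0: the Gibbs kernels cycle the prior conditionals; marginals of the
  # auxiliary inverse latents are Gamma(1/2, 1) with mean 1/2, and the
  # global scale is squared half-Cauchy with median 1
  Z0 <- matrix(numeric(0), 0, 3)
  ch <- gibbs_horseshoe(Z0, c_sparsity = 1, n_iter = 20000, burn_in = 2000,
                        seed = 6, store_latents = TRUE)
  keep <- 2001:20000
  inv_a <- ch$trace$inv_a[keep]
  inv_h <- ch$trace$inv_h1[keep]
  expect_lt(abs(mean(inv_a) - 0.5), 3 * batch_se(inv_a))
  expect_lt(abs(mean(inv_h) - 0.5), 3 * batch_se(inv_h))
  med_ind <- ch$trace$lambda_sq[keep] > 1
  expect_lt(abs(mean(med_ind) - 0.5), 3 * batch_se(med_ind))
})

test_that("every retained precision draw is positive definite", {
  Z <- toy_Z(30, 4, seed = 52)
  ch <- gibbs_horseshoe(Z, 1, n_iter = 300, burn_in = 100, seed = 2,
                        store_draws = 30)
  for (i in seq_len(dim(ch$draws)[3])) expect_silent(chol(ch$draws[, , i]))
  cb <- gibbs_bg(Z, rho = 0.3, n_iter = 300, burn_in = 100, seed = 2,
                 store_draws = 30)
  for (i in seq_len(dim(cb$draws)[3])) expect_silent(chol(cb$draws[, , i]))
})

test_that("spike-and-slab sampler reduces to conjugate regression when selection is off", {
  set.seed(53)
  n <- 50; p <- 3
  Z <- toy_Z(n, p, seed = 53)
  gsq <- 1e6   # flat slab: posterior mean of beta is the OLS solution
  ch <- gibbs_bg(Z, rho = 1, gsq = gsq, n_iter = 6000, burn_in = 1000,
                 seed = 3, store_latents = TRUE)
  expect_true(all(ch$upsilon_freq[lower.tri(diag(p))] == 1))
  ols <- qr.solve(Z[, 2:3], Z[, 1])
  b1 <- ch$trace$beta1[1001:6000, ]
  for (j in 1:2)
    expect_lt(abs(mean(b1[, j]) - ols[j]), 3 * batch_se(b1[, j]))
})

test_that("vanishing inclusion prior empties the indicator matrix", {
  Z <- toy_Z(30, 3, seed = 54)
  ch <- gibbs_bg(Z, rho = 1e-12, n_iter = 500, burn_in = 100, seed = 4)
  expect_true(all(ch$upsilon_freq[lower.tri(diag(3))] < 0.05))
  offd <- ch$omega_mean[row(diag(3)) != col(diag(3))]
  expect_true(all(abs(offd) < 0.05 * max(diag(ch$omega_mean))))
})

test_that("inclusion probabilities match exhaustive enumeration at p = 3", {
  set.seed(55)
  n <- 15; p <- 3
  Z <- toy_Z(n, p, seed = 55)
  rho <- 0.4; gsq <- 10; A <- 0.01; B <- 0.01
  ch <- gibbs_bg(Z, rho = rho, gsq = gsq, A = A, B = B,
                 n_iter = 52000, burn_in = 2000, seed = 7, store_latents = TRUE)
  # oracle: enumerate upsilon configurations with beta and sigma^2
  # integrated out (conjugate normal + 1-D quadrature)
  post_incl <- function(d) {
    ms <- (d + 1):p
    X <- Z[, ms, drop = FALSE]
    cfgs <- as.matrix(expand.grid(rep(list(0:1), length(ms))))
    lw <- apply(cfgs, 1, function(u) {
      bg_marginal(Z[, d], X, which(u == 1), gsq, A, B) +
        sum(u) * log(rho) + sum(1 - u) * log(1 - rho)
    })
    w <- exp(lw - max(lw)); w <- w / sum(w)
    drop(crossprod(cfgs, w))
  }
  for (d in 1:2) {
    th <- post_incl(d)
    got <- ch$upsilon_freq[(d + 1):p, d]
    for (j in seq_along(th)) {
      # conservative SE: 50k correlated draws, effective size taken as 5k
      se <- sqrt(max(th[j] * (1 - th[j]), 1e-4) / 5000)
      expect_lt(abs(got[j] - th[j]), 3 * se + 0.01)
    }
  }
})

test_that("variational and spike-and-slab Gibbs estimates agree on a well-identified instance", {
  # both engines receive the same inclusion prior so that the comparison
  # isolates the inference engines themselves
  set.seed(56)
  p <- 5; n <- 500
  Om <- sim_precision("circle", p)
  Z <- toy_Z(n, p, seed = 56, Omega = Om)
  rho <- 0.2
  vb <- vb_fit(Z, rho)
  est <- vb_precision(vb, n_draws = 2000, seed = 8)
  bg <- gibbs_bg(Z, rho, n_iter = 6000, burn_in = 1000, seed = 8)
  rel <- max(abs(est$omega - bg$omega_mean)) / max(abs(bg$omega_mean))
  expect_lt(rel, 0.10)
})
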