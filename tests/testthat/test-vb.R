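test_that("with all indicators on and a flat slab the fit reaches least squares", {
  set.seed(31)
  n <- 60; p <- 4
  Z <- matrix(rnorm(n * p), n)
  Z[, 1] <- 0.7 * Z[, 2] - 0.4 * Z[, 4] + 0.2 * rnorm(n)
  st <- vb_fit(Z, rho = 1, gsq = 1e8, tol = 1e-10)
  for (d in 1:(p - 1)) {
    ols <- qr.solve(Z[, (d + 1):p, drop = FALSE], Z[, d])
    expect_lt(max(abs(st$alpha[[d]] - ols)) / max(abs(ols), 1e-3), 1e-3)
    expect_true(all(st$w[[d]] == 1))
  }
})

test_that("vanishing prior inclusion collapses the fit to the empty model", {
  set.seed(32)
  Z <- toy_Z(30, 4, seed = 32)
  st <- vb_fit(Z, rho = 1e-300, tol = 1e-8)
  expect_true(all(unlist(st$w) < 1e-10))
  expect_true(all(abs(unlist(st$alpha)) < 1e-6))
})

test_that("the lower bound ascends on every sweep across seeded toy instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:50, 1); p <- sample(3:6, 1)
    Z <- toy_Z(n, p, seed = seed)
    st <- suppressWarnings(vb_fit(Z, rho = runif(1, 0.05, 0.6),
                                  max_sweeps = 50, tol = 1e-14))
    tr <- st$elbo_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("closed-form lower bound agrees with a Monte-Carlo ELBO estimate", {
  Z <- toy_Z(20, 4, seed = 41)
  st <- vb_fit(Z, rho = 0.3, max_sweeps = 200, tol = 1e-12)
  mc <- mc_elbo(Z, st, n_mc = 1e5)
  expect_lt(abs(vb_elbo(Z, st) - mc$est), 3 * mc$se)
})

test_that("lower bound handles empty data and degenerate inclusion probabilities", {
  Z0 <- matrix(numeric(0), 0, 3)
  st0 <- vb_sweep(Z0, npnchol:::vb_init(Z0, 0.4, npnchol:::vb_hyper()))
  expect_true(is.finite(vb_elbo(Z0, st0)))
  # w exactly 0/1 via the guards must not produce NaN
  Z <- toy_Z(25, 3, seed = 42)
  st <- vb_fit(Z, rho = 0.5, tol = 1e-8)
  st$w[[1]][1] <- 0; st$w[[1]][2] <- 1
  expect_true(is.finite(vb_elbo(Z, st)))
})

test_that("flipping one hard indicator changes the bound by the data term only", {
  Z <- toy_Z(20, 3, seed = 43)
  st <- vb_fit(Z, rho = 0.5, tol = 1e-8)
  sa <- st; sa$w[[2]] <- 0; sa$rho[[2]] <- 0.5
  sb <- st; sb$w[[2]] <- 1; sb$rho[[2]] <- 0.5
  # recompute (s, tau) consistently for each hard assignment
  des <- npnchol:::vb_design(Z)
  fix_s <- function(s) {
    d <- 2; ds <- des[[d]]; w <- s$w[[d]]
    Om <- tcrossprod(w) + diag(w * (1 - w), 1)
    quad <- ds$ztz - 2 * sum(w * s$alpha[[d]] * ds$Xty) +
      sum((ds$XtX * Om) * (tcrossprod(s$alpha[[d]]) + s$Sigma[[d]]))
    s$s[d] <- s$hyper$B + quad / 2
    s$tau[d] <- (s$hyper$A + s$n / 2) / s$s[d]
    s
  }
  sa <- fix_s(sa); sb <- fix_s(sb)
  dif <- vb_elbo(Z, sb) - vb_elbo(Z, sa)
  # with rho = 0.5 the Bernoulli terms cancel; the difference is the
  # (A + n/2) log s ratio, i.e. the data term
  a_post <- st$hyper$A + st$n / 2
  expect_equal(dif, -a_post * (log(sb$s[2]) - log(sa$s[2])), tolerance = 1e-10)
})

test_that("indicator second-moment matrix matches brute-force enumeration", {
  set.seed(44)
  for (m in 1:3) {
    w <- runif(m)
    Om <- tcrossprod(w) + diag(w * (1 - w), m)
    # enumerate all upsilon configurations
    configs <- as.matrix(expand.grid(rep(list(0:1), m)))
    probs <- apply(configs, 1, function(u) prod(w^u * (1 - w)^(1 - u)))
    M2 <- matrix(0, m, m)
    for (i in seq_len(nrow(configs)))
      M2 <- M2 + probs[i] * tcrossprod(configs[i, ])
    expect_equal(Om, M2, tolerance = 1e-12)
  }
})

test_that("tuning returns valid inclusion probabilities decreasing in the row index", {
  Z <- toy_Z(40, 5, seed = 45)
  tune <- vb_tune(Z, grid_len = 25)
  for (d in seq_along(tune$rho)) {
    r <- tune$rho[[d]]
    expect_true(all(r >= 0 & r <= 1))
    if (length(r) > 1) expect_true(all(diff(r) <= 0))
  }
  # the tuned (iota, c) maximizes the restricted bound on the grid
  expect_equal(max(tune$grid$vlb), tune$grid$vlb[which(
    tune$grid$iota == tune$iota & tune$grid$c == tune$c)])
  # stage-1 indicators are essentially binary (the MCMC initializer)
  expect_true(all(vapply(tune$upsilon_init, function(u) all(u %in% 0:1), logical(1))))
})

test_that("variational estimate applies the strict median probability rule", {
  Z <- toy_Z(50, 4, seed = 46)
  st <- vb_fit(Z, rho = 0.4, tol = 1e-8)
  # with all w forced to 1 the support frequencies are 1 and every edge is kept
  st1 <- st
  st1$w <- lapply(st1$w, function(w) rep(1, length(w)))
  est1 <- vb_precision(st1, n_draws = 50, seed = 2)
  expect_true(all(est1$edge_freq[upper.tri(diag(4))] == 1))
  expect_true(all(est1$edges[upper.tri(diag(4))] == 1))
  # a frequency of exactly one half is excluded
  expect_equal(median_prob_edges(matrix(0.5, 4, 4))[1, 2], 0L)
})

test_that("variational runs are deterministic given the seed", {
  Z <- toy_Z(40, 4, seed = 47)
  s1 <- vb_fit(Z, rho = 0.3, tol = 1e-8)
  s2 <- vb_fit(Z, rho = 0.3, tol = 1e-8)
  expect_identical(s1$elbo_trace, s2$elbo_trace)
  e1 <- vb_precision(s1, seed = 5); e2 <- vb_precision(s2, seed = 5)
  expect_identical(e1$omega, e2$omega)
})
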