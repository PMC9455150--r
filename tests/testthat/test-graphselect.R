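test_that("partial correlations follow the sign-flip formula", {
  expect_equal(partial_corr(diag(4)), diag(4))
  Om2 <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(partial_corr(Om2)[1, 2], 0.5)
  expect_error(partial_corr(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("partial correlations equal residual correlations from a regression oracle", {
  set.seed(61)
  p <- 5; n <- 4000
  Om <- rand_spd(p, seed = 61)
  e <- partial_corr(Om)
  # oracle: correlation of residuals of X_k and X_d regressed on the rest,
  # estimated on a large simulated sample
  X <- matrix(rnorm(n * p), n) %*% chol(solve(Om))
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    k <- pair[1]; d <- pair[2]
    rk <- lm.fit(cbind(1, X[, -c(k, d)]), X[, k])$residuals
    rd <- lm.fit(cbind(1, X[, -c(k, d)]), X[, d])$residuals
    expect_lt(abs(e[k, d] - cor(rk, rd)), 4 / sqrt(n) * 3)
  }
})

test_that("Wishart reference posterior matches the closed form", {
  # no data: prior mean 3I has zero partial correlations
  Z0 <- matrix(numeric(0), 0, 3)
  expect_equal(wishart_partial_corr(Z0), diag(3))
  set.seed(62)
  Z <- matrix(rnorm(20 * 4), 20)
  H <- (20 + 3) * solve(diag(4) + crossprod(Z))
  expect_equal(wishart_partial_corr(Z), partial_corr(H), tolerance = 1e-12)
})

test_that("0-1-loss threshold is strict and scale invariant", {
  e <- matrix(c(0, 0.3, 0.3, 0), 2)
  j <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(threshold_partial(e, j)[1, 2], 1L)        # |0.3/0.5| = 0.6 > 0.5
  expect_equal(threshold_partial(0.5 * j, j)[1, 2], 0L)  # ratio exactly 0.5
  expect_equal(threshold_partial(0 * j, j)[1, 2], 0L)
  # zero-reference conventions
  expect_equal(threshold_partial(e, 0 * j)[1, 2], 1L)
  expect_equal(threshold_partial(0 * e, 0 * j)[1, 2], 0L)
  # joint rescaling leaves decisions unchanged
  set.seed(63)
  ee <- matrix(rnorm(16), 4); ee <- ee + t(ee); diag(ee) <- 1
  jj <- matrix(rnorm(16), 4); jj <- jj + t(jj); diag(jj) <- 1
  expect_identical(threshold_partial(ee, jj),
                   threshold_partial(2.7 * ee, 2.7 * jj))
  expect_error(threshold_partial(ee * NA, jj), "NaN")
})

test_that("median probability edges use a strict majority and ignore draw order", {
  draws <- list(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 1, 1, 0), 2),
                matrix(c(0, 0, 0, 0), 2), matrix(c(0, 0, 0, 0), 2))
  expect_equal(median_prob_edges(draws)[1, 2], 0L)       # exactly half
  expect_equal(median_prob_edges(draws[c(3, 1, 4, 2)]),
               median_prob_edges(draws))
  expect_equal(median_prob_edges(draws[1:3])[1, 2], 1L)  # 2/3
  expect_error(median_prob_edges(list()), "no indicator")
  # binomial frequency: rate-0.7 mixture over many draws keeps the edge
  set.seed(64)
  arr <- array(0, c(2, 2, 1000))
  on <- rbinom(1000, 1, 0.7)
  arr[1, 2, ] <- arr[2, 1, ] <- on
  expect_equal(median_prob_edges(arr)[1, 2], 1L)
})

test_that("constrained MLE reproduces its closed forms and a brute-force solve", {
  set.seed(65)
  n <- 80; p <- 4
  S <- crossprod(matrix(rnorm(n * p), n))
  # no constraints: n S^{-1}
  full <- matrix(1, p, p) - diag(p)
  f_full <- constrained_mle(S, full, n)
  expect_lt(max(abs(f_full$omega - n * solve(S))), 1e-6)
  expect_true(f_full$converged)
  expect_lt(f_full$kkt, 1e-6)
  # diagonal pattern: separable 1-D maximizations
  f_diag <- constrained_mle(S, matrix(0, p, p), n)
  expect_equal(diag(f_diag$omega), n / diag(S), tolerance = 1e-10)
  expect_true(all(f_diag$omega[upper.tri(S)] == 0))
  # p = 3 with one zero: numeric optimization oracle over the 5 free entries
  S3 <- crossprod(matrix(rnorm(50 * 3), 50))
  ed3 <- matrix(1, 3, 3) - diag(3); ed3[1, 3] <- ed3[3, 1] <- 0
  f3 <- constrained_mle(S3, ed3, 50)
  nll <- function(x) {
    Om <- diag(exp(x[1:3]))
    Om[1, 2] <- Om[2, 1] <- x[4]; Om[2, 3] <- Om[3, 2] <- x[5]
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -100 * sum(log(diag(ch))) + sum(Om * S3)
  }
  op <- optim(c(log(diag(f3$omega)) + 0.2, f3$omega[1, 2] * 1.5,
                f3$omega[2, 3] * 0.5), nll,
              control = list(maxit = 20000, reltol = 1e-15))
  Om_o <- diag(exp(op$par[1:3]))
  Om_o[1, 2] <- Om_o[2, 1] <- op$par[4]; Om_o[2, 3] <- Om_o[3, 2] <- op$par[5]
  expect_lt(max(abs(f3$omega - Om_o)), 1e-4)
  # objective decreases monotonically
  expect_true(all(diff(f3$objective) <= 1e-9))
})

test_that("BIC follows the printed formula and prefers smaller penalties on ties", {
  # S = n I makes the diagonal refit exactly the identity, so
  # -l = -n log det I + tr(I \%*\% nI) = pn and BIC = 2 p n + k log n
  p <- 3; n <- 10
  S <- n * diag(p)
  ed_empty <- matrix(0, p, p)
  sel <- bic_select(list("1" = ed_empty), S, n)
  expect_equal(sel$omega_mle, diag(p), tolerance = 1e-8)
  expect_equal(sel$table$bic, 2 * p * n + p * log(n), tolerance = 1e-6)
  # and the reported value equals the formula applied to the refit
  negll <- -n * determinant(sel$omega_mle, logarithm = TRUE)$modulus[1] +
    sum(sel$omega_mle * S)
  expect_equal(sel$table$bic, 2 * negll + p * log(n), tolerance = 1e-8)
  # same fit with a spurious edge: larger k, larger BIC
  ed_one <- ed_empty; ed_one[1, 2] <- ed_one[2, 1] <- 1
  sel2 <- bic_select(list("0.1" = ed_empty, "1" = ed_one), S, n)
  expect_equal(sel2$c_star, 0.1)
  expect_true(sel2$table$bic[2] > sel2$table$bic[1])
  # identical edge matrices: tie broken toward the smaller c
  sel3 <- bic_select(list("10" = ed_empty, "0.1" = ed_empty), S, n)
  expect_equal(sel3$c_star, 0.1)
})
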