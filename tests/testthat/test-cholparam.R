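test_that("identity and diagonal cases are exact", {
  expect_equal(chol_to_precision(matrix(0, 3, 3), rep(1, 3)), diag(3))
  pr <- precision_to_chol(diag(3))
  expect_equal(pr$beta, matrix(0, 3, 3))
  expect_equal(pr$phi, rep(1, 3))
  prd <- precision_to_chol(diag(c(2, 5, 9)))
  expect_equal(prd$phi, c(2, 5, 9))
  expect_equal(prd$beta, matrix(0, 3, 3))
})

test_that("round trip through the dense Cholesky oracle holds to 1e-10", {
  # circle-model instance with the corner entry
  Om3 <- matrix(c(2, 1, 0.9, 1, 2, 1, 0.9, 1, 2), 3)
  pr <- precision_to_chol(Om3)
  expect_lt(max(abs(chol_to_precision(pr$beta, pr$phi) - Om3)), 1e-10)
  # random factors: extracting parameters from L reproduces LL'
  set.seed(8)
  for (r in 1:5) {
    p <- sample(3:8, 1)
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- rnorm(p * (p + 1) / 2)
    diag(L) <- abs(diag(L)) + 0.3
    Om <- tcrossprod(L)
    beta <- -L / rep(diag(L), each = p); beta[upper.tri(beta, diag = TRUE)] <- 0
    expect_lt(max(abs(chol_to_precision(beta, diag(L)^2) - Om)), 1e-10)
  }
  # 100 random SPD round trips, p up to 20
  set.seed(9)
  for (r in 1:100) {
    p <- sample(3:20, 1)
    Om <- rand_spd(p)
    pr <- precision_to_chol(Om)
    expect_lt(max(abs(chol_to_precision(pr$beta, pr$phi) - Om)), 1e-10)
    expect_true(all(pr$phi > 0))
  }
})

test_that("reconstruction is SPD for arbitrary coefficients", {
  set.seed(10)
  for (r in 1:20) {
    p <- sample(3:10, 1)
    beta <- matrix(rnorm(p * p, sd = 2), p)
    phi <- rexp(p) + 0.05
    Om <- chol_to_precision(beta, phi)
    expect_silent(chol(Om))
    expect_equal(Om, t(Om))
  }
  expect_error(chol_to_precision(matrix(0, 2, 2), c(1, -1)), "positive")
})

test_that("support probability formula and its degenerate cases", {
  expect_equal(edge_probability(0, 0.7, 3, 5), 0)
  expect_equal(edge_probability(1, 1, 2, 9), 1)
  expect_error(edge_probability(1.2, 0.5, 1, 1), "\\[0, 1\\]")
  # Monte-Carlo oracle: Bernoulli row supports of L
  set.seed(12)
  rho_k <- 0.3; rho_d <- 0.3; mkd <- 5
  reps <- 1e5
  act_k <- matrix(runif(reps * mkd) < rho_k, reps)
  act_d <- matrix(runif(reps * mkd) < rho_d, reps)
  freq <- mean(rowSums(act_k & act_d) > 0)
  pth <- edge_probability(rho_k, rho_d, mkd, mkd)
  expect_lt(abs(freq - pth), 3 * sqrt(pth * (1 - pth) / reps))
})

test_that("row-sparsity plan keeps the nonzero probability stable and obeys the limit law", {
  p <- 30
  plan <- sparsity_plan(p, 1)
  expect_true(all(diff(plan$rho) < 0))
  pk <- edge_probability(plan$rho[2:p], plan$rho[2:p], 2:p, 2:p)
  expect_lt(max(pk) / min(pk), 2)
  # k -> infinity with rho_k = c_p / sqrt(k): limit 1 - exp(-c_p^2)
  for (cp in c(0.5, 0.8, 1)) {
    k <- 1e4
    expect_lt(abs(edge_probability(cp / sqrt(k), cp / sqrt(k), k, k) -
                    (1 - exp(-cp^2))), 1e-3)
  }
})
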