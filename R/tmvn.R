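#' Exact Hamiltonian Monte Carlo for linearly constrained Gaussians
#'
#' Samples from \eqn{N(\mu, \Sigma)} truncated to the polytope
#' \eqn{\{x : Fx + g > 0\}} by simulating the exact Hamiltonian dynamics of a
#' standard Gaussian in whitened coordinates: trajectories are harmonic
#' oscillations \eqn{x(t) = x_0\cos t + v_0\sin t} and hitting a wall
#' reflects the velocity about the wall normal. Each returned draw is the
#' endpoint of one trajectory of length \code{total_time} (default
#' \eqn{\pi/2}) started from the previous state with a fresh Gaussian
#' momentum; the chain leaves the truncated normal invariant and mixes
#' rapidly because trajectories are rejection free.
#'
#' @param n_draws number of retained draws.
#' @param mean,cov mean vector and SPD covariance of the untruncated normal.
#' @param F,g constraint matrix (rows are walls) and offset; the support is
#'   \code{F \%*\% x + g > 0}. Use a \code{0 x m} matrix for no constraints.
#' @param init starting point, strictly inside the support.
#' @param burn number of discarded initial trajectories.
#' @param total_time travel time per trajectory.
#' @param seed optional integer seed (\code{set.seed} is called when given).
#' @return An \code{n_draws x m} matrix of draws.
#' @export
#' @examples
#' z <- rtmvn_hmc(2000, 0, matrix(1), matrix(1), 0, init = 0.5, seed = 1)
#' mean(z)  # close to sqrt(2/pi)
rtmvn_hmc <- function(n_draws, mean, cov, F, g, init, burn = 0L,
                      total_time = pi / 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mean <- as.numeric(mean)
  m <- length(mean)
  cov <- as.matrix(cov)
  F <- as.matrix(F)
  if (nrow(F) > 0L && ncol(F) != m) stop("constraint matrix has wrong width", call. = FALSE)
  g <- as.numeric(g)
  R <- tryCatch(chol(cov), error = function(e)
    stop("'cov' is not symmetric positive definite", call. = FALSE))
  # x = mean + t(R) u maps u ~ N(0, I) to N(mean, cov)
  init <- as.numeric(init)
  if (nrow(F) > 0L && any(F %*% init + g <= 0))
    stop("initial point does not strictly satisfy the constraints", call. = FALSE)
  u <- forwardsolve(t(R), init - mean)
  Fu <- if (nrow(F) > 0L) F %*% t(R) else matrix(0, 0L, m)
  gu <- if (nrow(F) > 0L) g + drop(F %*% mean) else numeric(0)

  out <- matrix(NA_real_, n_draws, m)
  total <- n_draws + burn
  for (it in seq_len(total)) {
    u <- hmc_trajectory(u, Fu, gu, total_time)
    if (it > burn) out[it - burn, ] <- mean + drop(crossprod(R, u))
  }
  out
}

# One exact-HMC trajectory for N(0, I) truncated to {u: Fu u + gu > 0};
# returns the endpoint. Walls are found from a sin t + b cos t = -g and the
# velocity is reflected at each hit. A small positive time tolerance avoids
# re-detecting the wall just bounced off.
hmc_trajectory <- function(u, Fu, gu, total_time = pi / 2,
                           max_events = 1000L, t_tol = 1e-9) {
  m <- length(u)
  q <- nrow(Fu)
  for (attempt in 1:5) {
    x <- u
    v <- stats::rnorm(m)
    t_left <- total_time
    last_wall <- 0L
    ok <- TRUE
    for (ev in seq_len(max_events)) {
      if (q > 0L) {
        a <- drop(Fu %*% v)
        b <- drop(Fu %*% x)
        r <- sqrt(a^2 + b^2)
        hit_t <- rep(Inf, q)
        can <- r > abs(gu) & r > 0
        if (any(can)) {
          psi <- atan2(a[can], b[can])
          ac <- acos(pmax(-1, pmin(1, -gu[can] / r[can])))
          t1 <- (psi + ac) %% (2 * pi)
          t2 <- (psi - ac) %% (2 * pi)
          tol_here <- ifelse(which(can) == last_wall, 1e-6, t_tol)
          t1[t1 <= tol_here] <- t1[t1 <= tol_here] + 2 * pi
          t2[t2 <= tol_here] <- t2[t2 <= tol_here] + 2 * pi
          hit_t[can] <- pmin(t1, t2)
        }
        j <- which.min(hit_t)
        th <- hit_t[j]
      } else {
        th <- Inf
        j <- 0L
      }
      if (th >= t_left) {
        x_new <- x * cos(t_left) + v * sin(t_left)
        x <- x_new
        break
      }
      x_new <- x * cos(th) + v * sin(th)
      v_new <- -x * sin(th) + v * cos(th)
      f <- Fu[j, ]
      v <- v_new - 2 * sum(f * v_new) / sum(f * f) * f
      x <- x_new
      last_wall <- j
      t_left <- t_left - th
      if (ev == max_events) ok <- FALSE
    }
    if (q == 0L || all(Fu %*% x + gu > 0)) return(x)
    # numerically outside after grazing events: retry with fresh momentum
    ok <- FALSE
  }
  u  # all retries failed; keep the previous (valid) state
}
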