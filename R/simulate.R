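#' Sparse precision matrices for the simulation designs
#'
#' Three families:
#' \describe{
#'   \item{circle}{\eqn{\omega_{ii} = 2}, \eqn{\omega_{i,i-1} = 1}, corner
#'     \eqn{\omega_{1p} = 0.9} (a single cycle); off-diagonal sparsity
#'     \eqn{200/(p-1)} percent.}
#'   \item{ar2}{\eqn{\omega_{ii} = 1}, \eqn{\omega_{i,i-1} = 0.5},
#'     \eqn{\omega_{i,i-2} = 0.25} (pentadiagonal band).}
#'   \item{percent}{random sparsity: a lower-triangular factor with
#'     \eqn{N(1, 0.1^2)} diagonal and \eqn{N(0,1)} entries placed uniformly
#'     at random until \eqn{\Omega = LL'} reaches the requested percentage
#'     of nonzero off-diagonals.}
#' }
#'
#' @param kind one of \code{"circle"}, \code{"ar2"}, \code{"percent"}.
#' @param p dimension, at least 3.
#' @param percent target percentage of nonzero off-diagonal entries
#'   (percent family only).
#' @param seed integer seed (percent family only).
#' @return SPD precision matrix.
#' @export
sim_precision <- function(kind = c("circle", "ar2", "percent"), p,
                          percent = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (p < 3) stop("'p' must be at least 3", call. = FALSE)
  Omega <- switch(kind,
    circle = {
      M <- diag(2, p)
      M[cbind(1:(p - 1), 2:p)] <- 1
      M[cbind(2:p, 1:(p - 1))] <- 1
      M[1, p] <- M[p, 1] <- 0.9
      M
    },
    ar2 = {
      M <- diag(1, p)
      M[cbind(1:(p - 1), 2:p)] <- 0.5
      M[cbind(2:p, 1:(p - 1))] <- 0.5
      M[cbind(1:(p - 2), 3:p)] <- 0.25
      M[cbind(3:p, 1:(p - 2))] <- 0.25
      M
    },
    percent = {
      if (is.null(percent) || percent <= 0 || percent > 100)
        stop("'percent' must be in (0, 100] for the percent family", call. = FALSE)
      set.seed(seed)
      target_pairs <- percent / 100 * p * (p - 1) / 2
      if (target_pairs < 1)
        stop("requested sparsity gives no off-diagonal entries", call. = FALSE)
      for (try in 1:20) {
        dg <- stats::rnorm(p, 1, 0.1)
        if (all(dg > 0.05)) break
      }
      L <- diag(dg, p)
      Lb <- diag(TRUE, p)
      slots <- which(lower.tri(L))
      slots <- sample(slots)
      count_pairs <- function(Lb) {
        Spat <- tcrossprod(Lb * 1)
        sum(Spat[upper.tri(Spat)] > 0)
      }
      i <- 0L
      while (count_pairs(Lb) < target_pairs && i < length(slots)) {
        i <- i + 1L
        Lb[slots[i]] <- TRUE
        L[slots[i]] <- stats::rnorm(1)
      }
      tcrossprod(L)
    })
  tryCatch(chol(Omega), error = function(e)
    stop("generated precision matrix failed the SPD check", call. = FALSE))
  Omega
}

#' Off-diagonal sparsity percentage
#'
#' @param Omega square matrix.
#' @param tol entries with absolute value above \code{tol} count as
#'   nonzero.
#' @return 100 times the fraction of nonzero off-diagonal entries.
#' @export
sparsity_fraction <- function(Omega, tol = 1e-10) {
  Omega <- as.matrix(Omega)
  if (nrow(Omega) != ncol(Omega)) stop("'Omega' must be square", call. = FALSE)
  p <- ncol(Omega)
  off <- abs(Omega[row(Omega) != col(Omega)]) > tol
  100 * sum(off) / (p * (p - 1))
}

#' Simulate nonparanormal data from a sparse precision matrix
#'
#' Latent rows are \eqn{Y_i \sim N(\mu, \Omega^{-1})} with the means on an
#' equally spaced grid between 0 and 2. Each observed column is
#' \eqn{X_d = G_d(Y_d)} where \eqn{G_d} is the cdf of a warp family fitted
#' to the latent column by maximum likelihood (families cycle through
#' asymmetric Laplace, extreme value, stable by default), so the observed
#' margins lie in \eqn{(0,1)} and are smooth monotone distortions of the
#' Gaussian latents. \code{identity = TRUE} skips the warps (\code{X = Y}),
#' which lets the sparse engines be exercised without the spline stage.
#'
#' @param Omega SPD precision matrix.
#' @param n sample size.
#' @param seed integer seed.
#' @param families warp family per column, recycled; any of
#'   \code{"alaplace"}, \code{"ev"}, \code{"stable"}.
#' @param identity skip the warps.
#' @param mu optional mean vector (default the grid \code{seq(0, 2,
#'   length.out = p)}).
#' @param stable_refine pass \code{refine = FALSE} to use the quantile-only
#'   stable fit (faster, slightly less accurate margins).
#' @return List with \code{X} (observed), \code{Y} (latent), \code{Omega},
#'   \code{truth} (binary edge matrix of the support of \eqn{\Omega}),
#'   \code{mu}, and the fitted \code{warps}.
#' @export
sim_nonparanormal <- function(Omega, n, seed = 1,
                              families = c("alaplace", "ev", "stable"),
                              identity = FALSE, mu = NULL,
                              stable_refine = TRUE) {
  Omega <- as.matrix(Omega)
  p <- ncol(Omega)
  R <- tryCatch(chol(Omega), error = function(e)
    stop("'Omega' must be SPD", call. = FALSE))
  if (is.null(mu)) mu <- seq(0, 2, length.out = p)
  set.seed(seed)
  # Y = mu + N(0, Omega^{-1}); solve R x = z gives cov (R'R)^{-1} = Omega^{-1}
  Y <- t(backsolve(R, matrix(stats::rnorm(n * p), p, n))) +
    matrix(mu, n, p, byrow = TRUE)
  truth <- (abs(Omega) > 1e-10) * 1L
  diag(truth) <- 0L
  if (identity) {
    return(list(X = Y, Y = Y, Omega = Omega, truth = truth, mu = mu,
                warps = NULL))
  }
  fams <- rep_len(families, p)
  warps <- vector("list", p)
  X <- matrix(NA_real_, n, p)
  for (d in seq_len(p)) {
    warps[[d]] <- if (fams[d] == "stable")
      fit_warp(Y[, d], fams[d], refine = stable_refine) else
      fit_warp(Y[, d], fams[d])
    X[, d] <- pmin(pmax(pwarp(Y[, d], warps[[d]]), 1e-12), 1 - 1e-12)
  }
  list(X = X, Y = Y, Omega = Omega, truth = truth, mu = mu, warps = warps)
}
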