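#' Partial correlation matrix of a precision matrix
#'
#' Computes \eqn{e_{kd} = -\omega_{kd}/\sqrt{\omega_{kk}\omega_{dd}}} with
#' unit diagonal: the correlation between variables \eqn{k} and \eqn{d}
#' given all the others.
#'
#' @param Omega SPD precision matrix.
#' @return Symmetric matrix with unit diagonal, off-diagonals in
#'   \eqn{[-1, 1]}.
#' @export
partial_corr <- function(Omega) {
  Omega <- as.matrix(Omega)
  tryCatch(chol(Omega), error = function(e)
    stop("'Omega' is not symmetric positive definite", call. = FALSE))
  s <- 1 / sqrt(diag(Omega))
  e <- -Omega * tcrossprod(s)
  diag(e) <- 1
  e
}

#' Reference partial correlations from the conjugate Wishart posterior
#'
#' For latent data \eqn{Z} (an \code{n x p} matrix) the non-sparse
#' reference posterior \eqn{\Omega \sim W_p(n + df, (I + S)^{-1})} with
#' \eqn{S = Z'Z} has mean \eqn{H = (n + df)(I + S)^{-1}}; the function
#' returns the partial correlations of \eqn{H}, the comparator of the
#' 0-1-loss rule.
#'
#' @param Z latent data matrix.
#' @param df prior degrees of freedom (default 3).
#' @return \code{p x p} matrix of reference partial correlations.
#' @export
wishart_partial_corr <- function(Z, df = 3) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  H <- (n + df) * chol2inv(chol(diag(p) + crossprod(Z)))
  partial_corr(H)
}

#' 0-1-loss thresholding of shrinkage partial correlations
#'
#' Declares \eqn{\omega_{kd} \neq 0} exactly when
#' \eqn{|e_{kd}/j_{kd}| > 0.5} (strict): the shrinkage-posterior partial
#' correlation must be at least half the size of the non-sparse Wishart
#' reference value. Conventions at \eqn{j_{kd} = 0}: a zero ratio when
#' \eqn{e_{kd} = 0} (no evidence), an infinite ratio otherwise.
#'
#' @param e partial correlations from the shrinkage posterior draw.
#' @param j reference partial correlations (same shape).
#' @return Binary matrix (0/1, zero diagonal).
#' @export
threshold_partial <- function(e, j) {
  e <- as.matrix(e); j <- as.matrix(j)
  if (!all(dim(e) == dim(j))) stop("shape mismatch between 'e' and 'j'", call. = FALSE)
  if (any(is.na(e)) || any(is.na(j))) stop("NaN/NA in thresholding input", call. = FALSE)
  out <- matrix(0L, nrow(e), ncol(e))
  nz <- j != 0
  out[nz] <- (abs(e[nz] / j[nz]) > 0.5) * 1L
  out[!nz] <- (e[!nz] != 0) * 1L
  diag(out) <- 0L
  out
}

#' Median probability model over indicator draws
#'
#' Averages binary edge indicators over posterior draws and keeps an edge
#' when its frequency strictly exceeds one half.
#'
#' @param ind a list of binary \code{p x p} matrices, a \code{p x p x M}
#'   array of indicators, or a single matrix of already-averaged
#'   frequencies.
#' @return Binary symmetric edge matrix with zero diagonal (class
#'   \code{matrix}, integer 0/1).
#' @export
median_prob_edges <- function(ind) {
  if (is.list(ind)) {
    if (length(ind) == 0L) stop("no indicator draws supplied", call. = FALSE)
    freq <- Reduce(`+`, ind) / length(ind)
  } else if (is.array(ind) && length(dim(ind)) == 3L) {
    if (dim(ind)[3] == 0L) stop("no indicator draws supplied", call. = FALSE)
    freq <- apply(ind, c(1, 2), mean)
  } else {
    freq <- as.matrix(ind)
  }
  edges <- ((freq + t(freq)) / 2 > 0.5) * 1L   # symmetrize, strict majority
  diag(edges) <- 0L
  storage.mode(edges) <- "integer"
  edges
}

#' Constrained maximum likelihood refit of the precision matrix
#'
#' Minimizes \eqn{-n \log\det\Omega + tr(\Omega S)} subject to
#' \eqn{\omega_{kd} = 0} wherever the estimated edge matrix has no edge.
#' The problem is smooth and convex over the free entries (diagonal plus
#' edges), so it is solved by a damped Newton method: the gradient is
#' \eqn{S - n\Omega^{-1}} restricted to the free pattern, the Hessian has
#' the closed form \eqn{n\,tr(\Sigma E_u \Sigma E_v)} over the basis
#' matrices of the free entries, and a backtracking line search keeps every
#' iterate positive definite with a monotonically decreasing objective.
#' Iterates stop when the stationarity residual
#' \eqn{\max |S - n\Omega^{-1}|} on the free pattern falls below
#' \code{tol} (relative to the scale of \code{S}).
#'
#' @param S sum-of-squares matrix \eqn{\bar Z'\bar Z} of the (averaged)
#'   latent data.
#' @param edges binary edge matrix; free entries are the diagonal plus the
#'   edges.
#' @param n sample size in the likelihood.
#' @param tol stationarity (KKT) tolerance.
#' @param max_iter maximum Newton iterations.
#' @return List with \code{omega} (the constrained MLE), \code{objective}
#'   trace per iteration, \code{kkt} (final residual) and \code{converged}.
#' @export
constrained_mle <- function(S, edges, n, tol = 1e-8, max_iter = 200) {
  S <- as.matrix(S)
  p <- ncol(S)
  edges <- as.matrix(edges)
  if (!all(dim(edges) == c(p, p))) stop("shape mismatch", call. = FALSE)
  if (any(diag(S) <= 0)) stop("'S' must have positive diagonal", call. = FALSE)
  if (min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values) <
      1e-10 * max(diag(S))) {
    warning("'S' is numerically singular; adding a small ridge to keep the refit bounded")
    S <- S + 1e-6 * mean(diag(S)) * diag(p)
  }
  pairs <- which(upper.tri(edges) & edges != 0, arr.ind = TRUE)
  n_free <- p + nrow(pairs)
  # free coordinates: p diagonal entries then the edge pairs
  idx_a <- c(seq_len(p), pairs[, 1])
  idx_b <- c(seq_len(p), pairs[, 2])
  is_pair <- c(rep(FALSE, p), rep(TRUE, nrow(pairs)))

  build <- function(x) {
    Om <- matrix(0, p, p)
    diag(Om) <- x[seq_len(p)]
    if (nrow(pairs)) {
      Om[pairs] <- x[-seq_len(p)]
      Om[pairs[, c(2, 1), drop = FALSE]] <- x[-seq_len(p)]
    }
    Om
  }
  obj <- function(Om) {
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    -2 * n * sum(log(diag(ch))) + sum(Om * S)
  }

  x <- c(n / diag(S), rep(0, nrow(pairs)))
  Omega <- build(x)
  objective <- obj(Omega)
  scale_S <- max(abs(S))
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    Sigma <- chol2inv(chol(Omega))
    grad <- (S[cbind(idx_a, idx_b)] - n * Sigma[cbind(idx_a, idx_b)]) *
      ifelse(is_pair, 2, 1)
    res <- max(abs(S[cbind(idx_a, idx_b)] - n * Sigma[cbind(idx_a, idx_b)]))
    if (res < tol * max(1, scale_S)) { converged <- TRUE; break }
    # Hessian H[u, v] = n tr(Sigma E_u Sigma E_v), E_u the basis matrix of
    # free coordinate u (e_a e_a' for the diagonal, e_a e_b' + e_b e_a' for
    # an edge). With T[u, v] = sigma_{a_u a_v} sigma_{b_u b_v} +
    # sigma_{a_u b_v} sigma_{b_u a_v} the trace equals T * 2^{pu + pv - 1}.
    T_ <- Sigma[idx_a, idx_a, drop = FALSE] * Sigma[idx_b, idx_b, drop = FALSE] +
      Sigma[idx_a, idx_b, drop = FALSE] * Sigma[idx_b, idx_a, drop = FALSE]
    mult <- ifelse(is_pair, 2, 1)
    H <- n * T_ * outer(mult, mult) / 2
    step <- tryCatch(-solve(H + 1e-12 * max(diag(H)) * diag(n_free), grad),
                     error = function(e) -grad / max(diag(H)))
    t_ls <- 1
    f0 <- objective[length(objective)]
    dec <- sum(grad * step)
    repeat {
      x_new <- x + t_ls * step
      f_new <- obj(build(x_new))
      if (is.finite(f_new) && f_new <= f0 + 1e-4 * t_ls * dec) break
      t_ls <- t_ls / 2
      if (t_ls < 1e-14) break
    }
    if (t_ls < 1e-14) break
    x <- x + t_ls * step
    Omega <- build(x)
    objective <- c(objective, obj(Omega))
  }
  if (!converged)
    warning("constrained MLE refit did not reach the stationarity tolerance")
  list(omega = Omega, objective = objective,
       kkt = if (converged) res / max(1, scale_S) else NA_real_,
       converged = converged)
}

#' BIC selection of the sparsity constant
#'
#' For each candidate sparsity constant \eqn{c}, refits the precision
#' matrix by [constrained_mle()] on that candidate's estimated edge matrix
#' and computes \eqn{BIC = -2\ell(\hat\Omega_{MLE}) + k \log n} with
#' \eqn{-\ell = -n\log\det\hat\Omega + tr(\hat\Omega S)} and \eqn{k} the
#' number of diagonal elements plus the number of edges. The smallest BIC
#' wins; ties break toward the smaller \eqn{c}.
#'
#' @param edges_by_c named list of binary edge matrices, one per candidate
#'   \eqn{c} (names are the numeric values, e.g. \code{"0.1"}).
#' @param S sum-of-squares matrix of the averaged latent data.
#' @param n sample size.
#' @return List with \code{c_star}, \code{edges}, \code{omega_mle} of the
#'   winner, and the full \code{table} (data frame of c, k, bic).
#' @export
bic_select <- function(edges_by_c, S, n) {
  if (length(edges_by_c) == 0L) stop("no candidate edge matrices", call. = FALSE)
  cs <- as.numeric(names(edges_by_c))
  if (any(is.na(cs))) stop("'edges_by_c' must be named by the numeric c values", call. = FALSE)
  ord <- order(cs)
  cs <- cs[ord]; edges_by_c <- edges_by_c[ord]
  p <- ncol(S)
  rows <- lapply(seq_along(cs), function(i) {
    ed <- edges_by_c[[i]]
    fit <- constrained_mle(S, ed, n)
    k <- p + sum(ed[upper.tri(ed)] != 0)
    negll <- -n * as.numeric(determinant(fit$omega, logarithm = TRUE)$modulus) +
      sum(fit$omega * S)
    list(fit = fit, bic = 2 * negll + k * log(n), k = k)
  })
  bics <- vapply(rows, `[[`, numeric(1), "bic")
  best <- which.min(bics)   # first minimum = smallest c on ties
  list(c_star = cs[best], edges = edges_by_c[[best]],
       omega_mle = rows[[best]]$fit$omega,
       table = data.frame(c = cs, k = vapply(rows, `[[`, numeric(1), "k"),
                          bic = bics))
}
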