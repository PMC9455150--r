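#' Edge confusion counts
#'
#' Compares an estimated edge matrix to the truth over the unordered
#' off-diagonal pairs (strict upper triangle).
#'
#' @param est,truth binary symmetric \code{p x p} matrices with zero
#'   diagonal.
#' @return List with \code{TP}, \code{TN}, \code{FP}, \code{FN}; the four
#'   counts sum to \eqn{p(p-1)/2}.
#' @export
confusion_edges <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth)) || nrow(est) != ncol(est))
    stop("'est' and 'truth' must be square matrices of the same size", call. = FALSE)
  if (any(est != t(est)) || any(truth != t(truth)))
    stop("edge matrices must be symmetric", call. = FALSE)
  if (any(diag(est) != 0) || any(diag(truth) != 0))
    stop("edge matrices must have zero diagonal", call. = FALSE)
  up <- upper.tri(est)
  e <- est[up] != 0; t_ <- truth[up] != 0
  list(TP = sum(e & t_), TN = sum(!e & !t_),
       FP = sum(e & !t_), FN = sum(!e & t_))
}

#' Sensitivity, specificity and Matthews correlation coefficient
#'
#' \eqn{SE = TP/(TP+FN)}, \eqn{SP = TN/(TN+FP)}, and
#' \eqn{MCC = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' A zero factor in the MCC denominator (e.g. an empty estimated graph)
#' yields \code{NaN}, which is propagated as a value, not an error.
#'
#' @param counts output of [confusion_edges()].
#' @return List with \code{SE}, \code{SP}, \code{MCC}.
#' @export
edge_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  se <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) NaN else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  list(SE = se, SP = sp, MCC = mcc)
}

#' Scaled L1 loss between precision matrices
#'
#' Average absolute entrywise deviation,
#' \eqn{p^{-2}\sum_k\sum_d |\hat\Omega_{kd} - \Omega_{kd}|}.
#'
#' @param Omega_hat,Omega_true matrices of the same shape.
#' @export
scaled_l1 <- function(Omega_hat, Omega_true) {
  Omega_hat <- as.matrix(Omega_hat); Omega_true <- as.matrix(Omega_true)
  if (!all(dim(Omega_hat) == dim(Omega_true)))
    stop("shape mismatch", call. = FALSE)
  mean(abs(Omega_hat - Omega_true))
}

#' Maximum number of edges of an undirected graph
#'
#' @param p number of nodes.
#' @return \eqn{p(p-1)/2}.
#' @export
max_edges <- function(p) p * (p - 1) / 2
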