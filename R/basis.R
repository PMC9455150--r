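#' Cubic B-spline basis on the unit interval
#'
#' Builds a clamped cubic B-spline basis with \code{J} basis functions and
#' equally spaced interior knots on \eqn{[0,1]}. The basis is a partition of
#' unity: at every point the \code{J} basis values are nonnegative and sum to
#' one, and each basis function has compact support. Monotone functions are
#' obtained from the expansion \eqn{f(x) = \sum_j \theta_j B_j(x)} whenever
#' the coefficient vector is increasing.
#'
#' @param J number of basis functions; integer, at least 4 (cubic order).
#' @return An object of class \code{npn_basis} with elements \code{J},
#'   \code{degree} and the full (clamped) knot vector \code{knots}.
#' @seealso [basis_eval()] to evaluate the design matrix.
#' @export
#' @examples
#' b <- spline_basis(6)
#' rowSums(basis_eval(b, c(0, 0.3, 1)))  # all 1
spline_basis <- function(J) {
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J) || J != round(J) || J < 4)
    stop("'J' must be a single integer >= 4", call. = FALSE)
  J <- as.integer(J)
  degree <- 3L
  # clamped knots: degree+1 copies at each end, J - degree - 1 interior knots
  n_inner <- J - degree - 1L
  inner <- if (n_inner > 0L) {
    seq(0, 1, length.out = n_inner + 2L)[-c(1L, n_inner + 2L)]
  } else numeric(0)
  knots <- c(rep(0, degree + 1L), inner, rep(1, degree + 1L))
  structure(list(J = J, degree = degree, knots = knots), class = "npn_basis")
}

#' Evaluate a B-spline basis
#'
#' @param basis an [spline_basis()] object.
#' @param x numeric vector of evaluation points in \eqn{[0,1]}.
#' @return A \code{length(x) x J} design matrix; rows sum to one.
#' @export
basis_eval <- function(basis, x) {
  if (!inherits(basis, "npn_basis")) stop("'basis' must be an 'npn_basis' object", call. = FALSE)
  if (length(x) == 0L) return(matrix(0, 0L, basis$J))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("evaluation points must be finite and inside [0, 1]", call. = FALSE)
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L)
}

#' @export
print.npn_basis <- function(x, ...) {
  cat(sprintf("Clamped cubic B-spline basis: J = %d, %d interior knots on [0,1]\n",
              x$J, max(0L, x$J - x$degree - 1L)))
  invisible(x)
}
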