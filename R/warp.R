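#' @title Warp distribution families for the nonparanormal generator
#' @description
#' The synthetic-data generator pushes Gaussian latent columns through
#' fitted cumulative distribution functions so that the observed margins
#' live in \eqn{(0,1)} and the inverse transformation is a smooth monotone
#' function. Three families are provided: the asymmetric Laplace, the
#' (minimum) extreme value / Gumbel, and the alpha-stable distribution. The
#' first two have closed-form densities and quantiles and are fitted by
#' maximum likelihood; the stable family has no closed-form density, so its
#' cdf and density are computed by numerical inversion of the
#' characteristic function (S0 parameterization) and the fit refines a
#' quantile-based starting point by maximum likelihood.
#' @name warps
NULL

# ---- asymmetric Laplace: location m, rate lambda, asymmetry kappa ----

pal <- function(q, m, lambda, kappa) {
  lo <- q < m
  out <- numeric(length(q))
  out[lo] <- kappa^2 / (1 + kappa^2) * exp((lambda / kappa) * (q[lo] - m))
  out[!lo] <- 1 - 1 / (1 + kappa^2) * exp(-lambda * kappa * (q[!lo] - m))
  out
}

qal <- function(p, m, lambda, kappa) {
  br <- kappa^2 / (1 + kappa^2)
  lo <- p <= br
  out <- numeric(length(p))
  out[lo] <- m + (kappa / lambda) * log(p[lo] * (1 + kappa^2) / kappa^2)
  out[!lo] <- m - log((1 - p[!lo]) * (1 + kappa^2)) / (lambda * kappa)
  out
}

dal_log <- function(x, m, lambda, kappa) {
  z <- x - m
  log(lambda) - log(kappa + 1 / kappa) - lambda * ifelse(z >= 0, kappa * z, -z / kappa)
}

fit_al <- function(y) {
  nll <- function(par) -sum(dal_log(y, par[1], exp(par[2]), exp(par[3])))
  st <- c(stats::median(y), log(1 / stats::sd(y)), 0)
  op <- stats::optim(st, nll, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
  list(m = op$par[1], lambda = exp(op$par[2]), kappa = exp(op$par[3]))
}

# ---- minimum extreme value (Gumbel-min): location mu, scale sigma ----

pev <- function(q, mu, sigma) 1 - exp(-exp((q - mu) / sigma))
qev <- function(p, mu, sigma) mu + sigma * log(-log1p(-p))
dev_log <- function(x, mu, sigma) {
  z <- (x - mu) / sigma
  z - exp(z) - log(sigma)
}

fit_ev <- function(y) {
  nll <- function(par) -sum(dev_log(y, par[1], exp(par[2])))
  st <- c(stats::median(y), log(stats::sd(y)))
  op <- stats::optim(st, nll, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
  list(mu = op$par[1], sigma = exp(op$par[2]))
}

# ---- alpha-stable (S0 parameterization, alpha restricted to (1, 2]) ----

# characteristic-function inversion; integrands decay like exp(-t^alpha)
# for alpha > 1, so plain adaptive quadrature is accurate
stable_std_cdf <- function(x, alpha, beta, rel.tol = 1e-12) {
  vapply(x, function(xx) {
    f <- function(t) {
      ph <- beta * tan(pi * alpha / 2) * (t - t^alpha)
      exp(-t^alpha) * sin(t * xx + ph) / t
    }
    val <- stats::integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = 1e-13,
                            stop.on.error = FALSE)$value
    min(max(0.5 + val / pi, 0), 1)
  }, numeric(1))
}

stable_std_pdf <- function(x, alpha, beta, rel.tol = 1e-10) {
  vapply(x, function(xx) {
    f <- function(t) {
      ph <- beta * tan(pi * alpha / 2) * (t - t^alpha)
      exp(-t^alpha) * cos(t * xx + ph)
    }
    max(stats::integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = 1e-13,
                         stop.on.error = FALSE)$value / pi, 1e-300)
  }, numeric(1))
}

pstab <- function(q, alpha, beta, gamma, delta)
  stable_std_cdf((q - delta) / gamma, alpha, beta)

dstab_log <- function(x, alpha, beta, gamma, delta)
  log(stable_std_pdf((x - delta) / gamma, alpha, beta)) - log(gamma)

qstab <- function(p, alpha, beta, gamma, delta, tol = 1e-12) {
  vapply(p, function(pp) {
    f <- function(z) stable_std_cdf(z, alpha, beta) - pp
    lo <- -5; hi <- 5
    while (f(lo) > 0 && lo > -1e6) lo <- lo * 2
    while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
    delta + gamma * stats::uniroot(f, c(lo, hi), tol = tol)$root
  }, numeric(1))
}

fit_stable <- function(y, refine = TRUE, maxit = 150) {
  # quantile-based start (moment-style surrogate of the ML problem)
  qs <- stats::quantile(y, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  gamma0 <- max((qs[4] - qs[2]) / 1.654, 1e-6)     # stable(2) IQR factor
  nu_b <- (qs[5] + qs[1] - 2 * qs[3]) / max(qs[5] - qs[1], 1e-12)
  start <- c(a = 1.9, b = max(-0.9, min(0.9, 2 * nu_b)),
             lg = log(gamma0), d = qs[3])
  par <- start
  if (refine) {
    nll <- function(p) {
      alpha <- 1.05 + 0.95 / (1 + exp(-p[1]))     # (1.05, 2)
      beta <- tanh(p[2])
      -sum(dstab_log(y, alpha, beta, exp(p[3]), p[4]))
    }
    tr <- c(log((start[1] - 1.05) / (2 - start[1])), atanh(start[2]),
            start[3], start[4])
    op <- tryCatch(stats::optim(tr, nll, method = "Nelder-Mead",
                                control = list(maxit = maxit, reltol = 1e-8)),
                   error = function(e) NULL)
    if (!is.null(op)) {
      par <- c(a = 1.05 + 0.95 / (1 + exp(-op$par[1])), b = tanh(op$par[2]),
               lg = op$par[3], d = op$par[4])
    } else {
      message("stable maximum-likelihood refinement failed; keeping the quantile-based fit")
    }
  }
  list(alpha = unname(par[1]), beta = unname(par[2]),
       gamma = unname(exp(par[3])), delta = unname(par[4]))
}

#' Fit a warp distribution to a latent column
#'
#' @param y numeric latent data.
#' @param family one of \code{"alaplace"}, \code{"ev"}, \code{"stable"}.
#' @param ... options for the stable fit (\code{refine}, \code{maxit}).
#' @return An object of class \code{npn_warp} with the family name and the
#'   fitted parameters.
#' @export
fit_warp <- function(y, family = c("alaplace", "ev", "stable"), ...) {
  family <- match.arg(family)
  par <- switch(family,
                alaplace = fit_al(y),
                ev = fit_ev(y),
                stable = fit_stable(y, ...))
  structure(list(family = family, par = par), class = "npn_warp")
}

#' Warp cdf and quantile function
#'
#' \code{pwarp} evaluates the fitted cdf \eqn{G(y) \in (0,1)};
#' \code{qwarp} is its inverse, exact for the closed-form families and a
#' high-accuracy root solve for the stable family.
#'
#' @param fit an [fit_warp()] object.
#' @param q,p numeric vectors.
#' @export
pwarp <- function(q, fit) {
  with(fit$par, switch(fit$family,
                       alaplace = pal(q, m, lambda, kappa),
                       ev = pev(q, mu, sigma),
                       stable = pstab(q, alpha, beta, gamma, delta)))
}

#' @rdname pwarp
#' @export
qwarp <- function(p, fit) {
  with(fit$par, switch(fit$family,
                       alaplace = qal(p, m, lambda, kappa),
                       ev = qev(p, mu, sigma),
                       stable = qstab(p, alpha, beta, gamma, delta)))
}
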