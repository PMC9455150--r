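#' End-to-end structure learning pipeline
#'
#' Composes the stages: (optional) min-max rescaling and monotone
#' transformation estimation, sparsity tuning, one of the three fitting
#' engines, graph selection, and (when the truth is known) evaluation.
#' \itemize{
#'   \item \code{engine = "vb"}: tuning by [vb_tune()], fit by [vb_fit()],
#'     estimate and median-probability edges by [vb_precision()].
#'   \item \code{engine = "bg"}: tuning as above, then [gibbs_bg()]
#'     initialized at the tuned indicators; edges from the support
#'     frequencies.
#'   \item \code{engine = "horseshoe"}: one [gibbs_horseshoe()] chain per
#'     candidate \eqn{c}, 0-1-loss thresholding against the Wishart
#'     reference, median-probability edges, then BIC over
#'     \eqn{c \in \{0.1, 1, 10\}} via the constrained MLE refit.
#' }
#' All randomness is routed through \code{seed}.
#'
#' @param X raw data matrix, or \code{NULL} when \code{sim} is given.
#' @param sim optional output of [sim_nonparanormal()] (provides \code{X}
#'   and the truth for evaluation).
#' @param engine \code{"vb"}, \code{"bg"} or \code{"horseshoe"}.
#' @param transform estimate the B-spline transformations first; when
#'   \code{FALSE} the engines run on the column-centered observations.
#' @param c_grid candidate sparsity constants for the horseshoe engine.
#' @param transform_args,engine_args named lists of overrides passed to
#'   [fit_transforms()] and to the engine.
#' @param seed integer seed for the whole run.
#' @param out optional output directory; when given, writes \code{Z},
#'   \eqn{\hat\Omega}, the edge list, and a JSON manifest.
#' @return List with \code{omega}, \code{edges}, \code{Z}, \code{engine},
#'   stage objects (\code{transform}, \code{tuning}, \code{fit}),
#'   \code{metrics} (when truth available) and \code{manifest}.
#' @export
npn_pipeline <- function(X = NULL, sim = NULL,
                         engine = c("vb", "bg", "horseshoe"),
                         transform = TRUE, c_grid = c(0.1, 1, 10),
                         transform_args = list(), engine_args = list(),
                         seed = 1, out = NULL) {
  engine <- match.arg(engine)
  t_start <- Sys.time()
  if (is.null(X)) {
    if (is.null(sim)) stop("supply 'X' or 'sim'", call. = FALSE)
    X <- sim$X
  }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)

  tf <- NULL
  if (transform) {
    Xs <- minmax_rescale(X)
    tf <- do.call(fit_transforms,
                  c(list(X = Xs, seed = seed), transform_args))
    Z <- tf$Z
    Z_tune <- tf$Z_init
  } else {
    Z <- sweep(X, 2L, colMeans(X))
    Z_tune <- Z
  }

  tuning <- NULL
  fit <- NULL
  if (engine %in% c("vb", "bg")) {
    tuning <- vb_tune(Z_tune)
    if (engine == "vb") {
      fit <- do.call(vb_fit, c(list(Z = Z, rho = tuning$rho,
                                    w_init = tuning$w), engine_args))
      est <- vb_precision(fit, seed = seed + 1L)
      omega <- est$omega
      edges <- est$edges
    } else {
      fit <- do.call(gibbs_bg, c(list(Z = Z, rho = tuning$rho,
                                      upsilon_init = tuning$upsilon_init,
                                      seed = seed + 1L), engine_args))
      omega <- fit$omega_mean
      edges <- median_prob_edges(fit$edge_freq)
    }
    bic <- NULL
  } else {
    jref <- wishart_partial_corr(Z)
    chains <- lapply(seq_along(c_grid), function(i)
      do.call(gibbs_horseshoe,
              c(list(Z = Z, c_sparsity = c_grid[i], ref_partial = jref,
                     seed = seed + i), engine_args)))
    edges_by_c <- lapply(chains, function(ch) median_prob_edges(ch$edge_freq))
    names(edges_by_c) <- as.character(c_grid)
    bic <- bic_select(edges_by_c, crossprod(Z), n)
    i_star <- match(bic$c_star, c_grid)
    fit <- chains[[i_star]]
    omega <- fit$omega_mean
    edges <- bic$edges
  }
  dimnames(edges) <- list(colnames(X), colnames(X))

  metrics <- NULL
  if (!is.null(sim) && !is.null(sim$truth)) {
    em <- edge_metrics(confusion_edges(edges, sim$truth))
    metrics <- c(em, list(scaled_l1 = scaled_l1(omega, sim$Omega),
                          n_edges = sum(edges[upper.tri(edges)])))
  }

  manifest <- list(
    engine = engine, transform = transform, n = n, p = p, seed = seed,
    c_star = if (!is.null(bic)) bic$c_star else NULL,
    tuned_rho = if (!is.null(tuning)) list(iota = tuning$iota, c = tuning$c) else NULL,
    n_edges = sum(edges[upper.tri(edges)] != 0),
    metrics = metrics,
    runtime_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  res <- list(omega = omega, edges = edges, Z = Z, engine = engine,
              transform = tf, tuning = tuning, fit = fit, bic = bic,
              metrics = metrics, manifest = manifest)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_matrix_file(Z, file.path(out, "Z.csv"))
    write_matrix_file(omega, file.path(out, "omega_hat.csv"))
    write_edges_file(edges, file.path(out, "edges.tsv"), weights = omega)
    write_manifest(manifest, file.path(out, "manifest.json"))
  }
  res
}

#' Reduced-scale replication of the simulation study
#'
#' Runs the nine (model, p, n) designs — percent sparsity 10/5/2 percent,
#' AR(2), and circle at \eqn{(p, n) \in \{(25,25), (50,100), (100,300)\}} —
#' for \code{ceiling(100/scale)} replications each, with the chain lengths
#' and variational iteration caps divided by \code{scale}, and tabulates
#' sensitivity, specificity, MCC and scaled L1 loss per engine with and
#' without the transformation stage.
#'
#' @param scale reduction factor (\code{scale = 1} reproduces the full
#'   study size; the default 20 is an afternoon-size run).
#' @param designs optional data frame with columns \code{model}, \code{p},
#'   \code{n}, \code{percent} overriding the nine standard designs.
#' @param engines character vector among \code{"vb"}, \code{"bg"},
#'   \code{"horseshoe"}.
#' @param transforms logical vector; designs are run with and/or without
#'   the spline stage.
#' @param seed base seed; replication r of design i uses a deterministic
#'   offset.
#' @return Data frame with one row per design x engine x transform x
#'   replication and columns \code{SE}, \code{SP}, \code{MCC},
#'   \code{scaled_l1}.
#' @export
replicate_study <- function(scale = 20, designs = NULL, engines = "vb",
                            transforms = c(TRUE, FALSE), seed = 1) {
  if (scale < 1) stop("'scale' must be >= 1", call. = FALSE)
  if (is.null(designs)) {
    designs <- data.frame(
      model = rep(c("percent", "ar2", "circle"), each = 3),
      p = rep(c(25, 50, 100), 3),
      n = rep(c(25, 100, 300), 3),
      percent = c(10, 5, 2, NA, NA, NA, NA, NA, NA))
  }
  n_rep <- max(1L, ceiling(100 / scale))
  iters <- max(300L, ceiling(15000 / scale))
  burn <- max(100L, ceiling(5000 / scale))
  rows <- list()
  for (i in seq_len(nrow(designs))) {
    de <- designs[i, ]
    for (r in seq_len(n_rep)) {
      sd_r <- seed + 1000L * i + r
      Om <- if (de$model == "percent")
        sim_precision("percent", de$p, percent = de$percent, seed = sd_r) else
        sim_precision(as.character(de$model), de$p)
      sim <- sim_nonparanormal(Om, de$n, seed = sd_r, stable_refine = FALSE)
      for (tr in transforms) for (eng in engines) {
        eng_args <- if (eng == "vb") list() else
          list(n_iter = iters, burn_in = burn)
        res <- npn_pipeline(sim = sim, engine = eng, transform = tr,
                            transform_args = list(n_iter = iters, burn_in = burn),
                            engine_args = eng_args, seed = sd_r)
        rows[[length(rows) + 1L]] <- data.frame(
          model = de$model, p = de$p, n = de$n, engine = eng,
          transform = tr, rep = r,
          SE = res$metrics$SE, SP = res$metrics$SP, MCC = res$metrics$MCC,
          scaled_l1 = res$metrics$scaled_l1)
      }
    }
  }
  do.call(rbind, rows)
}
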