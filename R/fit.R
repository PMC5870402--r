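#' Fitting options for the alternating estimator
#'
#' @param max_iter maximum number of weight/loading alternations.
#' @param tol relative penalised-loss change below which the alternation is
#'   declared converged.
#' @param n_random_starts number of random starting configurations run in
#'   addition to the rational (exact non-sparse) start.
#' @param seed optional integer seed; all randomness in the fit flows from it.
#' @param debias if `TRUE`, re-estimate the non-zero weights by an
#'   unpenalised fixed-support fit after convergence (undoes lasso
#'   shrinkage).
#' @return object of class `fit_options`.
#' @export
fit_options <- function(max_iter = 500L, tol = 1e-6, n_random_starts = 5L,
                        seed = NULL, debias = FALSE) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(
    list(max_iter = as.integer(max_iter), tol = tol,
         n_random_starts = as.integer(n_random_starts), seed = seed,
         debias = isTRUE(debias)),
    class = "fit_options"
  )
}

#' Conditional coordinate-descent update of the component weights
#'
#' Runs full sweeps of coordinate descent over the weight matrix with the
#' loadings held fixed.  Each single-coordinate update is the exact
#' minimiser of the univariate elastic-net problem: soft thresholding of the
#' partial-residual covariance at `lambda1 / 2`, divided by
#' `lambda2 + ||p_r||^2 ||x_j||^2`.  The penalised loss is non-increasing
#' over every update.
#'
#' @param x predictor block.
#' @param z concatenated target ([build_concatenated_target()]).
#' @param P concatenated loading matrix ((Jy + Jx) x R).
#' @param W starting weight matrix (Jx x R).
#' @param settings [penalty_settings()] supplying the penalties.
#' @param support optional logical mask; weights outside it are clamped to
#'   zero.
#' @param n_sweeps number of full sweeps.
#' @param coord_order integer order in which predictor columns are visited
#'   (default ascending).
#' @return list with updated `W` and scores `T = X W`.
#' @export
update_weights <- function(x, z, P, W, settings, support = NULL,
                           n_sweeps = 1L, coord_order = NULL) {
  x <- as_block(x, "x")
  if (is.null(support)) support <- matrix(TRUE, nrow(W), ncol(W))
  if (is.null(coord_order)) coord_order <- seq_len(nrow(W))
  cd_sweeps(x$values, z$z, P, W, support,
            settings$lambda1, settings$lambda2,
            as.integer(n_sweeps), as.integer(coord_order) - 1L)
}

#' Conditional update of the concatenated loadings
#'
#' With the scores `T = X W` fixed, updates the loading matrix under the
#' chosen identification constraint.  In `"unit_length"` mode each column is
#' set to the normalised cross-product of the deflated target with its score
#' column, cycling until stable.  In `"orthogonal"` mode the update is the
#' orthogonal Procrustes solution `P = V U^T` from the singular value
#' decomposition of `T^T Z`; when the number of variables is large the same
#' solution is obtained from the eigendecomposition of the small R x R matrix
#' `T^T Z Z^T T`.
#'
#' @param Tm score matrix (I x R), full column rank.
#' @param z concatenated target.
#' @param P current loading matrix (used as the starting point of the
#'   unit-length cycling).
#' @param mode `"unit_length"` or `"orthogonal"`.
#' @param method for the orthogonal mode: `"svd"`, `"eigen"` or `"auto"`
#'   (eigen path when the number of target columns exceeds 1000).
#' @return updated loading matrix.
#' @export
update_loadings <- function(Tm, z, P, mode = c("unit_length", "orthogonal"),
                            method = "auto") {
  mode <- match.arg(mode)
  Z <- z$z
  R <- ncol(Tm)
  if (mode == "orthogonal") {
    C <- crossprod(Tm, Z)                       # R x (Jy + Jx)
    use_eigen <- switch(method,
      svd = FALSE, eigen = TRUE, auto = ncol(Z) > 1000
    )
    if (use_eigen) {
      A <- tcrossprod(C)                        # R x R  = T^T Z Z^T T
      eg <- eigen(A, symmetric = TRUE)
      d <- sqrt(pmax(eg$values, 0))
      if (any(d <= R * .Machine$double.eps * max(d)))
        stop("T^T Z is rank deficient; orthogonal loading update undefined")
      U <- eg$vectors
      V <- crossprod(C, U) %*% diag(1 / d, R)
      P_new <- V %*% t(U)
    } else {
      s <- svd(C)
      P_new <- s$v %*% t(s$u)
    }
    return(P_new)
  }
  # unit-length mode: cycle the columns until stable
  ZtT <- crossprod(Z, Tm)                        # (Jy + Jx) x R
  TtT <- crossprod(Tm)
  P_new <- P
  for (cycle in seq_len(25L)) {
    max_change <- 0
    for (r in seq_len(R)) {
      q <- ZtT[, r] - P_new %*% TtT[, r] + P_new[, r] * TtT[r, r]
      nrm <- sqrt(sum(q^2))
      if (nrm <= .Machine$double.eps) {
        warning(sprintf("zero cross-product for loading column %d; left unchanged", r))
        next
      }
      q <- q / nrm
      max_change <- max(max_change, max(abs(q - P_new[, r])))
      P_new[, r] <- q
    }
    if (max_change < 1e-10) break
  }
  P_new
}

# Canonicalise a (W, P) pair that reproduces the same fitted matrix
# X W P^T so that P satisfies the requested constraint exactly, folding the
# column rescaling (or rotation) into W.
canonicalize_start <- function(W, P, mode) {
  if (mode == "unit_length") {
    nrm <- sqrt(colSums(P^2))
    nrm[nrm == 0] <- 1
    list(W = sweep(W, 2L, nrm, `*`), P = sweep(P, 2L, nrm, `/`))
  } else {
    # fold P = U D V^T into the weights: X W P^T = X (W V D) U^T
    s <- svd(P)
    list(W = W %*% (s$v %*% diag(s$d, ncol(P))), P = s$u)
  }
}

# Core alternation on a prepared concatenated target.  Returns W, P, the
# convergence log (penalised loss after every conditional step) and the
# final penalised loss.  Errors if any conditional step increases the loss
# by more than 1e-8 (an implementation fault, not a data problem).
alternate_fit <- function(xv, z, W, P, settings, options, support = NULL) {
  lambda1 <- settings$lambda1; lambda2 <- settings$lambda2
  if (is.null(support)) support <- matrix(TRUE, nrow(W), ncol(W))
  mode(support) <- "logical"
  coord_order <- seq_len(nrow(W))
  loss <- penalized_concat_loss(z$z, xv, W, P, lambda1, lambda2)
  log_loss <- c(start = loss)
  for (iter in seq_len(options$max_iter)) {
    upd <- cd_sweeps(xv, z$z, P, W, support, lambda1, lambda2, 1L,
                     coord_order - 1L)
    W <- upd$W
    loss_w <- penalized_concat_loss(z$z, xv, W, P, lambda1, lambda2)
    if (loss_w > loss + 1e-8)
      stop(sprintf("penalised loss increased in weight update (%.3e)", loss_w - loss))
    Tm <- upd$T
    if (all(W == 0)) {
      # no scores left: loadings are unidentified, stop here
      log_loss <- c(log_loss, loss_w)
      loss <- loss_w
      break
    }
    P <- update_loadings(Tm, z, P, mode = settings$loading_constraint)
    loss_p <- penalized_concat_loss(z$z, xv, W, P, lambda1, lambda2)
    if (loss_p > loss_w + 1e-8)
      stop(sprintf("penalised loss increased in loading update (%.3e)", loss_p - loss_w))
    log_loss <- c(log_loss, loss_w, loss_p)
    rel <- abs(loss - loss_p) / max(loss, .Machine$double.eps)
    loss <- loss_p
    if (rel < options$tol) break
  }
  list(W = W, P = P, loss = loss, log = unname(log_loss), iterations = iter)
}

# Rational start: the exact non-sparse solution, canonicalised to the
# requested loading constraint without changing the fitted values.
rational_start <- function(x, y, settings) {
  base <- solve_pcovr(x, y, penalty_settings(
    alpha = settings$alpha, n_components = settings$n_components,
    loading_constraint = settings$loading_constraint
  ))
  canonicalize_start(base$weights, attr(base, "P_concat"),
                     settings$loading_constraint)
}

random_start <- function(x, z, settings) {
  Jx <- x$n_vars; R <- settings$n_components
  W <- matrix(stats::rnorm(Jx * R), Jx, R)
  Tm <- x$values %*% W
  sds <- apply(Tm, 2L, stats::sd)
  sds[sds == 0] <- 1
  W <- sweep(W, 2L, sds, `/`)
  Tm <- x$values %*% W
  P <- crossprod(z$z, Tm)
  canonicalize_start(W, P, settings$loading_constraint)[c("W", "P")]
}

#' Fit a sparse principal covariates regression model
#'
#' Alternates conditional coordinate-descent updates of the component weights
#' ([update_weights()]) with conditional loading updates ([update_loadings()])
#' until the relative change in the penalised loss falls below `tol`.  The
#' multistart strategy runs the rational start (the exact non-sparse
#' solution) plus `n_random_starts` random configurations and keeps the
#' lowest-loss solution, mitigating local optima.
#'
#' @param x,y predictor and outcome blocks ([center_scale()] output or
#'   matrices).
#' @param settings [penalty_settings()].
#' @param options [fit_options()].
#' @param W_start optional list of additional warm-start weight matrices.
#' @return object of class `spcovr_fit`, a `component_model` with extra
#'   elements: `summary` (a `fit_summary`), `convergence` (penalised loss
#'   after every conditional step of the winning start), `settings`,
#'   `best_start`, `P_concat` and, when `debias = TRUE`, the penalised
#'   weights in `weights_penalized`.
#' @export
fit_spcovr <- function(x, y, settings, options = fit_options(),
                       W_start = NULL) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  z <- build_concatenated_target(x, y, settings)
  if (!is.null(options$seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(options$seed)
  }
  starts <- list(rational = rational_start(x, y, settings))
  if (options$n_random_starts > 0) {
    for (k in seq_len(options$n_random_starts))
      starts[[paste0("random", k)]] <- random_start(x, z, settings)
  }
  if (!is.null(W_start)) {
    for (k in seq_along(W_start)) {
      W0 <- W_start[[k]]
      Tm <- x$values %*% W0
      P0 <- crossprod(z$z, Tm)
      if (all(P0 == 0)) P0 <- starts$rational$P
      st <- canonicalize_start(W0, P0, settings$loading_constraint)
      starts[[paste0("warm", k)]] <- st
    }
  }
  best <- NULL
  best_name <- NA_character_
  for (nm in names(starts)) {
    st <- starts[[nm]]
    res <- alternate_fit(x$values, z, st$W, st$P, settings, options)
    if (is.null(best) || res$loss < best$loss - 1e-12) {
      best <- res
      best_name <- nm
    }
  }
  as_spcovr_fit(best, x, y, z, settings, options, best_start = best_name)
}

as_spcovr_fit <- function(res, x, y, z, settings, options, best_start = NA) {
  Tm <- x$values %*% res$W
  parts <- split_loadings(res$P, z, x, y, Tm)
  model <- component_model(res$W, parts$Px, parts$Py, x,
                           constraint_mode = settings$loading_constraint)
  if (isTRUE(options$debias) && any(res$W != 0)) {
    pen_model <- model
    refit <- refit_fixed_support(x, y, res$W != 0, settings)
    model <- refit
    model$weights_penalized <- pen_model$weights
  }
  model$summary <- evaluate_fit(model, x, y, settings)
  model$convergence <- res$log
  model$iterations <- res$iterations
  model$settings <- settings
  model$best_start <- best_start
  model$P_concat <- res$P
  class(model) <- c("spcovr_fit", class(model))
  model
}

#' @export
print.spcovr_fit <- function(x, ...) {
  cat(sprintf(
    "<spcovr_fit> alpha = %g, R = %d, lambda1 = %g, lambda2 = %g\n",
    x$settings$alpha, x$settings$n_components, x$settings$lambda1,
    x$settings$lambda2
  ))
  cat(sprintf("  %d / %d non-zero weights; best start: %s; %d alternations\n",
              sum(x$weights != 0), length(x$weights), x$best_start,
              x$iterations))
  print(x$summary)
  invisible(x)
}

#' Unpenalised refit on a fixed support
#'
#' Re-estimates the model with both penalties at zero and the weights outside
#' `support` clamped to zero.  Used to debias penalised estimates (the lasso
#' over-shrinks the surviving coefficients) and by the simulation generator
#' to obtain model-consistent weights and loadings from an initial sparse
#' pattern.
#'
#' @param x,y predictor and outcome blocks.
#' @param support logical Jx x R mask of allowed non-zero weights.
#' @param settings [penalty_settings()]; its penalties are ignored (set to 0).
#' @param options [fit_options()].
#' @param W_start optional starting weight matrix.
#' @return a `spcovr_fit`.
#' @export
refit_fixed_support <- function(x, y, support, settings,
                                options = fit_options(n_random_starts = 0L),
                                W_start = NULL) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  support <- as.matrix(support)
  mode(support) <- "logical"
  options$debias <- FALSE
  settings0 <- penalty_settings(
    alpha = settings$alpha, n_components = settings$n_components,
    lambda1 = 0, lambda2 = 0,
    loading_constraint = settings$loading_constraint
  )
  z <- build_concatenated_target(x, y, settings0)
  if (!any(support)) {
    warning("empty support: returning the all-zero model")
    W <- matrix(0, x$n_vars, settings0$n_components)
    P <- matrix(0, z$jy + z$jx, settings0$n_components)
    res <- list(W = W, P = P,
                loss = penalized_concat_loss(z$z, x$values, W, P, 0, 0),
                log = numeric(0), iterations = 0L)
    return(as_spcovr_fit(res, x, y, z, settings0, options))
  }
  if (is.null(W_start)) {
    st <- rational_start(x, y, settings0)
    W0 <- st$W * support
  } else {
    W0 <- as.matrix(W_start) * support
  }
  if (all(W0 == 0)) W0[support] <- 1e-3
  Tm <- x$values %*% W0
  P0 <- crossprod(z$z, Tm)
  if (all(abs(P0) < .Machine$double.eps))
    P0 <- matrix(stats::rnorm(length(P0)), nrow(P0), ncol(P0))
  st <- canonicalize_start(W0, P0, settings0$loading_constraint)
  res <- alternate_fit(x$values, z, st$W, st$P, settings0, options,
                       support = support)
  as_spcovr_fit(res, x, y, z, settings0, options)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
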