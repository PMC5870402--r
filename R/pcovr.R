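#' Exact (non-sparse) principal covariates regression
#'
#' Solves the unpenalised weighted criterion
#' \deqn{(1-\alpha)\,\|Y - XWP_y^T\|^2/\|Y\|^2 + \alpha\,\|X - XWP_x^T\|^2/\|X\|^2}
#' exactly under the orthonormality constraint \eqn{T^T T = I}.  Writing
#' `Z = [w1 Y, w2 X]`, the optimal scores are the top-R eigenvectors of
#' \eqn{H_X Z Z^T H_X} with \eqn{H_X} the projector on the column space of X;
#' the weights solve `X W = T` in least squares and the concatenated loadings
#' are `P = Z^T T`.  The eigenproblem is formed on the smaller of the two
#' possible Gram matrices so large `I` or large `J` are both handled.
#'
#' Serves both as the baseline non-sparse fit and as the rational start of
#' the sparse alternating algorithm.
#'
#' @param x,y predictor and outcome blocks ([center_scale()] output or
#'   matrices).
#' @param settings [penalty_settings()]; `lambda1`/`lambda2` must be zero.
#' @return a `component_model` with additional attribute `"loss"` (the
#'   achieved criterion value) and `"P_concat"` (the concatenated loadings).
#' @export
solve_pcovr <- function(x, y, settings) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  if (settings$lambda1 != 0 || settings$lambda2 != 0)
    stop("solve_pcovr is the non-sparse solver; lambda1 and lambda2 must be 0")
  concat <- build_concatenated_target(x, y, settings)
  R <- settings$n_components
  sv <- svd(x$values)
  rank_x <- sum(sv$d > max(dim(x$values)) * .Machine$double.eps * sv$d[1])
  if (R > rank_x)
    stop(sprintf("n_components (%d) exceeds rank of X (%d)", R, rank_x))
  Ux <- sv$u[, seq_len(rank_x), drop = FALSE]
  M <- crossprod(Ux, concat$z)            # rank_x x (Jy + Jx)
  eg <- eigen(tcrossprod(M), symmetric = TRUE)
  G <- eg$vectors[, seq_len(R), drop = FALSE]
  Tm <- Ux %*% G
  W <- sv$v[, seq_len(rank_x), drop = FALSE] %*%
    (G / sv$d[seq_len(rank_x)])
  P <- crossprod(concat$z, Tm)            # (Jy + Jx) x R
  parts <- split_loadings(P, concat, x, y, Tm)
  model <- component_model(W, parts$Px, parts$Py, x,
                           constraint_mode = settings$loading_constraint)
  attr(model, "loss") <- sum(concat$z^2) - sum(eg$values[seq_len(R)])
  attr(model, "P_concat") <- P
  attr(model, "eigenvalues") <- eg$values
  model
}

#' Maximum-likelihood choice of the weighting parameter
#'
#' Sets `alpha = Jx / (Jx + Jy * s2_ex / s2_ey)` with plug-in error-variance
#' estimates: `s2_ex` is the residual mean square of the r-component
#' principal component approximation of X, and `s2_ey` the residual mean
#' square of the least-squares regression of Y on those r principal component
#' scores.  The returned value is capped strictly below one (at 0.99): with
#' many predictors the raw expression approaches one, but some weight must
#' remain on the outcome for the components to be informed by it at all.
#'
#' @param x,y predictor and outcome blocks.
#' @param r number of components used for the plug-in variance estimates.
#' @param cap upper cap on alpha (default 0.99).
#' @return object of class `alpha_estimate`: list with `alpha`, `sigma2_ex`,
#'   `sigma2_ey` and `clamped`.
#' @export
maximum_likelihood_alpha <- function(x, y, r, cap = 0.99) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  stopifnot(r >= 1)
  sv <- svd(x$values, nu = min(r, x$n_obs), nv = 0)
  if (r > length(sv$d)) stop("r exceeds rank of X")
  s2_ex <- (sum(sv$d^2) - sum(sv$d[seq_len(r)]^2)) / (x$n_obs * x$n_vars)
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  res_y <- y$values - Ur %*% crossprod(Ur, y$values)
  s2_ey <- sum(res_y^2) / (y$n_obs * y$n_vars)
  clamped <- FALSE
  if (s2_ey <= .Machine$double.eps) {
    alpha <- cap
    clamped <- TRUE
  } else {
    alpha <- x$n_vars / (x$n_vars + y$n_vars * s2_ex / s2_ey)
    if (alpha > cap) {
      alpha <- cap
      clamped <- TRUE
    }
  }
  structure(
    list(alpha = alpha, sigma2_ex = s2_ex, sigma2_ey = s2_ey, clamped = clamped),
    class = "alpha_estimate"
  )
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf(
    "<alpha_estimate> alpha = %.4f%s (s2_ex = %.4g, s2_ey = %.4g)\n",
    x$alpha, if (x$clamped) " [capped]" else "", x$sigma2_ex, x$sigma2_ey
  ))
  invisible(x)
}

#' Scree procedure for the number of components
#'
#' Computes the exact criterion value for r = 1, ..., `r_max` components and
#' suggests the elbow: the r maximising the drop ratio
#' `(loss[r-1] - loss[r]) / (loss[r] - loss[r+1])` (with the zero-component
#' loss equal to the total normalised variance).  The loss sequence is also
#' returned for visual inspection, which remains the recommended procedure;
#' the automated suggestion is flagged low-confidence when no drop ratio
#' clearly dominates (max ratio below 2), as happens for unstructured noise.
#'
#' @param x,y predictor and outcome blocks.
#' @param alpha weighting parameter to use.
#' @param r_max largest number of components to consider (must not exceed
#'   the rank of X).
#' @return object of class `scree_result`: `losses` (length `r_max`),
#'   `suggested_r`, `confidence` ("ok"/"low") and `drop_ratios`.
#' @export
scree <- function(x, y, alpha, r_max) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  settings <- penalty_settings(alpha = alpha, n_components = 1)
  base <- solve_pcovr(x, y, settings)
  evals <- attr(base, "eigenvalues")
  if (r_max > length(evals) || r_max > min(dim(x$values)))
    stop("r_max exceeds the rank of X")
  concat <- build_concatenated_target(x, y, settings)
  total <- sum(concat$z^2)
  losses <- total - cumsum(evals)[seq_len(r_max)]
  if (r_max == 1L) {
    return(structure(
      list(losses = losses, suggested_r = 1L, confidence = "low",
           drop_ratios = numeric(0)),
      class = "scree_result"
    ))
  }
  all_loss <- c(total, losses)        # index r + 1 holds loss at r components
  eps <- 1e-12
  ratios <- vapply(seq_len(r_max - 1L), function(r) {
    drop_prev <- all_loss[r] - all_loss[r + 1L]
    drop_next <- all_loss[r + 1L] - all_loss[r + 2L]
    drop_prev / max(drop_next, eps)
  }, numeric(1))
  suggested <- which.max(ratios)
  structure(
    list(
      losses = losses, suggested_r = as.integer(suggested),
      confidence = if (max(ratios) >= 2) "ok" else "low",
      drop_ratios = ratios
    ),
    class = "scree_result"
  )
}

#' @export
print.scree_result <- function(x, ...) {
  cat("<scree_result> losses:", sprintf("%.4f", x$losses), "\n")
  cat(sprintf("  suggested number of components: %d (confidence: %s)\n",
              x$suggested_r, x$confidence))
  invisible(x)
}

#' Plot a scree curve
#'
#' @param x a `scree_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scree_result <- function(x, ...) {
  graphics::plot(seq_along(x$losses), x$losses, type = "b",
                 xlab = "number of components", ylab = "loss", ...)
  graphics::abline(v = x$suggested_r, lty = 2)
  invisible(x)
}
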