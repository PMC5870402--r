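#' Penalty and model-size settings
#'
#' Bundles the meta-parameters of a (sparse) principal covariates regression
#' model: the weighting parameter `alpha` balancing outcome prediction
#' (`alpha` near 0) against predictor reconstruction (`alpha` near 1), the
#' elastic-net penalties on the component weights, the number of components
#' and the identification constraint carried by the loadings.
#'
#' @param alpha weighting parameter in \[0, 1\]. `alpha = 1` gives principal
#'   components regression; `alpha = 0` with one component gives elastic-net
#'   regression.
#' @param n_components number of components R (>= 1).
#' @param lambda1 lasso penalty on the component weights (>= 0).
#' @param lambda2 ridge penalty on the component weights (>= 0).
#' @param loading_constraint `"unit_length"` (each concatenated loading
#'   column has norm one; allows correlated loadings) or `"orthogonal"`
#'   (orthonormal concatenated loadings).  Either constraint prevents the
#'   trivial solution in which vanishing weights are compensated by
#'   exploding loadings.
#' @return an object of class `penalty_settings`.
#' @export
penalty_settings <- function(alpha, n_components, lambda1 = 0, lambda2 = 0,
                             loading_constraint = c("unit_length", "orthogonal")) {
  loading_constraint <- match.arg(loading_constraint)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
    is.numeric(lambda1), lambda1 >= 0,
    is.numeric(lambda2), lambda2 >= 0,
    n_components >= 1
  )
  structure(
    list(
      alpha = alpha, lambda1 = lambda1, lambda2 = lambda2,
      n_components = as.integer(n_components),
      loading_constraint = loading_constraint
    ),
    class = "penalty_settings"
  )
}

#' @export
print.penalty_settings <- function(x, ...) {
  cat(sprintf(
    "<penalty_settings> alpha = %g, R = %d, lambda1 = %g, lambda2 = %g, constraint = %s\n",
    x$alpha, x$n_components, x$lambda1, x$lambda2, x$loading_constraint
  ))
  invisible(x)
}

#' Build the weighted concatenated target
#'
#' Stacks the outcome and predictor blocks into a single weighted matrix
#' `Z = [w1 Y, w2 X]` with `w1 = sqrt(1 - alpha) / ||Y||` and
#' `w2 = sqrt(alpha) / ||X||` (Frobenius norms), so that the least-squares
#' criterion `||Z - X W P^T||^2` equals the weighted sum of the two
#' normalised residual fractions.
#'
#' @param x predictor block (`scaled_block` or matrix).
#' @param y outcome block (`scaled_block`, matrix or vector).
#' @param settings a [penalty_settings()] object (only `alpha` is used).
#' @return object of class `concat_target` with elements `z`, `w1`, `w2`,
#'   `jy`, `jx` and the column index ranges of the two blocks.
#' @export
build_concatenated_target <- function(x, y, settings) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  if (x$n_obs != y$n_obs)
    stop("x and y must have the same number of rows")
  alpha <- settings$alpha
  nx <- sqrt(sum(x$values^2))
  ny <- sqrt(sum(y$values^2))
  w1 <- sqrt(1 - alpha) / ny
  w2 <- sqrt(alpha) / nx
  z <- cbind(w1 * y$values, w2 * x$values)
  structure(
    list(
      z = z, w1 = w1, w2 = w2, jy = y$n_vars, jx = x$n_vars,
      idx_y = seq_len(y$n_vars), idx_x = y$n_vars + seq_len(x$n_vars)
    ),
    class = "concat_target"
  )
}

#' Component model constructor
#'
#' Holds the parameters of a fitted component model: component weights `W`
#' (predictors to scores, the sparse quantity), predictor loadings `Px`,
#' regression weights `Py` and scores `T = X W`.
#'
#' @param weights Jx x R weight matrix.
#' @param loadings_x Jx x R predictor loadings.
#' @param loadings_y Jy x R regression weights.
#' @param x predictor block used to compute the scores.
#' @param constraint_mode the loading constraint under which the model was
#'   identified.
#' @return object of class `component_model`.
#' @export
component_model <- function(weights, loadings_x, loadings_y, x,
                            constraint_mode = "unit_length") {
  x <- as_block(x, "x")
  weights <- as.matrix(weights)
  loadings_y <- as.matrix(loadings_y)
  structure(
    list(
      weights = weights,
      loadings_x = as.matrix(loadings_x),
      loadings_y = loadings_y,
      scores = x$values %*% weights,
      constraint_mode = constraint_mode
    ),
    class = "component_model"
  )
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf(
    "<component_model> %d predictors, %d outcome variable(s), %d component(s); %d non-zero weights\n",
    nrow(x$weights), nrow(x$loadings_y), ncol(x$weights), sum(x$weights != 0)
  ))
  invisible(x)
}

# Split a concatenated loading matrix P = [w1 Py; w2 Px] back into the
# outcome and predictor loadings.  When a weight is zero (alpha at a
# boundary) the corresponding loadings are re-estimated by least squares of
# the block on the scores, so that predictions remain defined at alpha = 1.
split_loadings <- function(P, concat, x, y, Tm) {
  jy <- concat$jy
  Py_part <- P[concat$idx_y, , drop = FALSE]
  Px_part <- P[concat$idx_x, , drop = FALSE]
  ls_load <- function(block) {
    fit <- tryCatch(qr.solve(qr(Tm), block), error = function(e) {
      matrix(0, ncol(Tm), ncol(block))
    })
    t(fit)
  }
  Py <- if (concat$w1 > 0) Py_part / concat$w1 else ls_load(y$values)
  Px <- if (concat$w2 > 0) Px_part / concat$w2 else ls_load(x$values)
  list(Px = Px, Py = Py)
}

# || Z - X W P^T ||^2, the concatenated least-squares form of the criterion
concat_loss <- function(z, xv, W, P) {
  sum((z - xv %*% W %*% t(P))^2)
}

penalized_concat_loss <- function(z, xv, W, P, lambda1, lambda2) {
  concat_loss(z, xv, W, P) + lambda1 * sum(abs(W)) + lambda2 * sum(W^2)
}

#' Evaluate the fit of a component model
#'
#' Computes the weighted least-squares criterion, the penalised loss, and the
#' proportions of variance accounted for in the predictor and outcome blocks,
#' overall and per component (rank-one reconstruction sums of squares divided
#' by the total block sum of squares).
#'
#' @param model a `component_model`.
#' @param x,y the predictor and outcome blocks the model was fitted to.
#' @param settings the [penalty_settings()] used.
#' @return object of class `fit_summary` with elements `loss_unpenalized`,
#'   `loss_penalized`, `r2_x`, `r2_y`, `vaf_per_component_x`,
#'   `r2_y_per_component`.
#' @export
evaluate_fit <- function(model, x, y, settings) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  Tm <- x$values %*% model$weights
  ss_x <- sum(x$values^2)
  ss_y <- sum(y$values^2)
  res_x <- x$values - Tm %*% t(model$loadings_x)
  res_y <- y$values - Tm %*% t(model$loadings_y)
  r2_x <- 1 - sum(res_x^2) / ss_x
  r2_y <- 1 - sum(res_y^2) / ss_y
  loss <- (1 - settings$alpha) * (1 - r2_y) + settings$alpha * (1 - r2_x)
  pen <- loss + settings$lambda1 * sum(abs(model$weights)) +
    settings$lambda2 * sum(model$weights^2)
  R <- ncol(model$weights)
  vaf_x <- vapply(seq_len(R), function(r) {
    sum((Tm[, r] %o% model$loadings_x[, r])^2) / ss_x
  }, numeric(1))
  vaf_y <- vapply(seq_len(R), function(r) {
    sum((Tm[, r] %o% model$loadings_y[, r])^2) / ss_y
  }, numeric(1))
  structure(
    list(
      loss_unpenalized = loss, loss_penalized = pen,
      r2_x = r2_x, r2_y = r2_y,
      vaf_per_component_x = vaf_x, r2_y_per_component = vaf_y
    ),
    class = "fit_summary"
  )
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf(
    "<fit_summary> loss = %.6f (penalised %.6f); R2_X = %.4f, R2_Y = %.4f\n",
    x$loss_unpenalized, x$loss_penalized, x$r2_x, x$r2_y
  ))
  cat("  per-component VAF_X:", sprintf("%.4f", x$vaf_per_component_x), "\n")
  invisible(x)
}

#' Predict outcomes from a fitted component model
#'
#' Applies the prediction rule `Y_hat = X_new W Py^T` to new (already centred
#' and scaled) predictor data.
#'
#' @param object a `component_model`.
#' @param newdata a `scaled_block` or numeric matrix of predictors scaled the
#'   same way as the training block.
#' @param ... unused.
#' @return matrix of predicted outcome values.
#' @export
predict.component_model <- function(object, newdata, ...) {
  nd <- if (inherits(newdata, "scaled_block")) newdata$values else as.matrix(newdata)
  nd %*% object$weights %*% t(object$loadings_y)
}
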