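#' Centre and scale a data block
#'
#' Centres every column to mean zero and, by default, scales it to sum of
#' squares one.  This is the scaling convention assumed throughout the
#' package: with per-column sum of squares one, the squared Frobenius norm of
#' a block equals its number of variables, which makes the two terms of the
#' weighted least-squares criterion normalised fractions of unexplained
#' variance.
#'
#' @param raw numeric matrix (observations in rows) or an object coercible to
#'   one.
#' @param scale scaling variant: `"ss1"` (sum of squares one per column, the
#'   default and the convention used by all model fitting functions),
#'   `"sd"` (unit standard deviation, i.e. z-scores) or `"none"` (centre
#'   only; used e.g. for outcome vectors that enter the model centred but
#'   unscaled).
#' @return An object of class `scaled_block`: a list with elements `values`
#'   (the transformed matrix), `n_obs`, `n_vars`, `column_means` and
#'   `column_norms` (the divisors used, so the original data can be recovered
#'   exactly with [unscale()]).
#' @examples
#' b <- center_scale(matrix(rnorm(20), 5, 4))
#' colSums(b$values^2)  # all 1
#' @export
center_scale <- function(raw, scale = c("ss1", "sd", "none")) {
  scale <- match.arg(scale)
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("input must be a numeric matrix")
  if (nrow(raw) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(raw))) stop("non-finite entries in input matrix")
  mu <- colMeans(raw)
  v <- sweep(raw, 2L, mu, `-`)
  ss <- colSums(v^2)
  if (any(ss == 0)) {
    bad <- which(ss == 0)
    stop(sprintf("constant column(s): %s", paste(bad, collapse = ", ")))
  }
  nrm <- switch(scale,
    ss1 = sqrt(ss),
    sd = apply(raw, 2L, stats::sd),
    none = rep(1, ncol(raw))
  )
  v <- sweep(v, 2L, nrm, `/`)
  new_scaled_block(v, column_means = mu, column_norms = nrm, scaling = scale)
}

#' Construct a scaled_block from an already prepared matrix
#'
#' Low-level constructor; [center_scale()] is the user-facing entry point.
#' @param values numeric matrix.
#' @param column_means,column_norms per-column centring/scaling constants
#'   used to produce `values` from the raw data.
#' @param scaling which scaling convention `values` satisfies.
#' @keywords internal
new_scaled_block <- function(values, column_means = rep(0, ncol(values)),
                             column_norms = rep(1, ncol(values)),
                             scaling = "ss1") {
  values <- as.matrix(values)
  structure(
    list(
      values = values,
      n_obs = nrow(values),
      n_vars = ncol(values),
      column_means = column_means,
      column_norms = column_norms,
      scaling = scaling
    ),
    class = "scaled_block"
  )
}

#' @export
print.scaled_block <- function(x, ...) {
  cat(sprintf(
    "<scaled_block> %d observations x %d variables (scaling: %s)\n",
    x$n_obs, x$n_vars, x$scaling
  ))
  invisible(x)
}

#' Recover the raw data from a scaled block
#'
#' Inverts the centring and scaling applied by [center_scale()].
#' @param block a `scaled_block`.
#' @return the original numeric matrix.
#' @export
unscale <- function(block) {
  stopifnot(inherits(block, "scaled_block"))
  sweep(sweep(block$values, 2L, block$column_norms, `*`), 2L,
        block$column_means, `+`)
}

as_block <- function(x, what = "block") {
  if (inherits(x, "scaled_block")) return(x)
  if (is.numeric(x)) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    return(new_scaled_block(x))
  }
  stop(sprintf("%s must be a scaled_block or numeric matrix", what))
}
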