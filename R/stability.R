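#' Stability-selection settings
#'
#' @param n_resamples number of resamples N per lasso value (the flu-scale
#'   analyses use 500).
#' @param resample_fraction fraction f of the observations drawn (with
#'   replacement) into each resample; must satisfy 0.5 <= f < 1.
#' @param pi_threshold selection-probability threshold pi_thr (> 0.5); a
#'   coefficient is declared stable when its maximal selection proportion
#'   reaches this value.
#' @param expected_false target expected number of falsely selected
#'   coefficients E(V) used to derive the stopping bound.
#' @param q_override optional direct bound on the number of non-zero
#'   coefficients, bypassing the E(V)-derived bound (as done in simulation
#'   benchmarks where the true sparsity is known).
#' @param grid_size number of lasso values on the path.
#' @param seed optional integer seed controlling the resampling.
#' @return object of class `stability_settings`.
#' @export
stability_settings <- function(n_resamples = 500L, resample_fraction = 0.5,
                               pi_threshold = 0.90, expected_false = 1,
                               q_override = NULL, grid_size = 50L,
                               seed = NULL) {
  stopifnot(
    resample_fraction >= 0.5, resample_fraction < 1,
    pi_threshold > 0.5, pi_threshold <= 1,
    expected_false >= 0, n_resamples >= 1, grid_size >= 2
  )
  structure(
    list(n_resamples = as.integer(n_resamples),
         resample_fraction = resample_fraction,
         pi_threshold = pi_threshold, expected_false = expected_false,
         q_override = q_override, grid_size = as.integer(grid_size),
         seed = seed),
    class = "stability_settings"
  )
}

#' Smallest lasso value that zeroes every weight
#'
#' At `W = 0` a coordinate update keeps a weight at zero exactly when the
#' absolute covariance of the target with its rank-one direction does not
#' exceed `lambda1 / 2`; the returned value is twice the largest such
#' covariance, computed with the unit-normalised rational-start loadings, so
#' the lasso path can start from the fully sparse solution.
#'
#' @param x,y predictor and outcome blocks.
#' @param settings [penalty_settings()].
#' @return positive scalar.
#' @export
compute_lambda_max <- function(x, y, settings) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  st <- rational_start(x, y, settings)
  P <- st$P
  nrm <- sqrt(colSums(P^2))
  nrm[nrm == 0] <- 1
  Pn <- sweep(P, 2L, nrm, `/`)
  z <- build_concatenated_target(x, y, settings)
  # tiny inflation so that a coordinate sweep at exactly this value keeps
  # every weight at zero despite floating-point rounding
  2 * max(abs(crossprod(x$values, z$z %*% Pn))) * (1 + 1e-8)
}

#' Lasso path
#'
#' A strictly decreasing sequence from `lambda_max` down to
#' `1e-4 * lambda_max`, equally spaced on the log2 scale.
#'
#' @param lambda_max largest (first) value; must be positive.
#' @param grid_size number of values (>= 2).
#' @return numeric vector of class `lambda_path`.
#' @export
build_lambda_path <- function(lambda_max, grid_size = 50L) {
  if (!is.numeric(lambda_max) || lambda_max <= 0)
    stop("lambda_max must be positive")
  stopifnot(grid_size >= 2)
  structure(
    2^seq(log2(lambda_max), log2(lambda_max * 1e-4), length.out = grid_size),
    class = "lambda_path"
  )
}

#' Bound on the number of selected coefficients
#'
#' From the stability-selection error control: keeping the expected number of
#' falsely selected coefficients below `expected_false` at threshold
#' `pi_threshold` allows at most `sqrt(J (2 pi_thr - 1) E(V))` selections per
#' component, hence `R` times that for `r` components (floored to an
#' integer).
#'
#' @param j_vars number of candidate variables J.
#' @param r number of components.
#' @param pi_threshold selection-probability threshold (> 0.5).
#' @param expected_false E(V) >= 0.
#' @return integer bound q_R.
#' @export
q_bound <- function(j_vars, r, pi_threshold, expected_false) {
  if (pi_threshold <= 0.5)
    stop("pi_threshold must exceed 0.5 for the bound to be defined")
  stopifnot(expected_false >= 0)
  as.integer(floor(r * sqrt(j_vars * (2 * pi_threshold - 1) * expected_false)))
}

#' Stability selection for the lasso penalty
#'
#' Walks the lasso path from the fully sparse end.  A set of `n_resamples`
#' resamples (drawn with replacement, a fraction `resample_fraction` of the
#' rows) is fixed up front and reused at every lasso value.  At each value,
#' the full data are fitted to give a reference solution, then every
#' resample is fitted (warm-started from its fit at the previous value) and
#' its components permuted to maximal Tucker congruence with the reference
#' scores; a coefficient counts as selected in a resample once it has been
#' non-zero at any lasso value traversed so far.  The path is extended while
#' q_Lambda -- the average number of coefficients selected per resample over
#' the range so far, the quantity whose expectation the false-positive bound
#' controls -- does not exceed the bound q_R from [q_bound()] (or
#' `q_override`).  The stable set consists of the coefficients whose
#' selection probability over the traversed range reaches `pi_threshold`;
#' the final model re-estimates them without penalties
#' ([refit_fixed_support()]).
#'
#' @param x,y predictor and outcome blocks.
#' @param settings [penalty_settings()] (its `lambda1` is ignored; `lambda2`
#'   may be a number or the string fraction rule is applied by the caller).
#' @param stab [stability_settings()].
#' @param options [fit_options()] used for the reference fits; per-resample
#'   fits are warm-started from the reference at the same lasso value with no
#'   extra random starts.
#' @param lambda2_frac ridge penalty as a fraction of the current lasso value
#'   (default 0.05); ignored if `settings$lambda2 > 0`, in which case that
#'   fixed value is used throughout.
#' @return object of class `stability_result`: `pi_per_lambda` (list of
#'   Jx x R matrices), `pi_stable`, `stable_set`, `q_lambda`, `q_bound`,
#'   `lambdas_used`, `exhausted`, `reference_fits` (non-zero counts) and
#'   `final_model`.
#' @export
run_stability_selection <- function(x, y, settings, stab = stability_settings(),
                                    options = fit_options(), lambda2_frac = 0.05) {
  x <- as_block(x, "x"); y <- as_block(y, "y")
  I <- x$n_obs; Jx <- x$n_vars; R <- settings$n_components
  if (!is.null(stab$seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(stab$seed)
  }
  q_r <- if (!is.null(stab$q_override)) as.integer(stab$q_override)
         else q_bound(Jx, R, stab$pi_threshold, stab$expected_false)
  lambda_max <- compute_lambda_max(x, y, settings)
  path <- build_lambda_path(lambda_max, stab$grid_size)
  n_sub <- max(2L, round(stab$resample_fraction * I))

  # the resample index sets are drawn once and reused at every lasso value,
  # so that per-resample selections can be accumulated over the traversed
  # range: a coefficient counts as selected in a resample if it was non-zero
  # at any lasso value so far.  This union is the selection event whose
  # probability the expected-false-positive bound controls.
  resample_idx <- lapply(seq_len(stab$n_resamples), function(b) {
    sample.int(I, n_sub, replace = TRUE)
  })
  sel_union <- lapply(seq_len(stab$n_resamples), function(b) {
    matrix(FALSE, Jx, R)
  })

  pi_list <- list()
  lambdas_used <- numeric(0)
  q_lambda <- numeric(0)
  ref_nonzero <- integer(0)
  W_prev <- NULL
  exhausted <- TRUE

  fixed_l2 <- settings$lambda2 > 0
  for (li in seq_along(path)) {
    lam <- path[li]
    l2 <- if (fixed_l2) settings$lambda2 else lambda2_frac * lam
    set_l <- penalty_settings(
      alpha = settings$alpha, n_components = R, lambda1 = lam, lambda2 = l2,
      loading_constraint = settings$loading_constraint
    )
    ref <- fit_spcovr(x, y, set_l, options,
                      W_start = if (!is.null(W_prev)) list(W_prev) else NULL)
    W_prev <- ref$weights
    ref_scores <- ref$scores
    counts <- matrix(0, Jx, R)
    res_options <- fit_options(max_iter = options$max_iter, tol = options$tol,
                               n_random_starts = 0L)
    have_ref_scores <- any(ref_scores != 0)
    for (b in seq_len(stab$n_resamples)) {
      idx <- resample_idx[[b]]
      # the resampled data get the full analysis, including re-centring and
      # re-scaling, so the penalty acts on the same scale as the reference
      xb <- tryCatch(center_scale(x$values[idx, , drop = FALSE]),
                     error = function(e) NULL)
      yb <- tryCatch(center_scale(y$values[idx, , drop = FALSE],
                                  scale = y$scaling),
                     error = function(e) NULL)
      if (is.null(xb) || is.null(yb)) next  # constant column in resample
      zb <- build_concatenated_target(xb, yb, set_l)
      # warm start from the full-data reference at the current lasso value
      stb <- canonicalize_start(
        ref$weights,
        {P0 <- crossprod(zb$z, xb$values %*% ref$weights)
         if (all(P0 == 0)) ref$P_concat else P0},
        set_l$loading_constraint
      )
      fitb <- tryCatch(
        suppressWarnings(
          alternate_fit(xb$values, zb, stb$W, stb$P, set_l, res_options)
        ),
        error = function(e) NULL
      )
      if (is.null(fitb)) next
      Wb <- fitb$W
      if (have_ref_scores && any(Wb != 0)) {
        cand_scores <- xb$values %*% Wb
        al <- align_components(cand_scores, ref_scores[idx, , drop = FALSE])
        Wb <- apply_alignment(Wb, al)
      }
      counts <- counts + (Wb != 0)
      sel_union[[b]] <- sel_union[[b]] | (Wb != 0)
    }
    pi_list[[length(pi_list) + 1L]] <- counts / stab$n_resamples
    lambdas_used <- c(lambdas_used, lam)
    # q_Lambda: the average number of distinct coefficients selected per
    # resample over the range traversed so far
    q_running <- mean(vapply(sel_union, sum, numeric(1)))
    q_lambda <- c(q_lambda, q_running)
    ref_nonzero <- c(ref_nonzero, sum(ref$weights != 0))
    if (q_running > q_r) {
      exhausted <- FALSE
      break
    }
  }
  if (exhausted)
    warning("lasso path exhausted before the selection bound was reached")
  pi_stable <- Reduce(`+`, lapply(sel_union, function(m) m * 1)) /
    stab$n_resamples
  stable_set <- pi_stable >= stab$pi_threshold
  final_model <- if (any(stable_set)) {
    refit_fixed_support(x, y, stable_set, settings)
  } else {
    refit_fixed_support(x, y, matrix(FALSE, Jx, R), settings) |>
      suppressWarnings()
  }
  structure(
    list(
      pi_per_lambda = pi_list, pi_stable = pi_stable,
      stable_set = stable_set, q_lambda = q_lambda, q_bound = q_r,
      lambdas_used = lambdas_used, exhausted = exhausted,
      reference_nonzero = ref_nonzero, final_model = final_model,
      settings = settings, stab = stab
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> %d lasso values traversed; q_Lambda = %.1f, bound q_R = %d%s\n",
    length(x$lambdas_used), utils::tail(x$q_lambda, 1), x$q_bound,
    if (x$exhausted) " (path exhausted)" else ""
  ))
  cat(sprintf("  stable set: %d coefficients at pi >= %.2f\n",
              sum(x$stable_set), x$stab$pi_threshold))
  invisible(x)
}

#' Write a stability result to disk
#'
#' Writes one CSV row per coefficient (variable index, component, maximal
#' selection proportion, stable flag) plus a JSON summary of the traversed
#' range and counts.
#'
#' @param result a `stability_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_stability_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Jx <- nrow(result$pi_stable); R <- ncol(result$pi_stable)
  tab <- data.frame(
    variable = rep(seq_len(Jx), R),
    component = rep(seq_len(R), each = Jx),
    pi_stable = as.vector(result$pi_stable),
    selected = as.vector(result$stable_set)
  )
  csv_path <- file.path(dir, "stability_coefficients.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  summ <- list(
    lambdas_used = result$lambdas_used,
    q_lambda = result$q_lambda,
    q_bound = result$q_bound,
    n_stable = sum(result$stable_set),
    exhausted = result$exhausted,
    pi_threshold = result$stab$pi_threshold,
    expected_false = result$stab$expected_false,
    n_resamples = result$stab$n_resamples
  )
  json_path <- file.path(dir, "stability_summary.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
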