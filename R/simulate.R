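#' Simulation design for sparse covariates regression data
#'
#' Defines the factors of the benchmark design: a two-component sparse
#' weights model with controlled proportions of variance accounted for (VAF)
#' in the predictor block and in the outcome, a controlled split of the
#' predictor VAF over the two components, 80% sparsity in the true weights
#' and fixed regression weights `b = (1, -0.02)` so that the first component
#' drives the outcome.
#'
#' @param n_obs number of observations I (default 100).
#' @param n_vars number of predictor variables J (default 200).
#' @param n_components number of components R (default 2).
#' @param vaf_x total proportion of predictor variance accounted for by the
#'   components; benchmark levels 0.01, 0.40, 0.70.
#' @param vaf_y proportion of outcome variance accounted for; benchmark
#'   levels 0.02, 0.50, 0.80.
#' @param rel_strength share of the component variance carried by the first
#'   component (a scalar in (0, 1) for two components, or a vector of shares
#'   summing to one); benchmark levels 0.10, 0.50, 0.90.
#' @param sparsity fraction of true component weights set to zero (default
#'   0.80, i.e. 320 of the 400 weights at the default size).
#' @param b regression weights of the components on the outcome.
#' @param n_replicates default number of replicate datasets in study runs.
#' @param seed optional base seed.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_obs = 100L, n_vars = 200L, n_components = 2L,
                              vaf_x = 0.40, vaf_y = 0.50, rel_strength = 0.50,
                              sparsity = 0.80, b = c(1, -0.02),
                              n_replicates = 20L, seed = NULL) {
  if (length(rel_strength) == 1L) {
    stopifnot(n_components == 2L, rel_strength > 0, rel_strength < 1)
    rel_strength <- c(rel_strength, 1 - rel_strength)
  }
  stopifnot(
    vaf_x > 0, vaf_x < 1, vaf_y > 0, vaf_y < 1,
    abs(sum(rel_strength) - 1) < 1e-10,
    length(rel_strength) == n_components,
    length(b) == n_components,
    sparsity >= 0, sparsity < 1
  )
  structure(
    list(n_obs = as.integer(n_obs), n_vars = as.integer(n_vars),
         n_components = as.integer(n_components),
         vaf_x = vaf_x, vaf_y = vaf_y, rel_strength = rel_strength,
         sparsity = sparsity, b = b, n_replicates = as.integer(n_replicates),
         seed = seed),
    class = "simulation_design"
  )
}

rescale_to_strength <- function(W, xv, shares) {
  for (r in seq_len(ncol(W))) {
    t_r <- xv %*% W[, r]
    v <- stats::var(as.vector(t_r))
    if (v > 0) W[, r] <- W[, r] * sqrt(shares[r] / v)
  }
  W
}

#' Generate a dataset under the sparse covariates regression model
#'
#' Follows the benchmark recipe: (1) draw a standard-normal matrix, centre
#' and scale it, and take its first R right singular vectors as initial
#' weights; (2) set the designed fraction of randomly chosen weight entries
#' to zero; (3) rescale each weight column so the variances of the component
#' scores match the designed relative strengths; (4) form the initial outcome
#' from the fixed regression weights; (5) re-estimate weights and orthogonal
#' loadings with the zero pattern fixed, so that the data exactly satisfy a
#' sparse covariates regression model, and rescale the weights again;
#' (6) form the noise-free blocks `X_true = X0 W P^T` and
#' `y_true = X_true W b`; (7) add normal noise with one variance per block,
#' calibrated so that the signal fraction of the expected total sum of
#' squares equals the nominal VAF level.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed for this dataset.
#' @return object of class `spcovr_sim` with observed and noise-free blocks,
#'   the true weights/loadings/scores and the noise standard deviations
#'   (reused when generating matched test data).
#' @export
generate_dataset <- function(design, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
  }
  I <- design$n_obs; J <- design$n_vars; R <- design$n_components
  x0 <- center_scale(matrix(stats::rnorm(I * J), I, J))
  xv <- x0$values
  sv <- svd(xv, nu = 0, nv = R)
  W0 <- sv$v
  n_zero <- round(design$sparsity * J * R)
  repeat {
    zero_idx <- sample.int(J * R, n_zero)
    W <- W0
    W[zero_idx] <- 0
    if (all(colSums(W != 0) > 0)) break
  }
  W <- rescale_to_strength(W, xv, design$rel_strength)
  y0 <- xv %*% W %*% design$b

  # model-consistent refit: sparse weights with orthogonal predictor loadings
  refit <- refit_fixed_support(
    x0, new_scaled_block(y0), support = W != 0,
    settings = penalty_settings(alpha = 1, n_components = R,
                                loading_constraint = "orthogonal"),
    W_start = W
  )
  W <- rescale_to_strength(refit$weights, xv, design$rel_strength)
  P <- refit$loadings_x
  nrm <- sqrt(colSums(P^2))
  nrm[nrm == 0] <- 1
  P <- sweep(P, 2L, nrm, `/`)

  scores_build <- xv %*% W
  x_true <- scores_build %*% t(P)
  y_true <- x_true %*% W %*% matrix(design$b, ncol = 1L)

  ss_x <- sum(x_true^2)
  sd_x <- sqrt(ss_x * (1 - design$vaf_x) / (design$vaf_x * I * J))
  ss_y <- sum(y_true^2)
  sd_y <- sqrt(ss_y * (1 - design$vaf_y) / (design$vaf_y * I))
  x_obs <- x_true + matrix(stats::rnorm(I * J, sd = sd_x), I, J)
  y_obs <- y_true + stats::rnorm(I, sd = sd_y)

  structure(
    list(
      x_observed = x_obs, y_observed = y_obs,
      x_true = x_true, y_true = y_true,
      w_true = W, p_true = P,
      t_true = x_true %*% W, scores_build = scores_build,
      noise_sd = c(x = sd_x, y = sd_y),
      design = design, seed = seed
    ),
    class = "spcovr_sim"
  )
}

#' @export
print.spcovr_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "<spcovr_sim> I = %d, J = %d, R = %d; VAFX = %.2f, VAFY = %.2f, strengths = %s; %d zero weights\n",
    d$n_obs, d$n_vars, d$n_components, d$vaf_x, d$vaf_y,
    paste(d$rel_strength, collapse = "/"), sum(x$w_true == 0)
  ))
  invisible(x)
}

#' Generate matched test data for a simulated dataset
#'
#' Draws a fresh signal under the same model: new standard-normal base
#' matrix, the same true weights, loadings and regression weights, and fresh
#' noise at the same standard deviations as the training data.
#'
#' @param sim a `spcovr_sim` from [generate_dataset()].
#' @param seed integer seed.
#' @return a `spcovr_sim` sharing `w_true`, `p_true` and noise levels with
#'   `sim`.
#' @export
generate_test_set <- function(sim, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
  }
  d <- sim$design
  I <- d$n_obs; J <- d$n_vars
  x0 <- center_scale(matrix(stats::rnorm(I * J), I, J))
  scores_build <- x0$values %*% sim$w_true
  x_true <- scores_build %*% t(sim$p_true)
  y_true <- x_true %*% sim$w_true %*% matrix(d$b, ncol = 1L)
  x_obs <- x_true + matrix(stats::rnorm(I * J, sd = sim$noise_sd["x"]), I, J)
  y_obs <- y_true + stats::rnorm(I, sd = sim$noise_sd["y"])
  structure(
    list(
      x_observed = x_obs, y_observed = y_obs,
      x_true = x_true, y_true = y_true,
      w_true = sim$w_true, p_true = sim$p_true,
      t_true = x_true %*% sim$w_true, scores_build = scores_build,
      noise_sd = sim$noise_sd, design = d, seed = seed
    ),
    class = "spcovr_sim"
  )
}

#' Normalised prediction error sum of squares
#'
#' `sum((y - yhat)^2) / sum(y^2)`: the squared prediction error on held-out
#' data normalised by the total variation of the observed scores.  A value of
#' one corresponds to the null prediction; values above one indicate that the
#' model predicts worse than predicting zero.
#'
#' @param y_obs observed (centred) outcome values.
#' @param y_pred predicted values.
#' @return scalar PRESS.
#' @export
press <- function(y_obs, y_pred) {
  y_obs <- as.vector(y_obs); y_pred <- as.vector(y_pred)
  if (length(y_obs) != length(y_pred))
    stop("y_obs and y_pred must have the same length")
  denom <- sum(y_obs^2)
  if (denom == 0) stop("observed outcome has zero sum of squares")
  sum((y_obs - y_pred)^2) / denom
}

#' Built-in sparse PCovR method for study runs
#'
#' Returns a fitting function for [run_study()]: at the given `alpha`, the
#' lasso value is chosen by walking the path from the sparse end and keeping
#' the last value whose fitted non-zero count does not exceed
#' `nonzero_target` (the benchmark bound of 80 non-zero coefficients), the
#' ridge is tied to the lasso (`lambda2 = lambda2_frac * lambda1`), and the
#' selected support is re-estimated without penalties.
#'
#' @param alpha weighting parameter.
#' @param nonzero_target upper bound on the number of non-zero weights.
#' @param lambda2_frac ridge penalty as a fraction of the lasso value.
#' @param grid_size path resolution for the lasso search.
#' @param options [fit_options()] for the fits.
#' @return function of `(x, y)` returning a fitted `spcovr_fit`.
#' @export
spcovr_study_method <- function(alpha, nonzero_target = 80L,
                                lambda2_frac = 0.05, grid_size = 25L,
                                options = fit_options(n_random_starts = 1L)) {
  force(alpha)
  function(x, y) {
    x <- as_block(x, "x"); y <- as_block(y, "y")
    settings <- penalty_settings(alpha = alpha, n_components = 2L)
    lam_max <- compute_lambda_max(x, y, settings)
    path <- build_lambda_path(lam_max, grid_size)
    best <- NULL
    W_prev <- NULL
    for (lam in path) {
      set_l <- penalty_settings(alpha = alpha, n_components = 2L,
                                lambda1 = lam, lambda2 = lambda2_frac * lam)
      fit <- fit_spcovr(x, y, set_l, options,
                        W_start = if (!is.null(W_prev)) list(W_prev) else NULL)
      W_prev <- fit$weights
      nz <- sum(fit$weights != 0)
      if (nz > nonzero_target) break
      if (nz > 0) best <- fit
    }
    if (is.null(best)) return(NULL)
    refit_fixed_support(x, y, best$weights != 0, best$settings)
  }
}

#' Run a simulation study
#'
#' Generates replicate training and test datasets for each requested
#' condition, fits every method on the (re-scaled) training data, and records
#' the Tucker congruence between the recovered and true component scores
#' (after permutation/sign alignment) and the PRESS on the test outcome.
#'
#' @param conditions a list of [simulation_design()] objects (or a single
#'   one).
#' @param methods named list of fitting functions `(x, y) -> model`, e.g.
#'   from [spcovr_study_method()]; a `NULL` or error result is recorded as a
#'   failed fit.
#' @param n_replicates replicates per condition (default from each design).
#' @param seed base seed; replicate seeds are derived deterministically from
#'   it.
#' @return a tibble with one row per condition x method x replicate and
#'   columns `phi` (Tucker congruence) and `press`.
#' @export
run_study <- function(conditions, methods, n_replicates = NULL, seed = 1L) {
  if (inherits(conditions, "simulation_design")) conditions <- list(conditions)
  rows <- list()
  for (ci in seq_along(conditions)) {
    design <- conditions[[ci]]
    reps <- if (is.null(n_replicates)) design$n_replicates else n_replicates
    for (rep_i in seq_len(reps)) {
      # double arithmetic, reduced below 2^31, so large base seeds are safe
      seed_train <- as.integer((as.numeric(seed) * 10000 + ci * 100 + rep_i) %%
                                 2147483647)
      sim <- generate_dataset(design, seed = seed_train)
      test <- generate_test_set(sim, seed = (seed_train + 50L) %% 2147483647L)
      x_tr <- center_scale(sim$x_observed)
      y_tr <- center_scale(matrix(sim$y_observed, ncol = 1L))
      x_te <- center_scale(test$x_observed)
      y_te <- center_scale(matrix(test$y_observed, ncol = 1L))
      for (mi in seq_along(methods)) {
        fit <- tryCatch(methods[[mi]](x_tr, y_tr), error = function(e) NULL)
        ok <- !is.null(fit) && any(fit$weights != 0)
        phi <- NA_real_; prs <- NA_real_
        if (ok) {
          t_hat <- x_tr$values %*% fit$weights
          al <- align_components(t_hat, sim$t_true)
          phi <- tucker_congruence(sim$t_true, apply_alignment(t_hat, al))
          y_hat <- predict(fit, x_te)
          prs <- press(y_te$values, y_hat)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          condition = ci, vaf_x = design$vaf_x, vaf_y = design$vaf_y,
          rel_strength_1 = design$rel_strength[1L],
          method = names(methods)[mi], replicate = rep_i,
          converged = ok, phi = phi, press = prs
        )
      }
    }
  }
  do.call(rbind, rows)
}
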