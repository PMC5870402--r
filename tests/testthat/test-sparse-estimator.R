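test_that("each coordinate update matches a dense 1-D grid-search minimiser", {
  d <- random_blocks(i = 15L, jx = 5L, jy = 1L, seed = 41)
  s <- penalty_settings(alpha = 0.5, n_components = 2, lambda1 = 0.08,
                        lambda2 = 0.03)
  ct <- build_concatenated_target(d$x, d$y, s)
  set.seed(42)
  W <- matrix(rnorm(10, sd = 0.5), 5, 2)
  P <- crossprod(ct$z, d$x$values %*% W)
  P <- sweep(P, 2L, sqrt(colSums(P^2)), `/`)
  # run one sweep, then replay every single-coordinate update against the
  # brute-force minimiser using the exact state the sweep saw at that point
  upd <- update_weights(d$x, ct, P, W, s, n_sweeps = 1L)
  W_cur <- W
  for (r in 1:2) {
    for (j in 1:5) {
      w_oracle <- grid_search_coordinate(d$x$values, ct$z, P, W_cur, j, r,
                                         s$lambda1, s$lambda2)
      expect_lt(abs(upd$W[j, r] - w_oracle), 1.01e-4)
      W_cur[j, r] <- upd$W[j, r]
    }
  }
})

test_that("a large enough lasso keeps all weights at zero", {
  d <- random_blocks(i = 20L, jx = 8L, jy = 1L, seed = 43)
  s0 <- penalty_settings(alpha = 0.5, n_components = 2)
  lam_max <- compute_lambda_max(d$x, d$y, s0)
  ct <- build_concatenated_target(d$x, d$y, s0)
  st <- spcovr:::rational_start(d$x, d$y, s0)
  s_big <- penalty_settings(0.5, 2, lambda1 = lam_max, lambda2 = 0)
  upd <- update_weights(d$x, ct, st$P, matrix(0, 8, 2), s_big)
  expect_true(all(upd$W == 0))
  # just below the threshold at least one weight activates
  s_below <- penalty_settings(0.5, 2, lambda1 = 0.99 * lam_max, lambda2 = 0)
  upd2 <- update_weights(d$x, ct, st$P, matrix(0, 8, 2), s_below)
  expect_gt(sum(upd2$W != 0), 0)
})

test_that("single-predictor unpenalised update is the least-squares coefficient", {
  set.seed(44)
  x <- center_scale(matrix(rnorm(20), 20, 1))
  y <- center_scale(matrix(rnorm(20)))
  # alpha = 1: target is the x block itself, P = (0, 1) after normalisation
  s <- penalty_settings(alpha = 1, n_components = 1)
  ct <- build_concatenated_target(x, y, s)
  P <- matrix(c(0, 1), 2, 1)
  upd <- update_weights(x, ct, P, matrix(0, 1, 1), s)
  ols <- sum(ct$z[, 2] * x$values[, 1]) / sum(x$values[, 1]^2)
  expect_equal(upd$W[1, 1], ols, tolerance = 1e-12)
})

test_that("orthogonal loading update recovers a planted Procrustes solution", {
  set.seed(45)
  Tm <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  P0 <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  z <- list(z = Tm %*% t(P0))
  P_hat <- update_loadings(Tm, z, P = P0 * 0, mode = "orthogonal")
  expect_lt(max(abs(P_hat - P0)), 1e-10)
})

test_that("orthogonal loading update beats 1000 random orthonormal candidates", {
  set.seed(46)
  Tm <- matrix(rnorm(15 * 2), 15, 2)
  Z <- matrix(rnorm(15 * 6), 15, 6)
  z <- list(z = Z)
  P_hat <- update_loadings(Tm, z, P = matrix(0, 6, 2), mode = "orthogonal")
  obj <- function(P) sum(diag(crossprod(Z %*% P, Tm)))  # tr(P^T Z^T T)
  best <- obj(P_hat)
  for (k in 1:1000) {
    P_rand <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
    expect_lte(obj(P_rand), best + 1e-10)
  }
})

test_that("eigen and svd paths of the orthogonal update agree", {
  for (seed in 47:49) {
    set.seed(seed)
    Tm <- matrix(rnorm(12 * 3), 12, 3)
    z <- list(z = matrix(rnorm(12 * 9), 12, 9))
    P_svd <- update_loadings(Tm, z, P = matrix(0, 9, 3), mode = "orthogonal",
                             method = "svd")
    P_eig <- update_loadings(Tm, z, P = matrix(0, 9, 3), mode = "orthogonal",
                             method = "eigen")
    expect_lt(max(abs(P_svd - P_eig)), 1e-10)
  }
})

test_that("unit-length loading update yields unit columns and lowers the loss", {
  d <- random_blocks(i = 20L, jx = 8L, jy = 2L, seed = 50)
  s <- penalty_settings(0.5, 2)
  ct <- build_concatenated_target(d$x, d$y, s)
  st <- spcovr:::rational_start(d$x, d$y, s)
  set.seed(51)
  P_perturbed <- st$P + matrix(rnorm(20, sd = 0.2), 10, 2)
  Tm <- d$x$values %*% st$W
  before <- sum((ct$z - Tm %*% t(P_perturbed))^2)
  P_new <- update_loadings(Tm, ct, P_perturbed, mode = "unit_length")
  expect_lt(max(abs(colSums(P_new^2) - 1)), 1e-8)
  expect_lte(sum((ct$z - Tm %*% t(P_new))^2), before + 1e-10)
})

test_that("unpenalised alternating fit matches the closed form", {
  for (mode in c("unit_length", "orthogonal")) {
    d <- random_blocks(i = 25L, jx = 10L, jy = 2L, seed = 52)
    s <- penalty_settings(0.5, 2, loading_constraint = mode)
    exact <- attr(solve_pcovr(d$x, d$y, s), "loss")
    fit <- fit_spcovr(d$x, d$y, s, fit_options(seed = 53, n_random_starts = 2))
    expect_equal(fit$summary$loss_unpenalized, exact, tolerance = 1e-6)
  }
})

test_that("alpha = 0 with one component matches an independent elastic net", {
  skip_if_not_installed("glmnet")
  d <- random_blocks(i = 30L, jx = 10L, jy = 1L, seed = 54)
  lambda1 <- 0.02; lambda2 <- 0.01
  s <- penalty_settings(alpha = 0, n_components = 1,
                        lambda1 = lambda1, lambda2 = lambda2)
  fit <- fit_spcovr(d$x, d$y, s,
                    fit_options(seed = 55, n_random_starts = 3, tol = 1e-12,
                                max_iter = 5000))
  # with alpha = 0 the concatenated loading reduces to a sign; the identified
  # quantity is W times that sign
  p_sign <- sign(fit$P_concat[1, 1])
  w_ours <- as.vector(fit$weights) * p_sign
  ct <- build_concatenated_target(d$x, d$y, s)
  ytil <- ct$z[, 1]
  n <- length(ytil)
  # glmnet standardises the response internally, which multiplies the
  # effective ridge (but not the lasso) by 1/sd(y); compensate so its
  # objective is RSS + lambda1 |b|_1 + lambda2 |b|_2^2 exactly
  sy <- sqrt(sum(ytil^2) / n)
  a_g <- lambda1 / (lambda1 + 2 * lambda2 * sy)
  lam_g <- (lambda1 + 2 * lambda2 * sy) / (2 * n)
  g <- glmnet::glmnet(d$x$values, ytil, alpha = a_g, lambda = lam_g,
                      standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  w_glmnet <- as.vector(g$beta)
  expect_lt(max(abs(w_ours - w_glmnet)), 1e-6)
  expect_equal(which(w_ours != 0), which(w_glmnet != 0))
})

test_that("alpha = 1 matches a self-written sparse-PCA alternating oracle", {
  d <- random_blocks(i = 20L, jx = 10L, jy = 1L, seed = 56)
  lambda1 <- 0.05; lambda2 <- 0.02
  s <- penalty_settings(alpha = 1, n_components = 2,
                        lambda1 = lambda1, lambda2 = lambda2)
  fit <- fit_spcovr(d$x, d$y, s,
                    fit_options(seed = 57, n_random_starts = 3, tol = 1e-12,
                                max_iter = 5000))

  # the oracle is run from the rational start and from the fitted solution;
  # the best of the two guards against either side stalling in a worse
  # local optimum
  xv <- d$x$values
  st <- spcovr:::rational_start(d$x, d$y, s)
  loss_rational <- sparse_pca_oracle(xv, lambda1, lambda2,
                                     st$W, st$P[-1, , drop = FALSE])
  loss_fitted <- sparse_pca_oracle(xv, lambda1, lambda2, fit$weights,
                                   fit$P_concat[-1, , drop = FALSE])
  expect_equal(fit$summary$loss_penalized, min(loss_rational, loss_fitted),
               tolerance = 1e-6)
})

test_that("penalised loss never increases across conditional steps", {
  for (seed in 1:100) {
    set.seed(seed)
    i <- 15L + seed %% 10L
    d <- random_blocks(i = i, jx = 6L, jy = 1L, seed = seed + 1000)
    s <- penalty_settings(
      alpha = c(0.1, 0.5, 0.9, 0.99)[1 + seed %% 4],
      n_components = 1L + seed %% 2,
      lambda1 = 0.1 * (seed %% 5) / 4,
      lambda2 = 0.05 * (seed %% 3) / 2,
      loading_constraint = if (seed %% 2 == 0) "unit_length" else "orthogonal"
    )
    fit <- suppressWarnings(
      fit_spcovr(d$x, d$y, s, fit_options(seed = seed, n_random_starts = 1))
    )
    expect_monotone_decreasing(fit$convergence)
  }
})

test_that("fits are deterministic given the seed", {
  d <- random_blocks(i = 25L, jx = 10L, jy = 1L, seed = 60)
  s <- penalty_settings(0.5, 2, lambda1 = 0.05, lambda2 = 0.01)
  f1 <- fit_spcovr(d$x, d$y, s, fit_options(seed = 61))
  f2 <- fit_spcovr(d$x, d$y, s, fit_options(seed = 61))
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  expect_identical(f1$convergence, f2$convergence)
})

test_that("converged loss is robust to the coordinate sweep order", {
  d <- random_blocks(i = 25L, jx = 8L, jy = 1L, seed = 62)
  s <- penalty_settings(0.5, 2, lambda1 = 0.04, lambda2 = 0.01)
  ct <- build_concatenated_target(d$x, d$y, s)
  st <- spcovr:::rational_start(d$x, d$y, s)
  run_order <- function(ord) {
    W <- st$W; P <- st$P
    for (k in 1:400) {
      upd <- update_weights(d$x, ct, P, W, s, n_sweeps = 1L, coord_order = ord)
      W <- upd$W
      P <- update_loadings(upd$T, ct, P, mode = "unit_length")
    }
    spcovr:::penalized_concat_loss(ct$z, d$x$values, W, P, s$lambda1, s$lambda2)
  }
  expect_lt(abs(run_order(1:8) - run_order(8:1)), 1e-4)
})

test_that("fixed-support refit behaves at the boundaries and debiases", {
  d <- random_blocks(i = 25L, jx = 10L, jy = 1L, seed = 63)
  s <- penalty_settings(0.5, 2)
  # all-true support equals the unpenalised fit
  full <- refit_fixed_support(d$x, d$y, matrix(TRUE, 10, 2), s,
                              options = fit_options(tol = 1e-10,
                                                    max_iter = 2000,
                                                    n_random_starts = 0))
  exact <- attr(solve_pcovr(d$x, d$y, s), "loss")
  expect_equal(full$summary$loss_unpenalized, exact, tolerance = 1e-6)
  # empty support: all-zero model, loss 1
  expect_warning(
    empty <- refit_fixed_support(d$x, d$y, matrix(FALSE, 10, 2), s),
    "empty support"
  )
  expect_true(all(empty$weights == 0))
  expect_equal(empty$summary$loss_unpenalized, 1)
  # debiasing never worsens the data-fit term on the same support
  sp <- penalty_settings(0.5, 2, lambda1 = 0.08, lambda2 = 0.01)
  pen_fit <- fit_spcovr(d$x, d$y, sp, fit_options(seed = 64))
  support <- pen_fit$weights != 0
  skip_if(!any(support))
  deb <- refit_fixed_support(d$x, d$y, support, sp)
  pen_unpen_loss <- evaluate_fit(pen_fit, d$x, d$y,
                                 penalty_settings(0.5, 2))$loss_unpenalized
  expect_lte(deb$summary$loss_unpenalized, pen_unpen_loss + 1e-10)
})

test_that("noise-free sparse two-component weights are recovered in range", {
  # noise-free fixed-point model: X = T Px^T with X W = T exactly, so the
  # sparse pattern of W (which columns feed which component) is a
  # well-defined estimand; every column carries signal so scaling is defined
  set.seed(65)
  per <- 5L; j <- 10L; i <- 50L
  W_true <- matrix(0, j, 2)
  W_true[1:per, 1] <- sample(c(-1, 1), per, TRUE) * runif(per, 0.8, 1.2)
  W_true[per + (1:per), 2] <- sample(c(-1, 1), per, TRUE) * runif(per, 0.8, 1.2)
  Px <- W_true %*% solve(crossprod(W_true))
  Tm <- matrix(rnorm(i * 2), i, 2)
  x <- center_scale(Tm %*% t(Px))
  y <- center_scale(matrix(Tm %*% c(1, -0.02)))
  pl <- list(W = W_true)
  s0 <- penalty_settings(alpha = 0.99, n_components = 2)
  lam_max <- compute_lambda_max(x, y, s0)
  recovered <- FALSE
  for (lam in build_lambda_path(lam_max, 25)) {
    s <- penalty_settings(0.99, 2, lambda1 = lam, lambda2 = 0.05 * lam)
    fit <- suppressWarnings(
      fit_spcovr(x, y, s, fit_options(seed = 66, n_random_starts = 2))
    )
    al <- align_components(x$values %*% fit$weights, x$values %*% pl$W)
    w_al <- spcovr:::apply_alignment(fit$weights, al)
    if (identical(unname(w_al != 0), unname(pl$W != 0))) {
      recovered <- TRUE
      break
    }
  }
  expect_true(recovered)
})
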