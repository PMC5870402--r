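test_that("lambda_max zeroes every weight and is tight", {
  for (seed in 71:73) {
    d <- random_blocks(i = 25L, jx = 10L, jy = 1L, seed = seed)
    s0 <- penalty_settings(alpha = 0.5, n_components = 2)
    lam_max <- compute_lambda_max(d$x, d$y, s0)
    ct <- build_concatenated_target(d$x, d$y, s0)
    st <- spcovr:::rational_start(d$x, d$y, s0)
    at_max <- update_weights(d$x, ct, st$P, matrix(0, 10, 2),
                             penalty_settings(0.5, 2, lambda1 = lam_max))
    expect_true(all(at_max$W == 0))
    below <- update_weights(d$x, ct, st$P, matrix(0, 10, 2),
                            penalty_settings(0.5, 2, lambda1 = 0.99 * lam_max))
    expect_gt(sum(below$W != 0), 0)
  }
})

test_that("lambda_max on an orthonormal single-outcome design has closed form", {
  # alpha = 0, R = 1: the target is w1 * y and the loading column is the unit
  # scalar, so the update covariance is x_j' (w1 y) and
  # lambda_max = 2 max_j |x_j' y| * w1
  set.seed(74)
  q <- qr.Q(qr(matrix(rnorm(10 * 4), 10, 4)))
  x <- new_scaled_block(q)   # orthonormal columns: SS 1, but not centred
  yv <- rnorm(10)
  y <- center_scale(matrix(yv))
  s <- penalty_settings(alpha = 0, n_components = 1)
  lam_max <- compute_lambda_max(x, y, s)
  w1 <- 1 / sqrt(sum(y$values^2))
  expect_equal(lam_max, 2 * w1 * max(abs(crossprod(q, y$values))),
               tolerance = 1e-7)
})

test_that("the lasso path is log2-spaced over four decades", {
  p <- build_lambda_path(16, 3)
  expect_equal(log2(p), c(4, log2(16 * 1e-2), log2(16 * 1e-4)),
               tolerance = 1e-10)
  p2 <- build_lambda_path(7.3, 50)
  expect_true(all(diff(p2) < 0))
  expect_equal(p2[1], 7.3)
  expect_equal(p2[50] / p2[1], 1e-4, tolerance = 1e-10)
  gaps <- diff(log2(p2))
  expect_lt(max(abs(gaps - gaps[1])), 1e-10)
  expect_equal(build_lambda_path(5, 2), structure(c(5, 5e-4), class = "lambda_path"))
  expect_error(build_lambda_path(-1, 10), "positive")
})

test_that("the selection bound follows the expected-false-positive formula", {
  expect_equal(q_bound(200, 2, 0.9, 0), 0L)
  expect_equal(q_bound(200, 2, 0.9, 1), 25L)
  expect_equal(q_bound(200, 2, 0.9, 1), as.integer(floor(2 * sqrt(160))))
  # genome-scale setting: floor(2 sqrt(54675 * 0.8)) = 418
  expect_equal(q_bound(54675, 2, 0.9, 1), 418L)
  expect_error(q_bound(200, 2, 0.5, 1), "exceed 0.5")
})

test_that("component alignment recovers permutations and signs", {
  set.seed(75)
  ref <- matrix(rnorm(30 * 3), 30, 3)
  id <- align_components(ref, ref)
  expect_equal(id$perm, 1:3)
  expect_equal(id$signs, rep(1, 3))
  cand <- ref[, c(2, 3, 1)]
  cand[, 2] <- -cand[, 2]
  al <- align_components(cand, ref)
  # reference column 1 lives in candidate column 3, etc.
  expect_equal(al$perm, c(3, 1, 2))
  expect_equal(al$signs, c(1, 1, -1))
  expect_equal(al$congruence, rep(1, 3), tolerance = 1e-12)
  expect_lt(max(abs(spcovr:::apply_alignment(cand, al) - ref)), 1e-12)
})

test_that("alignment matches an exhaustive permutation-and-sign search", {
  for (seed in 76:78) {
    set.seed(seed)
    ref <- matrix(rnorm(20 * 2), 20, 2)
    cand <- matrix(rnorm(20 * 2), 20, 2)
    al <- align_components(cand, ref)
    cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    best <- -Inf
    for (p in list(1:2, 2:1)) {
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
        obj <- cosine(s1 * cand[, p[1]], ref[, 1]) +
          cosine(s2 * cand[, p[2]], ref[, 2])
        best <- max(best, obj)
      }
    }
    expect_equal(al$objective, best, tolerance = 1e-12)
  }
})

test_that("tucker congruence is a vectorised cosine with guarded errors", {
  set.seed(79)
  A <- matrix(rnorm(40), 20, 2)
  expect_equal(tucker_congruence(A, A), 1)
  expect_equal(tucker_congruence(A, -2 * A), -1)
  B <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  C <- cbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(tucker_congruence(B, C), 0)
  expect_error(tucker_congruence(A, A * 0), "zero matrix")
  expect_error(tucker_congruence(A, matrix(0, 3, 2)), "same shape")
  expect_equal(TUCKER_EQUAL, 0.95)
  expect_equal(TUCKER_FAIR, 0.85)
})

test_that("stability selection respects its structural invariants", {
  pl <- plant_fixed_point(i = 40L, j = 30L, per_comp = 4L, seed = 80)
  s <- penalty_settings(alpha = 0.99, n_components = 2)
  stab <- stability_settings(n_resamples = 20L, q_override = 20L,
                             grid_size = 15L, seed = 81)
  res <- suppressWarnings(run_stability_selection(
    pl$x, pl$y, s, stab, fit_options(n_random_starts = 0L, seed = 81)
  ))
  for (p in res$pi_per_lambda) {
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(res$pi_stable >= p))
  }
  expect_true(all(diff(res$q_lambda) >= 0))
  expect_equal(length(res$lambdas_used), length(res$pi_per_lambda))
  # stopping rule: the override bound was used, not the E(V) formula
  expect_equal(res$q_bound, 20L)
  # the range-wide selection probability dominates every per-lambda one,
  # and a coefficient selected in every resample at some lambda has
  # pi_stable 1
  per_lambda_max <- Reduce(pmax, res$pi_per_lambda)
  expect_true(all(res$pi_stable >= per_lambda_max - 1e-12))
  if (any(per_lambda_max == 1)) {
    expect_true(all(res$pi_stable[per_lambda_max == 1] == 1))
  }
  expect_s3_class(res$final_model, "spcovr_fit")
})

test_that("stability selection is reproducible given its seed", {
  pl <- plant_fixed_point(i = 30L, j = 20L, per_comp = 3L, seed = 82)
  s <- penalty_settings(alpha = 0.99, n_components = 2)
  stab <- stability_settings(n_resamples = 10L, q_override = 12L,
                             grid_size = 10L, seed = 83)
  r1 <- suppressWarnings(run_stability_selection(
    pl$x, pl$y, s, stab, fit_options(n_random_starts = 0L, seed = 83)))
  r2 <- suppressWarnings(run_stability_selection(
    pl$x, pl$y, s, stab, fit_options(n_random_starts = 0L, seed = 83)))
  expect_identical(r1$pi_stable, r2$pi_stable)
  expect_identical(r1$lambdas_used, r2$lambdas_used)
})

test_that("true-support coefficients rank above off-support ones", {
  pl <- plant_fixed_point(i = 60L, j = 40L, per_comp = 4L, vaf_x = 0.8,
                          seed = 84)
  s <- penalty_settings(alpha = 0.99, n_components = 2)
  stab <- stability_settings(n_resamples = 30L, q_override = 24L,
                             grid_size = 20L, seed = 85)
  # ridge at the lasso level: the within-component columns are strongly
  # correlated and must be grouped for per-coefficient selection to settle
  res <- suppressWarnings(run_stability_selection(
    pl$x, pl$y, s, stab, fit_options(n_random_starts = 0L, seed = 85),
    lambda2_frac = 1))
  al <- align_components(pl$x$values %*% pl$W,
                         pl$x$values %*% res$final_model$weights)
  wt <- pl$W[, al$perm]
  true_pi <- res$pi_stable[wt != 0]
  false_pi <- res$pi_stable[wt == 0]
  # screening: every true coefficient outranks all but at most E(V)=1 of the
  # off-support ones
  violations <- sum(false_pi >= min(true_pi))
  expect_lte(violations, 1)
})
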