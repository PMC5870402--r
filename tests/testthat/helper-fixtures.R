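# Shared fixture builders; everything is generated in code under fixed seeds.

random_blocks <- function(i = 30L, jx = 10L, jy = 1L, seed = 1L) {
  set.seed(seed)
  list(
    x = center_scale(matrix(rnorm(i * jx), i, jx)),
    y = center_scale(matrix(rnorm(i * jy), i, jy))
  )
}

# Noise-free rank-R data exactly satisfying the component model:
# X = T Px^T, Y = T Py^T with T = X W for the returned W.
planted_blocks <- function(i = 40L, jx = 12L, jy = 1L, r = 2L, seed = 2L) {
  set.seed(seed)
  base <- center_scale(matrix(rnorm(i * jx), i, jx))
  s <- penalty_settings(alpha = 0.5, n_components = r)
  m <- solve_pcovr(base, center_scale(matrix(rnorm(i * jy), i, jy)), s)
  Tm <- m$scores
  Px <- matrix(rnorm(jx * r), jx, r)
  Px <- qr.Q(qr(Px))
  Py <- matrix(rnorm(jy * r), jy, r)
  x_raw <- Tm %*% t(Px)
  y_raw <- Tm %*% t(Py)
  x <- center_scale(x_raw)
  y <- center_scale(y_raw)
  list(x = x, y = y, r = r)
}

# Independent dense grid-search minimiser of the univariate elastic-net
# problem: min_w sum((resid - a * w)^2) + k + lambda1 |w| + lambda2 w^2,
# where a = outer(x_j, p_r) is the rank-one direction.
grid_search_coordinate <- function(xv, z, P, W, j, r, lambda1, lambda2,
                                   grid = seq(-3, 3, by = 1e-4)) {
  a <- outer(xv[, j], P[, r])
  W0 <- W
  W0[j, r] <- 0
  resid <- z - xv %*% W0 %*% t(P)
  others <- sum(abs(W0)) ; others2 <- sum(W0^2)
  loss <- vapply(grid, function(w) {
    sum((resid - a * w)^2) + lambda1 * (others + abs(w)) +
      lambda2 * (others2 + w^2)
  }, numeric(1))
  grid[which.min(loss)]
}

# Synthetic planted instance that is an exact fixed point of the component
# model: loadings Px = W (W^T W)^{-1} give X_signal W = T exactly, so the
# sparse weight pattern is a well-defined estimand.  Supports of the two
# components are disjoint; off-support columns are pure noise.
plant_fixed_point <- function(i = 100L, j = 200L, per_comp = 8L,
                              vaf_x = 0.7, vaf_y = 0.8, b = c(1, -0.02),
                              seed = 1L) {
  set.seed(seed)
  W <- matrix(0, j, 2)
  W[1:per_comp, 1] <- sample(c(-1, 1), per_comp, TRUE) * runif(per_comp, 0.8, 1.2)
  W[per_comp + (1:per_comp), 2] <- sample(c(-1, 1), per_comp, TRUE) *
    runif(per_comp, 0.8, 1.2)
  Px <- W %*% solve(crossprod(W))
  Tm <- matrix(rnorm(i * 2), i, 2)
  Xs <- Tm %*% t(Px)
  ss_x <- sum(Xs^2)
  X <- Xs + matrix(rnorm(i * j, sd = sqrt(ss_x * (1 - vaf_x) / (vaf_x * i * j))), i, j)
  ys <- Tm %*% b
  yv <- ys + rnorm(i, sd = sqrt(sum(ys^2) * (1 - vaf_y) / (vaf_y * i)))
  list(x = center_scale(X), y = center_scale(matrix(yv)),
       x_signal = Xs, W = W, T = Tm)
}

# Independent, naive sparse-PCA alternating solver used as the oracle for
# the alpha = 1 case: criterion ||X||^-2 ||X - X W P^T||^2 + penalties with
# unit-length loadings; coordinate updates recompute the residual from
# scratch at every step.  Returns the converged penalised loss from the
# given start.
sparse_pca_oracle <- function(xv, lambda1, lambda2, W, P,
                              max_iter = 4000L) {
  R <- ncol(W); J <- ncol(xv)
  Zt <- xv / sqrt(sum(xv^2))
  pen_loss <- function(W, P) {
    sum((Zt - xv %*% W %*% t(P))^2) + lambda1 * sum(abs(W)) +
      lambda2 * sum(W^2)
  }
  for (it in seq_len(max_iter)) {
    old <- pen_loss(W, P)
    for (r in seq_len(R)) for (j in seq_len(J)) {
      W0 <- W; W0[j, r] <- 0
      a <- outer(xv[, j], P[, r])
      sxy <- sum((Zt - xv %*% W0 %*% t(P)) * a)
      W[j, r] <- sign(sxy) * max(abs(sxy) - lambda1 / 2, 0) /
        (lambda2 + sum(a^2))
    }
    Tm <- xv %*% W
    ZtT <- crossprod(Zt, Tm); TtT <- crossprod(Tm)
    for (cyc in 1:10) for (r in seq_len(R)) {
      q <- ZtT[, r] - P %*% TtT[, r] + P[, r] * TtT[r, r]
      if (sum(q^2) > 0) P[, r] <- q / sqrt(sum(q^2))
    }
    if (abs(old - pen_loss(W, P)) < 1e-13 * max(old, 1)) break
  }
  pen_loss(W, P)
}

expect_monotone_decreasing <- function(log, tol = 1e-8) {
  expect_true(all(diff(log) <= tol))
}
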