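#' Tucker congruence between component score matrices
#'
#' The cosine of the angle between the vectorised matrices:
#' \deqn{\phi = vec(T)^T vec(\hat T) / \sqrt{(vec(T)^T vec(T)) (vec(\hat T)^T vec(\hat T))}.}
#' Values of 0.95 and above indicate components that can be considered equal;
#' 0.85 to 0.94 indicates fair similarity (constants `TUCKER_EQUAL` and
#' `TUCKER_FAIR`).  Callers should permute and sign-match
#' the columns first (see [align_components()]); congruence is sensitive to
#' both.
#'
#' @param t_true,t_est matrices of the same shape.
#' @return scalar congruence in \[-1, 1\].
#' @export
tucker_congruence <- function(t_true, t_est) {
  t_true <- as.matrix(t_true); t_est <- as.matrix(t_est)
  if (!all(dim(t_true) == dim(t_est)))
    stop("score matrices must have the same shape")
  n1 <- sum(t_true^2); n2 <- sum(t_est^2)
  if (n1 == 0 || n2 == 0) stop("zero matrix passed to tucker_congruence")
  sum(t_true * t_est) / sqrt(n1 * n2)
}

#' Interpretation bands for Tucker congruence
#'
#' `TUCKER_EQUAL` (0.95): components at or above this congruence are
#' considered equal. `TUCKER_FAIR` (0.85): lower edge of the fair-similarity
#' band.
#' @export
TUCKER_EQUAL <- 0.95

#' @rdname TUCKER_EQUAL
#' @export
TUCKER_FAIR <- 0.85

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) {
      q <- integer(n)
      q[1L] <- i
      q[-1L] <- setdiff(seq_len(n), i)[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Match candidate components to a reference
#'
#' Components are identified only up to permutation and sign; before
#' comparing solutions (across resamples in stability selection, or against
#' simulation truth) the candidate columns must be permuted and sign-flipped
#' to maximal agreement with a reference, measured by the summed absolute
#' per-column Tucker congruence of the scores.  For up to 6 components the
#' search over permutations is exhaustive; above that a greedy best-pair
#' matching is used.
#'
#' @param candidate_scores,reference_scores score matrices with the same
#'   number of rows and columns.
#' @return list with `perm` (candidate column for each reference position),
#'   `signs` (+1/-1 per reference position), `congruence` (per matched pair,
#'   signed, after flipping) and `objective` (the summed absolute
#'   congruence).
#' @export
align_components <- function(candidate_scores, reference_scores) {
  cand <- as.matrix(candidate_scores); ref <- as.matrix(reference_scores)
  if (nrow(cand) != nrow(ref) || ncol(cand) != ncol(ref))
    stop("candidate and reference score matrices must have the same shape")
  R <- ncol(ref)
  # C[k, r]: cosine between candidate column k and reference column r
  C <- matrix(0, R, R)
  for (k in seq_len(R)) {
    nk <- sqrt(sum(cand[, k]^2))
    for (r in seq_len(R)) {
      nr <- sqrt(sum(ref[, r]^2))
      C[k, r] <- if (nk == 0 || nr == 0) 0 else
        sum(cand[, k] * ref[, r]) / (nk * nr)
    }
  }
  if (R <= 6L) {
    best <- NULL; best_obj <- -Inf
    for (p in all_permutations(R)) {
      obj <- sum(abs(C[cbind(p, seq_len(R))]))
      if (obj > best_obj) {
        best_obj <- obj
        best <- p
      }
    }
    perm <- best
  } else {
    perm <- integer(R)
    avail <- seq_len(R)
    A <- abs(C)
    for (step in seq_len(R)) {
      idx <- which(A[avail, , drop = FALSE] == max(A[avail, , drop = FALSE]),
                   arr.ind = TRUE)[1L, ]
      k <- avail[idx[1L]]; r <- idx[2L]
      perm[r] <- k
      avail <- setdiff(avail, k)
      A[, r] <- -Inf
    }
  }
  cong <- C[cbind(perm, seq_len(R))]
  signs <- ifelse(cong >= 0, 1, -1)
  list(perm = perm, signs = signs, congruence = cong * signs,
       objective = sum(abs(cong)))
}

# Apply an alignment to the columns of a matrix (scores or weights)
apply_alignment <- function(m, alignment) {
  m <- as.matrix(m)
  sweep(m[, alignment$perm, drop = FALSE], 2L, alignment$signs, `*`)
}
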