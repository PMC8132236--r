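#' Class-conditional group feature means
#'
#' For every group k and outcome class y in {0,1}, the mean feature vector
#' over the subgroup S_ky = {i : y_ki = y}, prepended with a 1 for the
#' intercept. These means define the fairness penalty: it shrinks the gap
#' between the groups' average linear predictors within each outcome class,
#' which bounds the gap in false positive / false negative rates through
#' the 1/4-Lipschitz property of the sigmoid.
#'
#' @param data a `grouped_data` object.
#' @return object of class `group_means`: list with `xbar` (a K-list of
#'   2-lists of length-(p+1) vectors, `xbar[[k]][[y+1]]`), `counts`
#'   (K x 2 matrix of subgroup sizes), `p`, `K`, `labels`.
#' @export
group_means <- function(data) {
  stopifnot(inherits(data, "grouped_data"))
  xbar <- vector("list", data$K)
  counts <- matrix(0L, data$K, 2, dimnames = list(data$labels, c("y0", "y1")))
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    xbar[[k]] <- vector("list", 2)
    for (y in 0:1) {
      idx <- which(g$y == y)
      if (length(idx) == 0L)
        stop(sprintf("group %s lacks outcome class %d", g$label, y))
      xbar[[k]][[y + 1]] <- c(1, colMeans(g$X[idx, , drop = FALSE]))
      counts[k, y + 1] <- length(idx)
    }
  }
  structure(list(xbar = xbar, counts = counts, p = data$p, K = data$K,
                 labels = data$labels),
            class = "group_means")
}

all_pairs <- function(K) {
  # pair order (j, k): j < k, enumerated as sum_{k=2}^{K} sum_{j=1}^{k-1}
  out <- list()
  for (k in 2:K) for (j in seq_len(k - 1)) out[[length(out) + 1L]] <- c(j, k)
  out
}

#' Stacked penalty operator for the fairness and similarity penalties
#'
#' Builds the sparse linear map D such that the sum of the fairness and
#' fused-lasso similarity penalties equals ||D b||_1 for the stacked,
#' intercept-augmented coefficient vector b. Rows are, in order: fairness
#' rows for outcome class 0 (one per group pair j < k), fairness rows for
#' class 1, then p similarity rows per pair. All pairs j < k are
#' enumerated, so the operator matches the penalty sums exactly for any K.
#' Fairness rows carry the class-conditional means (including the
#' intercept coordinate); similarity rows are +1/-1 contrasts on matching
#' slope coordinates and are zero on every intercept coordinate.
#'
#' @param means a `group_means` object.
#' @param lambda_f nonnegative fairness penalty weight (scales fairness rows).
#' @param lambda_sim nonnegative similarity penalty weight (scales
#'   similarity rows).
#' @param sparse store D as a sparse `Matrix`; by default dense storage is
#'   used below 1e5 entries (products agree to numerical precision either
#'   way).
#' @return object of class `penalty_operator`: list with `D`, `row_info`
#'   (data.frame: type, y, j, k, coord), `spectral_norm`, `M` (row count),
#'   `dim` (column count), `lambda_f`, `lambda_sim`.
#' @export
penalty_operator <- function(means, lambda_f, lambda_sim, sparse = NULL) {
  stopifnot(inherits(means, "group_means"))
  if (lambda_f < 0 || lambda_sim < 0) stop("penalty weights must be nonnegative")
  K <- means$K
  p <- means$p
  if (K < 2) stop("at least K = 2 groups are required")
  pb <- p + 1L                      # block width (intercept first)
  pairs <- all_pairs(K)
  n_pairs <- length(pairs)
  M <- 2L * n_pairs + p * n_pairs
  ncolD <- pb * K
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  info <- data.frame(type = character(M), y = NA_integer_,
                     j = integer(M), k = integer(M), coord = NA_integer_,
                     stringsAsFactors = FALSE)
  row <- 0L
  for (y in 0:1) {
    for (pr in pairs) {
      row <- row + 1L
      j <- pr[1]; k <- pr[2]
      ii <- c(ii, rep(row, 2L * pb))
      jj <- c(jj, (j - 1L) * pb + seq_len(pb), (k - 1L) * pb + seq_len(pb))
      vv <- c(vv, lambda_f * means$xbar[[j]][[y + 1]],
              -lambda_f * means$xbar[[k]][[y + 1]])
      info$type[row] <- "fairness"; info$y[row] <- y
      info$j[row] <- j; info$k[row] <- k
    }
  }
  for (pr in pairs) {
    j <- pr[1]; k <- pr[2]
    for (l in seq_len(p)) {
      row <- row + 1L
      ii <- c(ii, row, row)
      jj <- c(jj, (j - 1L) * pb + 1L + l, (k - 1L) * pb + 1L + l)
      vv <- c(vv, lambda_sim, -lambda_sim)
      info$type[row] <- "similarity"
      info$j[row] <- j; info$k[row] <- k; info$coord[row] <- l
    }
  }
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(M, ncolD))
  if (is.null(sparse)) sparse <- (as.numeric(M) * ncolD) >= 1e5
  if (!sparse) D <- as.matrix(D)
  op <- structure(list(D = D, row_info = info, M = M, dim = ncolD,
                       lambda_f = lambda_f, lambda_sim = lambda_sim,
                       p = p, K = K),
                  class = "penalty_operator")
  op$spectral_norm <- operator_norm(D)
  op
}

#' Penalty operator for the single fairness model
#'
#' The single fairness model shares one coefficient vector across groups,
#' so its fairness penalty acts on a single (p+1) block: one row per group
#' pair and outcome class, carrying the difference of class-conditional
#' means. There is no similarity penalty (nothing to fuse).
#'
#' @inheritParams penalty_operator
#' @export
sfm_penalty_operator <- function(means, lambda_f) {
  stopifnot(inherits(means, "group_means"))
  if (lambda_f < 0) stop("penalty weights must be nonnegative")
  K <- means$K; p <- means$p; pb <- p + 1L
  pairs <- all_pairs(K)
  M <- 2L * length(pairs)
  rows <- matrix(0, M, pb)
  info <- data.frame(type = rep("fairness", M), y = NA_integer_,
                     j = integer(M), k = integer(M), coord = NA_integer_)
  row <- 0L
  for (y in 0:1) for (pr in pairs) {
    row <- row + 1L
    rows[row, ] <- lambda_f * (means$xbar[[pr[1]]][[y + 1]] -
                               means$xbar[[pr[2]]][[y + 1]])
    info$y[row] <- y; info$j[row] <- pr[1]; info$k[row] <- pr[2]
  }
  op <- structure(list(D = rows, row_info = info, M = M, dim = pb,
                       lambda_f = lambda_f, lambda_sim = 0,
                       p = p, K = 1L),
                  class = "penalty_operator")
  op$spectral_norm <- operator_norm(rows)
  op
}

# Largest singular value by power iteration on t(D) %*% D with a fixed,
# deterministic start vector; tol 1e-8 on successive Rayleigh quotients.
operator_norm <- function(D, tol = 1e-8, max_iter = 1e4) {
  n <- ncol(D)
  if (n == 0 || nrow(D) == 0) return(0)
  nrm <- function(v) sqrt(sum(v^2))
  v <- 1 / sqrt(seq_len(n))          # deterministic, no zero/orthogonal start
  v <- v / nrm(v)
  lam_old <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(Matrix::crossprod(D, D %*% v))
    lam <- nrm(w)
    if (lam == 0) return(0)
    v <- w / lam
    if (abs(lam - lam_old) <= tol * max(1, lam)) break
    lam_old <- lam
  }
  sqrt(lam)
}

#' Evaluate the three penalties at a coefficient set
#'
#' @param cs a `coef_set`.
#' @param means a `group_means` object.
#' @param lambda_f,lambda_sim scalar penalty weights.
#' @param lambda_sp per-group sparsity weights (scalar recycled, or
#'   length-K vector).
#' @return named numeric vector `c(fairness=, similarity=, sparsity=)`.
#'   The fairness and similarity components sum exactly to
#'   `||D b||_1` for the operator built at the same weights.
#' @export
eval_penalties <- function(cs, means, lambda_f, lambda_sim, lambda_sp) {
  K <- means$K; p <- means$p
  stopifnot(cs$K == K, cs$p == p)
  lambda_sp <- rep_len(lambda_sp, K)
  pf <- 0; psim <- 0
  for (pr in all_pairs(K)) {
    j <- pr[1]; k <- pr[2]
    bj <- c(cs$intercepts[j], cs$beta[, j])
    bk <- c(cs$intercepts[k], cs$beta[, k])
    for (y in 0:1) {
      pf <- pf + abs(sum(means$xbar[[j]][[y + 1]] * bj) -
                     sum(means$xbar[[k]][[y + 1]] * bk))
    }
    psim <- psim + sum(abs(cs$beta[, j] - cs$beta[, k]))
  }
  psp <- sum(lambda_sp * colSums(abs(cs$beta)))
  c(fairness = lambda_f * pf, similarity = lambda_sim * psim, sparsity = psp)
}

#' Projection onto the unit L-infinity ball
#'
#' Componentwise clip to [-1, 1]; the closed-form maximizer of the dual
#' formulation behind the Nesterov smooth approximation.
#'
#' @param x numeric vector.
#' @export
project_linf <- function(x) {
  pmin(1, pmax(-1, x))
}

#' Nesterov smooth approximation of the stacked L1 penalty
#'
#' Replaces ||D b||_1 by its smoothed dual form
#' f_mu(b) = max over ||a||_inf <= 1 of a' D b - (mu/2) ||a||_2^2,
#' whose maximizer is a* = clip(D b / mu) and which satisfies
#' 0 <= ||D b||_1 - f_mu(b) <= mu M / 2 with M the row count of D.
#'
#' @param b stacked, intercept-augmented coefficient vector.
#' @param op a `penalty_operator`.
#' @param mu positive smoothing parameter.
#' @return list with `value`, `alpha` (the maximizer a*), and `Db`.
#' @export
smoothed_penalty <- function(b, op, mu) {
  if (mu <= 0) stop("mu must be positive")
  Db <- as.numeric(op$D %*% b)
  alpha <- project_linf(Db / mu)
  list(value = sum(alpha * Db) - (mu / 2) * sum(alpha^2),
       alpha = alpha, Db = Db)
}

#' Gradient of the Nesterov smooth approximation
#'
#' Equals D' a* with a* = clip(D b / mu); Lipschitz continuous with
#' constant ||D||_2^2 / mu.
#'
#' @inheritParams smoothed_penalty
#' @export
smoothed_gradient <- function(b, op, mu) {
  if (mu <= 0) stop("mu must be positive")
  alpha <- project_linf(as.numeric(op$D %*% b) / mu)
  as.numeric(Matrix::crossprod(op$D, alpha))
}
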