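# Independent convex oracle for the joint objective, deliberately on a
# different code path from the package solver: nlminb (PORT quasi-Newton)
# on an epsilon-smoothed objective, sqrt(x^2 + eps) replacing |x|, with
# continuation eps 1e-4 -> 1e-12 and analytic gradients. Returns the
# exact (non-smoothed) objective value at the minimizer.

oracle_minimize <- function(nll, nll_grad, A, sp, b0) {
  sabs <- function(x, eps) sqrt(x^2 + eps)
  has_A <- !is.null(A) && nrow(A) > 0
  b <- b0
  for (eps in c(1e-4, 1e-8, 1e-12)) {
    obj <- function(v) {
      val <- nll(v) + sum(sp * sabs(v, eps))
      if (has_A) val <- val + sum(sabs(drop(A %*% v), eps))
      val
    }
    grad <- function(v) {
      g <- nll_grad(v) + sp * v / sabs(v, eps)
      if (has_A) {
        u <- drop(A %*% v)
        g <- g + drop(crossprod(A, u / sabs(u, eps)))
      }
      g
    }
    r <- stats::nlminb(b, obj, grad,
                       control = list(iter.max = 3000, eval.max = 6000,
                                      rel.tol = 1e-14))
    b <- r$par
  }
  exact <- nll(b) + sum(sp * abs(b))
  if (has_A) exact <- exact + sum(abs(A %*% b))
  list(par = b, objective = exact)
}

# class-conditional means computed independently of the package
oracle_class_means <- function(data) {
  lapply(data$groups, function(g)
    lapply(0:1, function(cls)
      c(1, colMeans(g$X[g$y == cls, , drop = FALSE]))))
}

# penalty rows for the group-specific (joint) model, stacked layout
# (intercept first within each (p+1) block)
oracle_jfm_rows <- function(data, lambda_f, lambda_sim) {
  p <- data$p; K <- data$K; pb <- p + 1
  mns <- oracle_class_means(data)
  rows <- list()
  for (k in 2:K) for (j in seq_len(k - 1)) {
    for (cls in 1:2) {
      r <- numeric(pb * K)
      r[(j - 1) * pb + seq_len(pb)] <- lambda_f * mns[[j]][[cls]]
      r[(k - 1) * pb + seq_len(pb)] <- -lambda_f * mns[[k]][[cls]]
      rows[[length(rows) + 1]] <- r
    }
    for (l in seq_len(p)) {
      r <- numeric(pb * K)
      r[(j - 1) * pb + 1 + l] <- lambda_sim
      r[(k - 1) * pb + 1 + l] <- -lambda_sim
      rows[[length(rows) + 1]] <- r
    }
  }
  do.call(rbind, rows)
}

# exact joint objective of the group-specific model at a coef_set
oracle_jfm_objective_at <- function(cs, data, lambda_f, lambda_sim,
                                    lambda_sp_k) {
  val <- 0
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    eta <- cs$intercepts[k] + drop(g$X %*% cs$beta[, k])
    val <- val + mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - g$y * eta)
  }
  mns <- oracle_class_means(data)
  for (k in 2:data$K) for (j in seq_len(k - 1)) {
    for (cls in 1:2) {
      val <- val + lambda_f *
        abs(sum(mns[[j]][[cls]] * c(cs$intercepts[j], cs$beta[, j])) -
            sum(mns[[k]][[cls]] * c(cs$intercepts[k], cs$beta[, k])))
    }
    val <- val + lambda_sim * sum(abs(cs$beta[, j] - cs$beta[, k]))
  }
  val + sum(rep_len(lambda_sp_k, data$K) * colSums(abs(cs$beta)))
}

oracle_jfm <- function(data, lambda_f, lambda_sim, lambda_sp_k) {
  p <- data$p; K <- data$K; pb <- p + 1
  lambda_sp_k <- rep_len(lambda_sp_k, K)
  A <- if (lambda_f > 0 || lambda_sim > 0)
    oracle_jfm_rows(data, lambda_f, lambda_sim) else NULL
  sp <- as.numeric(vapply(seq_len(K),
                          function(k) c(0, rep(lambda_sp_k[k], p)),
                          numeric(pb)))
  nll <- function(b) {
    val <- 0
    for (k in seq_len(K)) {
      g <- data$groups[[k]]
      eta <- drop(cbind(1, g$X) %*% b[(k - 1) * pb + seq_len(pb)])
      val <- val + mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - g$y * eta)
    }
    val
  }
  nll_grad <- function(b) {
    g_out <- numeric(pb * K)
    for (k in seq_len(K)) {
      g <- data$groups[[k]]
      Xt <- cbind(1, g$X)
      eta <- drop(Xt %*% b[(k - 1) * pb + seq_len(pb)])
      g_out[(k - 1) * pb + seq_len(pb)] <-
        drop(crossprod(Xt, plogis(eta) - g$y)) / nrow(Xt)
    }
    g_out
  }
  oracle_minimize(nll, nll_grad, A, sp, numeric(pb * K))
}

# shared-coefficient (single fairness) model: unweighted summed likelihood
oracle_sfm <- function(data, lambda_f, lambda_sp) {
  p <- data$p; pb <- p + 1
  mns <- oracle_class_means(data)
  rows <- list()
  for (k in 2:data$K) for (j in seq_len(k - 1)) for (cls in 1:2)
    rows[[length(rows) + 1]] <- lambda_f * (mns[[j]][[cls]] - mns[[k]][[cls]])
  A <- if (lambda_f > 0) do.call(rbind, rows) else NULL
  X <- do.call(rbind, lapply(data$groups, function(g) g$X))
  y <- unlist(lapply(data$groups, function(g) g$y))
  Xt <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(Xt %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  }
  nll_grad <- function(b) drop(crossprod(Xt, plogis(drop(Xt %*% b)) - y))
  oracle_minimize(nll, nll_grad, A, c(0, rep(lambda_sp, p)), numeric(pb))
}
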