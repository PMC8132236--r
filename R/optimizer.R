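#' Solver options for the accelerated smoothing proximal gradient algorithm
#'
#' @param max_iter maximum number of iterations.
#' @param tol relative-change convergence tolerance on the smoothed
#'   objective, assessed over a 5-iteration window (momentum makes the
#'   single-iteration change noisy).
#' @param delta target accuracy of the smoothing: the smoothing parameter
#'   is chosen as mu = delta / M so the approximation gap is at most
#'   delta / 2. Smaller delta means a tighter solution but a smaller step
#'   size (the penalty part of the Lipschitz constant is ||D||_2^2 / mu).
#' @param restart reset the momentum sequence when the smoothed objective
#'   increases (adaptive restart; practical safeguard that does not affect
#'   the convergence guarantee).
#' @export
solver_options <- function(max_iter = 5000, tol = 1e-6, delta = 1e-4,
                           restart = TRUE) {
  stopifnot(max_iter >= 1, tol > 0, delta > 0)
  list(max_iter = as.integer(max_iter), tol = tol, delta = delta,
       restart = isTRUE(restart))
}

#' Hyperparameters of the joint fairness model
#'
#' @param lambda_f nonnegative fairness penalty weight.
#' @param lambda_sim nonnegative fused-lasso similarity weight.
#' @param lambda_sp sparsity weight: a single scalar is spread across
#'   groups as lambda_sp / sqrt(n_k) (sparsity inversely proportional to
#'   group sample size); a length-K vector gives per-group weights
#'   directly.
#' @param mu optional explicit smoothing parameter; by default chosen from
#'   the solver's `delta` via [choose_mu()].
#' @export
hyperparameters <- function(lambda_f = 0, lambda_sim = 0, lambda_sp = 0,
                            mu = NULL) {
  stopifnot(lambda_f >= 0, lambda_sim >= 0, all(lambda_sp >= 0))
  if (!is.null(mu)) stopifnot(mu > 0)
  list(lambda_f = lambda_f, lambda_sim = lambda_sim, lambda_sp = lambda_sp,
       mu = mu)
}

# spread a scalar sparsity weight across groups: lambda_sp / sqrt(n_k)
sparsity_weights <- function(lambda_sp, n_k) {
  K <- length(n_k)
  if (length(lambda_sp) == 1L) lambda_sp / sqrt(n_k) else rep_len(lambda_sp, K)
}

# overflow-safe log(1 + exp(eta))
softplus <- function(eta) {
  pmax(eta, 0) + log1p(exp(-abs(eta)))
}

sigmoid <- function(eta) 1 / (1 + exp(-eta))

#' Weighted negative log-likelihood of the grouped logistic model
#'
#' Sum over groups of (1/n_k) times the group's negative Bernoulli
#' log-likelihood at linear predictor intercept_k + X_k beta_k. The 1/n_k
#' weighting upweights small groups so no group dominates the joint fit.
#' Computed with a softplus form that is safe for |eta| up to 1e3 and
#' beyond.
#'
#' @param cs a `coef_set`.
#' @param data a `grouped_data`.
#' @export
neg_weighted_loglik <- function(cs, data) {
  stopifnot(cs$K == data$K, cs$p == data$p)
  val <- 0
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    eta <- cs$intercepts[k] + drop(g$X %*% cs$beta[, k])
    val <- val + sum(softplus(eta) - g$y * eta) / length(g$y)
  }
  val
}

#' Gradient of the weighted negative log-likelihood
#'
#' Stacked gradient in the intercept-augmented layout: block k equals
#' (1/n_k) X~_k' (sigmoid(eta_k) - y_k), where X~ has a leading column of
#' ones. Blocks are independent: group k's gradient does not involve any
#' other group's coefficients.
#'
#' @inheritParams neg_weighted_loglik
#' @return numeric vector of length (p + 1) * K.
#' @export
loglik_gradient <- function(cs, data) {
  stopifnot(cs$K == data$K, cs$p == data$p)
  out <- numeric((data$p + 1) * data$K)
  pb <- data$p + 1L
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    eta <- cs$intercepts[k] + drop(g$X %*% cs$beta[, k])
    r <- sigmoid(eta) - g$y
    out[(k - 1L) * pb + 1L] <- sum(r) / length(g$y)
    out[(k - 1L) * pb + 1L + seq_len(data$p)] <-
      drop(crossprod(g$X, r)) / length(g$y)
  }
  out
}

#' Soft-thresholding operator
#'
#' Componentwise `sign(x) * max(|x| - t, 0)`; the proximal operator of the
#' weighted L1 norm. Intercept coordinates are handled by passing a zero
#' threshold.
#'
#' @param x numeric vector.
#' @param thresholds nonnegative vector (recycled) of per-coordinate
#'   thresholds.
#' @export
soft_threshold <- function(x, thresholds) {
  if (any(thresholds < 0)) stop("thresholds must be nonnegative")
  sign(x) * pmax(abs(x) - thresholds, 0)
}

#' Smoothing parameter from a target accuracy
#'
#' mu = delta / M keeps the smoothing gap ||D b||_1 - f_mu(b) below
#' mu M / 2 = delta / 2. When the operator has no active rows (both
#' penalty weights zero) smoothing is inert and mu = 1 is returned.
#'
#' @param delta positive target accuracy.
#' @param op a `penalty_operator`.
#' @export
choose_mu <- function(delta, op) {
  stopifnot(delta > 0)
  active <- op$lambda_f > 0 || op$lambda_sim > 0
  if (!active || op$M == 0) return(1)
  delta / op$M
}

#' Lipschitz constant of the smoothed objective's gradient
#'
#' The likelihood part is block-diagonal, so its constant is the largest
#' blockwise value w_k ||X~_k||_2^2 / 4 (1/4 bounds the sigmoid
#' derivative); the smoothed penalty contributes ||D||_2^2 / mu.
#'
#' @param data a `grouped_data`.
#' @param op a `penalty_operator` built for this dataset.
#' @param mu positive smoothing parameter.
#' @export
lipschitz_constant <- function(data, op, mu) {
  if (mu <= 0) stop("mu must be positive")
  lik <- max(vapply(seq_len(data$K), function(k) {
    operator_norm(augmented_X(data, k))^2 / (4 * data$n_k[k])
  }, numeric(1)))
  lik + op$spectral_norm^2 / mu
}

# ---------------------------------------------------------------------------
# Generic FISTA core on:  G(b) = smooth(b) + sum_i sp[i] * |b[i]|
# smooth_fn(b) -> value, grad_fn(b) -> vector, L = Lipschitz constant.
# Returns the iterate trace of smoothed objective values and the solution.
aspg_core <- function(smooth_fn, grad_fn, sp, L, init, opts) {
  z <- init
  b <- init
  theta <- 1
  obj <- function(v) smooth_fn(v) + sum(sp * abs(v))
  step_t <- sp / L
  trace <- numeric(opts$max_iter + 1L)
  trace[1] <- obj(z)
  if (!is.finite(trace[1])) stop("non-finite objective at initialization")
  conv <- FALSE
  t_done <- 0L
  for (t in seq_len(opts$max_iter)) {
    z_new <- soft_threshold(b - grad_fn(b) / L, step_t)
    f_new <- obj(z_new)
    if (opts$restart && f_new > trace[t]) {
      # momentum overshoot: restart from the previous iterate (plain
      # proximal step, guaranteed non-increasing by the descent lemma)
      theta <- 1
      z_new <- soft_threshold(z - grad_fn(z) / L, step_t)
      f_new <- obj(z_new)
    }
    if (!is.finite(f_new))
      stop(sprintf("non-finite objective at iteration %d", t))
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    b <- z_new + ((theta - 1) / theta_new) * (z_new - z)
    z <- z_new
    theta <- theta_new
    trace[t + 1L] <- f_new
    t_done <- t
    if (t >= 5L) {
      recent <- trace[(t - 4L):(t + 1L)]
      if (abs(max(recent) - min(recent)) <
          opts$tol * max(1, abs(f_new))) {
        conv <- TRUE
        break
      }
    }
  }
  list(solution = z, trace = trace[seq_len(t_done + 1L)],
       converged = conv, iterations = t_done)
}

#' Fit the joint fairness model by accelerated smoothing proximal gradient
#'
#' Minimizes the joint objective: the 1/n_k-weighted negative
#' log-likelihoods plus the fairness, similarity and sparsity penalties.
#' The non-separable fairness + similarity part is smoothed (Nesterov) and
#' handled by gradient steps; the separable sparsity part by
#' soft-thresholding; convergence is accelerated by FISTA momentum with
#' adaptive restart. Intercepts are never penalized. Initialization is
#' beta = 0 with each intercept at the logit of its group's event rate.
#'
#' @param data a `grouped_data`.
#' @param hyper a [hyperparameters()] list.
#' @param opts a [solver_options()] list.
#' @param init optional `coef_set` to start from.
#' @return object of class `aspg_fit`: list with `coefficients`
#'   (a `coef_set`), `objective_trace` (smoothed objective per iteration,
#'   element 1 is the initial value), `converged`, `iterations`,
#'   `final_objective` (the exact, unsmoothed joint objective at the
#'   solution), `mu`, `L`, `penalties` (component values at the solution).
#' @export
aspg_fit <- function(data, hyper, opts = solver_options(), init = NULL) {
  stopifnot(inherits(data, "grouped_data"))
  means <- group_means(data)
  op <- penalty_operator(means, hyper$lambda_f, hyper$lambda_sim)
  mu <- if (!is.null(hyper$mu)) hyper$mu else choose_mu(opts$delta, op)
  L <- lipschitz_constant(data, op, mu)
  sp_k <- sparsity_weights(hyper$lambda_sp, data$n_k)
  pb <- data$p + 1L
  sp <- as.numeric(rbind(0, matrix(rep(sp_k, each = data$p), data$p, data$K)))

  Xs <- lapply(seq_len(data$K), function(k) augmented_X(data, k))
  ys <- lapply(data$groups, `[[`, "y")
  n_k <- data$n_k
  K <- data$K
  blk <- lapply(seq_len(K), function(k) (k - 1L) * pb + seq_len(pb))

  nll <- function(b) {
    v <- 0
    for (k in seq_len(K)) {
      eta <- drop(Xs[[k]] %*% b[blk[[k]]])
      v <- v + sum(softplus(eta) - ys[[k]] * eta) / n_k[k]
    }
    v
  }
  nll_grad <- function(b) {
    g <- numeric(pb * K)
    for (k in seq_len(K)) {
      eta <- drop(Xs[[k]] %*% b[blk[[k]]])
      g[blk[[k]]] <- drop(crossprod(Xs[[k]], sigmoid(eta) - ys[[k]])) / n_k[k]
    }
    g
  }
  smooth_fn <- function(b) nll(b) + smoothed_penalty(b, op, mu)$value
  grad_fn <- function(b) nll_grad(b) + smoothed_gradient(b, op, mu)

  if (is.null(init)) {
    b0 <- numeric(pb * K)
    for (k in seq_len(K)) b0[blk[[k]][1]] <- stats::qlogis(mean(ys[[k]]))
  } else {
    stopifnot(inherits(init, "coef_set"), init$K == K, init$p == data$p)
    b0 <- stack_coef(init)
  }

  res <- aspg_core(smooth_fn, grad_fn, sp, L, b0, opts)
  cs <- unstack_coef(res$solution, data$p, K, data$labels)
  rownames(cs$beta) <- data$feature_names
  pen <- eval_penalties(cs, means, hyper$lambda_f, hyper$lambda_sim, sp_k)
  structure(list(
    coefficients = cs,
    objective_trace = res$trace,
    converged = res$converged,
    iterations = res$iterations,
    final_objective = neg_weighted_loglik(cs, data) + sum(pen),
    penalties = pen,
    mu = mu, L = L,
    hyper = hyper, lambda_sp_k = sp_k
  ), class = "aspg_fit")
}

# Single-block lasso-logistic solver used by the separate / ignorant /
# single-fairness comparators. `op` may be NULL (pure lasso) or a
# penalty_operator on the (p+1) block; `weight` scales the negative
# log-likelihood (1/n for the mean form, 1 for an unweighted sum).
lasso_logistic_core <- function(X, y, lambda_sp, opts,
                                op = NULL, weight = 1 / length(y),
                                init = NULL) {
  Xt <- cbind(1, X)
  pb <- ncol(Xt)
  mu <- 1
  pen_L <- 0
  if (!is.null(op) && (op$lambda_f > 0 || op$lambda_sim > 0)) {
    mu <- choose_mu(opts$delta, op)
    pen_L <- op$spectral_norm^2 / mu
  }
  L <- weight * operator_norm(Xt)^2 / 4 + pen_L
  sp <- c(0, rep(lambda_sp, pb - 1L))
  nll <- function(b) {
    eta <- drop(Xt %*% b)
    weight * sum(softplus(eta) - y * eta)
  }
  nll_grad <- function(b) {
    eta <- drop(Xt %*% b)
    weight * drop(crossprod(Xt, sigmoid(eta) - y))
  }
  if (!is.null(op) && (op$lambda_f > 0 || op$lambda_sim > 0)) {
    smooth_fn <- function(b) nll(b) + smoothed_penalty(b, op, mu)$value
    grad_fn <- function(b) nll_grad(b) + smoothed_gradient(b, op, mu)
  } else {
    smooth_fn <- nll
    grad_fn <- nll_grad
  }
  b0 <- if (is.null(init)) c(stats::qlogis(mean(y)), numeric(pb - 1L)) else init
  res <- aspg_core(smooth_fn, grad_fn, sp, L, b0, opts)
  pen_exact <- if (!is.null(op)) sum(abs(op$D %*% res$solution)) else 0
  list(intercept = res$solution[1], beta = res$solution[-1],
       trace = res$trace, converged = res$converged,
       iterations = res$iterations,
       final_objective = nll(res$solution) + pen_exact +
         lambda_sp * sum(abs(res$solution[-1])),
       mu = mu, L = L)
}
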