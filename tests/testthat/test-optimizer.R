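test_that("weighted negative log-likelihood has its closed-form values", {
  d <- make_toy_data(n = c(25, 15), p = 3, seed = 21)
  zero <- coef_set(matrix(0, 3, 2), intercepts = c(0, 0))
  expect_equal(neg_weighted_loglik(zero, d), 2 * log(2))
  # independent direct Bernoulli log-likelihood
  cs <- random_coef_set(3, 2)
  direct <- 0
  for (k in 1:2) {
    g <- d$groups[[k]]
    pr <- plogis(cs$intercepts[k] + drop(g$X %*% cs$beta[, k]))
    direct <- direct - sum(dbinom(g$y, 1, pr, log = TRUE)) / length(g$y)
  }
  expect_equal(neg_weighted_loglik(cs, d), direct, tolerance = 1e-10)
})

test_that("log-likelihood is overflow-safe at |eta| = 1000", {
  d <- grouped_data(list(A = matrix(c(1, -1), 2), B = matrix(c(1, -1), 2)),
                    list(A = c(0, 1), B = c(0, 1)))
  # group A: both observations maximally wrong (eta = +-1000 against y);
  # group B: both maximally right
  cs <- coef_set(cbind(1000, -1000))
  v <- neg_weighted_loglik(cs, d)
  expect_true(is.finite(v))
  expect_equal(v, 1000, tolerance = 1e-6)
  g <- loglik_gradient(cs, d)
  expect_true(all(is.finite(g)))
})

test_that("log-likelihood gradient matches finite differences, by block", {
  d <- make_toy_data(n = c(40, 30), p = 4, seed = 22)
  set.seed(23)
  for (rep in 1:10) {
    cs <- random_coef_set(4, 2, scale = 0.7)
    b <- stack_coef(cs)
    g <- loglik_gradient(cs, d)
    h <- 1e-6
    fd <- vapply(seq_along(b), function(i) {
      e <- numeric(length(b)); e[i] <- h
      (neg_weighted_loglik(unstack_coef(b + e, 4, 2), d) -
         neg_weighted_loglik(unstack_coef(b - e, 4, 2), d)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
  # separability: block k unaffected by other blocks' coefficients
  cs1 <- random_coef_set(4, 2)
  cs2 <- cs1
  cs2$beta[, 2] <- rnorm(4)
  cs2$intercepts[2] <- 1
  expect_equal(loglik_gradient(cs1, d)[1:5], loglik_gradient(cs2, d)[1:5])
})

test_that("soft thresholding matches its closed form and a grid search", {
  expect_equal(soft_threshold(c(3, -0.5), c(1, 1)), c(2, 0))
  x <- rnorm(10)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(1, -0.1), "nonnegative")
  # exact minimizer of 0.5 (z - x)^2 + t |z| by grid search
  set.seed(24)
  for (rep in 1:10) {
    x <- rnorm(1, sd = 2); tt <- runif(1)
    grid <- seq(-5, 5, length.out = 1001)
    expect_lt(abs(soft_threshold(x, tt) -
                    grid[which.min(0.5 * (grid - x)^2 + tt * abs(grid))]),
              0.006)  # half a grid step
  }
})

test_that("Lipschitz constant combines likelihood and smoothing parts", {
  d <- make_toy_data(n = c(40, 30), p = 4, seed = 25)
  op <- penalty_operator(group_means(d), 0.5, 0.5)
  L1 <- lipschitz_constant(d, op, mu = 0.1)
  L2 <- lipschitz_constant(d, op, mu = 0.05)
  # halving mu doubles exactly the penalty part
  expect_equal(L2 - L1, op$spectral_norm^2 / 0.05 - op$spectral_norm^2 / 0.1)
  # likelihood part matches a dense SVD computation
  op0 <- penalty_operator(group_means(d), 0, 0)
  lik <- max(vapply(1:2, function(k)
    svd(cbind(1, d$groups[[k]]$X))$d[1]^2 / (4 * d$n_k[k]), numeric(1)))
  expect_equal(lipschitz_constant(d, op0, 1), lik, tolerance = 1e-6)
  expect_error(lipschitz_constant(d, op, 0), "positive")
  # observed gradient ratios never exceed L
  mu <- 0.1
  L <- lipschitz_constant(d, op, mu)
  gfull <- function(b) loglik_gradient(unstack_coef(b, 4, 2), d) +
    smoothed_gradient(b, op, mu)
  set.seed(26)
  for (rep in 1:50) {
    b1 <- rnorm(op$dim); b2 <- rnorm(op$dim)
    expect_lte(sqrt(sum((gfull(b1) - gfull(b2))^2)),
               L * sqrt(sum((b1 - b2)^2)) * (1 + 1e-10))
  }
})

test_that("smoothing parameter choice bounds the end-to-end gap by delta", {
  d <- make_toy_data(n = c(40, 30), p = 4, seed = 27)
  op <- penalty_operator(group_means(d), 0.5, 0.5)
  expect_equal(choose_mu(1e-2, list(lambda_f = 1, lambda_sim = 0, M = 50L)),
               2e-4)
  expect_equal(choose_mu(0.5, penalty_operator(group_means(d), 0, 0)), 1)
  set.seed(28)
  delta <- 1e-3
  mu <- choose_mu(delta, op)
  for (rep in 1:20) {
    b <- rnorm(op$dim, sd = 2)
    gap <- sum(abs(op$D %*% b)) - smoothed_penalty(b, op, mu)$value
    expect_gte(gap, -1e-12)
    expect_lte(gap, delta)
  }
})

test_that("saturated sparsity zeroes all slopes and leaves logit prevalences", {
  d <- make_toy_data(n = c(60, 40), p = 5, seed = 29)
  f <- aspg_fit(d, hyperparameters(lambda_sp = 1e3))
  expect_equal(max(abs(f$coefficients$beta)), 0)
  expect_equal(f$coefficients$intercepts,
               c(qlogis(mean(d$groups[[1]]$y)), qlogis(mean(d$groups[[2]]$y))),
               tolerance = 1e-6)
})

test_that("a huge similarity weight fuses the two groups' coefficients", {
  d <- make_toy_data(n = c(60, 40), p = 5, seed = 30)
  f <- aspg_fit(d, hyperparameters(lambda_sim = 1e6),
                solver_options(max_iter = 2000))
  expect_lt(max(abs(f$coefficients$beta[, 1] - f$coefficients$beta[, 2])),
            1e-3)
})

test_that("the solver reaches the convex oracle's objective", {
  d <- make_toy_data(n = c(100, 70), p = 8, seed = 31)
  lf <- 0.25; ls <- 0.15; sp <- c(0.04, 0.06)
  orc <- oracle_jfm(d, lf, ls, sp)
  f <- aspg_fit(d, hyperparameters(lf, ls, sp),
                solver_options(max_iter = 50000, tol = 1e-10, delta = 1e-4))
  expect_equal(f$final_objective, orc$objective, tolerance = 1e-4)
  # best-so-far trace is non-increasing and ends near the minimum
  best <- cummin(f$objective_trace)
  expect_true(all(diff(best) <= 0))
  expect_lt(abs(min(f$objective_trace) - tail(f$objective_trace, 1)),
            1e-6 * max(1, abs(tail(f$objective_trace, 1))))
})

test_that("smaller delta never worsens the final objective", {
  d <- make_toy_data(n = c(80, 50), p = 6, seed = 32)
  objs <- vapply(c(1e-1, 1e-2, 1e-3), function(delta) {
    aspg_fit(d, hyperparameters(0.3, 0.2, 0.05),
             solver_options(max_iter = 30000, tol = 1e-9,
                            delta = delta))$final_objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-4))
})

test_that("the solution is invariant to group input order", {
  d <- make_toy_data(n = c(60, 45), p = 5, seed = 33)
  drev <- grouped_data(list(B = d$groups[[2]]$X, A = d$groups[[1]]$X),
                       list(B = d$groups[[2]]$y, A = d$groups[[1]]$y))
  opts <- solver_options(max_iter = 30000, tol = 1e-10, delta = 1e-3)
  f1 <- aspg_fit(d, hyperparameters(0.3, 0.2, 0.05), opts)
  f2 <- aspg_fit(drev, hyperparameters(0.3, 0.2, 0.05), opts)
  expect_equal(f1$coefficients$beta[, "A"], f2$coefficients$beta[, "A"],
               tolerance = 1e-4)
  expect_equal(f1$coefficients$beta[, "B"], f2$coefficients$beta[, "B"],
               tolerance = 1e-4)
})

test_that("per-iteration work scales linearly in n at fixed p and K", {
  # operation-count property: one iteration touches each observation a
  # bounded number of times; measured through the flop-dominant matrix
  # sizes rather than wall-clock
  d1 <- make_toy_data(n = c(100, 80), p = 4, seed = 34)
  d2 <- make_toy_data(n = c(200, 160), p = 4, seed = 34)
  cost <- function(d) {
    op <- penalty_operator(group_means(d), 1, 1)
    sum(d$n_k) * (d$p + 1) +                    # likelihood products
      2 * length(if (is.matrix(op$D)) op$D else op$D@x)  # penalty products
  }
  expect_equal(cost(d2) - cost(d1), sum(d2$n_k - d1$n_k) * (d1$p + 1))
})
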