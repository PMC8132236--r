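test_that("JFM with positive similarity fuses two identical groups", {
  d0 <- make_toy_data(n = c(50, 50), p = 4, seed = 41)
  d <- grouped_data(list(A = d0$groups[[1]]$X, B = d0$groups[[1]]$X),
                    list(A = d0$groups[[1]]$y, B = d0$groups[[1]]$y))
  f <- fit_jfm(d, lambda_sim = 0.5, lambda_sp = 0.02)
  expect_lt(max(abs(f$coefficients$beta[, 1] - f$coefficients$beta[, 2])),
            1e-3)
})

test_that("JFM decouples into group-separate fits at zero coupling", {
  d <- make_toy_data(n = c(80, 60), p = 5, seed = 42)
  opts <- solver_options(max_iter = 30000, tol = 1e-9)
  f0 <- fit_jfm(d, lambda_f = 0, lambda_sim = 0, lambda_sp = 0.5, opts = opts)
  fs <- fit_separate(d, lambda_sp = 0.5, opts = opts)
  expect_equal(f0$final_objective, fs$final_objective, tolerance = 1e-4)
  expect_equal(f0$coefficients$beta, fs$coefficients$beta, tolerance = 1e-3)
})

test_that("group-separate fits match glmnet and are blockwise independent", {
  skip_if_not_installed("glmnet")
  d <- make_toy_data(n = c(150, 100), p = 6, seed = 43)
  lam <- 0.04
  fs <- fit_separate(d, lambda_sp = c(lam, lam),
                     opts = solver_options(max_iter = 30000, tol = 1e-9))
  for (k in 1:2) {
    g <- d$groups[[k]]
    gn <- glmnet::glmnet(g$X, g$y, family = "binomial", lambda = lam,
                         standardize = FALSE, thresh = 1e-14)
    obj <- function(b0, b) {
      eta <- b0 + drop(g$X %*% b)
      mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - g$y * eta) + lam * sum(abs(b))
    }
    expect_equal(obj(fs$coefficients$intercepts[k], fs$coefficients$beta[, k]),
                 obj(as.numeric(gn$a0), as.numeric(gn$beta)),
                 tolerance = 1e-5)
  }
  # group A's fit is invariant to group B's data
  d2 <- grouped_data(list(A = d$groups[[1]]$X,
                          B = d$groups[[2]]$X[1:50, ]),
                     list(A = d$groups[[1]]$y, B = d$groups[[2]]$y[1:50]))
  fs2 <- fit_separate(d2, lambda_sp = c(lam, lam),
                      opts = solver_options(max_iter = 30000, tol = 1e-9))
  expect_equal(fs$coefficients$beta[, 1], fs2$coefficients$beta[, 1],
               tolerance = 1e-8)
})

test_that("unpenalized separate fits approach the per-group MLE", {
  d <- make_toy_data(n = c(400, 300), p = 3, seed = 44)
  fs <- fit_separate(d, lambda_sp = 0,
                     opts = solver_options(max_iter = 50000, tol = 1e-11))
  for (k in 1:2) {
    g <- d$groups[[k]]
    ml <- glm(g$y ~ g$X, family = binomial())
    expect_equal(unname(fs$coefficients$beta[, k]), unname(coef(ml)[-1]),
                 tolerance = 1e-3)
  }
})

test_that("group-ignorant model matches glmnet on the indicator design", {
  skip_if_not_installed("glmnet")
  d <- make_toy_data(n = c(120, 90), p = 5, seed = 45)
  lam <- 0.03
  fi <- fit_ignorant(d, lambda_sp = lam,
                     opts = solver_options(max_iter = 30000, tol = 1e-9))
  X <- rbind(d$groups[[1]]$X, d$groups[[2]]$X)
  Xi <- cbind(X, c(rep(0, d$n_k[1]), rep(1, d$n_k[2])))
  y <- c(d$groups[[1]]$y, d$groups[[2]]$y)
  gn <- glmnet::glmnet(Xi, y, family = "binomial", lambda = lam,
                       standardize = FALSE, thresh = 1e-14)
  obj <- function(b0, b) {
    eta <- b0 + drop(Xi %*% b)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lam * sum(abs(b))
  }
  pkg_b <- c(fi$coefficients$beta[, 1],
             fi$shared$group_indicator[2])
  expect_equal(obj(fi$shared$intercept, pkg_b),
               obj(as.numeric(gn$a0), as.numeric(gn$beta)), tolerance = 1e-5)
  # prediction depends on group only through the indicator shift
  x0 <- matrix(rnorm(5), 1)
  eta_a <- predict(fi, x0, "A", type = "link")
  eta_b <- predict(fi, x0, "B", type = "link")
  expect_equal(eta_b - eta_a, unname(fi$shared$group_indicator[2]))
})

test_that("identical groups shrink the ignorant model's indicator to zero", {
  d0 <- make_toy_data(n = c(80, 80), p = 4, seed = 46)
  d <- grouped_data(list(A = d0$groups[[1]]$X, B = d0$groups[[1]]$X),
                    list(A = d0$groups[[1]]$y, B = d0$groups[[1]]$y))
  fi <- fit_ignorant(d, lambda_sp = 0.02)
  expect_lt(abs(fi$shared$group_indicator[2]), 1e-6)
})

test_that("the single fairness model matches its oracle and reductions", {
  skip_if_not_installed("glmnet")
  d <- make_toy_data(n = c(90, 60), p = 5, seed = 47)
  n <- sum(d$n_k)
  # lambda_f = 0 reduces to an ordinary pooled lasso (glmnet at lam/n)
  lam <- 6
  fm0 <- fit_sfm(d, lambda_f = 0, lambda_sp = lam,
                 opts = solver_options(max_iter = 30000, tol = 1e-9))
  X <- rbind(d$groups[[1]]$X, d$groups[[2]]$X)
  y <- c(d$groups[[1]]$y, d$groups[[2]]$y)
  gn <- glmnet::glmnet(X, y, family = "binomial", lambda = lam / n,
                       standardize = FALSE, thresh = 1e-14)
  obj <- function(b0, b) {
    eta <- b0 + drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lam * sum(abs(b))
  }
  expect_equal(obj(fm0$shared$intercept, fm0$shared$beta),
               obj(as.numeric(gn$a0), as.numeric(gn$beta)),
               tolerance = 1e-5 * n)
  # with an active fairness penalty, matches the nlminb oracle
  fm <- fit_sfm(d, lambda_f = 2, lambda_sp = lam,
                opts = solver_options(max_iter = 50000, tol = 1e-10,
                                      delta = 1e-3))
  orc <- oracle_sfm(d, lambda_f = 2, lambda_sp = lam)
  expect_equal(fm$final_objective, orc$objective, tolerance = 1e-4)
})

test_that("identical group distributions leave the SFM fairness penalty near zero", {
  d0 <- make_toy_data(n = c(70, 70), p = 4, seed = 48)
  d <- grouped_data(list(A = d0$groups[[1]]$X, B = d0$groups[[1]]$X),
                    list(A = d0$groups[[1]]$y, B = d0$groups[[1]]$y))
  fm <- fit_sfm(d, lambda_f = 1, lambda_sp = 1)
  op <- sfm_penalty_operator(group_means(d), 1)
  expect_lt(sum(abs(op$D %*% c(fm$shared$intercept, fm$shared$beta))), 1e-8)
})

test_that("predictions use the right group block and standardization", {
  d <- make_toy_data(n = c(60, 40), p = 3, seed = 49)
  f <- fit_jfm(d, lambda_sp = 0.05)
  # eta = 0 -> probability one half
  zero_fit <- f
  zero_fit$coefficients <- coef_set(matrix(0, 3, 2), c(0, 0), c("A", "B"))
  expect_equal(predict(zero_fit, matrix(rnorm(6), 2), c("A", "B")),
               c(0.5, 0.5))
  # hand computation on a 3-row fixture
  cs <- f$coefficients
  X0 <- matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2, byrow = FALSE)
  X0 <- cbind(X0, c(0.3, -0.2, 1))
  pr <- predict(f, X0, c("A", "B", "A"))
  for (i in 1:3) {
    g <- c("A", "B", "A")[i]
    expect_equal(pr[i], plogis(cs$intercepts[cs$labels == g] +
                                 sum(X0[i, ] * cs$beta[, g])))
  }
  # monotone in a feature with positive coefficient
  k <- which(cs$beta[, 1] > 0)[1]
  if (!is.na(k)) {
    Xm <- matrix(0, 2, 3); Xm[2, k] <- 1
    prm <- predict(f, Xm, "A")
    expect_gt(prm[2], prm[1])
  }
  expect_error(predict(f, X0, "C"), "unseen group")
})

test_that("fits serialize to JSON and back with identical predictions", {
  tab <- make_toy_table(n = c(40, 30), p = 3, seed = 50)
  d <- validate_dataset(tab, standardize = TRUE)
  f <- fit_jfm(d, lambda_f = 0.2, lambda_sim = 0.1, lambda_sp = 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  f2 <- read_fit_json(path)
  Xnew <- matrix(rnorm(15), 5, 3)
  expect_equal(predict(f2, Xnew, rep("A", 5)), predict(f, Xnew, rep("A", 5)))
  expect_equal(f2$hyper$lambda_f, 0.2)
  expect_equal(f2$standardize$center, unname(d$standardize$center))
})

test_that("doubling max_iter cannot worsen a converged objective beyond tol", {
  d <- make_toy_data(n = c(70, 50), p = 5, seed = 51)
  o1 <- solver_options(max_iter = 2000, tol = 1e-8)
  o2 <- solver_options(max_iter = 4000, tol = 1e-8)
  for (fitter in list(
    function(o) fit_jfm(d, 0.2, 0.1, 0.05, opts = o),
    function(o) fit_separate(d, 0.05, opts = o),
    function(o) fit_ignorant(d, 0.02, opts = o))) {
    f1 <- fitter(o1); f2 <- fitter(o2)
    expect_lte(f2$final_objective, f1$final_objective + 1e-6)
  }
})
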