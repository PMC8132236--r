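#' Fit the joint fairness model (JFM)
#'
#' Group-specific sparse logistic regressions estimated jointly: the
#' 1/n_k-weighted negative log-likelihoods plus an equalized-odds fairness
#' penalty (lambda_f), a fused-lasso similarity penalty (lambda_sim) and
#' per-group L1 sparsity penalties (lambda_sp). Small groups borrow
#' strength from large ones through the similarity penalty while the
#' fairness penalty equalizes class-conditional mean risk scores across
#' groups.
#'
#' @param data a `grouped_data` (or anything [validate_dataset()] accepts).
#' @param lambda_f,lambda_sim,lambda_sp penalty weights; see
#'   [hyperparameters()].
#' @param opts solver options from [solver_options()].
#' @param init optional warm start (`coef_set`).
#' @return object of classes `fair_fit` (common interface) with
#'   `kind = "jfm"`; carries the fitted `coef_set`, solver diagnostics and
#'   the hyperparameters used.
#' @export
fit_jfm <- function(data, lambda_f = 0, lambda_sim = 0, lambda_sp = 0,
                    opts = solver_options(), init = NULL) {
  data <- validate_dataset(data)
  hyper <- hyperparameters(lambda_f, lambda_sim, lambda_sp)
  fit <- aspg_fit(data, hyper, opts, init)
  new_fair_fit("jfm", data, fit$coefficients, fit,
               hyper = list(lambda_f = lambda_f, lambda_sim = lambda_sim,
                            lambda_sp = lambda_sp))
}

#' Fit the single fairness model (SFM)
#'
#' One shared coefficient vector for all groups, estimated under the same
#' equalized-odds fairness penalty plus an L1 sparsity penalty. The
#' log-likelihood is the unweighted sum over groups (no 1/n_k weights);
#' set `weighted = TRUE` for a group-weighted variant.
#'
#' @inheritParams fit_jfm
#' @param weighted weight each group's log-likelihood by 1/n_k instead of
#'   summing raw contributions.
#' @export
fit_sfm <- function(data, lambda_f = 0, lambda_sp = 0,
                    opts = solver_options(), weighted = FALSE) {
  data <- validate_dataset(data)
  means <- group_means(data)
  op <- sfm_penalty_operator(means, lambda_f)
  X <- do.call(rbind, lapply(data$groups, `[[`, "X"))
  y <- unlist(lapply(data$groups, `[[`, "y"), use.names = FALSE)
  if (weighted) {
    # replicate the 1/n_k weighting by scaling rows is not possible for a
    # shared likelihood; instead solve sum_k (1/n_k) ell_k via per-row weights
    w <- rep(1 / data$n_k, times = data$n_k)
    core <- weighted_lasso_logistic(X, y, w, lambda_sp, opts, op)
  } else {
    core <- lasso_logistic_core(X, y, lambda_sp, opts, op = op, weight = 1)
  }
  cs <- coef_set(matrix(core$beta, data$p, data$K,
                        dimnames = list(data$feature_names, data$labels)),
                 intercepts = rep(core$intercept, data$K),
                 labels = data$labels)
  new_fair_fit("sfm", data, cs, core,
               hyper = list(lambda_f = lambda_f, lambda_sp = lambda_sp),
               shared = list(intercept = core$intercept, beta = core$beta))
}

weighted_lasso_logistic <- function(X, y, w, lambda_sp, opts, op) {
  Xt <- cbind(1, X)
  mu <- choose_mu(opts$delta, op)
  pen_L <- if (op$lambda_f > 0) op$spectral_norm^2 / mu else 0
  L <- operator_norm(sqrt(w) * Xt)^2 / 4 + pen_L
  sp <- c(0, rep(lambda_sp, ncol(X)))
  nll <- function(b) {
    eta <- drop(Xt %*% b)
    sum(w * (softplus(eta) - y * eta))
  }
  grad <- function(b) {
    eta <- drop(Xt %*% b)
    drop(crossprod(Xt, w * (sigmoid(eta) - y)))
  }
  if (op$lambda_f > 0) {
    sfn <- function(b) nll(b) + smoothed_penalty(b, op, mu)$value
    gfn <- function(b) grad(b) + smoothed_gradient(b, op, mu)
  } else {
    sfn <- nll; gfn <- grad
  }
  b0 <- c(stats::qlogis(sum(w * y) / sum(w)), numeric(ncol(X)))
  res <- aspg_core(sfn, gfn, sp, L, b0, opts)
  list(intercept = res$solution[1], beta = res$solution[-1],
       trace = res$trace, converged = res$converged,
       iterations = res$iterations,
       final_objective = nll(res$solution) +
         sum(abs(op$D %*% res$solution)) +
         lambda_sp * sum(abs(res$solution[-1])),
       mu = mu, L = L)
}

#' Fit group-separate lasso-logistic models
#'
#' One independent L1-penalized logistic regression per group; the
#' baseline that uses no information sharing. A scalar `lambda_sp` is
#' spread as lambda_sp / sqrt(n_k).
#'
#' @inheritParams fit_jfm
#' @export
fit_separate <- function(data, lambda_sp = 0, opts = solver_options()) {
  data <- validate_dataset(data)
  sp_k <- sparsity_weights(lambda_sp, data$n_k)
  beta <- matrix(0, data$p, data$K,
                 dimnames = list(data$feature_names, data$labels))
  intercepts <- numeric(data$K)
  cores <- vector("list", data$K)
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    cores[[k]] <- lasso_logistic_core(g$X, g$y, sp_k[k], opts)
    beta[, k] <- cores[[k]]$beta
    intercepts[k] <- cores[[k]]$intercept
  }
  cs <- coef_set(beta, intercepts, data$labels)
  diag_ <- list(converged = all(vapply(cores, `[[`, logical(1), "converged")),
                iterations = vapply(cores, `[[`, integer(1), "iterations"),
                final_objective = sum(vapply(cores, `[[`, numeric(1),
                                             "final_objective")),
                group_fits = cores)
  new_fair_fit("separate", data, cs, diag_,
               hyper = list(lambda_sp = lambda_sp, lambda_sp_k = sp_k))
}

#' Fit the group-ignorant lasso-logistic model
#'
#' A single logistic regression on the pooled rows with K - 1 group
#' indicator columns appended (reference coding, reference = first group);
#' the indicators are penalized like any other feature.
#'
#' @inheritParams fit_jfm
#' @export
fit_ignorant <- function(data, lambda_sp = 0, opts = solver_options()) {
  data <- validate_dataset(data)
  X <- do.call(rbind, lapply(data$groups, `[[`, "X"))
  y <- unlist(lapply(data$groups, `[[`, "y"), use.names = FALSE)
  gidx <- rep(seq_len(data$K), times = data$n_k)
  ind <- matrix(0, nrow(X), data$K - 1L)
  for (k in 2:data$K) ind[gidx == k, k - 1L] <- 1
  colnames(ind) <- paste0(".group.", data$labels[-1])
  core <- lasso_logistic_core(cbind(X, ind), y, lambda_sp, opts)
  feat_beta <- core$beta[seq_len(data$p)]
  ind_coef <- c(0, core$beta[data$p + seq_len(data$K - 1L)])
  cs <- coef_set(matrix(feat_beta, data$p, data$K,
                        dimnames = list(data$feature_names, data$labels)),
                 intercepts = core$intercept + ind_coef,
                 labels = data$labels)
  new_fair_fit("ignorant", data, cs, core,
               hyper = list(lambda_sp = lambda_sp),
               shared = list(intercept = core$intercept, beta = feat_beta,
                             group_indicator = stats::setNames(ind_coef,
                                                               data$labels)))
}

new_fair_fit <- function(kind, data, cs, diagnostics, hyper, shared = NULL) {
  structure(list(
    kind = kind,
    coefficients = cs,
    labels = data$labels,
    feature_names = data$feature_names,
    standardize = data$standardize,
    hyper = hyper,
    shared = shared,
    converged = isTRUE(diagnostics$converged),
    iterations = diagnostics$iterations,
    final_objective = diagnostics$final_objective,
    objective_trace = diagnostics$objective_trace %||% diagnostics$trace,
    diagnostics = diagnostics
  ), class = "fair_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fair_fit <- function(x, ...) {
  cat(sprintf("fair_fit (%s): %d groups, %d features\n", x$kind,
              x$coefficients$K, x$coefficients$p))
  nz <- colSums(abs(x$coefficients$beta) > 1e-8)
  cat("  nonzero coefficients per group:",
      paste(sprintf("%s=%d", x$labels, nz), collapse = ", "), "\n")
  cat(sprintf("  final objective: %.6g (converged: %s)\n",
              x$final_objective, x$converged))
  invisible(x)
}

#' @export
coef.fair_fit <- function(object, ...) object$coefficients

#' Predicted event probabilities
#'
#' Applies the group's own coefficient block (jfm / separate) or the
#' shared block (sfm / ignorant, where group enters only through the
#' indicator shift absorbed into the per-group intercept). If the model
#' was trained on standardized features, the stored statistics are applied
#' to `newdata` first.
#'
#' @param object a `fair_fit`.
#' @param newdata numeric feature matrix on the original scale.
#' @param group group label per row of `newdata`.
#' @param type "response" for probabilities, "link" for linear predictors.
#' @param ... unused.
#' @export
predict.fair_fit <- function(object, newdata, group,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$coefficients$p)
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), object$coefficients$p))
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, nrow(X))
  bad <- setdiff(unique(group), object$labels)
  if (length(bad))
    stop(sprintf("unseen group label(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(object$standardize))
    X <- scale(X, center = object$standardize$center,
               scale = object$standardize$scale)
  gi <- match(group, object$labels)
  eta <- unname(object$coefficients$intercepts[gi] +
    rowSums(X * t(object$coefficients$beta)[gi, , drop = FALSE]))
  if (type == "link") eta else sigmoid(eta)
}

#' Serialize a fitted model to JSON
#'
#' Stores kind, group labels, intercepts, coefficient vectors,
#' hyperparameters, standardization statistics and solver diagnostics,
#' with sorted keys for byte-stable output.
#'
#' @param fit a `fair_fit`.
#' @param path output file path.
#' @export
write_fit_json <- function(fit, path) {
  doc <- list(
    kind = fit$kind,
    labels = as.list(fit$labels),
    feature_names = as.list(fit$feature_names),
    intercepts = as.numeric(fit$coefficients$intercepts),
    beta = lapply(seq_len(fit$coefficients$K),
                  function(k) as.numeric(fit$coefficients$beta[, k])),
    hyper = fit$hyper,
    standardize = if (is.null(fit$standardize)) NULL else
      list(center = as.numeric(fit$standardize$center),
           scale = as.numeric(fit$standardize$scale)),
    converged = fit$converged,
    iterations = fit$iterations,
    final_objective = fit$final_objective
  )
  doc <- doc[order(names(doc))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path file written by [write_fit_json()].
#' @return a `fair_fit` usable for prediction.
#' @export
read_fit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.character(doc$labels)
  beta <- if (is.matrix(doc$beta)) t(doc$beta) else
    do.call(cbind, lapply(doc$beta, as.numeric))
  rownames(beta) <- as.character(doc$feature_names)
  cs <- coef_set(beta, intercepts = as.numeric(doc$intercepts),
                 labels = labels)
  std <- NULL
  if (!is.null(doc$standardize) && length(doc$standardize))
    std <- list(center = as.numeric(doc$standardize$center),
                scale = as.numeric(doc$standardize$scale))
  structure(list(
    kind = doc$kind, coefficients = cs, labels = labels,
    feature_names = as.character(doc$feature_names),
    standardize = std, hyper = doc$hyper, shared = NULL,
    converged = isTRUE(doc$converged),
    iterations = doc$iterations,
    final_objective = doc$final_objective,
    objective_trace = NULL, diagnostics = NULL
  ), class = "fair_fit")
}
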