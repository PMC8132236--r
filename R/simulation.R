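#' Benchmark scenario specification
#'
#' Two-group synthetic designs used to benchmark the estimators. Features
#' are iid standard normal; outcomes are Bernoulli under group-specific
#' logistic models whose non-zero coefficients all equal `coef_value`;
#' intercepts are calibrated so each group's marginal event prevalence
#' hits its target. Group 1 is the over-represented group (prevalence
#' 50%), group 2 the under-represented one (prevalence 30%).
#'
#' Presets:
#' \itemize{
#'   \item scenario 1 (difference in true model): p = 100, n = (500, 200),
#'     40 non-zero coefficients per group, `shared_fraction` varied from
#'     0 to 1.
#'   \item scenario 2 (difference in sample size): p = 100, half the
#'     non-zero coefficients shared, n_1 = 500 and n_2 varied (50-300).
#'   \item scenario 3 (high dimensionality): n = (500, 200), half shared,
#'     p varied; 40 non-zero coefficients (set
#'     `nonzero_proportional = TRUE` for the variant with 40% of p
#'     non-zero at every p).
#' }
#'
#' @param scenario 1, 2 or 3.
#' @param shared_fraction fraction of each group's non-zero coefficients
#'   common to both groups.
#' @param n2 sample size of the under-represented group (scenario 2).
#' @param p feature count.
#' @param nonzero_proportional scenario-3 variant: 40% of p non-zero
#'   instead of a fixed 40.
#' @param n per-group training sample sizes (overrides the preset and
#'   `n2`).
#' @param n_nonzero non-zero coefficients per group (overrides the
#'   preset).
#' @param coef_value value taken by every non-zero coefficient.
#' @param prevalences target marginal event rates for (group 1, group 2).
#' @param test_n test-set size per group.
#' @param replicates default replicate count for [run_experiment()].
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = 1, shared_fraction = 0.5, n2 = NULL,
                          p = 100, nonzero_proportional = FALSE,
                          n = NULL, n_nonzero = NULL, coef_value = 3,
                          prevalences = c(0.5, 0.3), test_n = 1000L,
                          replicates = 20L) {
  stopifnot(scenario %in% 1:3)
  if (is.null(n_nonzero))
    n_nonzero <- if (scenario == 3 && nonzero_proportional)
      as.integer(round(0.4 * p)) else 40L
  if (is.null(n)) {
    n <- c(500L, 200L)
    if (!is.null(n2)) n[2] <- as.integer(n2)
  }
  spec <- list(
    scenario = scenario,
    p = as.integer(p),
    n = as.integer(n),
    n_nonzero = as.integer(n_nonzero),
    shared_fraction = shared_fraction,
    coef_value = coef_value,
    prevalences = prevalences,   # (over-, under-) represented groups
    test_n = as.integer(test_n),
    replicates = as.integer(replicates),
    labels = c("group1", "group2")
  )
  stopifnot(spec$shared_fraction >= 0, spec$shared_fraction <= 1,
            spec$n_nonzero <= spec$p,
            all(spec$prevalences > 0), all(spec$prevalences < 1))
  class(spec) <- "scenario_spec"
  spec
}

#' True coefficients for a two-group scenario
#'
#' Support placement is deterministic: group 1 occupies the first
#' n_nonzero coordinates; group 2 shares the first
#' round(shared_fraction * n_nonzero) of them and takes fresh coordinates
#' for the rest. Feature exchangeability under iid N(0,1) features makes
#' this equivalent to random placement while keeping the truth stable.
#' All non-zero values equal `coef_value`.
#'
#' @param spec a `scenario_spec`.
#' @return a `coef_set` (intercepts zero; calibrated later) with a
#'   `support` attribute listing each group's non-zero coordinates.
#' @export
make_coefficients <- function(spec) {
  m <- spec$n_nonzero
  s <- as.integer(round(spec$shared_fraction * m))
  need <- 2L * m - s
  if (need > spec$p)
    stop(sprintf("p = %d too small for two supports of %d sharing %d (need %d)",
                 spec$p, m, s, need))
  sup1 <- seq_len(m)
  sup2 <- c(seq_len(s), if (m > s) m + seq_len(m - s))
  beta <- matrix(0, spec$p, 2, dimnames = list(NULL, spec$labels))
  beta[sup1, 1] <- spec$coef_value
  beta[sup2, 2] <- spec$coef_value
  cs <- coef_set(beta, labels = spec$labels)
  attr(cs, "support") <- list(sup1, sup2)
  cs
}

#' Calibrate an intercept to a target marginal prevalence
#'
#' Solves E[sigmoid(b + X beta)] = target over standard-normal features.
#' Since X beta is exactly N(0, ||beta||_2^2), the expectation is
#' estimated on a fixed Monte-Carlo sample of normal draws and solved for
#' b by root finding; it is continuous and strictly increasing from 0 to
#' 1 in b, so a root always exists.
#'
#' @param beta coefficient vector of one group.
#' @param target_prev target event prevalence in (0, 1).
#' @param mc_n Monte-Carlo sample size.
#' @param seed seed for the Monte-Carlo draws.
#' @export
calibrate_intercept <- function(beta, target_prev, mc_n = 2e5, seed = 1) {
  stopifnot(target_prev > 0, target_prev < 1)
  s <- sqrt(sum(beta^2))
  if (s == 0) return(stats::qlogis(target_prev))
  z <- with_seed(as.integer(seed), stats::rnorm(mc_n)) * s
  f <- function(b) mean(sigmoid(b + z)) - target_prev
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate one train/test replicate of a scenario
#'
#' @param spec a `scenario_spec`.
#' @param seed integer replicate seed (all randomness derives from it).
#' @return list with `train` and `test` (`grouped_data`; test sizes
#'   `spec$test_n` per group) and `truth` (a `coef_set` with calibrated
#'   intercepts and a `support` attribute).
#' @export
generate_dataset <- function(spec, seed = 1) {
  truth <- make_coefficients(spec)
  for (k in 1:2)
    truth$intercepts[k] <- calibrate_intercept(truth$beta[, k],
                                               spec$prevalences[k])
  test_n <- rep_len(spec$test_n, 2)
  with_seed(as.integer(seed), {
    draw <- function(n_k) {
      xs <- list(); ys <- list()
      for (k in 1:2) {
        for (attempt in 1:2) {
          X <- matrix(stats::rnorm(n_k[k] * spec$p), n_k[k], spec$p)
          eta <- truth$intercepts[k] + drop(X %*% truth$beta[, k])
          y <- stats::rbinom(n_k[k], 1, sigmoid(eta))
          if (length(unique(y)) == 2L) break
          if (attempt == 2L)
            stop(sprintf("group %s: generated outcomes single-class twice",
                         spec$labels[k]))
        }
        xs[[spec$labels[k]]] <- X
        ys[[spec$labels[k]]] <- y
      }
      grouped_data(xs, ys)
    }
    train <- draw(spec$n)
    test <- draw(test_n)
    list(train = train, test = test, truth = truth)
  })
}

default_benchmark_grids <- function() {
  list(
    jfm = list(lambda_f = c(0, 0.3), lambda_sim = c(0.005, 0.03, 0.15),
               lambda_sp = c(0.05, 0.2)),
    sfm = list(lambda_f = c(0, 0.5), lambda_sp = c(0.002, 0.01)),
    separate = list(lambda_sp = c(0.02, 0.05, 0.2, 0.5)),
    ignorant = list(lambda_sp = c(0.002, 0.005, 0.02, 0.05))
  )
}

#' Run a replicated benchmark experiment
#'
#' For each replicate: generate train/test data, select hyperparameters
#' per estimator by cross-validation on the training set, refit on the
#' full training set, and evaluate on the test set (per-group AUC, Brier,
#' confusion rates, coefficient MSE, selection rates, AUC disparity).
#' Failed replicates are recorded and excluded from aggregation.
#'
#' @param spec a `scenario_spec`.
#' @param estimators subset of c("jfm", "sfm", "separate", "ignorant").
#' @param grids named list of per-estimator hyperparameter grids (see
#'   [cv_select()]); defaults are compact grids suitable for benchmarking.
#'   For the unweighted single fairness model, grid values are scaled by
#'   the total training sample size so the penalties match its summed
#'   (not averaged) log-likelihood.
#' @param replicates number of replicates (default from the spec).
#' @param folds cross-validation folds.
#' @param criterion selection criterion (vanilla models are selected by
#'   overall AUC; fairness-aware models by this criterion).
#' @param seed master seed; replicate r uses seed + r.
#' @param opts solver options for the final fits.
#' @param cv_opts solver options for the (cheaper) fold fits.
#' @return list with `results` (tidy data.frame: one row per replicate x
#'   estimator x group), `summary` (medians and IQRs by estimator x
#'   group), `failures`, `spec`.
#' @export
run_experiment <- function(spec, estimators = c("jfm", "sfm", "separate",
                                                "ignorant"),
                           grids = default_benchmark_grids(),
                           replicates = spec$replicates, folds = 5,
                           criterion = "group-harmonic-AUC", seed = 1,
                           opts = solver_options(max_iter = 2000, tol = 1e-6,
                                                 delta = 1e-2),
                           cv_opts = solver_options(max_iter = 600,
                                                    tol = 1e-5,
                                                    delta = 1e-2)) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  rows <- list()
  failures <- list()
  for (r in seq_len(replicates)) {
    rseed <- as.integer(seed) + r
    rep_data <- generate_dataset(spec, rseed)
    n_total <- sum(rep_data$train$n_k)
    for (est in estimators) {
      res <- tryCatch({
        gr <- grids[[est]] %||% list()
        if (est == "sfm") gr <- lapply(gr, function(v) v * n_total)
        crit <- if (est %in% c("jfm", "sfm")) criterion else "overall-AUC"
        sel <- cv_select(rep_data$train, est, gr, folds = folds,
                         criterion = crit, seed = rseed, opts = cv_opts)
        fit <- do.call(fit_at, list(rep_data$train, est, sel$best, opts))
        ev <- evaluate_fit(fit, rep_data$test, truth = rep_data$truth)
        ev$replicate <- r
        ev$estimator <- est
        ev$auc_disparity <- attr(ev, "auc_disparity")
        for (nm in names(sel$best)) ev[[nm]] <- sel$best[[nm]]
        ev
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          list(replicate = r, estimator = est, message = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, lapply(rows, function(d) {
    d[setdiff(names(d), c("lambda_f", "lambda_sim", "lambda_sp"))]
  }))
  metrics <- c("auc", "brier", "FPR", "FNR", "balanced_accuracy",
               "coef_mse", "sel_TPR", "sel_TNR", "auc_disparity")
  metrics <- intersect(metrics, names(results))
  summ <- do.call(rbind, lapply(split(results,
                                      list(results$estimator, results$group),
                                      drop = TRUE), function(d) {
    out <- data.frame(estimator = d$estimator[1], group = d$group[1],
                      n_replicates = length(unique(d$replicate)))
    for (m in metrics) {
      out[[paste0(m, "_median")]] <- stats::median(d[[m]], na.rm = TRUE)
      out[[paste0(m, "_iqr")]] <- stats::IQR(d[[m]], na.rm = TRUE)
    }
    out
  }))
  rownames(summ) <- NULL
  list(results = results, summary = summ, failures = failures, spec = spec)
}
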