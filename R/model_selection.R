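#' Stratified cross-validation folds for grouped data
#'
#' Fold assignment is stratified jointly on group and outcome class, so
#' every training split keeps both classes in every group (required for
#' the fairness penalty) and fold sizes per group x class cell differ by
#' at most one. Deterministic given `seed`.
#'
#' @param data a `grouped_data`.
#' @param folds number of folds (reduced with a warning when the smallest
#'   group x class cell has fewer members).
#' @param seed integer seed for the shuffle.
#' @return list of K integer vectors (fold id per observation within each
#'   group), with a `folds` attribute.
#' @export
stratified_group_folds <- function(data, folds = 5, seed = 1) {
  data <- validate_dataset(data)
  stopifnot(folds >= 2)
  min_cell <- min(vapply(data$groups, function(g)
    min(sum(g$y == 0), sum(g$y == 1)), numeric(1)))
  if (min_cell < 1) stop("a group lacks an outcome class")
  if (min_cell < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest group x class cell)",
                    folds, max(2, min_cell)))
    folds <- max(2, min_cell)
  }
  assign <- with_seed(as.integer(seed), {
    lapply(data$groups, function(g) {
      f <- integer(length(g$y))
      for (cls in 0:1) {
        idx <- which(g$y == cls)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    })
  })
  names(assign) <- data$labels
  attr(assign, "folds") <- folds
  assign
}

# run expr with a temporary RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# subset a grouped_data by per-group logical/integer index lists
subset_grouped <- function(data, keep) {
  xs <- list(); ys <- list()
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    xs[[g$label]] <- g$X[keep[[k]], , drop = FALSE]
    ys[[g$label]] <- g$y[keep[[k]]]
  }
  out <- grouped_data(xs, ys)
  out$standardize <- data$standardize
  out
}

#' Default hyperparameter grid
#'
#' Zero plus seven logarithmically spaced points between 1e-3 and 10.
#' @export
default_lambda_grid <- function() {
  c(0, 10^seq(-3, 1, length.out = 7))
}

fit_at <- function(data, kind, par, opts) {
  switch(kind,
    jfm = fit_jfm(data, lambda_f = par$lambda_f, lambda_sim = par$lambda_sim,
                  lambda_sp = par$lambda_sp, opts = opts),
    sfm = fit_sfm(data, lambda_f = par$lambda_f, lambda_sp = par$lambda_sp,
                  opts = opts),
    separate = fit_separate(data, lambda_sp = par$lambda_sp, opts = opts),
    ignorant = fit_ignorant(data, lambda_sp = par$lambda_sp, opts = opts),
    stop(sprintf("unknown model kind '%s'", kind)))
}

score_heldout <- function(fit, test, criterion) {
  aucs <- numeric(test$K); briers <- numeric(test$K)
  pooled_pr <- c(); pooled_y <- c()
  for (k in seq_len(test$K)) {
    g <- test$groups[[k]]
    pr <- predict(fit, g$X, g$label)
    aucs[k] <- roc_auc(pr, g$y)
    briers[k] <- brier_score(pr, g$y)
    pooled_pr <- c(pooled_pr, pr); pooled_y <- c(pooled_y, g$y)
  }
  switch(criterion,
    "group-harmonic-AUC" = harmonic_mean(aucs),
    "group-arithmetic-AUC" = mean(aucs),
    "overall-AUC" = roc_auc(pooled_pr, pooled_y),
    "group-harmonic-Brier" = -harmonic_mean(pmax(briers, 1e-12)),
    "AUC-minus-disparity" = mean(aucs) - group_disparity(aucs),
    stop(sprintf("unknown criterion '%s'", criterion)))
}

#' Cross-validated hyperparameter selection
#'
#' Grid search with stratified K-fold cross-validation. Each grid point is
#' fitted on every fold complement and scored on the held-out rows with a
#' group-aware criterion; scores are averaged over folds and the argmax is
#' returned. Ties break toward the smallest lambda_f, then lambda_sim,
#' then lambda_sp (most parsimonious fairness machinery).
#'
#' @param data a `grouped_data` training set.
#' @param kind one of "jfm", "sfm", "separate", "ignorant".
#' @param grids named list of candidate values for the hyperparameters the
#'   model kind uses (`lambda_f`, `lambda_sim`, `lambda_sp`); missing
#'   entries default to [default_lambda_grid()] (inactive ones are pinned
#'   at 0).
#' @param folds number of folds (default 5).
#' @param criterion selection criterion; default the harmonic mean of
#'   groupwise AUCs.
#' @param seed integer seed for the fold shuffle.
#' @param opts solver options used for the fold fits.
#' @return list with `best` (named hyperparameter values), `score_table`
#'   (one row per grid point with per-fold and mean scores) and `folds`.
#' @export
cv_select <- function(data, kind = c("jfm", "sfm", "separate", "ignorant"),
                      grids = list(), folds = 5,
                      criterion = "group-harmonic-AUC", seed = 1,
                      opts = solver_options(max_iter = 1000, tol = 1e-5,
                                            delta = 1e-2)) {
  kind <- match.arg(kind)
  criterion <- match.arg(criterion,
                         c("group-harmonic-AUC", "group-arithmetic-AUC",
                           "overall-AUC", "group-harmonic-Brier",
                           "AUC-minus-disparity"))
  data <- validate_dataset(data)
  active <- switch(kind,
    jfm = c("lambda_f", "lambda_sim", "lambda_sp"),
    sfm = c("lambda_f", "lambda_sp"),
    separate = "lambda_sp",
    ignorant = "lambda_sp")
  gr <- list()
  for (nm in c("lambda_sp", "lambda_sim", "lambda_f")) {
    gr[[nm]] <- if (nm %in% active)
      sort(unique(grids[[nm]] %||% default_lambda_grid())) else 0
  }
  # expand.grid varies the first column fastest; with lambda_sp first and
  # lambda_f last, row order is lexicographic in (lambda_f, lambda_sim,
  # lambda_sp), so which.max implements the tie-break.
  grid <- expand.grid(lambda_sp = gr$lambda_sp, lambda_sim = gr$lambda_sim,
                      lambda_f = gr$lambda_f, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$lambda_f, grid$lambda_sim, grid$lambda_sp), ,
               drop = FALSE]
  rownames(grid) <- NULL

  assign <- stratified_group_folds(data, folds, seed)
  folds <- attr(assign, "folds")
  scores <- matrix(NA_real_, nrow(grid), folds)
  for (i in seq_len(nrow(grid))) {
    par <- as.list(grid[i, ])
    for (f in seq_len(folds)) {
      train <- subset_grouped(data, lapply(assign, function(a) a != f))
      test <- subset_grouped(data, lapply(assign, function(a) a == f))
      sc <- tryCatch(
        score_heldout(fit_at(train, kind, par, opts), test, criterion),
        error = function(e) {
          warning(sprintf("grid point %d, fold %d failed: %s",
                          i, f, conditionMessage(e)))
          -Inf
        })
      scores[i, f] <- sc
    }
  }
  mean_score <- rowMeans(scores)
  best_i <- which.max(mean_score)
  tab <- cbind(grid, scores, mean_score = mean_score)
  names(tab)[ncol(grid) + seq_len(folds)] <- paste0("fold", seq_len(folds))
  list(best = as.list(grid[best_i, intersect(c("lambda_f", "lambda_sim",
                                               "lambda_sp"), active),
                           drop = FALSE]),
       score_table = tab, folds = folds, criterion = criterion)
}
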