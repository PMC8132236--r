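#' Grouped binary-outcome dataset
#'
#' Bundles K groups of observations that share one feature space: per group
#' a numeric feature matrix `X` (n_k x p), a binary outcome vector `y`, and
#' a group label. All estimators in the package consume this container.
#' Every group must contain both outcome classes, because the equalized-odds
#' fairness penalty is built from class-conditional feature means and is
#' undefined when a class is absent.
#'
#' @param x numeric matrix of features (n x p), or a list of K matrices.
#' @param y binary outcome vector (values coercible to 0/1), or a list of
#'   K vectors matching `x`.
#' @param group group membership vector of length n (ignored when `x` is a
#'   list; then labels come from `names(x)` or are auto-generated). Group
#'   order is first-appearance order and is kept fixed: all pairwise
#'   penalties enumerate pairs in this order.
#' @return an object of class `grouped_data`: a list with elements
#'   `groups` (list of `list(label, X, y)`), `labels`, `K`, `p`, `n_k`,
#'   `feature_names`, and optional `standardize` statistics.
#' @export
grouped_data <- function(x, y, group = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    stopifnot(is.list(y), length(x) == length(y))
    labels <- names(x)
    if (is.null(labels)) labels <- paste0("group", seq_along(x))
    xs <- lapply(x, as.matrix)
    ys <- y
  } else {
    x <- as.matrix(x)
    if (is.null(group)) stop("`group` is required when `x` is a single matrix")
    group <- as.character(group)
    if (length(group) != nrow(x) || length(y) != nrow(x))
      stop("`x`, `y` and `group` must have matching number of rows")
    labels <- unique(group)  # first-appearance order
    xs <- lapply(labels, function(g) x[group == g, , drop = FALSE])
    ys <- lapply(labels, function(g) y[group == g])
    names(xs) <- names(ys) <- labels
  }
  if (length(xs) < 2L) stop("at least K = 2 groups are required")
  all_y <- unlist(ys, use.names = FALSE)
  if (anyNA(all_y)) stop("missing values in outcome")
  lev <- sort(unique(all_y))
  if (!(all(lev %in% c(0, 1)) || length(lev) == 2L))
    stop(sprintf("outcome has %d distinct values; exactly two (or {0,1}) required",
                 length(lev)))
  ys <- lapply(ys, function(yk) {
    if (is.logical(yk) || all(lev %in% c(0, 1))) as.integer(yk)
    else as.integer(yk == lev[2])
  })
  p <- unique(vapply(xs, ncol, integer(1)))
  if (length(p) != 1L) stop("all groups must share the same feature dimension")
  if (p < 1L) stop("p = 0: at least one feature column is required")
  groups <- vector("list", length(xs))
  for (k in seq_along(xs)) {
    Xk <- xs[[k]]
    storage.mode(Xk) <- "double"
    if (anyNA(Xk)) stop(sprintf("missing values in features of group %s", labels[k]))
    yk <- ys[[k]]
    if (nrow(Xk) != length(yk))
      stop(sprintf("group %s: X has %d rows but y has %d values",
                   labels[k], nrow(Xk), length(yk)))
    for (cls in 0:1) {
      if (!any(yk == cls))
        stop(sprintf("group %s lacks outcome class %d (fairness penalty undefined)",
                     labels[k], cls))
    }
    groups[[k]] <- list(label = labels[k], X = Xk, y = yk)
  }
  fn <- colnames(xs[[1]])
  if (is.null(fn)) fn <- paste0("x", seq_len(p))
  structure(list(
    groups = groups,
    labels = labels,
    K = length(groups),
    p = as.integer(p),
    n_k = vapply(groups, function(g) nrow(g$X), integer(1)),
    feature_names = fn,
    standardize = NULL
  ), class = "grouped_data")
}

#' Validate and partition a flat table into a grouped dataset
#'
#' @param raw data.frame with feature columns, one outcome column and one
#'   group column.
#' @param outcome,group names of the outcome and group columns.
#' @param standardize if TRUE, features are centred and scaled to unit
#'   variance using pooled statistics; the statistics are stored on the
#'   returned object so that predictions can apply the same transform.
#' @return a `grouped_data` object (idempotent: passing a `grouped_data`
#'   returns it unchanged).
#' @export
validate_dataset <- function(raw, outcome = "y", group = "group",
                             standardize = FALSE) {
  if (inherits(raw, "grouped_data")) return(raw)
  raw <- as.data.frame(raw)
  for (col in c(outcome, group)) {
    if (!col %in% names(raw)) stop(sprintf("column '%s' not found", col))
    if (anyNA(raw[[col]])) stop(sprintf("missing values in column '%s'", col))
  }
  feat_cols <- setdiff(names(raw), c(outcome, group))
  feat_cols <- feat_cols[vapply(raw[feat_cols], is.numeric, logical(1))]
  if (length(feat_cols) == 0L) stop("p = 0: no numeric feature columns found")
  for (col in feat_cols) {
    if (anyNA(raw[[col]])) stop(sprintf("missing values in column '%s'", col))
  }
  X <- as.matrix(raw[feat_cols])
  std <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- scale(X, center = ctr, scale = scl)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    std <- list(center = ctr, scale = scl)
  }
  out <- grouped_data(X, raw[[outcome]], raw[[group]])
  out$standardize <- std
  out
}

#' Read a grouped dataset from CSV
#'
#' Header row is required; all numeric columns other than the outcome and
#' group columns are treated as features.
#'
#' @inheritParams validate_dataset
#' @param path path to a CSV file.
#' @export
read_grouped_csv <- function(path, outcome = "y", group = "group",
                             standardize = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(raw, outcome = outcome, group = group,
                   standardize = standardize)
}

#' @export
print.grouped_data <- function(x, ...) {
  cat(sprintf("grouped_data: K = %d groups, p = %d features, n = %d\n",
              x$K, x$p, sum(x$n_k)))
  for (k in seq_len(x$K)) {
    g <- x$groups[[k]]
    cat(sprintf("  %s: n = %d, events = %d (%.1f%%)\n", g$label,
                length(g$y), sum(g$y), 100 * mean(g$y)))
  }
  invisible(x)
}

#' Per-group coefficients with unpenalized intercepts
#'
#' Coefficient container used throughout: a p x K matrix of slopes plus a
#' length-K intercept vector. Intercepts are part of each group's linear
#' predictor (and therefore of the fairness penalty) but are never touched
#' by the sparsity or similarity penalties.
#'
#' @param beta p x K numeric matrix (one column per group) or list of K
#'   length-p vectors.
#' @param intercepts length-K numeric vector.
#' @param labels group labels (optional).
#' @export
coef_set <- function(beta, intercepts = NULL, labels = NULL) {
  if (is.list(beta)) beta <- do.call(cbind, beta)
  beta <- as.matrix(beta)
  K <- ncol(beta)
  if (is.null(intercepts)) intercepts <- numeric(K)
  stopifnot(length(intercepts) == K)
  if (is.null(labels)) labels <- colnames(beta)
  if (is.null(labels)) labels <- paste0("group", seq_len(K))
  colnames(beta) <- labels
  structure(list(beta = beta, intercepts = as.numeric(intercepts),
                 labels = labels, p = nrow(beta), K = K),
            class = "coef_set")
}

#' Stack a coefficient set into one vector
#'
#' Block order is the group order; within each block the intercept comes
#' first, then the p slopes. This is the layout every penalty operator and
#' the solver work in.
#'
#' @param cs a `coef_set`.
#' @return numeric vector of length (p + 1) * K.
#' @export
stack_coef <- function(cs) {
  as.numeric(rbind(cs$intercepts, cs$beta))
}

#' Unstack a coefficient vector into a coef_set
#'
#' Exact inverse of [stack_coef()].
#'
#' @param v stacked vector of length (p + 1) * K.
#' @param p number of features.
#' @param K number of groups.
#' @param labels optional group labels.
#' @export
unstack_coef <- function(v, p, K, labels = NULL) {
  stopifnot(length(v) == (p + 1) * K)
  m <- matrix(v, nrow = p + 1, ncol = K)
  coef_set(m[-1, , drop = FALSE], intercepts = m[1, ], labels = labels)
}

# intercept-augmented design matrix for group k
augmented_X <- function(data, k) {
  cbind(1, data$groups[[k]]$X)
}
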