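# small seeded two-group logistic datasets used across the test files

make_toy_data <- function(n = c(120, 80), p = 8, seed = 1,
                          beta = NULL, intercepts = c(0, -0.5)) {
  K <- length(n)
  if (is.null(beta)) {
    beta <- matrix(0, p, K)
    beta[1:min(3, p), 1] <- c(1.5, -1, 0.8)[1:min(3, p)]
    beta[1:min(3, p), K] <- c(1.5, 0, -0.7)[1:min(3, p)]
  }
  set.seed(seed)
  xs <- list(); ys <- list()
  labels <- LETTERS[seq_len(K)]
  for (k in seq_len(K)) {
    repeat {
      X <- matrix(rnorm(n[k] * p), n[k], p)
      y <- rbinom(n[k], 1, plogis(intercepts[k] + drop(X %*% beta[, k])))
      if (length(unique(y)) == 2) break
    }
    xs[[labels[k]]] <- X
    ys[[labels[k]]] <- y
  }
  grouped_data(xs, ys)
}

# flat data.frame version for the validators / CLI
make_toy_table <- function(n = c(30, 20), p = 3, seed = 2) {
  d <- make_toy_data(n, p, seed)
  do.call(rbind, lapply(d$groups, function(g) {
    df <- as.data.frame(g$X)
    names(df) <- paste0("x", seq_len(p))
    df$y <- g$y
    df$group <- g$label
    df
  }))
}

random_coef_set <- function(p, K, scale = 1) {
  coef_set(matrix(rnorm(p * K, sd = scale), p, K),
           intercepts = rnorm(K, sd = scale))
}
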