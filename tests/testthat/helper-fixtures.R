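# Shared fixtures, all generated in code.

# the 2x2 worked example used across the scatter and discriminant tests:
# two samples per class on a square
toy_square <- function() {
  feature_table(
    rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)),
    labels = c("a", "a", "b", "b")
  )
}

# random C-class Gaussian dataset, well-conditioned (N >> M)
random_dataset <- function(seed, n_per_class = 12, m = 5, c = 3, sep = 2) {
  withr::with_seed(seed, {
    means <- matrix(rnorm(c * m, sd = sep), c, m)
    Y <- do.call(rbind, lapply(seq_len(c), function(j) {
      matrix(rnorm(n_per_class * m), n_per_class, m) +
        matrix(means[j, ], n_per_class, m, byrow = TRUE)
    }))
    feature_table(Y, labels = rep(paste0("c", seq_len(c)), each = n_per_class))
  })
}

# random binary problem with nonsingular within-class scatter (N > M)
random_binary <- function(seed, n_per_class = 30, m = 10, sep = 2) {
  random_dataset(seed, n_per_class = n_per_class, m = m, c = 2, sep = sep)
}

# brute-force scatter matrices straight from their definitions (double loop
# over samples; independent of the package implementation)
oracle_scatter <- function(data) {
  feat <- as.matrix(data[, setdiff(names(data), c("id", "label"))])
  labs <- as.character(data$label)
  classes <- unique(labs)
  m <- ncol(feat)
  gm <- colMeans(feat)
  S_W <- matrix(0, m, m)
  S_B <- matrix(0, m, m)
  for (cl in classes) {
    rows <- feat[labs == cl, , drop = FALSE]
    mu <- colMeans(rows)
    for (i in seq_len(nrow(rows))) {
      d <- rows[i, ] - mu
      S_W <- S_W + d %o% d
    }
    e <- mu - gm
    S_B <- S_B + e %o% e
  }
  list(S_W = S_W, S_B = S_B)
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(unname(a) - unname(b))), tol)
}
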