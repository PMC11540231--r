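#' Class means and the global mean
#'
#' Computes the per-class mean feature vectors and the overall (global) mean
#' of a feature table. Classes are ordered by first appearance in the label
#' column. The global mean always equals the class means weighted by their
#' class sizes N_j / N.
#'
#' @param data a feature table (see [feature_table()]).
#' @return A tibble with one row per class: `class`, `n`, then one column per
#'   feature. The global mean is attached as attribute `"global_mean"` (a
#'   named numeric vector).
#' @examples
#' ft <- feature_table(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)),
#'                     labels = c("a", "a", "b", "b"))
#' class_means(ft)
#' @export
class_means <- function(data) {
  p <- ft_parts(data)
  cm <- matrix(0, p$c, p$m, dimnames = list(NULL, p$feature_names))
  for (j in seq_len(p$c)) {
    rows <- p$labels == (j - 1L)
    cm[j, ] <- colMeans(p$Y[rows, , drop = FALSE])
  }
  out <- tibble::as_tibble(cm)
  out <- tibble::add_column(out, class = p$classes, n = p$counts, .before = 1L)
  attr(out, "global_mean") <- colMeans(p$Y)
  out
}

#' Between- and within-class scatter matrices
#'
#' Computes, for a labelled feature table, the per-class within-class scatter
#' matrices S_Wj = sum_k (y_k^j - mean_j)(y_k^j - mean_j)^T, their sum
#' S_W, and the between-class scatter
#' S_B = sum_j (mean_j - mean)(mean_j - mean)^T (one unweighted rank-one term
#' per class, so rank(S_B) <= C - 1).
#'
#' @param data a feature table.
#' @return An object of class `"scatter_stats"`: a list with elements
#'   `S_B`, `S_W` (M x M matrices), `S_Wj` (list of C matrices),
#'   `class_means` (C x M matrix), `global_mean`, `classes`, `counts`,
#'   `n`, `m`.
#' @seealso [binary_scatter_stats()] for the two-class variant.
#' @export
scatter_stats <- function(data) {
  p <- ft_parts(data)
  gm <- colMeans(p$Y)
  S_Wj <- vector("list", p$c)
  cm <- matrix(0, p$c, p$m)
  S_W <- matrix(0, p$m, p$m)
  S_B <- matrix(0, p$m, p$m)
  for (j in seq_len(p$c)) {
    Yj <- p$Y[p$labels == (j - 1L), , drop = FALSE]
    mj <- colMeans(Yj)
    cm[j, ] <- mj
    Dj <- sweep(Yj, 2L, mj)
    S_Wj[[j]] <- crossprod(Dj)
    S_W <- S_W + S_Wj[[j]]
    dj <- mj - gm
    S_B <- S_B + tcrossprod(dj)
  }
  # enforce exact symmetry against accumulated round-off
  S_W <- (S_W + t(S_W)) / 2
  S_B <- (S_B + t(S_B)) / 2
  structure(
    list(
      S_B = S_B, S_W = S_W, S_Wj = S_Wj,
      class_means = cm, global_mean = gm,
      classes = p$classes, counts = p$counts, n = p$n, m = p$m
    ),
    class = "scatter_stats"
  )
}

#' @export
print.scatter_stats <- function(x, ...) {
  cat("Scatter statistics: ", x$n, " samples, ", x$m, " features, ",
      length(x$classes), " classes\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  tr(S_W) =", format(sum(diag(x$S_W))),
      " tr(S_B) =", format(sum(diag(x$S_B))), "\n")
  invisible(x)
}

#' Binary (two-class) scatter statistics
#'
#' For a two-class feature table, computes the mean-difference vector
#' s_b = mean_1 - mean_2, the rank-one between-class scatter
#' S~_B = s_b s_b^T, and the pooled within-class scatter
#' S~_W = beta S_W1 + (1 - beta) S_W2 with
#' beta = (N_2 - 1) / (N_1 + N_2 - 2). Class 1 is the class that appears
#' first in the label column.
#'
#' @param data a feature table with exactly two classes.
#' @return An object of class `"binary_scatter_stats"`: list with `s_b`,
#'   `S_tilde_B`, `S_tilde_W`, `beta`, `classes`, `counts`, `m`, `n`.
#' @export
binary_scatter_stats <- function(data) {
  p <- ft_parts(data)
  if (p$c != 2L) {
    stop(
      "binary scatter statistics are defined for exactly two classes; ",
      "got ", p$c, ". Use scatter_stats() for the multiclass case."
    )
  }
  Y1 <- p$Y[p$labels == 0L, , drop = FALSE]
  Y2 <- p$Y[p$labels == 1L, , drop = FALSE]
  m1 <- colMeans(Y1)
  m2 <- colMeans(Y2)
  s_b <- m1 - m2
  n1 <- nrow(Y1)
  n2 <- nrow(Y2)
  beta <- (n2 - 1) / (n1 + n2 - 2)
  SW1 <- crossprod(sweep(Y1, 2L, m1))
  SW2 <- crossprod(sweep(Y2, 2L, m2))
  S_tilde_W <- beta * SW1 + (1 - beta) * SW2
  S_tilde_W <- (S_tilde_W + t(S_tilde_W)) / 2
  structure(
    list(
      s_b = s_b, S_tilde_B = tcrossprod(s_b), S_tilde_W = S_tilde_W,
      beta = beta, classes = p$classes, counts = c(n1, n2),
      m = p$m, n = p$n
    ),
    class = "binary_scatter_stats"
  )
}

#' @export
print.binary_scatter_stats <- function(x, ...) {
  cat("Binary scatter statistics (", x$counts[1], " vs ", x$counts[2],
      " samples, ", x$m, " features)\n", sep = "")
  cat("  class 1 =", x$classes[1], " class 2 =", x$classes[2], "\n")
  cat("  beta =", format(x$beta), " |s_b| =", format(sqrt(sum(x$s_b^2))), "\n")
  invisible(x)
}

#' Fisher discriminant ratio of a direction
#'
#' Evaluates R(d) = (d^T S~_B d) / (d^T S~_W d) for a candidate projection
#' direction `d` against binary scatter statistics. The ratio is invariant to
#' rescaling of `d`.
#'
#' @param direction numeric vector of length M (need not be unit norm, but
#'   must be nonzero).
#' @param stats a [binary_scatter_stats()] object.
#' @return the scalar Fisher ratio.
#' @export
fisher_ratio <- function(direction, stats) {
  stopifnot(inherits(stats, "binary_scatter_stats"))
  d <- as.numeric(direction)
  if (length(d) != stats$m) {
    stop("direction has length ", length(d), "; expected ", stats$m, ".")
  }
  if (all(d == 0)) stop("direction must be nonzero.")
  num <- drop(crossprod(d, stats$S_tilde_B %*% d))
  den <- drop(crossprod(d, stats$S_tilde_W %*% d))
  if (den == 0) stop("direction lies in the null space of the within-class scatter.")
  num / den
}
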