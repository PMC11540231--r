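#' Run code with a temporary RNG seed (internal)
#'
#' Saves and restores .Random.seed so seeded fits never disturb the caller's
#' RNG stream.
#' @noRd
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
nmf_input_matrix <- function(data, strict = FALSE) {
  Y <- if (is.matrix(data)) {
    storage.mode(data) <- "double"
    data
  } else {
    ft_parts(data)$Y
  }
  if (anyNA(Y) || any(!is.finite(Y))) stop("input contains non-finite values.")
  n_neg <- sum(Y < 0)
  if (n_neg > 0) {
    if (strict) {
      stop("input has ", n_neg, " negative entries; NMF requires Y >= 0 ",
           "(strict = TRUE).")
    }
    message("nmf: clipping ", n_neg, " negative entries to zero.")
    Y[Y < 0] <- 0
  }
  Y
}

#' @noRd
nmf_init <- function(n, m, p, y_mean) {
  s <- sqrt(max(y_mean, .Machine$double.eps) / p)
  # entries in (0, 1] scaled so K X starts on the data's magnitude
  K <- matrix((1 - stats::runif(n * p)) * s, n, p)
  X <- matrix((1 - stats::runif(p * m)) * s, p, m)
  list(K = K, X = X)
}

NMF_EPS <- 1e-12

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix Y (N x M) as Y ~ K X with K (N x p) and
#' X (p x M) non-negative, minimizing the squared Frobenius error
#' ||Y - K X||_F^2 by the classic alternating multiplicative updates
#' K <- K * (Y X^T) / (K X X^T), X <- X * (K^T Y) / (K^T K X).
#' Denominators are guarded with a pointwise epsilon (1e-12) so zero rows or
#' columns never produce NaN. The objective is recorded after every
#' iteration and is non-increasing (to rounding).
#'
#' Negative input entries are clipped at zero with a message (penultimate
#' layer post-ReLU deep features are non-negative, so this is usually a
#' no-op); `strict = TRUE` errors instead. Initialization draws entries
#' uniformly from (0, 1] scaled by sqrt(mean(Y)/p), from `seed`; the run is
#' a pure function of `(Y, rank, n_iter, seed)`.
#'
#' @param data a feature table (feature columns used; labels ignored) or a
#'   bare non-negative numeric matrix.
#' @param rank factorization rank p, `1 <= p < min(N, M)`.
#' @param n_iter number of full update sweeps; default 3000.
#' @param seed RNG seed for the initialization.
#' @param strict error on negative entries instead of clipping.
#' @return An object of class `"nmf_fit"`: list with `basis_X` (p x M),
#'   `coeff_K` (N x p), `rank`, `objective_trace` (length `n_iter`, squared
#'   Frobenius objective), `n_iter`, `seed`, `converged_at` (first iteration
#'   whose relative improvement fell below 1e-9, for diagnostics; the run
#'   never stops early), and the training matrix `Y`.
#' @examples
#' pl <- generate_planted_nmf(n = 30, m = 20, rank = 2, seed = 1)
#' fit <- fit_nmf(pl$Y, rank = 2, n_iter = 300, seed = 1)
#' reconstruction_error(fit)
#' @export
fit_nmf <- function(data, rank, n_iter = 3000L, seed = 1L, strict = FALSE) {
  Y <- nmf_input_matrix(data, strict = strict)
  n <- nrow(Y)
  m <- ncol(Y)
  p <- as.integer(rank)
  if (p < 1L || p >= min(n, m)) {
    stop("`rank` must satisfy 1 <= p < min(N, M) = ", min(n, m), "; got ", p, ".")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("`n_iter` must be >= 1.")
  init <- with_seed_(seed, nmf_init(n, m, p, mean(Y)))
  K <- init$K
  X <- init$X
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    K <- K * (Y %*% t(X)) / (K %*% tcrossprod(X) + NMF_EPS)
    X <- X * (crossprod(K, Y)) / (crossprod(K) %*% X + NMF_EPS)
    trace[it] <- sum((Y - K %*% X)^2)
  }
  structure(
    list(
      basis_X = X, coeff_K = K, rank = p,
      objective_trace = trace, n_iter = n_iter, seed = as.integer(seed),
      converged_at = converged_iteration(trace), Y = Y
    ),
    class = "nmf_fit"
  )
}

#' @noRd
converged_iteration <- function(trace, tol = 1e-9) {
  if (length(trace) < 2L) return(NA_integer_)
  rel <- abs(diff(trace)) / pmax(trace[-length(trace)], .Machine$double.eps)
  i <- which(rel < tol)
  if (length(i)) i[1] + 1L else NA_integer_
}

#' Out-of-sample NMF coefficients
#'
#' Infers non-negative coefficients for new rows under a fitted basis X by
#' running the coefficient multiplicative update with X held fixed, from a
#' constant positive start, until the relative objective change drops below
#' `tol` or `max_iter` sweeps. This matches the training objective and code
#' path (rather than switching to an NNLS solver at test time).
#'
#' @param model an [fit_nmf()] (or the factorization of a [fit_snmf()]) fit.
#' @param data new rows: feature table or non-negative matrix, width M.
#' @param max_iter update cap (default 500).
#' @param tol relative objective-change stopping tolerance (default 1e-8).
#' @return non-negative coefficient matrix, `nrow(data)` x p.
#' @export
nmf_transform <- function(model, data, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(model, "nmf_fit"))
  Y <- nmf_input_matrix(data)
  X <- model$basis_X
  if (ncol(Y) != ncol(X)) {
    stop("data has ", ncol(Y), " features but the factorization was fitted on ",
         ncol(X), ".")
  }
  p <- nrow(X)
  XXt <- tcrossprod(X)
  c0 <- max(mean(Y), .Machine$double.eps) / max(p * mean(X), .Machine$double.eps)
  K <- matrix(c0, nrow(Y), p)
  obj <- sum((Y - K %*% X)^2)
  for (it in seq_len(max_iter)) {
    K <- K * (Y %*% t(X)) / (K %*% XXt + NMF_EPS)
    obj_new <- sum((Y - K %*% X)^2)
    if (abs(obj - obj_new) <= tol * max(obj, .Machine$double.eps)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  K
}

#' Frobenius reconstruction error of a factorization
#'
#' Returns ||Y - K X||_F, the square root of the factorization objective.
#' With `data = NULL` the stored training matrix and coefficients are used;
#' otherwise coefficients for `data` are inferred with [nmf_transform()]
#' first.
#'
#' @param model an [fit_nmf()] fit.
#' @param data optional new rows (feature table or matrix).
#' @param relative divide by ||Y||_F (default FALSE).
#' @return a scalar.
#' @export
reconstruction_error <- function(model, data = NULL, relative = FALSE) {
  stopifnot(inherits(model, "nmf_fit"))
  if (is.null(data)) {
    Y <- model$Y
    K <- model$coeff_K
  } else {
    Y <- nmf_input_matrix(data)
    if (ncol(Y) != ncol(model$basis_X)) {
      stop("data has ", ncol(Y), " features but the factorization was fitted on ",
           ncol(model$basis_X), ".")
    }
    K <- nmf_transform(model, Y)
  }
  err <- sqrt(sum((Y - K %*% model$basis_X)^2))
  if (relative) err / sqrt(sum(Y^2)) else err
}

#' Supervised NMF for binary problems
#'
#' Couples the factorization to the class labels by factorizing jointly the
#' features and a one-hot label matrix Z (N x 2):
#' min ||Y - K X||_F^2 + w ||Z - K B||_F^2 over non-negative K, X, B,
#' by multiplicative updates (the K update blends both data terms; X and B
#' keep their standard updates). The shared coefficient matrix K is thereby
#' pulled toward class-specific patterns. With `coupling_weight = 0` the
#' K and X trajectories are exactly those of plain NMF from the same seed.
#'
#' The coupling weight has no universal default — it trades reconstruction
#' against label fit and is data-scale dependent — so it must be supplied
#' explicitly.
#'
#' @param data a feature table with exactly two classes and non-negative
#'   features (negatives clipped as in [fit_nmf()]).
#' @param rank factorization rank p.
#' @param coupling_weight non-negative scalar w weighting the label term
#'   (required, no default).
#' @param n_iter update sweeps; default 3000.
#' @param seed RNG seed.
#' @param strict error on negative entries instead of clipping.
#' @return An object of class `"snmf_fit"`: list with `factorization` (an
#'   `"nmf_fit"` whose `objective_trace` is the data-fit term
#'   `||Y - KX||_F^2`), `label_basis_B` (p x 2), `coupling_weight`,
#'   `total_objective_trace` (data + weighted label term), `classes`.
#' @export
fit_snmf <- function(data, rank, coupling_weight, n_iter = 3000L, seed = 1L,
                     strict = FALSE) {
  p_parts <- ft_parts(data)
  if (p_parts$c != 2L) {
    stop("supervised NMF is restricted to binary problems; got ",
         p_parts$c, " classes.")
  }
  if (missing(coupling_weight)) {
    stop("`coupling_weight` is required and has no default; pass 0 for the ",
         "uncoupled (plain NMF) limit.")
  }
  if (!is.numeric(coupling_weight) || length(coupling_weight) != 1L ||
      coupling_weight < 0) {
    stop("`coupling_weight` must be a non-negative scalar.")
  }
  w <- as.numeric(coupling_weight)
  Y <- nmf_input_matrix(p_parts$Y, strict = strict)
  n <- nrow(Y)
  m <- ncol(Y)
  p <- as.integer(rank)
  if (p < 1L || p >= min(n, m)) {
    stop("`rank` must satisfy 1 <= p < min(N, M) = ", min(n, m), "; got ", p, ".")
  }
  n_iter <- as.integer(n_iter)
  Z <- matrix(0, n, 2L)
  Z[cbind(seq_len(n), p_parts$labels + 1L)] <- 1
  # K and X are initialized first, in the same order as plain NMF, so the
  # w = 0 limit reproduces fit_nmf() trajectories bit-for-bit
  init <- with_seed_(seed, {
    kx <- nmf_init(n, m, p, mean(Y))
    kx$B <- matrix((1 - stats::runif(p * 2L)) * sqrt(max(mean(Z), .Machine$double.eps) / p), p, 2L)
    kx
  })
  K <- init$K
  X <- init$X
  B <- init$B
  trace_data <- numeric(n_iter)
  trace_total <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    num <- Y %*% t(X) + w * (Z %*% t(B))
    den <- K %*% tcrossprod(X) + w * (K %*% tcrossprod(B)) + NMF_EPS
    K <- K * num / den
    X <- X * (crossprod(K, Y)) / (crossprod(K) %*% X + NMF_EPS)
    B <- B * (crossprod(K, Z)) / (crossprod(K) %*% B + NMF_EPS)
    trace_data[it] <- sum((Y - K %*% X)^2)
    trace_total[it] <- trace_data[it] + w * sum((Z - K %*% B)^2)
  }
  fact <- structure(
    list(
      basis_X = X, coeff_K = K, rank = p,
      objective_trace = trace_data, n_iter = n_iter, seed = as.integer(seed),
      converged_at = converged_iteration(trace_total), Y = Y
    ),
    class = "nmf_fit"
  )
  structure(
    list(
      factorization = fact, label_basis_B = B, coupling_weight = w,
      total_objective_trace = trace_total, classes = p_parts$classes
    ),
    class = "snmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("NMF factorization: ", nrow(x$coeff_K), " x ", ncol(x$basis_X),
      " matrix at rank ", x$rank, " (", x$n_iter, " iterations, seed ",
      x$seed, ")\n", sep = "")
  cat("  final objective ||Y-KX||_F^2 =",
      format(x$objective_trace[x$n_iter]), "\n")
  invisible(x)
}

#' @export
print.snmf_fit <- function(x, ...) {
  cat("Supervised NMF (binary: ", paste(x$classes, collapse = " vs "),
      "), coupling weight ", format(x$coupling_weight), "\n", sep = "")
  print(x$factorization)
  invisible(x)
}

#' @method tidy nmf_fit
#' @export
tidy.nmf_fit <- function(x, ...) {
  tibble::tibble(
    iteration = seq_len(x$n_iter),
    objective = x$objective_trace
  )
}

#' @method glance nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, n_iter = x$n_iter, seed = x$seed,
    final_objective = x$objective_trace[x$n_iter],
    reconstruction_error = sqrt(x$objective_trace[x$n_iter]),
    converged_at = x$converged_at
  )
}

#' @method tidy snmf_fit
#' @export
tidy.snmf_fit <- function(x, ...) {
  tibble::tibble(
    iteration = seq_len(x$factorization$n_iter),
    objective = x$factorization$objective_trace,
    total_objective = x$total_objective_trace
  )
}

#' @method glance snmf_fit
#' @export
glance.snmf_fit <- function(x, ...) {
  out <- glance(x$factorization)
  out$coupling_weight <- x$coupling_weight
  out
}
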