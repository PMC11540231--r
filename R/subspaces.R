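#' Fix basis-column signs for reproducibility (internal)
#'
#' Each column's largest-magnitude entry is made positive; ties resolved by
#' lowest row index (the first maximum found).
#' @noRd
fix_signs <- function(B) {
  for (k in seq_len(ncol(B))) {
    i <- which.max(abs(B[, k]))
    if (B[i, k] < 0) B[, k] <- -B[, k]
  }
  B
}

new_linear_subspace <- function(basis, spectrum, centering, method_tag, delta = NA_real_,
                                extra = list()) {
  structure(
    c(
      list(
        basis = basis, spectrum = spectrum, centering = centering,
        method_tag = method_tag, delta = delta,
        m = nrow(basis), dim = ncol(basis)
      ),
      extra
    ),
    class = "linear_subspace"
  )
}

#' Principal component (SVD) subspace
#'
#' Fits a PCA subspace to the feature columns of a training table: the data
#' matrix is centered with the training mean (optional), decomposed by SVD,
#' and the top `dim` right singular vectors retained as an orthonormal
#' projection basis. The spectrum holds the corresponding singular values in
#' non-increasing order.
#'
#' Centering uses the *training* mean only; [project()] subtracts that same
#' mean from any new data, so test rows are never used to fit the subspace.
#'
#' @param data a feature table (labels are ignored by PCA).
#' @param dim number of components to keep; must satisfy
#'   `1 <= dim <= min(N, M)`.
#' @param center center with the training mean before the SVD (default TRUE).
#'   Set FALSE for the raw-SVD variant.
#' @return a `"linear_subspace"` object with `method_tag = "pca"`.
#' @examples
#' ft <- generate_mixture(mixture_spec(n_classes = 3, n_features = 8,
#'                                     per_class_n = 20, seed = 1))
#' sub <- fit_pca(ft, dim = 2)
#' head(project(sub, ft))
#' @export
fit_pca <- function(data, dim, center = TRUE) {
  p <- ft_parts(data)
  dim <- as.integer(dim)
  if (dim < 1L || dim > min(p$n, p$m)) {
    stop("`dim` must be in 1..min(N, M) = 1..", min(p$n, p$m), "; got ", dim, ".")
  }
  mu <- if (center) colMeans(p$Y) else rep(0, p$m)
  Yc <- sweep(p$Y, 2L, mu)
  sv <- svd(Yc, nu = 0L, nv = dim)
  basis <- fix_signs(sv$v[, seq_len(dim), drop = FALSE])
  names(mu) <- p$feature_names
  rownames(basis) <- p$feature_names
  new_linear_subspace(
    basis = basis, spectrum = sv$d[seq_len(dim)],
    centering = if (center) mu else NULL, method_tag = "pca"
  )
}

#' Regularized multiclass Fisher discriminant subspace
#'
#' Solves the generalized eigenproblem S_B v = lambda (S_W + delta I) v and
#' keeps the eigenvectors of the `dim` largest eigenvalues (at most C - 1,
#' the rank bound of S_B). The ridge `delta` makes the within-class scatter
#' invertible in the small-sample regime where N < M renders S_W singular.
#'
#' Numerically, the problem is reduced to a symmetric eigenproblem via the
#' Cholesky factor of S_W + delta I (transform, symmetric eigensolve,
#' back-transform), which is mathematically identical to eigendecomposing
#' (S_W + delta I)^{-1} S_B but stable. The raw generalized eigenvectors are
#' retained in `$eigvecs` (they satisfy the eigen identity but are not
#' mutually orthogonal); the projection `$basis` is their re-orthonormalized
#' span.
#'
#' @param data a feature table with C >= 2 classes.
#' @param dim number of discriminant directions; defaults to C - 1 and may
#'   not exceed it.
#' @param delta ridge added to S_W; must be positive. Default `5e-3`.
#' @return a `"linear_subspace"` object with `method_tag = "multiclass_da"`,
#'   eigenvalues (descending) in `$spectrum`, raw unit-norm generalized
#'   eigenvectors in `$eigvecs`, and no centering.
#' @export
fit_multiclass_da <- function(data, dim = NULL, delta = 5e-3) {
  st <- scatter_stats(data)
  C <- length(st$classes)
  if (C < 2L) stop("discriminant analysis needs at least two classes.")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be a positive scalar; got ", format(delta), ".")
  }
  if (is.null(dim)) dim <- C - 1L
  dim <- as.integer(dim)
  if (dim < 1L || dim > C - 1L) {
    stop("`dim` must be in 1..C-1 = 1..", C - 1L, "; got ", dim, ".")
  }
  SWhat <- st$S_W + diag(delta, st$m)
  R <- chol(SWhat)
  # W = R^{-T} S_B R^{-1} is symmetric with the same eigenvalues
  W <- backsolve(R, t(backsolve(R, t(st$S_B), transpose = TRUE)), transpose = TRUE)
  W <- (W + t(W)) / 2
  ed <- eigen(W, symmetric = TRUE)
  idx <- seq_len(dim)
  lambda <- ed$values[idx]
  V <- backsolve(R, ed$vectors[, idx, drop = FALSE])
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  V <- fix_signs(V)
  basis <- fix_signs(qr.Q(qr(V)))
  rownames(basis) <- rownames(V) <- colnames(st$S_W) %||% NULL
  new_linear_subspace(
    basis = basis, spectrum = lambda, centering = NULL,
    method_tag = "multiclass_da", delta = delta,
    extra = list(eigvecs = V, classes = st$classes)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recursive orthogonal discriminant directions for binary problems
#'
#' Computes the Foley-Sammon basis: a sequence of mutually orthogonal
#' unit-norm directions d_1, ..., d_L, each maximizing the Fisher ratio
#' R(d) = (d^T S~_B d)/(d^T S~_W d) subject to orthogonality with all
#' earlier directions. The first direction is
#' d_1 = alpha_1 S~_W^{-1} s_b; subsequent directions come from the
#' recursion d_n = alpha_n S~_W^{-1} (s_b - D_{n-1} S_{n-1}^{-1} e_1/alpha_1)
#' where S_{n-1} is the Gram matrix with entries d_i^T S~_W^{-1} d_j.
#' Each direction carries a discrim-value gamma_n (its Fisher ratio), and
#' the sequence satisfies gamma_1 >= gamma_2 >= ... >= 0 — the discriminant
#' analogue of a singular-value spectrum.
#'
#' In the few-shot regime (N < M) S~_W is singular; a ridge delta I is then
#' added before inversion. `delta = NULL` (the default) applies the ridge
#' 5e-3 automatically when N <= M or the condition number exceeds 1e12, and
#' no ridge otherwise; an explicit `delta > 0` always applies it and
#' `delta = 0` never does.
#'
#' @param data a feature table with exactly two classes.
#' @param n_dirs number of directions L, `1 <= L <= M`.
#' @param delta ridge for S~_W (see Details); `NULL` for automatic.
#' @return An object of class `"foley_sammon"`: list with `directions`
#'   (M x L, orthonormal columns), `alphas`, `gram` (the S_L bookkeeping
#'   matrix), `discrim_values` (regularized denominator when a ridge was
#'   used), `discrim_values_raw` (raw S~_W denominator), `delta_used`,
#'   `stats` (the binary scatter statistics), `m`, `dim`.
#' @examples
#' ft <- generate_variance_trap(n_per_class = 30, n_features = 6, seed = 1)
#' fs <- fit_foley_sammon(ft, n_dirs = 3)
#' tidy(fs)
#' @export
fit_foley_sammon <- function(data, n_dirs, delta = NULL) {
  stats <- binary_scatter_stats(data)
  fit_foley_sammon_stats(stats, n_dirs = n_dirs, delta = delta)
}

#' Foley-Sammon basis from precomputed binary scatter statistics
#'
#' Workhorse behind [fit_foley_sammon()]; useful when the same scatter
#' statistics feed several fits.
#'
#' @param stats a [binary_scatter_stats()] object.
#' @inheritParams fit_foley_sammon
#' @return see [fit_foley_sammon()].
#' @export
fit_foley_sammon_stats <- function(stats, n_dirs, delta = NULL) {
  stopifnot(inherits(stats, "binary_scatter_stats"))
  L <- as.integer(n_dirs)
  M <- stats$m
  if (L < 1L || L > M) stop("`n_dirs` must be in 1..M = 1..", M, "; got ", L, ".")
  if (!is.null(delta) && (!is.numeric(delta) || delta < 0)) {
    stop("`delta` must be NULL or a non-negative scalar.")
  }
  delta_used <- resolve_binary_ridge(stats, delta)
  SWr <- stats$S_tilde_W + diag(delta_used, M)
  R <- tryCatch(chol(SWr), error = function(e) {
    stop(
      "within-class scatter is numerically singular (ridge ",
      format(delta_used), "); supply a positive `delta`."
    )
  })
  solve_sw <- function(x) backsolve(R, backsolve(R, x, transpose = TRUE))

  s_b <- stats$s_b
  D <- matrix(0, M, L)
  Q <- matrix(0, M, L) # columns: S~_W^{-1} d_i
  alphas <- numeric(L)

  u <- solve_sw(s_b)
  nu <- sqrt(sum(u^2))
  if (nu == 0) {
    # identical class means: every direction has zero Fisher ratio; the
    # basis is not defined by the recursion
    stop("class means coincide (s_b = 0); discriminant directions are undefined.")
  }
  alphas[1] <- 1 / nu
  D[, 1] <- u / nu
  Q[, 1] <- solve_sw(D[, 1])

  if (L > 1L) {
    for (n in 2:L) {
      Sn1 <- crossprod(D[, 1:(n - 1), drop = FALSE], Q[, 1:(n - 1), drop = FALSE])
      Sn1 <- (Sn1 + t(Sn1)) / 2
      e1 <- c(1 / alphas[1], rep(0, n - 2))
      coef <- tryCatch(solve(Sn1, e1), error = function(e) {
        stop("Gram matrix S_", n - 1, " is numerically singular at step n = ", n, ".")
      })
      rhs <- s_b - D[, 1:(n - 1), drop = FALSE] %*% coef
      u <- drop(solve_sw(rhs))
      # in exact arithmetic u is already orthogonal to d_1..d_{n-1}; two
      # Gram-Schmidt sweeps strip the round-off the recursion accumulates
      Dprev <- D[, 1:(n - 1), drop = FALSE]
      for (sweep_i in 1:2) u <- u - Dprev %*% crossprod(Dprev, u)
      nu <- sqrt(sum(u^2))
      if (!is.finite(nu) || nu < .Machine$double.eps * 1e4) {
        stop("no further discriminant direction recoverable at step n = ", n, ".")
      }
      alphas[n] <- 1 / nu
      dn <- drop(u / nu)
      # sign convention: largest-magnitude entry positive (d_1 keeps the sign
      # the normalizing constant alpha_1 > 0 induces; flipping later
      # directions does not perturb the recursion)
      i <- which.max(abs(dn))
      if (dn[i] < 0) dn <- -dn
      D[, n] <- dn
      Q[, n] <- solve_sw(dn)
    }
  }
  gram <- crossprod(D, Q)
  gram <- (gram + t(gram)) / 2
  num <- drop(crossprod(D, s_b))^2 # d^T S~_B d = (d . s_b)^2
  den_reg <- colSums(D * (SWr %*% D))
  den_raw <- colSums(D * (stats$S_tilde_W %*% D))
  structure(
    list(
      directions = D, alphas = alphas, gram = gram,
      discrim_values = num / den_reg,
      discrim_values_raw = ifelse(den_raw > 0, num / den_raw, NA_real_),
      delta_used = delta_used, stats = stats, m = M, dim = L,
      method_tag = "foley_sammon"
    ),
    class = "foley_sammon"
  )
}

#' @noRd
resolve_binary_ridge <- function(stats, delta, default_ridge = 5e-3,
                                 cond_limit = 1e12) {
  if (!is.null(delta)) return(as.numeric(delta))
  if (stats$n <= stats$m) return(default_ridge)
  ev <- eigen(stats$S_tilde_W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_limit) default_ridge else 0
}

#' Discrim-values of a Foley-Sammon basis
#'
#' Evaluates gamma_n = (d_n^T S~_B d_n) / (d_n^T S~_W d_n) for every stored
#' direction against (possibly new) binary scatter statistics. When the
#' basis was fitted with a ridge, the denominator is regularized the same
#' way by default; `regularized = FALSE` uses the raw within-class scatter.
#'
#' @param basis a [fit_foley_sammon()] object.
#' @param stats a [binary_scatter_stats()] object on the same feature space.
#' @param regularized use the `delta_used` ridge in the denominator
#'   (default TRUE).
#' @return numeric vector of length L, non-increasing.
#' @export
discrim_values <- function(basis, stats, regularized = TRUE) {
  stopifnot(inherits(basis, "foley_sammon"), inherits(stats, "binary_scatter_stats"))
  if (basis$m != stats$m) {
    stop("basis has ", basis$m, " features but stats has ", stats$m, ".")
  }
  D <- basis$directions
  num <- drop(crossprod(D, stats$s_b))^2
  SW <- stats$S_tilde_W
  if (regularized && basis$delta_used > 0) {
    SW <- SW + diag(basis$delta_used, stats$m)
  }
  den <- colSums(D * (SW %*% D))
  if (any(den == 0)) {
    stop("zero within-class denominator; refit with a positive `delta`.")
  }
  num / den
}

#' Project feature rows onto a fitted subspace
#'
#' Applies a fitted projection to the feature columns of a table: PCA
#' subspaces first subtract the training mean stored at fit time;
#' discriminant subspaces apply no centering. The `id` and `label` columns,
#' when present, are carried through so the result is itself a valid feature
#' table in the reduced space.
#'
#' @param object a `"linear_subspace"` or `"foley_sammon"` fit.
#' @param data a feature table (or bare numeric matrix) whose feature width
#'   matches the training space.
#' @param ... unused.
#' @return a tibble with the carried-over `id`/`label` columns and one
#'   numeric column per retained direction (`pc1..`, `ld1..` or `fs1..`).
#' @export
project <- function(object, data, ...) UseMethod("project")

#' @noRd
project_matrix <- function(object, Y) {
  if (ncol(Y) != object$m) {
    stop("data has ", ncol(Y), " features but the subspace was fitted on ",
         object$m, ".")
  }
  if (inherits(object, "foley_sammon")) {
    return(Y %*% object$directions)
  }
  if (!is.null(object$centering)) Y <- sweep(Y, 2L, object$centering)
  Y %*% object$basis
}

#' @noRd
projection_prefix <- function(object) {
  switch(object$method_tag,
    pca = "pc", multiclass_da = "ld", foley_sammon = "fs", "s"
  )
}

#' @rdname project
#' @export
project.linear_subspace <- function(object, data, ...) {
  project_impl(object, data)
}

#' @rdname project
#' @export
project.foley_sammon <- function(object, data, ...) {
  project_impl(object, data)
}

#' @noRd
project_impl <- function(object, data) {
  if (is.matrix(data)) {
    Z <- project_matrix(object, data)
    colnames(Z) <- paste0(projection_prefix(object), seq_len(ncol(Z)))
    return(tibble::as_tibble(Z))
  }
  p <- ft_parts(data)
  Z <- project_matrix(object, p$Y)
  colnames(Z) <- paste0(projection_prefix(object), seq_len(ncol(Z)))
  out <- tibble::as_tibble(Z)
  if ("label" %in% names(data)) out <- tibble::add_column(out, label = as.character(data$label), .before = 1L)
  if ("id" %in% names(data)) out <- tibble::add_column(out, id = as.character(data$id), .before = 1L)
  out
}

#' @export
print.linear_subspace <- function(x, ...) {
  cat("Linear subspace [", x$method_tag, "]: ", x$m, " features -> ",
      x$dim, " dimensions\n", sep = "")
  if (!is.na(x$delta)) cat("  ridge delta =", format(x$delta), "\n")
  cat("  spectrum:", paste(signif(x$spectrum, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.foley_sammon <- function(x, ...) {
  cat("Foley-Sammon discriminant basis: ", x$m, " features -> ", x$dim,
      " orthogonal directions (ridge ", format(x$delta_used), ")\n", sep = "")
  cat("  discrim-values:", paste(signif(x$discrim_values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy linear_subspace
#' @export
tidy.linear_subspace <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$dim),
    value = x$spectrum,
    kind = if (x$method_tag == "pca") "singular_value" else "eigenvalue"
  )
}

#' @method glance linear_subspace
#' @export
glance.linear_subspace <- function(x, ...) {
  tibble::tibble(
    method = x$method_tag, n_features = x$m, dim = x$dim,
    delta = x$delta, centered = !is.null(x$centering)
  )
}

#' @method tidy foley_sammon
#' @export
tidy.foley_sammon <- function(x, ...) {
  tibble::tibble(
    direction = seq_len(x$dim),
    alpha = x$alphas,
    discrim_value = x$discrim_values,
    discrim_value_raw = x$discrim_values_raw
  )
}

#' @method glance foley_sammon
#' @export
glance.foley_sammon <- function(x, ...) {
  tibble::tibble(
    method = "foley_sammon", n_features = x$m, dim = x$dim,
    delta_used = x$delta_used,
    leading_discrim_value = x$discrim_values[1]
  )
}
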