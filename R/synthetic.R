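#' Specification for a class-structured Gaussian mixture
#'
#' Describes a synthetic feature table emulating penultimate-layer deep
#' features: one Gaussian mode per class with per-coordinate spreads drawn
#' once per spec from a long-tailed (log-normal) distribution, mimicking the
#' heterogeneous activation scales of post-ReLU features. Generation is a
#' pure function of the spec (identical spec, identical table).
#'
#' @param n_classes number of classes C.
#' @param n_features feature dimension M; default 512, the width of the
#'   penultimate layer of the common ResNet18 extractor.
#' @param per_class_n samples per class (scalar or length-C vector).
#' @param class_means optional C x M matrix of mode centres; drawn
#'   N(0, mean_spread^2) from the seed when omitted.
#' @param mean_spread spread of auto-drawn class means; default 1.
#' @param within_scales optional length-M positive vector of per-coordinate
#'   standard deviations; drawn log-normal(0, 0.75) when omitted.
#' @param nonneg rectify negative entries at zero (post-ReLU emulation).
#' @param seed RNG seed.
#' @return an object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(n_classes, n_features = 512L, per_class_n,
                         class_means = NULL, mean_spread = 1,
                         within_scales = NULL, nonneg = FALSE, seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_features <- as.integer(n_features)
  if (n_classes < 1L) stop("`n_classes` must be >= 1.")
  if (n_features < 1L) stop("`n_features` must be >= 1.")
  per_class_n <- as.integer(per_class_n)
  if (length(per_class_n) == 1L) per_class_n <- rep(per_class_n, n_classes)
  if (length(per_class_n) != n_classes || any(per_class_n < 1L)) {
    stop("`per_class_n` must be a positive scalar or length-C vector.")
  }
  if (!is.null(class_means)) {
    class_means <- as.matrix(class_means)
    if (nrow(class_means) != n_classes || ncol(class_means) != n_features) {
      stop("`class_means` must be ", n_classes, " x ", n_features,
           "; got ", nrow(class_means), " x ", ncol(class_means), ".")
    }
  }
  if (!is.null(within_scales)) {
    within_scales <- as.numeric(within_scales)
    if (length(within_scales) == 1L) within_scales <- rep(within_scales, n_features)
    if (length(within_scales) != n_features || any(within_scales <= 0)) {
      stop("`within_scales` must be positive, length 1 or M.")
    }
  }
  structure(
    list(
      n_classes = n_classes, n_features = n_features,
      per_class_n = per_class_n, class_means = class_means,
      mean_spread = mean_spread, within_scales = within_scales,
      nonneg = isTRUE(nonneg), seed = as.integer(seed)
    ),
    class = "mixture_spec"
  )
}

#' Generate a Gaussian-mixture feature table
#'
#' Draws rows class-wise from the Gaussians a [mixture_spec()] describes,
#' in class order, and returns a validated feature table with labels
#' `class_1 .. class_C`.
#'
#' @param spec a [mixture_spec()], or arguments forwarded to it.
#' @param ... forwarded to [mixture_spec()] when `spec` is not already one.
#' @return a feature table tibble.
#' @examples
#' ft <- generate_mixture(mixture_spec(n_classes = 2, n_features = 16,
#'                                     per_class_n = 30, seed = 7))
#' dplyr::count(ft, label)
#' @export
generate_mixture <- function(spec, ...) {
  if (missing(spec)) {
    spec <- mixture_spec(...)
  } else if (!inherits(spec, "mixture_spec")) {
    spec <- mixture_spec(spec, ...)
  }
  with_seed_(spec$seed, {
    scales <- spec$within_scales %||%
      stats::rlnorm(spec$n_features, meanlog = 0, sdlog = 0.75)
    means <- spec$class_means %||%
      matrix(stats::rnorm(spec$n_classes * spec$n_features, sd = spec$mean_spread),
             spec$n_classes, spec$n_features)
    blocks <- vector("list", spec$n_classes)
    for (j in seq_len(spec$n_classes)) {
      nj <- spec$per_class_n[j]
      E <- matrix(stats::rnorm(nj * spec$n_features), nj, spec$n_features)
      blocks[[j]] <- sweep(E, 2L, scales, "*") +
        matrix(means[j, ], nj, spec$n_features, byrow = TRUE)
    }
    Y <- do.call(rbind, blocks)
    if (spec$nonneg) Y[Y < 0] <- 0
    labels <- rep(paste0("class_", seq_len(spec$n_classes)), spec$per_class_n)
    feature_table(Y, labels)
  })
}

#' Generate a variance-trap binary mixture
#'
#' An adversarial benchmark for variance-preserving dimensionality
#' reduction: the two class means differ by `signal_gap` only along the
#' *last* coordinate, whose total variance is small, while the first M - 1
#' coordinates carry large class-independent noise. The leading principal
#' component of the pooled sample therefore aligns with a nuisance
#' coordinate and is near-orthogonal to the true discriminant direction
#' (the last basis vector), so a 1-D PCA projection discards the class
#' signal that a 1-D discriminant projection retains.
#'
#' The generator refuses specs in which the signal coordinate's total
#' variance (signal_gap^2 / 4 + signal_sd^2) is not strictly below the
#' nuisance variance, since the construction would then not trap PCA.
#'
#' @param n_per_class samples per class; default 60.
#' @param n_features total dimension M >= 2; default 10.
#' @param signal_gap distance between class means on the last coordinate;
#'   default 2.
#' @param signal_sd within-class spread on the last coordinate; default 0.5.
#' @param nuisance_sd spread of the class-independent coordinates; default 5.
#' @param seed RNG seed.
#' @return a feature table with classes `"case"` and `"control"`.
#' @export
generate_variance_trap <- function(n_per_class = 60L, n_features = 10L,
                                   signal_gap = 2, signal_sd = 0.5,
                                   nuisance_sd = 5, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  n_features <- as.integer(n_features)
  if (n_features < 2L) stop("`n_features` must be >= 2.")
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1.")
  signal_var <- signal_gap^2 / 4 + signal_sd^2
  nuisance_var <- nuisance_sd^2
  if (signal_var >= nuisance_var) {
    stop(
      "signal coordinate variance (", format(signal_var),
      ") must be strictly below the nuisance variance (",
      format(nuisance_var), ") for the trap to hold."
    )
  }
  with_seed_(seed, {
    n <- 2L * n_per_class
    Y <- matrix(stats::rnorm(n * n_features, sd = nuisance_sd), n, n_features)
    signal_mean <- rep(c(signal_gap / 2, -signal_gap / 2), each = n_per_class)
    Y[, n_features] <- signal_mean + stats::rnorm(n, sd = signal_sd)
    labels <- rep(c("case", "control"), each = n_per_class)
    feature_table(Y, labels)
  })
}

#' Specification for a planted low-rank non-negative matrix
#'
#' @param n,m matrix size N x M.
#' @param rank planted rank p* < min(N, M).
#' @param factor_sparsity probability in [0, 1) that a factor entry is
#'   zeroed; default 0.3.
#' @param noise_scale scale of additive rectified Gaussian noise; default 0
#'   (exactly representable instance).
#' @param seed RNG seed.
#' @return an object of class `"planted_nmf_spec"`.
#' @export
planted_nmf_spec <- function(n, m, rank, factor_sparsity = 0.3,
                             noise_scale = 0, seed = 1L) {
  n <- as.integer(n)
  m <- as.integer(m)
  rank <- as.integer(rank)
  if (rank < 1L || rank >= min(n, m)) {
    stop("`rank` must satisfy 1 <= p* < min(N, M) = ", min(n, m), ".")
  }
  if (factor_sparsity < 0 || factor_sparsity >= 1) {
    stop("`factor_sparsity` must be in [0, 1).")
  }
  if (noise_scale < 0) stop("`noise_scale` must be >= 0.")
  structure(
    list(
      n = n, m = m, rank = rank, factor_sparsity = factor_sparsity,
      noise_scale = noise_scale, seed = as.integer(seed)
    ),
    class = "planted_nmf_spec"
  )
}

#' Generate a planted low-rank non-negative matrix
#'
#' Builds Y = K* X* + rectified noise with non-negative ground-truth factors
#' (entries uniform on (0.2, 1], a `factor_sparsity` fraction zeroed, and
#' every row of K* / column of X* guaranteed at least one positive entry so
#' the planted rank is genuine). The ground truth is returned for recovery
#' experiments.
#'
#' @param spec a [planted_nmf_spec()], or arguments forwarded to it.
#' @param ... forwarded to [planted_nmf_spec()] when `spec` is not one.
#' @return list with `Y` (N x M, all entries >= 0), `K_true` (N x p*),
#'   `X_true` (p* x M), and the `spec`.
#' @export
generate_planted_nmf <- function(spec, ...) {
  if (missing(spec)) {
    spec <- planted_nmf_spec(...)
  } else if (!inherits(spec, "planted_nmf_spec")) {
    spec <- planted_nmf_spec(spec, ...)
  }
  with_seed_(spec$seed, {
    draw_factor <- function(nr, nc) {
      F <- matrix(0.2 + 0.8 * stats::runif(nr * nc), nr, nc)
      mask <- matrix(stats::runif(nr * nc) < spec$factor_sparsity, nr, nc)
      F[mask] <- 0
      # keep the planted rank genuine: no all-zero row or column
      for (i in seq_len(nr)) if (all(F[i, ] == 0)) F[i, sample.int(nc, 1L)] <- 0.5
      for (j in seq_len(nc)) if (all(F[, j] == 0)) F[sample.int(nr, 1L), j] <- 0.5
      F
    }
    K <- draw_factor(spec$n, spec$rank)
    X <- draw_factor(spec$rank, spec$m)
    Y <- K %*% X
    if (spec$noise_scale > 0) {
      Y <- Y + pmax(matrix(stats::rnorm(spec$n * spec$m, sd = spec$noise_scale),
                           spec$n, spec$m), 0)
    }
    list(Y = Y, K_true = K, X_true = X, spec = spec)
  })
}
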