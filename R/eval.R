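#' Draw one few-shot episode (per-class train/test split)
#'
#' Samples, for every class independently and without replacement,
#' `per_class_train` training rows and `per_class_test` disjoint test rows
#' (the Table-style split convention: e.g. an 8-class problem at 75/25 per
#' class yields 600 training and 200 test rows). Sampling is a pure
#' function of `seed`.
#'
#' @param data a feature table.
#' @param per_class_train,per_class_test positive per-class counts.
#' @param seed RNG seed for the draw.
#' @return An object of class `"episode_split"`: list with integer
#'   `train_indices`, `test_indices` (row positions in `data`, disjoint),
#'   `per_class_train`, `per_class_test`, `seed`.
#' @export
make_episode <- function(data, per_class_train, per_class_test, seed) {
  p <- ft_parts(data)
  per_class_train <- as.integer(per_class_train)
  per_class_test <- as.integer(per_class_test)
  if (per_class_train < 1L) stop("`per_class_train` must be >= 1.")
  if (per_class_test < 1L) stop("`per_class_test` must be >= 1.")
  need <- per_class_train + per_class_test
  train <- integer(0)
  test <- integer(0)
  with_seed_(seed, {
    for (j in seq_len(p$c)) {
      rows <- which(p$labels == (j - 1L))
      if (length(rows) < need) {
        stop(
          "class `", p$classes[j], "` has ", length(rows),
          " rows but the episode needs ", need,
          " (", per_class_train, " train + ", per_class_test, " test)."
        )
      }
      pick <- sample(rows, need, replace = FALSE)
      train <- c(train, pick[seq_len(per_class_train)])
      test <- c(test, pick[per_class_train + seq_len(per_class_test)])
    }
  })
  structure(
    list(
      train_indices = sort(train), test_indices = sort(test),
      per_class_train = per_class_train, per_class_test = per_class_test,
      seed = as.integer(seed)
    ),
    class = "episode_split"
  )
}

#' @export
print.episode_split <- function(x, ...) {
  cat("Episode split (seed ", x$seed, "): ", length(x$train_indices),
      " train / ", length(x$test_indices), " test rows (",
      x$per_class_train, "/", x$per_class_test, " per class)\n", sep = "")
  invisible(x)
}

#' K-nearest-neighbour classification accuracy
#'
#' Fraction of test rows whose majority label among the K nearest training
#' rows (Euclidean distance) matches the true label. Fully deterministic:
#' equidistant neighbours are ordered by training-row index, and tied
#' majority votes are broken by the nearest neighbour belonging to a tied
#' class, then by lowest class index (class order = first appearance in the
#' training labels).
#'
#' @param train_proj,test_proj numeric matrices (or data frames of numeric
#'   columns) with matching widths.
#' @param train_labels,test_labels label vectors.
#' @param k neighbourhood size, `1 <= k <= nrow(train_proj)`.
#' @return accuracy in [0, 1].
#' @export
knn_accuracy <- function(train_proj, train_labels, test_proj, test_labels, k) {
  pred <- knn_predict(train_proj, train_labels, test_proj, k)
  mean(pred == as.character(test_labels))
}

#' @noRd
knn_predict <- function(train_proj, train_labels, test_proj, k) {
  Xtr <- as.matrix(train_proj)
  Xte <- as.matrix(test_proj)
  storage.mode(Xtr) <- storage.mode(Xte) <- "double"
  if (ncol(Xtr) != ncol(Xte)) {
    stop("train and test feature widths differ (", ncol(Xtr), " vs ",
         ncol(Xte), ").")
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(Xtr)) {
    stop("`k` must be in 1..", nrow(Xtr), " (training size); got ", k, ".")
  }
  labs <- as.character(train_labels)
  if (length(labs) != nrow(Xtr)) stop("one training label per training row required.")
  classes <- unique(labs)
  lab_idx <- match(labs, classes)
  # squared Euclidean cross-distances, double precision throughout
  d2 <- outer(rowSums(Xtr^2), rep(1, nrow(Xte))) -
    2 * tcrossprod(Xtr, Xte) +
    outer(rep(1, nrow(Xtr)), rowSums(Xte^2))
  pred <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    ord <- order(d2[, i]) # stable: distance ties fall back to row index
    nb <- lab_idx[ord[seq_len(k)]]
    votes <- tabulate(nb, nbins = length(classes))
    tied <- which(votes == max(votes))
    if (length(tied) == 1L) {
      pred[i] <- classes[tied]
    } else {
      # nearest neighbour among the tied classes decides; every tied class
      # has at least one vote so a hit always exists, and were several ties
      # to coincide the lowest class index (earliest in `nb`) prevails
      first_hit <- nb[nb %in% tied][1]
      pred[i] <- classes[first_hit]
    }
  }
  pred
}

#' Evaluation configuration for the few-shot protocol
#'
#' Bundles the protocol constants: neighbourhood sizes K in {1, 5, 10, 15}
#' averaged by the KNN classifier, 10 repeated random per-class samplings,
#' ridge delta = 5e-3 for the discriminant subspaces, 3000 multiplicative
#' updates for NMF/SNMF, subspace dimension defaulting to C - 1 for
#' multiclass discriminant analysis and 30 for PCA/NMF/SNMF.
#'
#' @param method one of `"feature_space"`, `"pca"`, `"multiclass_da"`,
#'   `"foley_sammon"`, `"nmf"`, `"snmf"`.
#' @param per_class_train,per_class_test per-class episode counts.
#' @param dim subspace dimension; `NULL` resolves to the method default
#'   (C - 1 for `multiclass_da`/`foley_sammon`, 30 for `pca`/`nmf`/`snmf`,
#'   ignored for `feature_space`).
#' @param knn_k KNN neighbourhood sizes to average; default `c(1, 5, 10, 15)`.
#' @param n_repeats number of random samplings; default 10.
#' @param delta discriminant ridge; default 5e-3.
#' @param nmf_iters NMF/SNMF update sweeps; default 3000.
#' @param classifier `"knn"` (default) or `"svm"` (radial-kernel
#'   [e1071::svm()], fixed seed).
#' @param coupling_weight SNMF label-coupling weight; required when
#'   `method = "snmf"`.
#' @param master_seed base seed; repeat r uses `master_seed + r`.
#' @param center_pca center PCA with the training mean (default TRUE).
#' @return an object of class `"eval_config"` (a validated list).
#' @export
eval_config <- function(method = "feature_space",
                        per_class_train, per_class_test,
                        dim = NULL,
                        knn_k = c(1L, 5L, 10L, 15L),
                        n_repeats = 10L,
                        delta = 5e-3,
                        nmf_iters = 3000L,
                        classifier = c("knn", "svm"),
                        coupling_weight = NULL,
                        master_seed = 1L,
                        center_pca = TRUE) {
  method <- match.arg(
    method,
    c("feature_space", "pca", "multiclass_da", "foley_sammon", "nmf", "snmf")
  )
  classifier <- match.arg(classifier)
  knn_k <- as.integer(knn_k)
  if (length(knn_k) < 1L || any(knn_k < 1L)) stop("`knn_k` must be positive integers.")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1.")
  if (delta <= 0) stop("`delta` must be positive.")
  if (as.integer(nmf_iters) < 1L) stop("`nmf_iters` must be >= 1.")
  if (method == "snmf" && is.null(coupling_weight)) {
    stop("`coupling_weight` is required for method = \"snmf\" (no default).")
  }
  structure(
    list(
      method = method, dim = if (is.null(dim)) NULL else as.integer(dim),
      per_class_train = as.integer(per_class_train),
      per_class_test = as.integer(per_class_test),
      knn_k = knn_k, n_repeats = n_repeats, delta = delta,
      nmf_iters = as.integer(nmf_iters), classifier = classifier,
      coupling_weight = coupling_weight,
      master_seed = as.integer(master_seed), center_pca = isTRUE(center_pca)
    ),
    class = "eval_config"
  )
}

#' @export
print.eval_config <- function(x, ...) {
  cat("Few-shot evaluation config\n")
  cat("  method:", x$method, " dim:",
      if (is.null(x$dim)) "(method default)" else x$dim, "\n")
  cat("  episode:", x$per_class_train, "train /", x$per_class_test,
      "test per class,", x$n_repeats, "repeats (master seed",
      x$master_seed, ")\n")
  cat("  classifier:", x$classifier,
      if (x$classifier == "knn") paste0("K = {", paste(x$knn_k, collapse = ", "), "}"),
      "\n")
  cat("  delta:", format(x$delta), " nmf_iters:", x$nmf_iters, "\n")
  invisible(x)
}

#' @noRd
resolve_dim <- function(config, n_classes) {
  if (!is.null(config$dim)) return(config$dim)
  switch(config$method,
    feature_space = NA_integer_,
    multiclass_da = n_classes - 1L,
    foley_sammon = 1L,
    30L
  )
}

#' @noRd
fit_subspace_for <- function(config, train, dim, repeat_seed) {
  switch(config$method,
    feature_space = NULL,
    pca = fit_pca(train, dim = dim, center = config$center_pca),
    multiclass_da = fit_multiclass_da(train, dim = dim, delta = config$delta),
    foley_sammon = fit_foley_sammon(train, n_dirs = dim, delta = config$delta),
    nmf = fit_nmf(train, rank = dim, n_iter = config$nmf_iters, seed = repeat_seed),
    snmf = fit_snmf(train,
      rank = dim, coupling_weight = config$coupling_weight,
      n_iter = config$nmf_iters, seed = repeat_seed
    )
  )
}

#' @noRd
project_for <- function(config, fit, data) {
  if (is.null(fit)) return(as.matrix(ft_parts(data)$Y))
  if (inherits(fit, "snmf_fit")) fit <- fit$factorization
  if (inherits(fit, "nmf_fit")) {
    return(nmf_transform(fit, nmf_input_matrix(ft_parts(data)$Y)))
  }
  project_matrix(fit, ft_parts(data)$Y)
}

#' Run the full few-shot evaluation protocol
#'
#' For each repeat r = 1..n_repeats: draw an episode with seed
#' `master_seed + r`, fit the configured subspace on the *training* episode
#' only, project both splits, and score the classifier. With KNN the
#' accuracy is computed for every K in `knn_k` and the per-repeat summary is
#' the mean over K; the reported `mean_accuracy` and `sd_accuracy` are then
#' the mean and (n-1)-denominator standard deviation of those per-repeat
#' summaries. The per-repeat, per-K table is retained for finer analysis,
#' and `sd_accuracy_pooled` additionally pools K-level variation.
#'
#' @param data a feature table.
#' @param config an [eval_config()].
#' @return An object of class `"eval_report"`: list with `accuracy` (tibble:
#'   `repeat_id`, `k`, `accuracy`), `per_repeat` (K-averaged accuracies),
#'   `mean_accuracy`, `sd_accuracy`, `sd_accuracy_pooled`, `config`,
#'   `n_classes`.
#' @examples
#' ft <- generate_variance_trap(n_per_class = 40, n_features = 6, seed = 1)
#' cfg <- eval_config(method = "multiclass_da", dim = 1,
#'                    per_class_train = 25, per_class_test = 15,
#'                    n_repeats = 3)
#' rep <- evaluate_pipeline(ft, cfg)
#' glance(rep)
#' @export
evaluate_pipeline <- function(data, config) {
  stopifnot(inherits(config, "eval_config"))
  p <- ft_parts(data)
  dim <- resolve_dim(config, p$c)
  rows <- list()
  per_repeat <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    repeat_seed <- config$master_seed + r
    res <- tryCatch(
      evaluate_one_repeat(data, config, dim, repeat_seed),
      error = function(e) {
        stop("repeat ", r, " (seed ", repeat_seed, "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
    rows[[r]] <- tibble::tibble(
      repeat_id = r, k = res$k, accuracy = res$accuracy
    )
    per_repeat[r] <- mean(res$accuracy)
  }
  acc <- dplyr::bind_rows(rows)
  structure(
    list(
      accuracy = acc,
      per_repeat = per_repeat,
      mean_accuracy = mean(per_repeat),
      sd_accuracy = stats::sd(per_repeat),
      sd_accuracy_pooled = stats::sd(acc$accuracy),
      config = config,
      n_classes = p$c,
      dim_used = dim
    ),
    class = "eval_report"
  )
}

#' @noRd
evaluate_one_repeat <- function(data, config, dim, repeat_seed) {
  ep <- make_episode(data, config$per_class_train, config$per_class_test,
                     seed = repeat_seed)
  train <- data[ep$train_indices, , drop = FALSE]
  test <- data[ep$test_indices, , drop = FALSE]
  fit <- fit_subspace_for(config, train, dim, repeat_seed)
  Ztr <- project_for(config, fit, train)
  Zte <- project_for(config, fit, test)
  ytr <- as.character(train$label)
  yte <- as.character(test$label)
  if (config$classifier == "svm") {
    m <- with_seed_(repeat_seed, e1071::svm(
      x = Ztr, y = factor(ytr), kernel = "radial", scale = FALSE
    ))
    acc <- mean(as.character(stats::predict(m, Zte)) == yte)
    list(k = NA_integer_, accuracy = acc)
  } else {
    ks <- config$knn_k
    acc <- vapply(ks, function(k) {
      knn_accuracy(Ztr, ytr, Zte, yte, k = k)
    }, numeric(1))
    list(k = ks, accuracy = acc)
  }
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Few-shot evaluation [", x$config$method, ", dim ",
      ifelse(is.na(x$dim_used), "-", x$dim_used), ", ", x$config$classifier,
      "]\n", sep = "")
  cat("  accuracy: ", sprintf("%.4f +/- %.4f", x$mean_accuracy, x$sd_accuracy),
      " over ", x$config$n_repeats, " repeats", sep = "")
  if (x$config$classifier == "knn") {
    cat(" (K averaged over ", paste(x$config$knn_k, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$accuracy

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    method = x$config$method,
    classifier = x$config$classifier,
    dim = x$dim_used,
    n_repeats = x$config$n_repeats,
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = x$sd_accuracy,
    sd_accuracy_pooled = x$sd_accuracy_pooled
  )
}

#' Two-sample Z-test on per-repeat accuracies
#'
#' Compares the mean per-repeat accuracy of two evaluation arms with a
#' two-sided Z-test using the standard error
#' sqrt(s_a^2 / n_a + s_b^2 / n_b) of the repeat-level accuracies. When both
#' arms are constant and equal, z = 0 and p = 1 by convention.
#'
#' @param acc_a,acc_b numeric vectors of per-repeat accuracies (length >= 2),
#'   or `"eval_report"` objects (their K-averaged per-repeat accuracies are
#'   used).
#' @return a one-row tibble: `z_statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
z_test_accuracy <- function(acc_a, acc_b) {
  if (inherits(acc_a, "eval_report")) acc_a <- acc_a$per_repeat
  if (inherits(acc_b, "eval_report")) acc_b <- acc_b$per_repeat
  acc_a <- as.numeric(acc_a)
  acc_b <- as.numeric(acc_b)
  if (length(acc_a) < 2L || length(acc_b) < 2L) {
    stop("both accuracy vectors need length >= 2.")
  }
  diff <- mean(acc_a) - mean(acc_b)
  se <- sqrt(stats::var(acc_a) / length(acc_a) + stats::var(acc_b) / length(acc_b))
  if (se == 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / se
  }
  tibble::tibble(
    z_statistic = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    mean_a = mean(acc_a), mean_b = mean(acc_b),
    n_a = length(acc_a), n_b = length(acc_b)
  )
}
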