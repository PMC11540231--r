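test_that("episodes have exact per-class arithmetic and are seed-deterministic", {
  ft <- generate_mixture(mixture_spec(n_classes = 8, n_features = 6,
                                      per_class_n = 110, seed = 1))
  ep <- make_episode(ft, per_class_train = 75, per_class_test = 25, seed = 3)
  expect_length(ep$train_indices, 8 * 75)
  expect_length(ep$test_indices, 8 * 25)
  expect_length(intersect(ep$train_indices, ep$test_indices), 0)
  # each class contributes exactly the requested counts
  tr_labels <- ft$label[ep$train_indices]
  te_labels <- ft$label[ep$test_indices]
  expect_true(all(table(tr_labels) == 75))
  expect_true(all(table(te_labels) == 25))
  # same seed, same split; different seed, different split
  ep2 <- make_episode(ft, 75, 25, seed = 3)
  expect_identical(ep, ep2)
  ep3 <- make_episode(ft, 75, 25, seed = 4)
  expect_false(identical(ep$train_indices, ep3$train_indices))
  # degenerate and insufficient requests error with the class named
  expect_error(make_episode(ft, 75, 0, seed = 1), "per_class_test")
  expect_error(make_episode(ft, 100, 25, seed = 1), "class_1")
})

test_that("KNN accuracy matches trivial cases and a brute-force oracle", {
  ft <- random_dataset(2, n_per_class = 10, m = 3, c = 3)
  Y <- as.matrix(ft[, -(1:2)])
  labs <- ft$label
  # test = train at K = 1: perfect
  expect_equal(knn_accuracy(Y, labs, Y, labs, k = 1), 1.0)
  # all train labels identical: accuracy = prevalence of that label
  one <- rep("z", nrow(Y))
  expect_equal(knn_accuracy(Y, one, Y, labs, k = 5), mean(labs == "z"))
  expect_error(knn_accuracy(Y, labs, Y, labs, k = 31), "training size")

  # brute-force oracle with explicit loops, random blobs, K = 5
  withr::local_seed(9)
  tr <- matrix(rnorm(60 * 2), 60, 2) + rep(c(0, 3, -3), each = 20)
  ytr <- rep(c("a", "b", "c"), each = 20)
  te <- matrix(rnorm(30 * 2), 30, 2) + rep(c(0, 3, -3), each = 10)
  yte <- rep(c("a", "b", "c"), each = 10)
  oracle_pred <- vapply(seq_len(30), function(i) {
    d <- sqrt(colSums((t(tr) - te[i, ])^2))
    nb <- ytr[order(d)][1:5]
    tab <- table(factor(nb, levels = unique(ytr)))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else nb[nb %in% top][1]
  }, character(1))
  expect_equal(knn_accuracy(tr, ytr, te, yte, k = 5), mean(oracle_pred == yte))
})

test_that("separable classes give perfect accuracy for every method", {
  ft <- generate_mixture(mixture_spec(
    n_classes = 3, n_features = 8, per_class_n = 30,
    class_means = 40 * rbind(c(1, rep(0, 7)), c(0, 1, rep(0, 6)), c(0, 0, 1, rep(0, 5))),
    within_scales = 0.2, nonneg = TRUE, seed = 2
  ))
  for (method in c("feature_space", "pca", "multiclass_da", "nmf")) {
    cfg <- eval_config(
      method = method, dim = if (method == "multiclass_da") 2L else 3L,
      per_class_train = 20, per_class_test = 10, n_repeats = 3,
      knn_k = c(1, 5), nmf_iters = 200, master_seed = 11
    )
    rep <- evaluate_pipeline(ft, cfg)
    expect_equal(rep$mean_accuracy, 1.0, info = method)
  }
})

test_that("config echoes the protocol defaults", {
  cfg <- eval_config(method = "pca", per_class_train = 75, per_class_test = 25)
  expect_identical(cfg$knn_k, c(1L, 5L, 10L, 15L))
  expect_identical(cfg$n_repeats, 10L)
  expect_identical(cfg$delta, 5e-3)
  expect_identical(cfg$nmf_iters, 3000L)
  expect_identical(cfg$classifier, "knn")
  # dimension defaults resolve per method: C - 1 for DA, 30 for pca/nmf/snmf
  expect_identical(resolve_dim(eval_config("multiclass_da", 10, 5), n_classes = 8L), 7L)
  expect_identical(resolve_dim(cfg, n_classes = 8L), 30L)
  expect_identical(resolve_dim(eval_config("nmf", 10, 5), n_classes = 2L), 30L)
  expect_error(eval_config("snmf", 10, 5), "coupling_weight")
})

test_that("the evaluation is deterministic and leak-free", {
  ft <- generate_variance_trap(n_per_class = 40, n_features = 6, seed = 5)
  cfg <- eval_config(
    method = "multiclass_da", dim = 1, per_class_train = 25,
    per_class_test = 10, n_repeats = 4, knn_k = c(1, 5), master_seed = 2
  )
  r1 <- evaluate_pipeline(ft, cfg)
  r2 <- evaluate_pipeline(ft, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$mean_accuracy, r2$mean_accuracy)

  # shuffling test labels cannot change the fitted subspace: fit on the
  # train episode only, compare bases via digest of the numeric content
  ep <- make_episode(ft, 25, 10, seed = 3)
  train <- ft[ep$train_indices, ]
  fit_a <- fit_multiclass_da(train, dim = 1)
  ft_shuffled <- ft
  ft_shuffled$label[ep$test_indices] <-
    withr::with_seed(1, sample(ft$label[ep$test_indices]))
  fit_b <- fit_multiclass_da(ft_shuffled[ep$train_indices, ], dim = 1)
  expect_identical(fit_a$basis, fit_b$basis)
})

test_that("accuracies stay in bounds and the K-then-repeat averaging convention holds", {
  ft <- generate_mixture(mixture_spec(n_classes = 3, n_features = 6,
                                      per_class_n = 30, seed = 4))
  cfg <- eval_config(method = "pca", dim = 3, per_class_train = 15,
                     per_class_test = 10, n_repeats = 5, knn_k = c(1, 5, 10),
                     master_seed = 1)
  rep <- evaluate_pipeline(ft, cfg)
  expect_true(all(rep$accuracy$accuracy >= 0 & rep$accuracy$accuracy <= 1))
  by_repeat <- tapply(rep$accuracy$accuracy, rep$accuracy$repeat_id, mean)
  expect_equal(as.numeric(by_repeat), rep$per_repeat)
  expect_equal(rep$mean_accuracy, mean(rep$per_repeat))
  expect_equal(rep$sd_accuracy, sd(rep$per_repeat)) # unbiased n-1 denominator
  expect_gte(rep$mean_accuracy, min(rep$per_repeat))
  expect_lte(rep$mean_accuracy, max(rep$per_repeat))
  # glance/tidy expose the same numbers
  g <- glance(rep)
  expect_equal(g$mean_accuracy, rep$mean_accuracy)
  expect_equal(nrow(tidy(rep)), 5L * 3L)
})

test_that("the SVM arm runs and reports one accuracy per repeat", {
  ft <- generate_mixture(mixture_spec(n_classes = 2, n_features = 6,
                                      per_class_n = 30, mean_spread = 3, seed = 6))
  cfg <- eval_config(method = "pca", dim = 2, per_class_train = 20,
                     per_class_test = 10, n_repeats = 3, classifier = "svm",
                     master_seed = 4)
  rep <- evaluate_pipeline(ft, cfg)
  expect_equal(nrow(rep$accuracy), 3L)
  expect_true(all(is.na(rep$accuracy$k)))
  expect_true(all(rep$accuracy$accuracy >= 0 & rep$accuracy$accuracy <= 1))
  expect_identical(evaluate_pipeline(ft, cfg)$accuracy, rep$accuracy)
})

test_that("DA accuracy is non-decreasing in dimension up to C-1 on separable data", {
  ft <- generate_mixture(mixture_spec(
    n_classes = 4, n_features = 10, per_class_n = 40,
    mean_spread = 3, within_scales = 1, seed = 9
  ))
  means <- sds <- numeric(3)
  for (d in 1:3) {
    cfg <- eval_config(method = "multiclass_da", dim = d, per_class_train = 25,
                       per_class_test = 10, n_repeats = 5, knn_k = c(1, 5),
                       master_seed = 3)
    r <- evaluate_pipeline(ft, cfg)
    means[d] <- r$mean_accuracy
    sds[d] <- r$sd_accuracy
  }
  pooled <- sqrt(mean(sds^2))
  expect_true(all(diff(means) >= -pooled))
})

test_that("the Z-test matches closed-form expectations", {
  # identical vectors: no difference
  z0 <- z_test_accuracy(rep(0.7, 5), rep(0.7, 5))
  expect_equal(z0$z_statistic, 0)
  expect_equal(z0$p_value, 1)
  # strongly separated arms with tiny jitter: overwhelming evidence
  withr::local_seed(2)
  a <- 0.9 + rnorm(10, sd = 0.01)
  b <- 0.5 + rnorm(10, sd = 0.01)
  zt <- z_test_accuracy(a, b)
  expect_lt(zt$p_value, 1e-3)
  # closed form check
  z_manual <- (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 10)
  expect_equal(zt$z_statistic, z_manual, tolerance = 1e-12)
  expect_equal(zt$p_value, 2 * pnorm(-abs(z_manual)), tolerance = 1e-12)
  # antisymmetry
  zr <- z_test_accuracy(b, a)
  expect_equal(zr$z_statistic, -zt$z_statistic)
  expect_equal(zr$p_value, zt$p_value)
  expect_error(z_test_accuracy(0.5, c(0.5, 0.6)), "length >= 2")
})
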