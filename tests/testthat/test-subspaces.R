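test_that("PCA reconstructs rank-1 data exactly and preserves distances at full rank", {
  # points on a line in 4-D
  withr::local_seed(2)
  t_vals <- rnorm(12)
  dir <- c(1, -2, 0.5, 3)
  Y <- outer(t_vals, dir) + matrix(rep(c(5, 0, -1, 2), each = 12), 12, 4)
  ft <- feature_table(Y, labels = rep("a", 12))
  sub <- fit_pca(ft, dim = 1)
  Z <- as.matrix(project(sub, ft)[, -(1:2)])
  back <- Z %*% t(sub$basis)
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_lt(max(abs(back - Yc)), 1e-10)

  # full-rank projection is an isometry on centered rows
  ft2 <- random_dataset(5, n_per_class = 10, m = 4, c = 2)
  Y2 <- as.matrix(ft2[, -(1:2)])
  sub2 <- fit_pca(ft2, dim = 4)
  Z2 <- as.matrix(project(sub2, ft2)[, -(1:2)])
  expect_equal(as.matrix(dist(Z2)), as.matrix(dist(sweep(Y2, 2, colMeans(Y2)))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA spectrum matches a full-SVD oracle and variances decrease", {
  withr::local_seed(7)
  Y <- matrix(rnorm(30 * 8), 30, 8)
  ft <- feature_table(Y, labels = rep(c("a", "b"), 15))
  for (p in c(2, 5)) {
    sub <- fit_pca(ft, dim = p)
    d_full <- svd(scale(Y, scale = FALSE))$d
    expect_equal(sum(sub$spectrum^2), sum(d_full[1:p]^2), tolerance = 1e-10)
  }
  sub <- fit_pca(ft, dim = 6)
  vars <- apply(as.matrix(project(sub, ft)[, -(1:2)]), 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  # orthonormal basis
  expect_lt(max(abs(crossprod(sub$basis) - diag(6))), 1e-8)
  # out-of-range dimension is a contract error
  expect_error(fit_pca(ft, dim = 9), "min\\(N, M\\)")
})

test_that("projection handles identity bases, width checks, and in-span norms", {
  ft <- random_dataset(3, n_per_class = 6, m = 3, c = 2)
  Y <- as.matrix(ft[, -(1:2)])
  sub <- fit_pca(ft, dim = 3, center = FALSE)
  # orthonormal projection preserves norms of in-span vectors
  withr::local_seed(1)
  W <- sub$basis %*% matrix(rnorm(3 * 4), 3, 4) # columns lie in the span
  PW <- t(sub$basis) %*% W
  expect_equal(sqrt(colSums(PW^2)), sqrt(colSums(W^2)), tolerance = 1e-10)
  # column count equals the subspace dimension
  expect_equal(ncol(project(sub, ft)) - 2L, 3L)
  # width mismatch errors
  expect_error(project(sub, matrix(0, 2, 5)), "features")
})

test_that("multiclass DA recovers a planted discriminant plane and satisfies the eigen identity", {
  # 3 classes in 3-D separated only along axes 1-2. The within-class
  # deviations are exactly symmetric (+/- 1e-3 along each axis) so the
  # realized scatters equal their isotropic population values and the
  # discriminant plane is identified exactly.
  means <- rbind(c(2, 0, 0), c(0, 2, 0), c(-2, -2, 0))
  dev <- 1e-3 * rbind(diag(3), -diag(3))
  Y <- do.call(rbind, lapply(1:3, function(j) {
    sweep(dev, 2, means[j, ], `+`)
  }))
  ft <- feature_table(Y, labels = rep(1:3, each = 6))
  fit <- fit_multiclass_da(ft, delta = 1e-9)
  expect_equal(fit$dim, 2L) # C - 1 directions by default
  # principal angle between fitted span and the e1-e2 plane
  Qtrue <- diag(3)[, 1:2]
  sv <- svd(crossprod(Qtrue, fit$basis))$d
  expect_lt(acos(min(pmin(sv, 1))), 1e-3)

  # eigen identity with the stored raw eigenvectors
  st <- scatter_stats(ft)
  SWhat <- st$S_W + diag(1e-9, 3)
  for (k in 1:2) {
    v <- fit$eigvecs[, k]
    resid <- st$S_B %*% v - fit$spectrum[k] * (SWhat %*% v)
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum((st$S_B %*% v)^2)), 1e-8)
  }
  # contract errors
  expect_error(fit_multiclass_da(ft, delta = 0), "positive")
  expect_error(fit_multiclass_da(ft, dim = 3), "C-1")
})

test_that("multiclass DA agrees with a dense generalized eigensolver on noisy data", {
  for (seed in c(4, 15)) {
    ft <- random_dataset(seed, n_per_class = 20, m = 6, c = 4)
    delta <- 5e-3
    fit <- fit_multiclass_da(ft, delta = delta)
    st <- scatter_stats(ft)
    # independent oracle: nonsymmetric eigensolve of (S_W + delta I)^{-1} S_B
    A <- solve(st$S_W + diag(delta, 6)) %*% st$S_B
    ev <- eigen(A)
    ord <- order(Re(ev$values), decreasing = TRUE)[1:3]
    expect_equal(fit$spectrum, Re(ev$values)[ord], tolerance = 1e-8)
    for (k in 1:3) {
      v <- Re(ev$vectors[, ord[k]])
      cosine <- abs(sum(v * fit$eigvecs[, k])) / sqrt(sum(v^2))
      expect_gt(cosine, 1 - 1e-8)
    }
  }
})

test_that("binary multiclass DA direction is collinear with the first Foley-Sammon direction", {
  for (seed in 1:5) {
    ft <- random_binary(seed, n_per_class = 40, m = 6)
    da <- fit_multiclass_da(ft, delta = 1e-10)
    fs <- fit_foley_sammon(ft, n_dirs = 1, delta = 0)
    cosine <- abs(sum(da$basis[, 1] * fs$directions[, 1]))
    expect_gt(cosine, 1 - 1e-6)
  }
})

test_that("Foley-Sammon directions match closed-form toys", {
  # identity within-class scatter: d1 is s_b normalized
  make_ft_from_stats <- function(SW_target, s_b) {
    # build a 2-class sample whose binary scatter equals the targets:
    # symmetric pairs around each class mean give exact S_Wj
    R <- chol(SW_target)
    m <- length(s_b)
    rows1 <- rbind(R, -R) # class 1 deviations; SW1 = 2 * SW_target
    mu1 <- s_b
    mu2 <- rep(0, m)
    Y <- rbind(sweep(rows1, 2, mu1, `+`), sweep(rows1, 2, mu2, `+`))
    feature_table(Y, labels = rep(c("p", "q"), each = 2 * m))
  }
  # with both classes built from the same deviations, beta = 1/2 and
  # S~_W = 2 * SW_target; the ratio only rescales alphas, not directions
  ft <- make_ft_from_stats(diag(2), c(3, 4))
  fs <- fit_foley_sammon(ft, n_dirs = 1, delta = 0)
  expect_equal(unname(fs$directions[, 1]), c(0.6, 0.8), tolerance = 1e-10)

  ft2 <- make_ft_from_stats(diag(c(1, 2)), c(1, 1))
  fs2 <- fit_foley_sammon(ft2, n_dirs = 2, delta = 0)
  expect_equal(unname(fs2$directions[, 1]), c(2, 1) / sqrt(5), tolerance = 1e-10)
  expect_equal(abs(unname(fs2$directions[, 2])), c(1, 2) / sqrt(5), tolerance = 1e-8)
  # discrim-values on the same toy: scale-invariant, so the factor 2 in
  # S~_W cancels between numerator scatter and denominator
  g <- discrim_values(fs2, fs2$stats)
  expect_equal(g, unname(fs2$discrim_values), tolerance = 1e-12)
  expect_equal(unname(g[1] / g[2]), (3 / 2) / (1 / 9), tolerance = 1e-8)

  # contract errors
  expect_error(fit_foley_sammon(random_dataset(1, c = 3), n_dirs = 1),
               "two classes")
  expect_error(fit_foley_sammon(ft2, n_dirs = 5), "1..M")
})

test_that("d1 matches the dominant generalized eigenvector on random problems", {
  worst <- 1
  for (seed in 1:50) {
    m <- 3 + (seed %% 18) # M <= 20
    ft <- random_binary(seed, n_per_class = 30, m = m)
    bs <- binary_scatter_stats(ft)
    fs <- fit_foley_sammon_stats(bs, n_dirs = 1, delta = 0)
    # independent oracle: dense eigensolve of S~_W^{-1} S~_B
    ev <- eigen(solve(bs$S_tilde_W) %*% bs$S_tilde_B)
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    v <- v / sqrt(sum(v^2))
    worst <- min(worst, abs(sum(v * fs$directions[, 1])))
  }
  expect_gt(worst, 1 - 1e-8)
})

test_that("Foley-Sammon bases are orthonormal with ordered discrim-values", {
  for (seed in 1:50) {
    m <- 4 + (seed %% 17)
    ft <- random_binary(seed + 100, n_per_class = 30, m = m)
    L <- min(10, m)
    fs <- fit_foley_sammon(ft, n_dirs = L, delta = 0)
    D <- fs$directions
    expect_lt(max(abs(crossprod(D) - diag(L))), 1e-8)
    expect_equal(sqrt(colSums(D^2)), rep(1, L), tolerance = 1e-10)
    g <- fs$discrim_values
    expect_true(all(diff(g) <= 1e-10))
    expect_gte(min(g), 0)
  }
})

test_that("d1 maximizes the Fisher ratio over random directions", {
  for (seed in c(2, 9, 17)) {
    ft <- random_binary(seed, n_per_class = 25, m = 6)
    bs <- binary_scatter_stats(ft)
    fs <- fit_foley_sammon_stats(bs, n_dirs = 1, delta = 0)
    r1 <- fisher_ratio(fs$directions[, 1], bs)
    rand_ratios <- withr::with_seed(seed, {
      vapply(1:1000, function(i) {
        v <- rnorm(6)
        fisher_ratio(v / sqrt(sum(v^2)), bs)
      }, numeric(1))
    })
    expect_gte(r1, max(rand_ratios) - 1e-12)
  }
})

test_that("the Fisher ratio is scale invariant and vanishes orthogonal to s_b", {
  ft <- random_binary(12, n_per_class = 20, m = 4)
  bs <- binary_scatter_stats(ft)
  d <- c(1, -2, 0.5, 1)
  expect_equal(fisher_ratio(d, bs), fisher_ratio(-3.7 * d, bs), tolerance = 1e-10)
  # a direction orthogonal to s_b has zero between-class scatter
  v <- withr::with_seed(1, rnorm(4))
  v <- v - sum(v * bs$s_b) / sum(bs$s_b^2) * bs$s_b
  expect_equal(fisher_ratio(v, bs), 0, tolerance = 1e-12)
  expect_error(fisher_ratio(rep(0, 4), bs), "nonzero")
})

test_that("discrim-values vanish when class means coincide", {
  same <- feature_table(
    rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
          c(1.5, 0), c(-1.5, 0), c(0, 1.5), c(0, -1.5)),
    labels = rep(c("a", "b"), each = 4)
  )
  bs <- binary_scatter_stats(same)
  expect_equal(unname(bs$s_b), c(0, 0))
  ft <- random_binary(5, n_per_class = 20, m = 2)
  fs <- fit_foley_sammon(ft, n_dirs = 2, delta = 0)
  expect_equal(unname(discrim_values(fs, bs)), c(0, 0), tolerance = 1e-12)
})

test_that("sign fixing makes fits deterministic across runs", {
  ft <- random_dataset(42, n_per_class = 15, m = 6, c = 3)
  expect_identical(fit_pca(ft, dim = 3), fit_pca(ft, dim = 3))
  expect_identical(fit_multiclass_da(ft), fit_multiclass_da(ft))
  bft <- random_binary(42, n_per_class = 20, m = 6)
  expect_identical(fit_foley_sammon(bft, n_dirs = 4), fit_foley_sammon(bft, n_dirs = 4))
  # largest-magnitude entry of every basis column is positive
  for (B in list(fit_pca(ft, dim = 3)$basis, fit_multiclass_da(ft)$basis)) {
    picks <- apply(B, 2, function(col) col[which.max(abs(col))])
    expect_true(all(picks > 0))
  }
})

test_that("the automatic ridge engages exactly in the singular regime", {
  # N <= M: ridge on by default
  small <- random_binary(8, n_per_class = 4, m = 10)
  fs <- fit_foley_sammon(small, n_dirs = 2)
  expect_equal(fs$delta_used, 5e-3)
  # N >> M with good conditioning: no ridge
  big <- random_binary(8, n_per_class = 40, m = 5)
  fs2 <- fit_foley_sammon(big, n_dirs = 2)
  expect_equal(fs2$delta_used, 0)
  # explicit delta wins
  fs3 <- fit_foley_sammon(big, n_dirs = 2, delta = 0.01)
  expect_equal(fs3$delta_used, 0.01)
})

test_that("fitted subspaces serialize to JSON and round-trip bit-identically", {
  ft <- random_dataset(19, n_per_class = 12, m = 5, c = 3)
  path <- withr::local_tempfile(fileext = ".json")
  sub <- fit_pca(ft, dim = 3)
  write_fit(sub, path)
  back <- read_fit(path)
  expect_identical(back$basis, unname(sub$basis))
  expect_identical(back$spectrum, sub$spectrum)
  expect_identical(unname(back$centering), unname(sub$centering))

  bft <- random_binary(19, n_per_class = 15, m = 5)
  fs <- fit_foley_sammon(bft, n_dirs = 3)
  write_fit(fs, path)
  back2 <- read_fit(path)
  expect_identical(back2$directions, fs$directions)
  expect_identical(back2$discrim_values, unname(fs$discrim_values))
  expect_identical(back2$stats$S_tilde_W, unname(fs$stats$S_tilde_W))
})
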