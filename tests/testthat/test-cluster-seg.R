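test_that("superpixels tile the image deterministically at the requested scale", {
  sc <- generate_scene(small_single_spec(seed = 21))
  a <- superpixels(sc$image, 100, seed = 0)
  b <- superpixels(sc$image, 100, seed = 0)
  expect_identical(unclass(a), unclass(b))
  L <- max(unclass(a))
  expect_gte(L, 50); expect_lte(L, 150)
  expect_true(all(unclass(a) > 0L))          # full tiling
  expect_identical(sort(unique(as.vector(unclass(a)))), seq_len(L))
  # every label is one connected region
  for (j in sample(seq_len(L), 10))
    expect_equal(max(round(as.matrix(EBImage::bwlabel((unclass(a) == j) + 0L)))), 1)
})

test_that("superpixels respect a high-contrast straight boundary", {
  img <- matrix(40L, 60, 60); img[, 31:60] <- 210L
  sp <- unclass(superpixels(gray_image(img), 36))
  for (j in seq_len(max(sp))) {
    left <- sum(sp[, 1:30] == j); right <- sum(sp[, 31:60] == j)
    minority <- min(left, right)
    rows_spanned <- length(unique(which(sp == j, arr.ind = TRUE)[, 1]))
    expect_lte(minority, rows_spanned)   # at most a 1-pixel straddle layer
  }
})

test_that("one-superpixel-per-pixel limit behaves as documented", {
  img <- gray_image(matrix(sample(0:255, 64, TRUE), 8, 8))
  expect_error(superpixels(img, 100), "exceeds pixel count")
  sp <- unclass(superpixels(img, 64))
  expect_true(all(sp > 0L))
})

test_that("feature tables expose intensity and optional spatial columns", {
  const <- gray_image(matrix(99L, 6, 6))
  ft <- build_features(const, "pixels")
  expect_equal(nrow(ft$X), 36)
  expect_true(all(ft$X[, 1] == 99 / 255))

  ft0 <- build_features(const, "pixels", spatial = TRUE, w_s = 0)
  expect_true(all(ft0$X[, 2:3] == 0))     # w_s = 0 reduces to the plain variant
  expect_identical(ft0$X[, 1], ft$X[, 1])

  # superpixel rows are the mean over member pixels (brute-force check)
  sc <- generate_scene(small_single_spec(seed = 22))
  sp <- superpixels(sc$image, 60)
  fts <- build_features(sc$image, sp)
  m <- unclass(sc$image); lm <- unclass(sp)
  for (j in sample(fts$unit_labels, 8)) {
    i <- which(fts$unit_labels == j)
    expect_equal(fts$X[i, 1], mean(m[lm == j]) / 255, tolerance = 1e-12)
  }
})

test_that("K-means++ seeding is D-squared sampling", {
  X <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 1)   # 3 distinct rows, duplicated
  C <- kmeans_pp_init(X, 3, seed = 7)
  expect_setequal(as.vector(C), c(0, 1, 2))    # duplicates can never repeat
  expect_error(kmeans_pp_init(X, 4, seed = 1), "distinct")

  C1 <- kmeans_pp_init(X, 1, seed = 3)
  expect_true(as.vector(C1) %in% c(0, 1, 2))
  expect_identical(kmeans_pp_init(X, 2, seed = 5), kmeans_pp_init(X, 2, seed = 5))

  # two far blobs: the second center lands in the opposite blob almost surely
  Y <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 100, 0.1)), ncol = 1)
  hits <- 0
  for (s in 1:200) {
    C2 <- kmeans_pp_init(Y, 2, seed = s)
    if (abs(diff(sort(as.vector(C2)))) > 50) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.95)
})

test_that("Lloyd iterations converge with a non-increasing objective", {
  X <- matrix(c(0, 0, 10, 10, 20, 20), ncol = 1)
  fit <- fit_kmeans(X, 3, matrix(c(0, 10, 20), 3, 1))
  expect_equal(fit$objective, 0)
  expect_length(fit$trace, 1)

  set.seed(31)
  blob <- matrix(c(rnorm(30, 0, 0.5), rnorm(40, 10, 0.5)), ncol = 1)
  f2 <- fit_kmeans(blob, 2, kmeans_pp_init(blob, 2, seed = 1))
  ctr <- sort(as.vector(f2$centers))
  expect_equal(ctr[1], mean(blob[blob < 5]), tolerance = 1e-9)
  expect_equal(ctr[2], mean(blob[blob > 5]), tolerance = 1e-9)
  expect_identical(f2$assignment[1] == f2$assignment[30], TRUE)
  expect_false(f2$assignment[1] == f2$assignment[31])

  for (i in 1:10) {
    Z <- matrix(rnorm(60), ncol = 2)
    fz <- fit_kmeans(Z, 3, kmeans_pp_init(Z, 3, seed = i))
    expect_true(all(diff(fz$trace) <= 1e-9))
    # independent check: Lloyd from the converged centers cannot improve
    ref <- suppressWarnings(stats::kmeans(Z, fz$centers, iter.max = 50,
                                          algorithm = "Lloyd"))
    expect_equal(ref$tot.withinss, fz$objective, tolerance = 1e-6)
  }
})

test_that("EM fits a diagonal Gaussian mixture with non-decreasing likelihood", {
  set.seed(41)
  X <- matrix(rnorm(400, 5, 2), ncol = 1)
  f1 <- fit_em_gmm(X, 1, seed = 1)
  expect_equal(as.vector(f1$centers), mean(X), tolerance = 1e-6)
  expect_equal(as.vector(f1$variances), mean((X - mean(X))^2), tolerance = 1e-6)

  for (i in 1:5) {
    Z <- matrix(rnorm(100), ncol = 2)
    fz <- fit_em_gmm(Z, 3, seed = i)
    expect_true(all(diff(fz$trace) >= -1e-8))
  }

  Y <- matrix(c(rnorm(50, 0, 0.3), rnorm(50, 8, 0.3)), ncol = 1)
  f2 <- fit_em_gmm(Y, 2, seed = 2)
  # responsibilities recover hard blob membership
  expect_length(unique(f2$assignment[1:50]), 1)
  expect_length(unique(f2$assignment[51:100]), 1)
  expect_false(f2$assignment[1] == f2$assignment[51])
  # posterior agrees with the brute-force two-Gaussian posterior
  post <- function(x, mu, s2, w) {
    d <- w * dnorm(x, mu, sqrt(s2)); d / sum(d)
  }
  for (i in c(1, 25, 75, 100)) {
    p <- post(Y[i], as.vector(f2$centers), as.vector(f2$variances), f2$weights)
    expect_identical(which.max(p), f2$assignment[i])
  }
})

test_that("all four single-cell methods recover a high-contrast phantom", {
  sc <- generate_scene(small_single_spec(seed = 23))
  truth <- cytoplasm_union(sc$truth)
  for (m in c("pixel-kmeans", "pixel-spatial-kmeans",
              "superpixel-em", "superpixel-kmeans-pp")) {
    pred <- segment_cell(sc$image, method = m, seed = 0, n_superpixels = 150)
    expect_length(pred$cells, 1)
    expect_gte(zsi(unclass(pred$cells[[1]]$cytoplasm), truth), 0.9)
  }
  expect_error(segment_cell(gray_image(matrix(7L, 30, 30)), "pixel-kmeans"),
               "degenerate")
})

test_that("single-cell segmentation is deterministic for a fixed seed", {
  sc <- generate_scene(small_single_spec(seed = 24))
  a <- segment_cell(sc$image, "superpixel-kmeans-pp", seed = 9,
                    n_superpixels = 150)
  b <- segment_cell(sc$image, "superpixel-kmeans-pp", seed = 9,
                    n_superpixels = 150)
  expect_identical(unclass(a$cells[[1]]$cytoplasm), unclass(b$cells[[1]]$cytoplasm))
  expect_identical(unclass(a$cells[[1]]$nucleus), unclass(b$cells[[1]]$nucleus))
})

test_that("superpixel and pixel K-means agree when superpixels are constant", {
  # piecewise-constant image whose superpixels are internally uniform
  img <- matrix(30L, 32, 32)
  img[1:16, 17:32] <- 120L
  img[17:32, 1:16] <- 200L
  img[17:32, 17:32] <- 250L
  g <- gray_image(img)
  sp <- superpixels(g, 16, compactness = 5)
  # check premise: each superpixel is internally constant
  for (j in seq_len(max(unclass(sp))))
    expect_length(unique(img[unclass(sp) == j]), 1)
  ftp <- build_features(g, "pixels")
  fts <- build_features(g, sp)
  init <- matrix(c(30, 120, 250) / 255, 3, 1)
  fp <- fit_kmeans(ftp, 3, init)
  fs <- fit_kmeans(fts, 3, init)
  # map superpixel assignment back to pixels and compare
  lut <- integer(max(fts$unit_labels)); lut[fts$unit_labels] <- fs$assignment
  expect_identical(matrix(fp$assignment, 32, 32), matrix(lut[unclass(sp)], 32, 32))
})
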