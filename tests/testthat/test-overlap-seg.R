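test_that("the min cut equals exhaustive enumeration on tiny images", {
  set.seed(51)
  for (i in 1:20) {
    H <- sample(2:3, 1); W <- sample(2:4, 1)
    m <- matrix(sample(0:255, H * W, TRUE), H, W)
    if (length(unique(as.vector(m))) < 2) m[1, 1] <- (m[1, 1] + 128) %% 256
    lambda <- runif(1, 0.2, 3); sigma <- runif(1, 5, 30)
    got <- separate_clumps(gray_image(m), lambda = lambda, sigma = sigma,
                           min_hole_area = 0)
    models <- attr(got, "models")
    # oracle: enumerate all 2^(H*W) labelings and minimize the energy
    n <- H * W
    best <- Inf
    for (code in 0:(2^n - 1)) {
      mask <- matrix(as.integer(intToBits(code)[1:n]), H, W)
      e <- cytoseg:::cut_energy(m, mask, lambda, sigma, models$fg, models$bg)
      if (e < best) best <- e
    }
    e_got <- cytoseg:::cut_energy(m, unclass(got), lambda, sigma,
                                  models$fg, models$bg)
    expect_equal(e_got, best, tolerance = 1e-6)
    expect_equal(attr(got, "cut_value"), best, tolerance = 1e-6)
  }
})

test_that("zero smoothness reduces the cut to per-pixel maximum likelihood", {
  set.seed(52)
  m <- matrix(sample(0:255, 80, TRUE), 8, 10)
  got <- separate_clumps(gray_image(m), lambda = 0, min_hole_area = 0)
  models <- attr(got, "models")
  Dfg <- cytoseg:::unary_cost(m, models$fg)
  Dbg <- cytoseg:::unary_cost(m, models$bg)
  expect_identical(cytoseg:::px(got), (Dfg < Dbg) + 0L)
})

test_that("graph cut recovers the clump mask of a phantom scene", {
  sc <- generate_scene(small_scene_spec(seed = 53, n_cells = 2, overlap = 0.25))
  got <- separate_clumps(sc$image, min_hole_area = 50)
  expect_gte(zsi(unclass(got), cytoplasm_union(sc$truth)), 0.95)
  expect_error(separate_clumps(gray_image(matrix(100L, 6, 6))), "degenerate")
})

test_that("Voronoi partitioning matches the brute-force nearest-seed oracle", {
  # symmetric two-seed rectangle: the bisector column splits it
  cm <- matrix(1L, 21, 31)
  seeds <- list(list(centroid = c(11, 10)), list(centroid = c(11, 22)))
  part <- unclass(voronoi_partition(binary_mask(cm), seeds))
  expect_true(all(part[, 1:16] == 1L))   # ties at the bisector go to seed 1
  expect_true(all(part[, 17:31] == 2L))

  one <- voronoi_partition(binary_mask(cm), seeds[1])
  expect_true(all(unclass(one) == 1L))
  expect_error(voronoi_partition(binary_mask(cm), list()), "zero seeds")

  set.seed(54)
  for (i in 1:50) {
    H <- sample(8:20, 1); W <- sample(8:20, 1)
    cm <- random_mask(H, W, 0.6)
    k <- sample(1:4, 1)
    seeds <- lapply(seq_len(k), function(j)
      list(centroid = c(runif(1, 1, H), runif(1, 1, W))))
    part <- unclass(voronoi_partition(binary_mask(cm), seeds))
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (cm[r, c] == 0L) { expect_identical(part[r, c], 0L); next }
      d <- vapply(seeds, function(s)
        (r - s$centroid[1])^2 + (c - s$centroid[2])^2, 0)
      expect_identical(part[r, c], which.min(d))  # first minimum = lowest index
    }
  }
})

test_that("nuclei are detected at their true locations and filtered by size", {
  sc <- generate_scene(small_scene_spec(seed = 55, n_cells = 3, overlap = 0,
                                        size = 256))
  clump <- binary_mask(cytoplasm_union(sc$truth))
  nuc <- detect_nuclei(sc$image, clump, min_area = 15, max_area = 1500)
  expect_length(nuc, 3)
  true_ctr <- t(vapply(sc$truth$cells, function(cl)
    cytoseg:::mask_centroid(unclass(cl$nucleus)), c(0, 0)))
  got_ctr <- t(vapply(nuc, function(x) x$centroid, c(0, 0)))
  # each detection sits within 3 px of a distinct true nucleus
  used <- logical(3)
  for (i in 1:3) {
    d <- sqrt(rowSums(sweep(true_ctr, 2, got_ctr[i, ], "-")^2))
    j <- which.min(d)
    expect_lt(d[j], 3); expect_false(used[j]); used[j] <- TRUE
  }
  # masks disjoint and inside the clump
  u <- matrix(0L, 256, 256)
  for (x in nuc) {
    expect_true(all(unclass(x$mask) <= unclass(clump)))
    expect_identical(sum(u & unclass(x$mask)), 0L)
    u <- pmax(u, unclass(x$mask))
  }

  # a clump with no dark blobs yields an empty set
  flat <- matrix(150L, 64, 64)
  set.seed(1); flat <- pmin(pmax(flat + matrix(rnorm(64^2, 0, 4), 64, 64), 0), 255)
  flat <- gray_image(round(flat))
  none <- detect_nuclei(flat, binary_mask(matrix(1L, 64, 64)), min_area = 30)
  expect_length(none, 0)

  # blobs below min_area are filtered out
  img <- matrix(150L, 40, 40); img[20:21, 20:21] <- 40L
  got <- detect_nuclei(gray_image(img), binary_mask(matrix(1L, 40, 40)),
                       min_area = 30)
  expect_length(got, 0)
})

test_that("overlap compensation is a monotone no-op-at-zero extension", {
  sc <- generate_scene(small_scene_spec(seed = 56, n_cells = 2, overlap = 0.25))
  clump <- separate_clumps(sc$image, min_hole_area = 50)
  nuc <- detect_nuclei(sc$image, clump, min_area = 15, max_area = 1500)
  expect_length(nuc, 2)
  part <- voronoi_partition(clump, nuc)

  zero <- compensate_overlap(sc$image, part, nuc, max_extension = 0)
  for (s in 1:2)
    expect_identical(unclass(zero[[s]]), (unclass(part) == s) + 0L)

  prev <- NULL
  for (ext in c(15, 30, 60)) {
    cur <- compensate_overlap(sc$image, part, nuc, max_extension = ext)
    if (!is.null(prev)) for (s in 1:2)
      expect_true(all(unclass(cur[[s]]) >= unclass(prev[[s]])))
    prev <- cur
  }

  # the compensated masks jointly recover the true overlap region
  tr <- lapply(sc$truth$cells, function(cl) unclass(cl$cytoplasm))
  ov <- tr[[1]] & tr[[2]]
  got <- compensate_overlap(sc$image, part, nuc, max_extension = 60)
  joint <- (unclass(got[[1]]) | unclass(got[[2]])) & ov
  expect_gte(sum(joint) / sum(ov), 0.95)
})

test_that("compensation adds nothing when cells do not overlap", {
  spec <- small_scene_spec(seed = 57, n_cells = 2, overlap = 0, size = 256,
                           noise_sd = 0)
  sc <- generate_scene(spec)
  clump <- separate_clumps(sc$image, min_hole_area = 50)
  nuc <- detect_nuclei(sc$image, clump, min_area = 15, max_area = 1500)
  part <- voronoi_partition(clump, nuc)
  got <- compensate_overlap(sc$image, part, nuc, max_extension = 60)
  for (s in seq_along(nuc)) {
    added <- unclass(got[[s]]) - (unclass(part) == s)
    expect_identical(sum(added), 0L)   # no absorbance evidence, no growth
  }
})

test_that("merging conserves the cell count and covers the clump", {
  sc <- generate_scene(small_scene_spec(seed = 58, n_cells = 3, overlap = 0.2,
                                        size = 256))
  cfg <- scaled_overlap_config(256)
  pred <- suppressWarnings(segment_overlapping(sc$image, cfg))
  clump <- separate_clumps(sc$image, min_hole_area = cfg$min_hole_area)
  # union of predicted cytoplasm covers the clump up to a thin erosion band
  u <- cytoplasm_union(pred)
  er <- round(as.matrix(EBImage::erode(unclass(clump),
                                       EBImage::makeBrush(5, "disc"))))
  expect_gte(sum(u & er) / max(sum(er), 1), 0.98)

  # single-cell clump: the cell equals the clump
  sc1 <- generate_scene(small_single_spec(seed = 59, size = 192))
  pred1 <- segment_overlapping(sc1$image, scaled_overlap_config(192))
  expect_length(pred1$cells, 1)
  cl1 <- separate_clumps(sc1$image, min_hole_area = 20)
  expect_gte(zsi(unclass(pred1$cells[[1]]$cytoplasm), unclass(cl1)), 0.98)
})

test_that("the full overlap pipeline is deterministic and handles blank input", {
  sc <- generate_scene(small_scene_spec(seed = 60))
  cfg <- scaled_overlap_config(192)
  a <- suppressWarnings(segment_overlapping(sc$image, cfg))
  b <- suppressWarnings(segment_overlapping(sc$image, cfg))
  expect_identical(length(a$cells), length(b$cells))
  for (i in seq_along(a$cells))
    expect_identical(unclass(a$cells[[i]]$cytoplasm), unclass(b$cells[[i]]$cytoplasm))

  blank <- segment_overlapping(gray_image(matrix(220L, 64, 64)))
  expect_length(blank$cells, 0)

  # per-cell quality on a moderately overlapping scene
  r <- evaluate_scene(a, sc$truth)
  expect_identical(r$n_pred_cells, length(detect_nuclei(
    sc$image, separate_clumps(sc$image, min_hole_area = cfg$min_hole_area),
    min_area = cfg$nucleus_min_area, max_area = cfg$nucleus_max_area,
    min_solidity = cfg$nucleus_min_solidity,
    max_compactness = cfg$nucleus_max_compactness)))
  expect_gt(r$mean_zsi, 0.7)
})
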