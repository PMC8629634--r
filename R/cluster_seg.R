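#' SLIC-style superpixel oversegmentation
#'
#' Compactness-controlled local K-means in joint intensity + position
#' space. Cluster centers start on a regular grid with spacing
#' `S = sqrt(H * W / n_segments)`; each iteration assigns every pixel to
#' the nearest center within a `2S` search window under the distance
#' `d_color^2 + (compactness / S)^2 * d_xy^2`, then recenters. Afterwards
#' connectivity is enforced: each label keeps its largest connected
#' component and orphan pixels are adopted by an adjacent region. The
#' algorithm is deterministic; `seed` is accepted for interface stability
#' but no step is randomized.
#'
#' @param image a [gray_image] or [color_image].
#' @param n_segments requested number of superpixels (>= 2); the realized
#'   count may differ but stays within +/-50%.
#' @param compactness spatial regularization weight on the 0-255 intensity
#'   scale; larger values give squarer superpixels.
#' @param seed unused (deterministic algorithm); kept in the signature.
#' @param max_iter local K-means sweeps.
#' @return a [label_map] with contiguous labels `1..L` tiling the image.
#' @export
superpixels <- function(image, n_segments, compactness = 20, seed = 0L,
                        max_iter = 10L) {
  if (inherits(image, "color_image")) {
    a <- unclass(image)
    chans <- lapply(1:3, function(i) a[, , i] * 1.0)
  } else {
    chans <- list(as_gray_matrix(image) * 1.0)
  }
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  if (n_segments < 2L) stop("superpixels: n_segments must be >= 2")
  if (n_segments > H * W) stop("superpixels: n_segments exceeds pixel count")
  S <- sqrt(H * W / n_segments)
  nr <- max(1L, round(H / S)); nc <- max(1L, round(W / S))
  cr <- (seq_len(nr) - 0.5) * H / nr
  cc <- (seq_len(nc) - 0.5) * W / nc
  centers <- cbind(rep(cr, times = nc), rep(cc, each = nr))
  K <- nrow(centers)
  feat <- t(vapply(seq_len(K), function(j) {
    r <- pmin(pmax(round(centers[j, 1]), 1L), H)
    c <- pmin(pmax(round(centers[j, 2]), 1L), W)
    vapply(chans, function(ch) ch[r, c], 0)
  }, numeric(length(chans))))
  if (length(chans) == 1L) feat <- matrix(feat, ncol = 1L)
  mS2 <- (compactness / S)^2
  lab <- matrix(0L, H, W)
  for (it in seq_len(max_iter)) {
    best <- matrix(Inf, H, W)
    lab <- matrix(0L, H, W)
    for (j in seq_len(K)) {
      if (centers[j, 1] < 0) next   # parked empty cluster
      r0 <- max(1L, floor(centers[j, 1] - S)); r1 <- min(H, ceiling(centers[j, 1] + S))
      c0 <- max(1L, floor(centers[j, 2] - S)); c1 <- min(W, ceiling(centers[j, 2] + S))
      rs <- r0:r1; cs <- c0:c1
      d <- mS2 * outer((rs - centers[j, 1])^2, (cs - centers[j, 2])^2, "+")
      for (ci in seq_along(chans))
        d <- d + (chans[[ci]][rs, cs, drop = FALSE] - feat[j, ci])^2
      win <- best[rs, cs, drop = FALSE]
      upd <- d < win
      win[upd] <- d[upd]
      best[rs, cs] <- win
      lw <- lab[rs, cs, drop = FALSE]
      lw[upd] <- j
      lab[rs, cs] <- lw
    }
    # orphans (outside every window): assign to nearest grid center
    if (any(lab == 0L)) {
      orf <- which(lab == 0L, arr.ind = TRUE)
      gi <- pmin(pmax(ceiling(orf[, 1] / (H / nr)), 1L), nr)
      gj <- pmin(pmax(ceiling(orf[, 2] / (W / nc)), 1L), nc)
      lab[lab == 0L] <- (gj - 1L) * nr + gi
    }
    labv <- as.vector(lab)
    cnt <- tabulate(labv, nbins = K)
    idx <- which(cnt > 0L)          # rowsum rows follow sort(unique(labv)) = idx
    centers[idx, 1] <- rowsum(as.vector(row(lab)), labv)[, 1] / cnt[idx]
    centers[idx, 2] <- rowsum(as.vector(col(lab)), labv)[, 1] / cnt[idx]
    for (ci in seq_along(chans))
      feat[idx, ci] <- rowsum(as.vector(chans[[ci]]), labv)[, 1] / cnt[idx]
    if (length(idx) < K) {
      # park empty clusters far outside so they stay inert
      centers[-idx, 1] <- -10 * H
      centers[-idx, 2] <- -10 * W
    }
  }
  compact_labels(enforce_connectivity(lab))
}

# Keep the largest connected component per label; orphaned pixels adopt
# the label of an adjacent assigned pixel (deterministic sweep order).
enforce_connectivity <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  out <- matrix(0L, H, W)
  for (j in sort(unique(as.vector(lab)))) {
    if (j == 0L) next
    comp <- round(as.matrix(EBImage::bwlabel((lab == j) + 0L)))
    if (max(comp) == 0L) next
    areas <- tabulate(comp[comp > 0L])
    keep <- which.max(areas)
    out[comp == keep] <- j
  }
  while (any(out == 0L)) {
    assigned <- out > 0L
    grew <- FALSE
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shift_mat(out, sh[1], sh[2])
      fill <- out == 0L & nb > 0L
      if (any(fill)) { out[fill] <- nb[fill]; grew <- TRUE }
    }
    if (!grew) stop("superpixels: connectivity enforcement failed to converge")
  }
  out
}

# Shift a matrix by (dr, dc), padding with 0.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Build a clustering feature table from pixels or superpixels
#'
#' One row per unit. Intensity features are the gray value (or the three
#' RGB channels) scaled to `[0, 1]`. With `spatial = TRUE`, the unit's
#' (row, col) centroid, normalized to `[0, 1]`, is appended scaled by the
#' spatial weight `w_s`; `w_s = 0` therefore reduces the spatial variant
#' to the plain one (up to zero columns).
#'
#' @param image a [gray_image] or [color_image].
#' @param units `"pixels"` or a [label_map] of superpixels.
#' @param spatial logical; append scaled centroid coordinates.
#' @param w_s spatial weight after coordinate normalization (default 0.1).
#' @return an object of class `feature_table` with fields `X` (numeric
#'   matrix), `unit_type`, `unit_labels`, `map` (the label map or `NULL`)
#'   and `dim`.
#' @export
build_features <- function(image, units = "pixels", spatial = FALSE,
                           w_s = 0.1) {
  if (inherits(image, "color_image")) {
    a <- unclass(image)
    chans <- lapply(1:3, function(i) a[, , i] / 255)
  } else {
    chans <- list(as_gray_matrix(image) / 255)
  }
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  rn <- (row(chans[[1]]) - 1) / max(H - 1, 1)
  cn <- (col(chans[[1]]) - 1) / max(W - 1, 1)
  if (identical(units, "pixels")) {
    X <- do.call(cbind, lapply(chans, as.vector))
    if (spatial) X <- cbind(X, w_s * as.vector(rn), w_s * as.vector(cn))
    ft <- list(X = X, unit_type = "pixel", unit_labels = seq_len(H * W),
               map = NULL, dim = c(H, W))
  } else {
    map <- px(label_map(units))
    if (!identical(dim(map), c(H, W)))
      stop("build_features: label map shape mismatch")
    labv <- as.vector(map)
    ids <- sort(unique(labv[labv > 0L]))
    cnt <- tabulate(labv, nbins = max(ids))[ids]
    X <- do.call(cbind, lapply(chans, function(ch)
      rowsum(as.vector(ch), labv)[as.character(ids), 1] / cnt))
    if (spatial) {
      mr <- rowsum(as.vector(rn), labv)[as.character(ids), 1] / cnt
      mc <- rowsum(as.vector(cn), labv)[as.character(ids), 1] / cnt
      X <- cbind(X, w_s * mr, w_s * mc)
    }
    ft <- list(X = X, unit_type = "superpixel", unit_labels = ids,
               map = label_map(map), dim = c(H, W))
  }
  dimnames(ft$X) <- NULL
  if (any(!is.finite(ft$X))) stop("build_features: non-finite features")
  structure(ft, class = "feature_table")
}

ft_matrix <- function(features) {
  if (inherits(features, "feature_table")) features$X else as.matrix(features)
}

#' Histogram-mode initialization for intensity clustering
#'
#' Deterministic K-means initialization for pixel-level tissue
#' clustering: the gray histogram is smoothed with a Gaussian kernel and
#' the `k` most prominent local maxima (with a minimum mode separation)
#' become the initial intensity centers; any remaining feature columns
#' (e.g. spatial coordinates) are initialized at the mean feature vector
#' of the pixels within a few gray levels of each mode. Intensity
#' clustering with few classes is prone to local minima when centers are
#' drawn at random (a nucleus occupies a tiny pixel fraction and is
#' almost never sampled); mode seeking guarantees one center per
#' dominant intensity population. Falls back to evenly spaced occupied
#' quantiles when fewer than `k` modes exist.
#'
#' @param image a [gray_image] (or convertible).
#' @param features the `feature_table` the K-means will run on (pixel
#'   units).
#' @param k number of centers.
#' @param min_sep minimum mode separation in gray levels.
#' @return a `k x p` matrix of centers.
#' @export
mode_init <- function(image, features, k, min_sep = 16L) {
  gm <- as_gray_matrix(if (inherits(image, "color_image")) to_gray(image) else image)
  X <- ft_matrix(features)
  counts <- tabulate(as.vector(gm) + 1L, nbins = 256L)
  kern <- dnorm(-8:8, sd = 3)
  sm <- as.vector(stats::filter(c(rep(0, 8), counts, rep(0, 8)), kern,
                                sides = 2))[9:264]
  is_max <- sm >= c(-Inf, sm[-256]) & sm > c(sm[-1], -Inf) & counts > 0
  cand <- order(sm, decreasing = TRUE)
  cand <- cand[is_max[cand]]
  modes <- integer(0)
  for (v in cand) {
    if (length(modes) == k) break
    if (all(abs(v - modes) >= min_sep)) modes <- c(modes, v)
  }
  if (length(modes) < k) {
    occ <- which(counts > 0)
    q <- stats::quantile(rep(occ - 1L, counts[occ]),
                         probs = seq(0, 1, length.out = k))
    modes <- unique(round(q)) + 1L
    if (length(modes) < k)
      stop("mode_init: fewer than k distinct intensity levels")
  }
  modes <- sort(modes) - 1L   # gray values of the modes
  centers <- matrix(0, k, ncol(X))
  gv <- as.vector(gm)
  for (i in seq_len(k)) {
    sel <- abs(gv - modes[i]) <= 8
    if (!any(sel)) sel <- which.min(abs(gv - modes[i]))
    centers[i, ] <- colMeans(X[sel, , drop = FALSE])
    centers[i, 1] <- modes[i] / 255
  }
  centers
}

#' K-means++ seeding (D-squared sampling)
#'
#' The first center is drawn uniformly from the rows; each subsequent
#' center is drawn with probability proportional to the squared distance
#' to its nearest already-chosen center, so duplicate rows of a chosen
#' point can never be picked again.
#'
#' @param features a `feature_table` or numeric matrix.
#' @param k number of centers; must not exceed the number of distinct rows.
#' @param seed RNG seed (deterministic for a fixed value).
#' @return a `k x p` matrix of centers.
#' @export
kmeans_pp_init <- function(features, k, seed = 0L) {
  X <- ft_matrix(features)
  n <- nrow(X)
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stop("kmeans_pp_init: k exceeds the number of distinct rows")
  with_seed(seed, {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    d2 <- rowSums(sweep(X, 2, X[idx[1], ], "-")^2)
    if (k > 1L) for (j in 2:k) {
      idx[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ], "-")^2))
    }
    X[idx, , drop = FALSE]
  })
}

# Squared Euclidean distances from every row of X to every row of C.
dist2 <- function(X, C) {
  D <- matrix(rowSums(X^2), nrow(X), nrow(C)) -
    2 * X %*% t(C) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE)
  pmax(D, 0)
}

#' Lloyd K-means from explicit initial centers
#'
#' Alternates nearest-center assignment (ties to the lowest cluster
#' index) and recentering; the within-cluster sum of squares is recorded
#' after every assignment step and is non-increasing. A cluster that
#' empties is re-seeded at the point farthest from its assigned center,
#' which cannot increase the objective.
#'
#' @param features a `feature_table` or numeric matrix.
#' @param k number of clusters.
#' @param init `k x p` matrix of initial centers (e.g. from
#'   [kmeans_pp_init]).
#' @param max_iter iteration cap.
#' @param tol stop when the objective decreases by less than this.
#' @return an object of class `cluster_model` with fields `k`, `centers`,
#'   `assignment`, `objective`, `trace`, `method = "kmeans"`.
#' @export
fit_kmeans <- function(features, k, init, max_iter = 100L, tol = 1e-8) {
  X <- ft_matrix(features)
  C <- as.matrix(init)
  if (nrow(C) != k || ncol(C) != ncol(X))
    stop("fit_kmeans: init must be a k x p matrix")
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- dist2(X, C)
    a <- max.col(-D, ties.method = "first")
    for (j in which(tabulate(a, nbins = k) == 0L)) {
      far <- which.max(D[cbind(seq_len(nrow(X)), a)])
      C[j, ] <- X[far, ]
      D[, j] <- rowSums(sweep(X, 2, C[j, ], "-")^2)
      a <- max.col(-D, ties.method = "first")
    }
    obj <- sum(D[cbind(seq_len(nrow(X)), a)])
    trace <- c(trace, obj)
    if (length(trace) > 1L && trace[length(trace) - 1L] - obj < tol) break
    Cnew <- C
    for (j in seq_len(k))
      Cnew[j, ] <- colMeans(X[a == j, , drop = FALSE])
    if (identical(Cnew, C)) break   # fixed point: recentering is a no-op
    C <- Cnew
  }
  structure(list(k = k, centers = C, assignment = a,
                 objective = trace[length(trace)], trace = trace,
                 method = "kmeans"),
            class = "cluster_model")
}

#' Diagonal-covariance Gaussian mixture via EM
#'
#' Initialized with K-means++ centers, uniform weights and the pooled
#' per-dimension variance. The E/M iterations use log-sum-exp for
#' stability; per-dimension variances are floored at `1e-6` to avoid
#' degeneracy on (near-)duplicate data. The log-likelihood is recorded
#' each iteration and is non-decreasing; the assignment is the argmax
#' responsibility (ties to the lowest component index).
#'
#' @param features a `feature_table` or numeric matrix.
#' @param k number of mixture components.
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap.
#' @param tol stop when the log-likelihood gain falls below this.
#' @return an object of class `cluster_model` with fields `k`, `centers`,
#'   `variances`, `weights`, `assignment`, `objective` (final
#'   log-likelihood), `trace`, `method = "em_gmm"`.
#' @export
fit_em_gmm <- function(features, k, seed = 0L, max_iter = 200L, tol = 1e-8) {
  X <- ft_matrix(features)
  n <- nrow(X); p <- ncol(X)
  if (k < 1L) stop("fit_em_gmm: k must be >= 1")
  mu <- kmeans_pp_init(X, k, seed)
  v0 <- pmax(apply(X, 2, var), 1e-6)
  if (anyNA(v0)) v0 <- rep(1e-6, p)
  sig2 <- matrix(v0, k, p, byrow = TRUE)
  w <- rep(1 / k, k)
  trace <- numeric(0)
  logresp <- NULL
  for (it in seq_len(max_iter)) {
    lp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      z <- sweep(X, 2, mu[j, ], "-")
      lp[, j] <- log(w[j]) -
        0.5 * sum(log(2 * pi * sig2[j, ])) -
        0.5 * rowSums(sweep(z^2, 2, sig2[j, ], "/"))
    }
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    logresp <- lp - lse
    if (length(trace) > 1L && ll - trace[length(trace) - 1L] < tol) break
    r <- exp(logresp)
    Nj <- pmax(colSums(r), 1e-10)
    w <- Nj / n
    mu <- t(r) %*% X / Nj
    sig2 <- pmax(t(r) %*% X^2 / Nj - mu^2, 1e-6)
  }
  a <- max.col(logresp, ties.method = "first")
  structure(list(k = k, centers = mu, variances = sig2, weights = w,
                 assignment = a, objective = trace[length(trace)],
                 trace = trace, method = "em_gmm"),
            class = "cluster_model")
}

#' Segment a single-cell cytology image by clustering
#'
#' Implements the four clustering segmenters compared on single-cell /
#' partially overlapping material: `"pixel-kmeans"` (gray value per
#' pixel, random seeded initialization), `"pixel-spatial-kmeans"` (gray
#' value plus spatially weighted coordinates), `"superpixel-em"`
#' (Gaussian-mixture EM over superpixel mean intensities) and
#' `"superpixel-kmeans-pp"` (superpixel means plus spatial features with
#' K-means++ seeding). Clustering uses `k = 3` tissue classes mapped to
#' nucleus / cytoplasm / background by ascending mean gray value (nuclei
#' stain darkest, background is brightest; ties go to the lower cluster
#' label). The largest connected foreground (non-background) component,
#' hole-filled, becomes the cell footprint; the nucleus is the largest
#' darkest-class component inside it, falling back to an automatic
#' threshold inside the footprint when the darkest class has no pixels
#' there.
#'
#' @param image a [gray_image] or [color_image] containing one dominant
#'   cell.
#' @param method one of the four method names above.
#' @param seed RNG seed; fixed seed gives an identical segmentation.
#' @param k number of tissue classes (3: background/cytoplasm/nucleus).
#' @param n_superpixels superpixel count for the superpixel variants.
#' @param w_s spatial feature weight for the spatial variants.
#' @param compactness superpixel compactness.
#' @param n_init number of K-means++ restarts for the
#'   `superpixel-kmeans-pp` method; the fit with the lowest
#'   within-cluster sum of squares is kept.
#' @return a [scene_segmentation] with a single [cell_instance].
#' @export
segment_cell <- function(image,
                         method = c("pixel-kmeans", "pixel-spatial-kmeans",
                                    "superpixel-em", "superpixel-kmeans-pp"),
                         seed = 0L, k = 3L, n_superpixels = 300L,
                         w_s = 0.1, compactness = 20, n_init = 10L) {
  method <- match.arg(method)
  gm <- as_gray_matrix(if (inherits(image, "color_image")) to_gray(image) else image)
  if (length(unique(as.vector(gm))) < 2L)
    stop("segment_cell: degenerate input (single gray level)")
  if (method %in% c("superpixel-em", "superpixel-kmeans-pp")) {
    sp <- superpixels(image, n_segments = n_superpixels,
                      compactness = compactness, seed = seed)
  } else sp <- NULL
  model <- switch(method,
    "pixel-kmeans" = {
      ft <- build_features(image, "pixels", spatial = FALSE)
      fit_kmeans(ft, k, mode_init(image, ft, k))
    },
    "pixel-spatial-kmeans" = {
      ft <- build_features(image, "pixels", spatial = TRUE, w_s = w_s)
      fit_kmeans(ft, k, mode_init(image, ft, k))
    },
    "superpixel-em" = {
      ft <- build_features(image, sp, spatial = FALSE)
      fit_em_gmm(ft, k, seed = seed)
    },
    "superpixel-kmeans-pp" = {
      ft <- build_features(image, sp, spatial = TRUE, w_s = w_s)
      # several D^2-seeded restarts, keep the lowest objective: a single
      # unlucky draw can strand Lloyd in a background-splitting minimum
      fits <- lapply(seq_len(n_init), function(r)
        fit_kmeans(ft, k, kmeans_pp_init(ft, k, seed = seed + 1009L * (r - 1L))))
      fits[[which.min(vapply(fits, function(f) f$objective, 0))]]
    })
  ft <- switch(method,
    "pixel-kmeans" = ,
    "pixel-spatial-kmeans" = build_features(image, "pixels"),
    build_features(image, sp))
  H <- nrow(gm); W <- ncol(gm)
  if (is.null(sp)) {
    pixclust <- matrix(model$assignment, H, W)
  } else {
    lut <- integer(max(ft$unit_labels))
    lut[ft$unit_labels] <- model$assignment
    pixclust <- matrix(lut[px(sp)], H, W)
  }
  kk <- model$k
  cl_mean <- vapply(seq_len(kk), function(j) {
    sel <- pixclust == j
    if (any(sel)) mean(gm[sel]) else Inf
  }, 0)
  present <- which(is.finite(cl_mean))
  ord <- present[order(cl_mean[present])]   # stable: ties to lower label
  dark_cl <- ord[1]
  bg_cl <- ord[length(ord)]
  fg <- (pixclust != bg_cl) + 0L
  if (sum(fg) == 0L) stop("segment_cell: no foreground pixels found")
  comp <- round(as.matrix(EBImage::bwlabel(fg)))
  areas <- tabulate(comp[comp > 0L])
  cyt <- (comp == which.max(areas)) + 0L
  cyt <- round(as.matrix(EBImage::fillHull(cyt)))
  nuc_px <- (pixclust == dark_cl) * cyt
  nuc <- largest_component(nuc_px)
  if (sum(nuc) == 0L) {
    h <- gray_histogram(gray_image(matrix(gm[cyt == 1L], ncol = 1L)))
    t <- tryCatch(max_variance_threshold(h)$t_star, error = function(e) NA)
    if (!is.na(t)) nuc <- largest_component((gm <= t) * cyt)
  }
  if (sum(nuc) == 0L) stop("segment_cell: could not locate a nucleus")
  scene_segmentation(list(cell_instance(cyt, nuc)))
}

# Largest 8-connected component of a 0/1 matrix (all-zero stays all-zero).
largest_component <- function(m) {
  comp <- round(as.matrix(EBImage::bwlabel(m + 0L)))
  if (max(comp) == 0L) return(m * 0L)
  areas <- tabulate(comp[comp > 0L])
  (comp == which.max(areas)) + 0L
}
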