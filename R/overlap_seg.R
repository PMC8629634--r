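#' Configuration for the overlapping-cell pipeline
#'
#' All tunable parameters of [segment_overlapping] in one place, with
#' defaults chosen for 8-bit Pap-stain-contrast material at roughly
#' 512 x 512 scale.
#'
#' @param lambda smoothness weight of the graph-cut pairwise term.
#' @param sigma intensity scale (gray levels) of the contrast-weighted
#'   pairwise term `lambda * exp(-(dI)^2 / (2 sigma^2))`.
#' @param graph_max_dim solve the min-cut on a block-averaged grid whose
#'   largest side does not exceed this; the labeling is upsampled and the
#'   boundary band re-labeled per pixel by maximum likelihood. Use `Inf`
#'   for an exact full-resolution cut.
#' @param min_hole_area background holes inside the clump mask smaller
#'   than this many pixels are filled.
#' @param nucleus_min_area,nucleus_max_area admissible nucleus blob area
#'   (pixels).
#' @param nucleus_min_solidity minimum blob solidity (area / convex hull
#'   area).
#' @param nucleus_max_compactness maximum of `area / (pi r_in^2)` where
#'   `r_in` is the largest inscribed-disc radius; elongated or
#'   lens-shaped dark blobs (typical of overlap shadows) exceed this
#'   while roundish nuclei do not.
#' @param intensity_margin gray levels below the single-layer cytoplasm
#'   level at which a pixel counts as multi-layer absorbance evidence for
#'   overlap compensation.
#' @param max_extension radial cap (pixels, from the nucleus centroid) on
#'   overlap compensation growth.
#' @param close_radius disc radius of the final morphological closing of
#'   each cell mask.
#' @return a named list of class `overlap_config`.
#' @export
overlap_config <- function(lambda = 2, sigma = 10, graph_max_dim = 128L,
                           min_hole_area = 200L, nucleus_min_area = 30L,
                           nucleus_max_area = 6000L,
                           nucleus_min_solidity = 0.8,
                           nucleus_max_compactness = 2.2,
                           intensity_margin = 30, max_extension = 120,
                           close_radius = 5L) {
  cfg <- list(lambda = lambda, sigma = sigma, graph_max_dim = graph_max_dim,
              min_hole_area = min_hole_area,
              nucleus_min_area = nucleus_min_area,
              nucleus_max_area = nucleus_max_area,
              nucleus_min_solidity = nucleus_min_solidity,
              nucleus_max_compactness = nucleus_max_compactness,
              intensity_margin = intensity_margin,
              max_extension = max_extension, close_radius = close_radius)
  stopifnot(cfg$lambda >= 0, cfg$sigma > 0, cfg$max_extension >= 0)
  structure(cfg, class = "overlap_config")
}

# Energy of a binary labeling under the Boykov-Jolly model used by
# separate_clumps: sum of unary -log likelihoods plus the contrast
# Potts penalty over cut 4-neighbor pairs. Used by tests as the
# exhaustive-oracle counterpart of the min-cut value.
cut_energy <- function(gm, mask, lambda, sigma, fg_model, bg_model) {
  Dfg <- unary_cost(gm, fg_model)
  Dbg <- unary_cost(gm, bg_model)
  e <- sum(ifelse(mask == 1L, Dfg, Dbg))
  H <- nrow(gm); W <- ncol(gm)
  if (W > 1L) {
    cut <- mask[, -W] != mask[, -1]
    dI <- gm[, -W] - gm[, -1]
    e <- e + sum(lambda * exp(-dI[cut]^2 / (2 * sigma^2)))
  }
  if (H > 1L) {
    cut <- mask[-H, ] != mask[-1, ]
    dI <- gm[-H, ] - gm[-1, ]
    e <- e + sum(lambda * exp(-dI[cut]^2 / (2 * sigma^2)))
  }
  e
}

unary_cost <- function(gm, model) {
  pmin(-dnorm(gm, model$mean, model$sd, log = TRUE), 1e3)
}

# Two-Gaussian intensity model seeded from the maximum between-class
# variance split: class 1 (<= t) is the darker cell/clump class.
otsu_intensity_models <- function(gm) {
  h <- gray_histogram(gray_image(gm))
  t <- max_variance_threshold(h)$t_star
  lo <- gm <= t
  safe_sd <- function(x) {
    s <- sd(x)
    if (is.na(s)) 1 else max(s, 1)   # single-pixel class: unit spread
  }
  list(t = t,
       fg = list(mean = mean(gm[lo]), sd = safe_sd(gm[lo])),
       bg = list(mean = mean(gm[!lo]), sd = safe_sd(gm[!lo])))
}

#' Separate cell clumps from the background by graph cut
#'
#' Binary min-cut labeling of the pixel grid: unary costs are negative
#' log-likelihoods under two Gaussian intensity models seeded from the
#' maximum between-class variance split (cells are the darker class);
#' pairwise costs are a contrast-weighted Potts penalty
#' `lambda * exp(-(dI)^2 / (2 sigma^2))` on 4-neighbor pairs. With
#' `lambda = 0` the result reduces to per-pixel maximum-likelihood
#' labeling. For large images the cut is solved on a block-averaged grid
#' (side capped at `graph_max_dim`), upsampled, and the boundary band
#' re-labeled per pixel by maximum likelihood. Background holes smaller
#' than `min_hole_area` are filled.
#'
#' @param image a [gray_image] (or convertible).
#' @param lambda,sigma,graph_max_dim,min_hole_area see [overlap_config].
#' @return a [binary_mask] of the clump (foreground) pixels, with
#'   attributes `cut_value` (the min-cut value on the solved grid),
#'   `threshold` and `models`.
#' @export
separate_clumps <- function(image, lambda = 2, sigma = 10,
                            graph_max_dim = 128L, min_hole_area = 200L) {
  gm <- as_gray_matrix(if (inherits(image, "color_image")) to_gray(image) else image)
  storage.mode(gm) <- "double"
  if (length(unique(as.vector(gm))) < 2L)
    stop("separate_clumps: degenerate (single-level) image")
  H <- nrow(gm); W <- ncol(gm)
  f <- max(1L, as.integer(ceiling(max(H, W) / graph_max_dim)))
  gs <- if (f > 1L) block_average(gm, f) else gm
  models <- otsu_intensity_models(gm)
  Dfg <- unary_cost(gs, models$fg)
  Dbg <- unary_cost(gs, models$bg)
  mask_s <- mincut_binary(gs, Dfg, Dbg, lambda, sigma)
  cut_value <- attr(mask_s, "cut_value")
  if (f > 1L) {
    mask <- kronecker(mask_s, matrix(1L, f, f))[seq_len(H), seq_len(W), drop = FALSE]
    # refine the +/- f boundary band by per-pixel maximum likelihood
    band <- round(as.matrix(EBImage::dilate(mask, EBImage::makeBrush(brush_size(f), "disc")))) -
      round(as.matrix(EBImage::erode(mask, EBImage::makeBrush(brush_size(f), "disc"))))
    bandpix <- band == 1L
    if (any(bandpix)) {
      Df <- unary_cost(gm, models$fg); Db <- unary_cost(gm, models$bg)
      mask[bandpix] <- (Df[bandpix] < Db[bandpix]) + 0L
    }
  } else mask <- mask_s
  mask <- fill_small_holes(mask, min_hole_area)
  out <- binary_mask(mask)
  attr(out, "cut_value") <- cut_value
  attr(out, "threshold") <- models$t
  attr(out, "models") <- models[c("fg", "bg")]
  out
}

brush_size <- function(f) {
  s <- 2L * as.integer(f) + 1L
  if (s %% 2L == 0L) s + 1L else s
}

block_average <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  Hp <- as.integer(ceiling(H / f) * f); Wp <- as.integer(ceiling(W / f) * f)
  if (Hp > H) m <- rbind(m, m[rep(H, Hp - H), , drop = FALSE])
  if (Wp > W) m <- cbind(m, m[, rep(W, Wp - W), drop = FALSE])
  rsum <- rowsum(m, rep(seq_len(Hp / f), each = f))
  t(rowsum(t(rsum), rep(seq_len(Wp / f), each = f))) / f^2
}

# Min s-t cut of the 4-connected pixel grid with the given unary costs.
# Returns the 0/1 foreground mask with the cut value as an attribute.
mincut_binary <- function(gs, Dfg, Dbg, lambda, sigma) {
  H <- nrow(gs); W <- ncol(gs); n <- H * W
  if (lambda == 0) {
    out <- (Dfg < Dbg) + 0L
    attr(out, "cut_value") <- sum(pmin(Dfg, Dbg))
    return(out)
  }
  idx <- matrix(seq_len(n), H, W)
  e_h <- cbind(as.vector(idx[, -W, drop = FALSE]), as.vector(idx[, -1, drop = FALSE]))
  e_v <- cbind(as.vector(idx[-H, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE]))
  pw <- rbind(e_h, e_v)
  wpw <- lambda * exp(-(gs[pw[, 1]] - gs[pw[, 2]])^2 / (2 * sigma^2))
  src <- n + 1L; snk <- n + 2L
  edges <- rbind(pw, pw[, 2:1, drop = FALSE],
                 cbind(src, seq_len(n)), cbind(seq_len(n), snk))
  caps <- c(wpw, wpw, as.vector(Dbg), as.vector(Dfg))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  mf <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  fgset <- as.integer(mf$partition1)       # source side = foreground
  out <- matrix(0L, H, W)
  out[fgset[fgset <= n]] <- 1L
  attr(out, "cut_value") <- mf$value
  out
}

fill_small_holes <- function(mask, min_hole_area) {
  filled <- round(as.matrix(EBImage::fillHull(mask)))
  holes <- filled - mask
  if (sum(holes) > 0L) {
    hl <- round(as.matrix(EBImage::bwlabel(holes)))
    areas <- tabulate(hl[hl > 0L])
    small <- which(areas < min_hole_area)
    mask[hl %in% small] <- 1L
  }
  # symmetrically, drop foreground specks below the same area scale
  fl <- round(as.matrix(EBImage::bwlabel(mask)))
  if (max(fl) > 1L) {
    areas <- tabulate(fl[fl > 0L])
    mask[fl %in% which(areas < min_hole_area)] <- 0L
  }
  mask
}

#' Detect nuclei inside a clump mask
#'
#' Applies the maximum between-class variance threshold to the clump's
#' own intensity histogram; connected components of the dark class are
#' kept as nuclei when they pass area, solidity and compactness filters.
#' The compactness filter (`area / (pi r_in^2)` with `r_in` the largest
#' inscribed-disc radius) rejects elongated or lens-shaped dark blobs
#' such as the absorbance shadow of an overlap region, which would
#' otherwise masquerade as nuclei. A component that fails the filters is
#' refined recursively (to depth 2): nuclei are darker than a
#' single-overlap shadow, so re-thresholding the failing component's own
#' intensities splits merged nucleus+shadow blobs into sub-blobs that
#' are filtered again; shadow-only residue fails the filters and is
#' dropped. An empty result is valid.
#'
#' @param image a [gray_image].
#' @param clump a [binary_mask] of the clump.
#' @param min_area,max_area,min_solidity,max_compactness see
#'   [overlap_config].
#' @return an object of class `nucleus_set`: a list of
#'   `list(mask, centroid)` with pairwise-disjoint masks inside the
#'   clump.
#' @export
detect_nuclei <- function(image, clump, min_area = 30L, max_area = 6000L,
                          min_solidity = 0.8, max_compactness = 2.2) {
  gm <- as_gray_matrix(image)
  cm <- px(binary_mask(clump))
  if (sum(cm) == 0L) stop("detect_nuclei: empty clump mask")
  vals <- gm[cm == 1L]
  masks <- list()
  if (length(unique(vals)) >= 2L) {
    h <- gray_histogram(gray_image(matrix(vals, ncol = 1L)))
    t <- max_variance_threshold(h)$t_star
    dark <- (gm <= t) * cm
    masks <- refine_nucleus_blobs(gm, dark, min_area, max_area,
                                  min_solidity, max_compactness,
                                  depth = 3L, top = TRUE)
    masks <- dedup_nucleus_blobs(masks)
  }
  nuclei <- lapply(masks, function(m)
    list(mask = binary_mask(m), centroid = mask_centroid(m)))
  structure(nuclei, class = "nucleus_set")
}

# Filter the connected components of a dark mask; components failing the
# shape filters are re-thresholded within themselves (depth levels deep)
# because nuclei are darker than overlap shadows they may be fused with.
# Blobs first appearing below the top level come out of a noise-cutting
# split, so they must clear a higher area floor (max_area / 30) than the
# user's min_area: noise-threshold fragments of a shadow region are
# small, whole nuclei are not. All work is done on bounding-box crops.
refine_nucleus_blobs <- function(gm, dark, min_area, max_area, min_solidity,
                                 max_compactness, depth, top = TRUE) {
  H <- nrow(gm)
  out <- list()
  floor_a <- if (top) min_area else max(min_area, max_area %/% 30L)
  comp <- round(as.matrix(EBImage::bwlabel(dark)))
  for (j in seq_len(max(comp))) {
    sel <- comp == j
    if (sum(sel) < floor_a) next
    bb <- mask_bbox(sel + 0L)
    r0 <- max(1L, bb[1] - 4L); r1 <- min(nrow(gm), bb[2] + 4L)
    c0 <- max(1L, bb[3] - 4L); c1 <- min(ncol(gm), bb[4] + 4L)
    ms <- sel[r0:r1, c0:c1, drop = FALSE] + 0L
    gs <- gm[r0:r1, c0:c1, drop = FALSE]
    # fill noise-scale holes before shape measurement: speckle holes
    # destroy the inscribed-disc radius and solidity of a clean blob;
    # structural holes (nucleus-sized or larger) must stay open so an
    # annular residue does not swallow its interior back
    ms <- fill_holes_below(ms, min_area)
    a <- sum(ms)
    if (a < floor_a) next
    ok <- a <= max_area && blob_solidity(ms) >= min_solidity
    if (ok) {
      rin <- max(as.matrix(EBImage::distmap(ms)))
      ok <- a / (pi * rin^2) <= max_compactness
    }
    if (ok) {
      full <- matrix(0L, nrow(gm), ncol(gm))
      full[r0:r1, c0:c1] <- ms
      out[[length(out) + 1L]] <- full
    } else if (depth > 0L) {
      vals <- gs[ms == 1L]
      if (length(unique(vals)) < 2L) next
      t2 <- tryCatch(
        max_variance_threshold(gray_histogram(gray_image(matrix(vals, ncol = 1L))))$t_star,
        error = function(e) NA_integer_)
      if (is.na(t2)) next
      sub_dark <- (gs <= t2) * ms
      sub_bright <- ms - sub_dark
      if (sum(sub_dark) == 0L || sum(sub_bright) == 0L) next
      # a fused blob can hold >2 intensity layers (doubly-shadowed
      # nucleus parts, plain nuclei, single-overlap shadow): refine both
      # sides of the split
      for (sub in list(sub_dark, sub_bright)) {
        leaves <- refine_nucleus_blobs(gs, sub, min_area, max_area,
                                       min_solidity, max_compactness,
                                       depth - 1L, top = FALSE)
        for (lf in leaves) {
          full <- matrix(0L, nrow(gm), ncol(gm))
          full[r0:r1, c0:c1] <- lf
          out[[length(out) + 1L]] <- full
        }
      }
    }
  }
  out
}

fill_holes_below <- function(m, maxa) {
  filled <- round(as.matrix(EBImage::fillHull(m)))
  holes <- filled - m
  if (sum(holes) == 0L) return(m)
  hl <- round(as.matrix(EBImage::bwlabel(holes)))
  areas <- tabulate(hl[hl > 0L])
  m[hl %in% which(areas < maxa)] <- 1L
  m
}

# A nucleus split across intensity layers yields several blobs whose
# centroids all lie inside the nucleus; keep the largest blob of any
# such group. A smaller blob counts as a fragment of a kept blob when
# its centroid falls within 1.25 equivalent radii of the kept blob's
# centroid — distinct nuclei sit much farther apart than that.
dedup_nucleus_blobs <- function(masks) {
  if (length(masks) < 2L) return(masks)
  areas <- vapply(masks, sum, 0L)
  ctrs <- t(vapply(masks, mask_centroid, c(0, 0)))
  ord <- order(areas, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      d <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
      if (d <= 1.25 * sqrt(areas[j] / pi)) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  masks[sort(kept)]
}

# Solidity = pixel area / lattice-point area of the convex hull
# (Pick-corrected: interior + boundary lattice points of the hull
# polygon over pixel centers).
blob_solidity <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  a <- nrow(idx)
  if (a <= 3L) return(1)
  hull <- chull(idx[, 2], idx[, 1])
  pts <- idx[hull, , drop = FALSE]
  nh <- nrow(pts)
  x <- pts[, 2]; y <- pts[, 1]
  area2 <- abs(sum(x * y[c(2:nh, 1)] - x[c(2:nh, 1)] * y))
  B <- sum(vapply(seq_len(nh), function(i) {
    j <- if (i == nh) 1L else i + 1L
    gcd2(abs(x[i] - x[j]), abs(y[i] - y[j]))
  }, 0))
  hull_pts <- area2 / 2 - B / 2 + 1 + B   # Pick: I + B = A - B/2 + 1 + B
  min(a / max(hull_pts, a), 1)
}

gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

#' Voronoi coarse partition of a clump by nucleus seeds
#'
#' Assigns every clump pixel the label of the nearest seed centroid under
#' Euclidean distance; ties go to the lowest seed index.
#'
#' @param clump a [binary_mask].
#' @param seeds a `nucleus_set` (or list of `list(centroid = ...)`)
#'   with at least one seed.
#' @return a `coarse_partition`: a [label_map] over the clump (0 outside)
#'   whose label count equals the seed count.
#' @export
voronoi_partition <- function(clump, seeds) {
  cm <- px(binary_mask(clump))
  if (length(seeds) == 0L) stop("voronoi_partition: zero seeds")
  H <- nrow(cm); W <- ncol(cm)
  rr <- row(cm); cc <- col(cm)
  best <- matrix(Inf, H, W)
  lab <- matrix(0L, H, W)
  for (s in seq_along(seeds)) {
    ctr <- seeds[[s]]$centroid
    d <- (rr - ctr[1])^2 + (cc - ctr[2])^2
    upd <- cm == 1L & d < best     # strict: first (lowest) seed wins ties
    lab[upd] <- s
    best[upd] <- d[upd]
  }
  out <- label_map(lab)
  class(out) <- c("coarse_partition", class(out))
  out
}

#' Compensate the overlap regions of a coarse partition
#'
#' The Voronoi partition splits an overlap region between the adjacent
#' cells, but a truly overlapping region belongs to every cell covering
#' it. Under an absorbance imaging model, pixels covered by two cytoplasm
#' layers are systematically darker than single-layer cytoplasm, so the
#' compensation step treats clump pixels whose intensity falls at least
#' `intensity_margin` gray levels below the single-layer cytoplasm level
#' (the median of the clump's bright Otsu class) as overlap evidence.
#' Each cell annexes the evidence pixels that are 8-connected to its
#' coarse region and lie within `max_extension` of its nucleus centroid;
#' the resulting masks may overlap, stay connected, and always contain
#' the coarse region. With `max_extension = 0` the coarse regions are
#' returned unchanged, and growth is monotone in `max_extension`.
#'
#' @param image a [gray_image].
#' @param partition a `coarse_partition` from [voronoi_partition].
#' @param seeds the `nucleus_set` used for the partition.
#' @param max_extension radial growth cap in pixels.
#' @param intensity_margin evidence margin in gray levels.
#' @return a list of per-cell [binary_mask]s, one per seed.
#' @export
compensate_overlap <- function(image, partition, seeds, max_extension = 120,
                               intensity_margin = 30) {
  gm <- as_gray_matrix(image)
  part <- px(partition)
  if (length(seeds) != max(part))
    stop("compensate_overlap: seed count does not match partition labels")
  clump <- part > 0L
  H <- nrow(part); W <- ncol(part)
  rr <- row(part); cc <- col(part)
  evidence <- matrix(FALSE, H, W)
  if (max_extension > 0 && any(clump)) {
    vals <- gm[clump]
    cyto_level <- tryCatch({
      h <- gray_histogram(gray_image(matrix(vals, ncol = 1L)))
      t <- max_variance_threshold(h)$t_star
      median(vals[vals > t])
    }, error = function(e) median(vals))
    evidence <- clump & (gm <= cyto_level - intensity_margin)
  }
  out <- vector("list", length(seeds))
  for (s in seq_along(seeds)) {
    coarse <- (part == s) + 0L
    if (max_extension <= 0 || !any(evidence)) {
      out[[s]] <- binary_mask(coarse)
      next
    }
    ctr <- seeds[[s]]$centroid
    d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
    cand <- (evidence & d2 <= max_extension^2) | coarse == 1L
    comp <- round(as.matrix(EBImage::bwlabel(cand + 0L)))
    keep <- unique(comp[coarse == 1L & comp > 0L])
    grown <- (comp %in% keep & cand) + 0L
    dim(grown) <- dim(coarse)
    out[[s]] <- binary_mask(pmax(grown, coarse))
  }
  out
}

#' Merge coarse regions and compensated extensions into complete cells
#'
#' Each cell's cytoplasm is the union of its coarse region and its
#' compensated extension, morphologically closed (disc of
#' `close_radius`), hole-filled, and reduced to the connected component
#' containing its nucleus; the nucleus mask is attached. A nucleus that
#' no longer touches its cell mask signals an upstream bug and raises an
#' error.
#'
#' @param partition a `coarse_partition`.
#' @param masks list of compensated [binary_mask]s from
#'   [compensate_overlap].
#' @param nuclei the matching `nucleus_set`.
#' @param close_radius disc radius of the final closing.
#' @return a [scene_segmentation] with one [cell_instance] per nucleus.
#' @export
merge_cells <- function(partition, masks, nuclei, close_radius = 5L) {
  part <- px(partition)
  if (length(masks) != length(nuclei))
    stop("merge_cells: mask / nucleus counts differ")
  brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
  cells <- vector("list", length(nuclei))
  for (s in seq_along(nuclei)) {
    m <- pmax(px(masks[[s]]), px(nuclei[[s]]$mask))
    m <- round(as.matrix(EBImage::closing(m, brush)))
    m <- round(as.matrix(EBImage::fillHull(m)))
    comp <- round(as.matrix(EBImage::bwlabel(m)))
    nuc_lab <- unique(comp[px(nuclei[[s]]$mask) == 1L])
    nuc_lab <- nuc_lab[nuc_lab > 0L]
    if (length(nuc_lab) == 0L)
      stop("merge_cells: nucleus ", s, " detached from its cell mask")
    m <- (comp == nuc_lab[1]) + 0L
    m <- pmax(m, px(nuclei[[s]]$mask))
    cells[[s]] <- cell_instance(m, px(nuclei[[s]]$mask),
                                nuclei[[s]]$centroid)
  }
  scene_segmentation(cells)
}

#' Segment an overlapping-cell scene
#'
#' The combined pipeline for multicell images with overlapping
#' cytoplasm: graph-cut clump/background separation, nucleus detection
#' inside each clump, Voronoi coarse division seeded at the nucleus
#' centroids, absorbance-evidence overlap compensation, and a final
#' merge into complete cells. Clumps in which no nucleus passes the
#' detection filters contribute no cells (with a warning). The pipeline
#' is deterministic; a blank (single-level) image yields an empty scene.
#'
#' @param image a [gray_image] or [color_image].
#' @param config an [overlap_config].
#' @return a [scene_segmentation]; the cell count equals the number of
#'   detected nuclei.
#' @export
segment_overlapping <- function(image, config = overlap_config()) {
  gm <- as_gray_matrix(if (inherits(image, "color_image")) to_gray(image) else image)
  empty <- function() scene_segmentation(
    list(), binary_mask(matrix(1L, nrow(gm), ncol(gm))))
  if (length(unique(as.vector(gm))) < 2L) return(empty())
  clumps <- separate_clumps(gray_image(gm), lambda = config$lambda,
                            sigma = config$sigma,
                            graph_max_dim = config$graph_max_dim,
                            min_hole_area = config$min_hole_area)
  lab <- round(as.matrix(EBImage::bwlabel(px(clumps))))
  cells <- list()
  for (j in seq_len(max(lab))) {
    cm <- (lab == j) + 0L
    if (sum(cm) < config$nucleus_min_area) next
    nuc <- detect_nuclei(gray_image(gm), binary_mask(cm),
                         min_area = config$nucleus_min_area,
                         max_area = config$nucleus_max_area,
                         min_solidity = config$nucleus_min_solidity,
                         max_compactness = config$nucleus_max_compactness)
    if (length(nuc) == 0L) {
      warning("segment_overlapping: no nucleus detected in clump ", j,
              "; emitting no cells for it")
      next
    }
    part <- voronoi_partition(binary_mask(cm), nuc)
    masks <- compensate_overlap(gray_image(gm), part, nuc,
                                max_extension = config$max_extension,
                                intensity_margin = config$intensity_margin)
    sc <- merge_cells(part, masks, nuc, close_radius = config$close_radius)
    cells <- c(cells, sc$cells)
  }
  if (length(cells) == 0L) return(empty())
  scene_segmentation(cells)
}
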