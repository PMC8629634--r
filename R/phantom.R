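#' Specification of a synthetic cytology phantom scene
#'
#' Describes a Pap-stain-like scene: bright near-uniform background, one
#' or more cells with elliptical (boundary-perturbed) cytoplasm and a
#' concentric darker nucleus, optional pairwise cytoplasm overlap, a
#' smooth illumination gradient and Gaussian noise. Default intensity
#' levels (background 220, cytoplasm 150, nucleus 60, noise sd 8) give
#' the contrast ordering nucleus < cytoplasm < background that Pap
#' staining produces. Cell sizes default to fractions of the image side:
#' single-cell scenes get one large centered cell (Herlev-style crop),
#' multicell scenes get smaller cells (ISBI-style field of view).
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_cells number of cells.
#' @param overlap_fraction target mean pairwise cytoplasm overlap,
#'   measured as `|A n B| / min(|A|, |B|)`, in `[0, 0.6]`.
#' @param bg_level,cyto_level,nucleus_level mean intensities in
#'   `[0, 255]`, strictly decreasing from background to nucleus.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param cyto_axes,nucleus_axes semi-axis ranges in pixels (`NULL` =
#'   size-based defaults).
#' @param boundary_pert relative amplitude of the cytoplasm boundary
#'   perturbation harmonics (0 gives exact ellipses).
#' @param gradient_amp amplitude of the smooth background gradient.
#' @param seed RNG seed; a spec with its seed fully determines the scene.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512L, 512L), n_cells = 3L,
                         overlap_fraction = 0.2, bg_level = 220,
                         cyto_level = 150, nucleus_level = 60,
                         noise_sd = 8, cyto_axes = NULL,
                         nucleus_axes = NULL, boundary_pert = 0.08,
                         gradient_amp = 10, seed = 0L) {
  s <- min(image_size)
  if (is.null(cyto_axes))
    cyto_axes <- if (n_cells == 1L) c(0.20, 0.28) * s else c(0.11, 0.16) * s
  if (is.null(nucleus_axes))
    nucleus_axes <- if (n_cells == 1L) c(0.055, 0.085) * s else c(0.027, 0.043) * s
  spec <- list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
               overlap_fraction = overlap_fraction, bg_level = bg_level,
               cyto_level = cyto_level, nucleus_level = nucleus_level,
               noise_sd = noise_sd, cyto_axes = cyto_axes,
               nucleus_axes = nucleus_axes, boundary_pert = boundary_pert,
               gradient_amp = gradient_amp, seed = as.integer(seed))
  if (!(spec$nucleus_level < spec$cyto_level && spec$cyto_level < spec$bg_level))
    stop("phantom_spec: need nucleus_level < cyto_level < bg_level")
  if (spec$overlap_fraction < 0 || spec$overlap_fraction > 0.6)
    stop("phantom_spec: overlap_fraction must lie in [0, 0.6]")
  if (max(spec$nucleus_axes) >= min(spec$cyto_axes))
    stop("phantom_spec: nucleus axes must be smaller than cytoplasm axes")
  if (spec$n_cells < 1L || any(spec$image_size < 8L))
    stop("phantom_spec: infeasible geometry")
  if (2.4 * max(spec$cyto_axes) > s)
    stop("phantom_spec: cells too large for the image")
  structure(spec, class = "phantom_spec")
}

# Sample the geometric parameters of one cell from the current RNG state.
sample_cell_geometry <- function(spec) {
  a <- runif(1, spec$cyto_axes[1], spec$cyto_axes[2])
  b <- a * runif(1, 0.65, 1)
  ang <- runif(1, 0, pi)
  pert <- if (spec$boundary_pert > 0) {
    list(am = rnorm(3, 0, spec$boundary_pert / (2:4)),
         bm = rnorm(3, 0, spec$boundary_pert / (2:4)))
  } else list(am = numeric(3), bm = numeric(3))
  na <- runif(1, spec$nucleus_axes[1], spec$nucleus_axes[2])
  nb <- na * runif(1, 0.7, 1)
  nang <- runif(1, 0, pi)
  off_r <- runif(1, 0, 0.35) * max(b - na, 0)
  off_phi <- runif(1, 0, 2 * pi)
  list(a = a, b = b, ang = ang, pert = pert,
       na = na, nb = nb, nang = nang,
       off = off_r * c(sin(off_phi), cos(off_phi)))
}

# Rasterize an ellipse with optional radial harmonic perturbation into a
# full-size 0/1 matrix. Perturbation zero => exact analytic ellipse.
raster_ellipse <- function(size, center, a, b, ang, pert = NULL) {
  H <- size[1]; W <- size[2]
  pad <- ceiling(max(a, b) * 1.35) + 1
  r0 <- max(1L, floor(center[1] - pad)); r1 <- min(H, ceiling(center[1] + pad))
  c0 <- max(1L, floor(center[2] - pad)); c1 <- min(W, ceiling(center[2] + pad))
  out <- matrix(0L, H, W)
  if (r1 < r0 || c1 < c0) return(out)
  rs <- r0:r1; cs <- c0:c1
  dr <- matrix(rs - center[1], length(rs), length(cs))
  dc <- matrix(cs - center[2], length(rs), length(cs), byrow = TRUE)
  u <- dc * cos(ang) + dr * sin(ang)
  v <- -dc * sin(ang) + dr * cos(ang)
  e <- sqrt((u / a)^2 + (v / b)^2)
  if (is.null(pert) || (all(pert$am == 0) && all(pert$bm == 0))) {
    rho <- 1
  } else {
    phi <- atan2(v / b, u / a)
    rho <- 1
    for (m in 2:4)
      rho <- rho + pert$am[m - 1] * cos(m * phi) + pert$bm[m - 1] * sin(m * phi)
    rho <- pmin(pmax(rho, 0.75), 1.25)
  }
  out[rs, cs] <- (e <= rho) + 0L
  out
}

# Build cytoplasm + nucleus masks for a cell geometry at a given center.
raster_cell <- function(spec, geom, center) {
  cyt <- raster_ellipse(spec$image_size, center, geom$a, geom$b, geom$ang,
                        geom$pert)
  nuc <- raster_ellipse(spec$image_size, center + geom$off, geom$na,
                        geom$nb, geom$nang)
  nuc <- nuc * cyt
  list(cytoplasm = cyt, nucleus = nuc)
}

#' Generate a single phantom cell
#'
#' Draws a cell geometry from the current RNG state (seeded by the
#' caller) and rasterizes it at `center` (image center by default):
#' a rotated ellipse cytoplasm with low-order harmonic boundary
#' perturbation and a concentric smaller ellipse nucleus, clipped so
#' the nucleus is always contained in the cytoplasm.
#'
#' @param spec a [phantom_spec].
#' @param center optional `(row, col)` center.
#' @return a [cell_instance].
#' @export
generate_cell <- function(spec, center = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(center)) center <- (spec$image_size + 1) / 2
  for (try in 1:50) {
    geom <- sample_cell_geometry(spec)
    m <- raster_cell(spec, geom, center)
    if (sum(m$nucleus) > 0L && sum(m$cytoplasm) > 0L)
      return(cell_instance(m$cytoplasm, m$nucleus))
  }
  stop("generate_cell: infeasible geometry")
}

#' Mean pairwise cytoplasm overlap of a scene
#'
#' The mean over all unordered cell pairs of
#' `|A n B| / min(|A|, |B|)`; 0 for scenes with fewer than two cells.
#'
#' @param x a [scene_segmentation] or list of [cell_instance]s.
#' @return a real in `[0, 1]`.
#' @export
pairwise_overlap <- function(x) {
  cells <- if (inherits(x, "scene_segmentation")) x$cells else x
  n <- length(cells)
  if (n < 2L) return(0)
  masks <- lapply(cells, function(cl) px(cl$cytoplasm))
  areas <- vapply(masks, sum, 0L)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, sum(masks[[i]] & masks[[j]]) / min(areas[i], areas[j]))
  mean(vals)
}

#' Generate a phantom scene with exact ground truth
#'
#' Places `n_cells` cells, tuning their spacing until the realized mean
#' pairwise overlap is within 20% (relative) of `overlap_fraction`
#' (exactly disjoint when the target is 0), then renders the image under
#' an additive absorbance model: every cytoplasm layer covering a pixel
#' subtracts `bg_level - cyto_level` and every nucleus additionally
#' subtracts `cyto_level - nucleus_level`, so overlap regions are
#' rendered darker than single-layer cytoplasm and carry intensity
#' evidence of the overlap. A smooth illumination gradient and Gaussian
#' noise are added and the result is clipped to `[0, 255]`.
#'
#' @param spec a [phantom_spec].
#' @return a list with `image` (a [gray_image]), `truth` (a
#'   [scene_segmentation]) and `realized_overlap`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    n <- spec$n_cells
    ctr <- c(H + 1, W + 1) / 2
    if (n == 1L) {
      jit <- runif(2, -0.04, 0.04) * c(H, W)
      cells <- list(generate_cell(spec, ctr + jit))
      placed <- TRUE
    } else if (spec$overlap_fraction == 0) {
      cells <- list(); masks <- list()
      margin <- 1.3 * spec$cyto_axes[2]
      placed <- TRUE
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in 1:300) {
          cen <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
          geom <- sample_cell_geometry(spec)
          m <- raster_cell(spec, geom, cen)
          if (sum(m$nucleus) == 0L) next
          disj <- all(vapply(masks, function(pm) sum(pm & m$cytoplasm) == 0L,
                             TRUE))
          if (disj) {
            masks[[i]] <- m$cytoplasm
            cells[[i]] <- cell_instance(m$cytoplasm, m$nucleus)
            ok <- TRUE; break
          }
        }
        if (!ok) { placed <- FALSE; break }
      }
      if (!placed) stop("generate_scene: placement failure (disjoint)")
    } else {
      placed <- FALSE
      for (attempt in 1:40) {
        geoms <- replicate(n, sample_cell_geometry(spec), simplify = FALSE)
        phis <- 2 * pi * (seq_len(n) - 1) / n + runif(n, -0.25, 0.25)
        dirs <- cbind(sin(phis), cos(phis))
        R0 <- mean(vapply(geoms, function(g) (g$a + g$b) / 2, 0))
        smax <- (min(H, W) / 2 - 1.3 * spec$cyto_axes[2]) / R0
        lo <- 0.1; hi <- max(smax, 0.3)
        realize <- function(s) {
          cen <- lapply(seq_len(n), function(i) ctr + s * R0 * dirs[i, ])
          ms <- lapply(seq_len(n), function(i) raster_cell(spec, geoms[[i]], cen[[i]]))
          if (any(vapply(ms, function(m) sum(m$nucleus) == 0L, TRUE)))
            return(NULL)
          cl <- lapply(ms, function(m) cell_instance(m$cytoplasm, m$nucleus))
          list(cells = cl, ov = pairwise_overlap(cl))
        }
        sol <- NULL
        for (bs in 1:24) {
          mid <- (lo + hi) / 2
          r <- realize(mid)
          if (is.null(r)) break
          if (abs(r$ov - spec$overlap_fraction) <= 0.2 * spec$overlap_fraction) {
            sol <- r; break
          }
          if (r$ov > spec$overlap_fraction) lo <- mid else hi <- mid
        }
        if (!is.null(sol)) { cells <- sol$cells; placed <- TRUE; break }
      }
      if (!placed) stop("generate_scene: placement failure (overlap target)")
    }
    theta <- runif(1, 0, 2 * pi)
    rn <- (row(matrix(0, H, W)) - 1) / max(H - 1, 1) - 0.5
    cn <- (col(matrix(0, H, W)) - 1) / max(W - 1, 1) - 0.5
    plane <- spec$bg_level + spec$gradient_amp * (cos(theta) * rn + sin(theta) * cn)
    absorb <- matrix(0, H, W)
    for (cl in cells) {
      absorb <- absorb + (spec$bg_level - spec$cyto_level) * px(cl$cytoplasm) +
        (spec$cyto_level - spec$nucleus_level) * px(cl$nucleus)
    }
    img <- plane - absorb
    if (spec$noise_sd > 0) img <- img + rnorm(H * W, 0, spec$noise_sd)
    img <- pmin(pmax(round(img), 0), 255)
    list(image = gray_image(img),
         truth = scene_segmentation(cells),
         realized_overlap = pairwise_overlap(cells))
  })
}

#' Generate and write a phantom dataset
#'
#' Writes `n_images` scenes under `out_dir`: `scene_<i>.png` (the image),
#' `scene_<i>/` (the per-cell ground-truth masks, see [write_scene]) and
#' a `manifest.json` listing every entry with its seed. Scene `i` uses
#' seed `base_seed + i - 1`, so the dataset is fully reproducible from
#' `(spec, base_seed)`.
#'
#' @param n_images number of scenes (>= 1).
#' @param spec a [phantom_spec] (its own seed field is ignored).
#' @param base_seed integer seed of the first scene.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(n_images, spec, base_seed = 0L, out_dir) {
  stopifnot(n_images >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec; sp$seed <- as.integer(base_seed + i - 1L)
    sc <- generate_scene(sp)
    img_file <- sprintf("scene_%03d.png", i)
    truth_dir <- sprintf("scene_%03d", i)
    write_image(sc$image, file.path(out_dir, img_file))
    write_scene(sc$truth, file.path(out_dir, truth_dir))
    entries[[i]] <- list(id = i, image = img_file, truth = truth_dir,
                         seed = sp$seed, n_cells = length(sc$truth$cells),
                         realized_overlap = round(sc$realized_overlap, 4))
  }
  man <- list(n_images = n_images, base_seed = as.integer(base_seed),
              image_size = spec$image_size, n_cells = spec$n_cells,
              overlap_fraction = spec$overlap_fraction, entries = entries)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(man)
}
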