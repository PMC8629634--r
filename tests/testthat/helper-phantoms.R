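# Small fixtures built in code: keeps tests fast and the repository
# free of binary data.

# Herlev-style single-cell phantom at reduced resolution.
small_single_spec <- function(seed, size = 96L, noise_sd = 8) {
  phantom_spec(image_size = c(size, size), n_cells = 1L,
               overlap_fraction = 0, noise_sd = noise_sd, seed = seed)
}

# Compact multicell scene for pipeline tests.
small_scene_spec <- function(seed, n_cells = 2L, overlap = 0.25,
                             size = 192L, noise_sd = 8) {
  phantom_spec(image_size = c(size, size), n_cells = n_cells,
               overlap_fraction = overlap, noise_sd = noise_sd, seed = seed)
}

# Overlap-pipeline config scaled to small test scenes (area parameters
# shrink with the squared size ratio relative to the 512-px defaults).
scaled_overlap_config <- function(size, ...) {
  f <- (size / 512)^2
  overlap_config(min_hole_area = max(20L, as.integer(200 * f)),
                 nucleus_min_area = max(15L, as.integer(30 * f)),
                 nucleus_max_area = max(200L, as.integer(6000 * f)),
                 max_extension = 120 * size / 512, ...)
}

# A random 256-bin histogram with at least two occupied bins.
random_histogram <- function() {
  counts <- integer(256)
  occ <- sample.int(256, sample(2:40, 1))
  counts[occ] <- sample.int(50, length(occ), replace = TRUE)
  structure(list(counts = counts, total = sum(counts)),
            class = "gray_histogram")
}

# A random small 0/1 mask with at least one foreground pixel.
random_mask <- function(H, W, p = 0.3) {
  m <- matrix(rbinom(H * W, 1, p), H, W)
  if (sum(m) == 0L) m[sample.int(H * W, 1)] <- 1L
  m
}
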