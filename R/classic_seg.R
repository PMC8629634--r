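#' Gray-level histogram of an image
#'
#' 256-bin count histogram; `counts[v + 1]` is the number of pixels with
#' intensity `v`, and `total` equals the image area.
#'
#' @param image a [gray_image] (or integer matrix in `[0,255]`).
#' @return an object of class `gray_histogram` with fields `counts`
#'   (length 256) and `total`.
#' @export
gray_histogram <- function(image) {
  m <- px(gray_image(as_gray_matrix(image)))
  counts <- tabulate(as.vector(m) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)),
            class = "gray_histogram")
}

as_gray_matrix <- function(image) {
  if (inherits(image, "color_image")) return(px(to_gray(image)))
  if (inherits(image, "gray_image")) return(px(image))
  image
}

#' Fixed-threshold binary segmentation
#'
#' A pixel maps to 1 when its gray value is greater than or equal to `T`,
#' and to 0 otherwise (the boundary value `T` itself maps to 1).
#'
#' @param image a [gray_image].
#' @param T threshold in `[0, 255]`.
#' @return a [binary_mask].
#' @export
binary_threshold <- function(image, T) {
  if (length(T) != 1L || T < 0 || T > 255)
    stop("binary_threshold: T must lie in [0, 255]")
  m <- as_gray_matrix(image)
  binary_mask((m >= T) + 0L)
}

#' Multilevel threshold bands
#'
#' `thresholds` is a strictly increasing vector `T_0 < ... < T_{n-1}` in
#' `[0, 255]`; `output_values` supplies the `n + 1` output marks
#' `g_0 ... g_n` (non-negative integers). Band intervals are
#' left-open/right-closed: a pixel maps to `g_0` when `f <= T_0`, to `g_k`
#' when `T_{k-1} < f <= T_k`, and to `g_n` when `f > T_{n-1}`. Note this
#' boundary convention differs from [binary_threshold], which maps the
#' boundary pixel up; both conventions are deliberate and documented.
#'
#' @param thresholds strictly increasing numeric vector.
#' @param output_values non-negative integer vector, one longer than
#'   `thresholds`.
#' @return an object of class `threshold_bands`.
#' @export
threshold_bands <- function(thresholds, output_values) {
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0))
    stop("threshold_bands: thresholds must be strictly increasing")
  if (any(thresholds < 0 | thresholds > 255))
    stop("threshold_bands: thresholds must lie in [0, 255]")
  if (length(output_values) != length(thresholds) + 1L)
    stop("threshold_bands: need one more output value than thresholds")
  if (any(output_values < 0 | output_values != round(output_values)))
    stop("threshold_bands: output values must be non-negative integers")
  structure(list(thresholds = as.numeric(thresholds),
                 output_values = as.integer(output_values)),
            class = "threshold_bands")
}

#' Multilevel gray-threshold segmentation
#'
#' Assigns every pixel the output mark of its band (see
#' [threshold_bands] for the boundary semantics).
#'
#' @param image a [gray_image].
#' @param bands a [threshold_bands] object.
#' @return a [label_map] whose values are the band output marks.
#' @export
multilevel_threshold <- function(image, bands) {
  if (!inherits(bands, "threshold_bands"))
    bands <- threshold_bands(bands$thresholds, bands$output_values)
  m <- as_gray_matrix(image)
  idx <- findInterval(as.vector(m), bands$thresholds, left.open = TRUE)
  label_map(matrix(bands$output_values[idx + 1L], nrow(m), ncol(m)))
}

#' Class statistics of a histogram split at threshold t
#'
#' Splits the gray levels into class 1 (`<= t`) and class 2 (`> t`) and
#' returns the class probabilities `theta1`, `theta2`, class means `mu1`,
#' `mu2`, the global mean `mu` (which satisfies
#' `mu = mu1 * theta1 + mu2 * theta2`), and the between-class variance
#' `sigmaB2 = theta1 * (mu1 - mu)^2 + theta2 * (mu2 - mu)^2`, which equals
#' `theta1 * theta2 * (mu1 - mu2)^2`.
#'
#' @param hist a [gray_histogram].
#' @param t split threshold; both classes must be nonempty.
#' @return an object of class `class_stats`.
#' @export
class_stats <- function(hist, t) {
  stopifnot(inherits(hist, "gray_histogram"))
  v <- 0:255
  lo <- v <= t
  n1 <- sum(hist$counts[lo]); n2 <- hist$total - n1
  if (n1 == 0L) stop("class_stats: class 1 empty (t below minimum intensity)")
  if (n2 == 0L) stop("class_stats: class 2 empty (t at or above maximum intensity)")
  theta1 <- n1 / hist$total; theta2 <- n2 / hist$total
  mu1 <- sum(hist$counts[lo] * v[lo]) / n1
  mu2 <- sum(hist$counts[!lo] * v[!lo]) / n2
  mu <- theta1 * mu1 + theta2 * mu2
  sigmaB2 <- theta1 * (mu1 - mu)^2 + theta2 * (mu2 - mu)^2
  structure(list(t = t, theta1 = theta1, theta2 = theta2, mu1 = mu1,
                 mu2 = mu2, mu = mu, sigmaB2 = sigmaB2),
            class = "class_stats")
}

#' Automatic threshold by maximum between-class variance
#'
#' Scans all thresholds `t` for which both classes are nonempty and
#' returns the one maximizing the between-class variance; ties are broken
#' toward the smallest `t`, so the result is deterministic.
#'
#' @param hist a [gray_histogram] with at least two occupied bins.
#' @return a list with `t_star` and the corresponding [class_stats].
#' @export
max_variance_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (sum(hist$counts > 0L) < 2L)
    stop("max_variance_threshold: single-valued histogram, no valid split")
  v <- 0:255
  cn <- cumsum(hist$counts)           # pixels <= t
  cs <- cumsum(hist$counts * v)       # intensity sum <= t
  n <- hist$total; s <- cs[256]
  valid <- which(cn > 0L & cn < n)    # both classes nonempty, t = valid - 1
  theta1 <- cn[valid] / n
  mu1 <- cs[valid] / cn[valid]
  mu2 <- (s - cs[valid]) / (n - cn[valid])
  sigmaB2 <- theta1 * (1 - theta1) * (mu1 - mu2)^2
  t_star <- valid[which.max(sigmaB2)] - 1L   # which.max -> first max
  list(t_star = t_star, stats = class_stats(hist, t_star))
}

# --- edge operators ---------------------------------------------------------

# Pad a matrix by one pixel of edge reflection.
pad1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, W, drop = FALSE])
}

# Correlate a 3x3 kernel with reflect border handling.
corr3 <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  p <- pad1(m)
  out <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0)
      out <- out + w * p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  out
}

kirsch_kernels <- local({
  base <- c(5, 5, 5, -3, 0, -3, -3, -3, -3)
  ring <- c(1, 2, 3, 6, 9, 8, 7, 4)   # clockwise ring positions
  lapply(0:7, function(s) {
    k <- numeric(9)
    k[5] <- 0
    k[ring] <- base[c(1:4, 6:9)][((seq_len(8) - 1 + s) %% 8) + 1]
    matrix(k, 3, 3, byrow = TRUE)
  })
})

#' Edge response of a gray image
#'
#' Computes the per-pixel edge response for one of five classical
#' operators. `gradient` is the forward-difference magnitude
#' `|f(r+1,c)-f(r,c)| + |f(r,c+1)-f(r,c)|`; `roberts` the cross-difference
#' magnitude; `sobel` the 3x3 Sobel gradient magnitude
#' `sqrt(gx^2 + gy^2)`; `laplacian` the signed 4-neighbor second
#' difference (sign carries the step/pulse shape information, so it is not
#' rectified); `kirsch` the maximum response over the eight compass
#' kernels. Borders are handled by edge reflection, so constant images
#' give an identically zero response for every operator.
#'
#' @param image a [gray_image].
#' @param operator one of `"gradient"`, `"roberts"`, `"sobel"`,
#'   `"laplacian"`, `"kirsch"`.
#' @return a real-valued response matrix of the image's shape.
#' @export
edge_magnitude <- function(image,
                           operator = c("gradient", "roberts", "sobel",
                                        "laplacian", "kirsch")) {
  operator <- match.arg(operator)
  m <- as_gray_matrix(image)
  storage.mode(m) <- "double"
  H <- nrow(m); W <- ncol(m)
  if (H < 2L || W < 2L) stop("edge_magnitude: image smaller than kernel")
  p <- pad1(m)
  switch(operator,
    gradient = {
      dx <- p[3:(H + 2), 2:(W + 1)] - m   # f(r+1,c) - f(r,c)
      dy <- p[2:(H + 1), 3:(W + 2)] - m   # f(r,c+1) - f(r,c)
      abs(dx) + abs(dy)
    },
    roberts = {
      d1 <- m - p[3:(H + 2), 3:(W + 2)]
      d2 <- p[3:(H + 2), 2:(W + 1)] - p[2:(H + 1), 3:(W + 2)]
      abs(d1) + abs(d2)
    },
    sobel = {
      kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
      ky <- t(kx)
      sqrt(corr3(m, kx)^2 + corr3(m, ky)^2)
    },
    laplacian = {
      k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)
      corr3(m, k)
    },
    kirsch = {
      out <- matrix(-Inf, H, W)
      for (k in kirsch_kernels) out <- pmax(out, corr3(m, k))
      pmax(out, 0)
    })
}

#' Binarize an edge response, optionally linking small gaps
#'
#' Retains pixels whose absolute response strictly exceeds `threshold`
#' (so `threshold = 0` keeps exactly the nonzero responses). With
#' `link = TRUE` a 3x3 morphological closing bridges gaps of up to one
#' pixel, so the boundary of a simple convex object becomes a closed
#' 8-connected curve.
#'
#' @param magnitude response matrix from [edge_magnitude].
#' @param threshold non-negative cutoff.
#' @param link logical; close 1-pixel gaps morphologically.
#' @return a [binary_mask].
#' @export
edge_mask <- function(magnitude, threshold, link = FALSE) {
  if (threshold < 0) stop("edge_mask: threshold must be >= 0")
  m <- (abs(magnitude) > threshold) + 0L
  if (link) {
    m <- EBImage::closing(m, EBImage::makeBrush(3, "box"))
    m <- round(as.matrix(m))
  }
  binary_mask(m)
}
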