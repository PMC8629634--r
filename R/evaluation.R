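#' Zijdenbos similarity index of two masks
#'
#' `ZSI(A, B) = 2|A n B| / (|A| + |B|)`, identical in form to the Dice
#' coefficient: 1 for identical nonempty masks, 0 for disjoint ones,
#' symmetric, always in `[0, 1]`.
#'
#' @param a,b [binary_mask]s (or 0/1 matrices) of the same shape, not
#'   both empty.
#' @return a real in `[0, 1]`.
#' @export
zsi <- function(a, b) {
  ma <- px(binary_mask(a)); mb <- px(binary_mask(b))
  if (!identical(dim(ma), dim(mb))) stop("zsi: shape mismatch")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0L) stop("zsi: both masks empty")
  2 * sum(ma & mb) / (sa + sb)
}

#' Match predicted cells to ground-truth cells by cytoplasm ZSI
#'
#' Greedy assignment without replacement: pairs are taken in descending
#' cytoplasm ZSI (ties toward the lower true index, then the lower
#' predicted index), each true and each predicted cell used at most
#' once. Unmatched true cells receive ZSI 0.
#'
#' @param pred,truth [scene_segmentation]s over the same image shape.
#' @return a data frame with one row per true cell: `true_idx`,
#'   `pred_idx` (NA when unmatched) and `zsi`.
#' @export
match_cells <- function(pred, truth) {
  nt <- length(truth$cells); np <- length(pred$cells)
  res <- data.frame(true_idx = seq_len(nt), pred_idx = rep(NA_integer_, nt),
                    zsi = rep(0, nt))
  if (nt == 0L || np == 0L) return(res)
  Z <- matrix(0, nt, np)
  for (i in seq_len(nt)) for (j in seq_len(np))
    Z[i, j] <- zsi(truth$cells[[i]]$cytoplasm, pred$cells[[j]]$cytoplasm)
  used_t <- logical(nt); used_p <- logical(np)
  for (step in seq_len(min(nt, np))) {
    M <- Z
    M[used_t, ] <- -1; M[, used_p] <- -1
    best <- which(M == max(M), arr.ind = TRUE)
    if (max(M) < 0) break
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    res$pred_idx[best[1]] <- best[2]
    res$zsi[best[1]] <- Z[best[1], best[2]]
    used_t[best[1]] <- TRUE; used_p[best[2]] <- TRUE
  }
  res
}

#' Object-based false negative rate
#'
#' The fraction of per-cell ZSI values at or below the threshold; a cell
#' whose ZSI equals the threshold exactly counts as an error (the
#' boundary is inclusive).
#'
#' @param per_cell_zsi nonempty numeric vector of per-true-cell ZSI.
#' @param threshold the good-segmentation cutoff (default 0.7).
#' @return a real in `[0, 1]`.
#' @export
fno <- function(per_cell_zsi, threshold = 0.7) {
  if (length(per_cell_zsi) == 0L) stop("fno: empty ZSI list")
  mean(per_cell_zsi <= threshold)
}

#' Pixel-based true and false positive rates
#'
#' `tpp = |pred n truth| / |truth|` and
#' `fpp = |pred n !truth| / |!truth|`, computed on the (union) foreground
#' masks.
#'
#' @param pred,truth [binary_mask]s of the same shape; the truth must
#'   have nonempty foreground and background.
#' @return a list with `tpp` and `fpp`.
#' @export
pixel_rates <- function(pred, truth) {
  mp <- px(binary_mask(pred)); mt <- px(binary_mask(truth))
  if (!identical(dim(mp), dim(mt))) stop("pixel_rates: shape mismatch")
  nt <- sum(mt); nb <- length(mt) - nt
  if (nt == 0L || nb == 0L)
    stop("pixel_rates: truth foreground and background must both be nonempty")
  list(tpp = sum(mp & mt) / nt, fpp = sum(mp & !mt) / nb)
}

#' Evaluate a predicted scene against ground truth
#'
#' Matches cells with [match_cells], reports the per-true-cell cytoplasm
#' ZSI list with its mean and standard deviation, the object-based false
#' negative rate [fno], the pixel rates [pixel_rates] of the cytoplasm
#' union masks, and the cell counts. Nucleus agreement (mean ZSI over
#' matched pairs) is reported separately, never mixed into the cytoplasm
#' score.
#'
#' @param pred,truth [scene_segmentation]s.
#' @param fno_threshold boundary for [fno].
#' @return an object of class `eval_report`.
#' @export
evaluate_scene <- function(pred, truth, fno_threshold = 0.7) {
  m <- match_cells(pred, truth)
  nz <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!is.na(m$pred_idx[i]))
      nz[i] <- zsi(truth$cells[[i]]$nucleus,
                   pred$cells[[m$pred_idx[i]]]$nucleus)
  }
  pu <- if (length(pred$cells)) cytoplasm_union(pred) else 0L * px(truth$background)
  tu <- cytoplasm_union(truth)
  pr <- pixel_rates(pu, tu)
  make_eval_report(m$zsi, nz, pr, length(truth$cells), length(pred$cells),
                   fno_threshold)
}

make_eval_report <- function(zv, nz, pr, nt, np, fno_threshold) {
  structure(list(per_cell_zsi = zv,
                 mean_zsi = mean(zv),
                 std_zsi = if (length(zv) > 1L) sd(zv) else 0,
                 nucleus_mean_zsi = if (any(!is.na(nz))) mean(nz, na.rm = TRUE) else NA_real_,
                 fno = fno(zv, fno_threshold),
                 tpp = pr$tpp, fpp = pr$fpp,
                 n_true_cells = nt, n_pred_cells = np),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d true / %d predicted cells\n",
              x$n_true_cells, x$n_pred_cells))
  cat(sprintf("  ZSI %.3f +/- %.3f  FNo %.3f  TPp %.3f  FPp %.3f\n",
              x$mean_zsi, x$std_zsi, x$fno, x$tpp, x$fpp))
  invisible(x)
}

#' Evaluate a dataset of (pred, truth) scene pairs
#'
#' Concatenates the per-true-cell ZSI lists across scenes (so the flat
#' list equals the union of the per-scene lists) and aggregates the
#' pixel counts scene by scene.
#'
#' @param pairs nonempty list of `list(pred = , truth = )` pairs.
#' @param fno_threshold boundary for [fno].
#' @return an `eval_report` over all cells of all scenes.
#' @export
evaluate_dataset <- function(pairs, fno_threshold = 0.7) {
  if (length(pairs) == 0L) stop("evaluate_dataset: empty dataset")
  zv <- numeric(0); nz <- numeric(0)
  nt <- 0L; np <- 0L
  tp_n <- 0; t_n <- 0; fp_n <- 0; b_n <- 0
  for (p in pairs) {
    r <- evaluate_scene(p$pred, p$truth, fno_threshold)
    zv <- c(zv, r$per_cell_zsi)
    nz <- c(nz, r$nucleus_mean_zsi)
    nt <- nt + r$n_true_cells; np <- np + r$n_pred_cells
    tu <- cytoplasm_union(p$truth)
    pu <- if (length(p$pred$cells)) cytoplasm_union(p$pred) else 0L * tu
    tp_n <- tp_n + sum(pu & tu); t_n <- t_n + sum(tu)
    fp_n <- fp_n + sum(pu & !tu); b_n <- b_n + sum(tu == 0L)
  }
  make_eval_report(zv, nz, list(tpp = tp_n / t_n, fpp = fp_n / b_n),
                   nt, np, fno_threshold)
}

#' Render a per-method results table
#'
#' One row per method in the conventional reporting layout:
#' `mean ZSI +/- std`, FNo, TPp, FPp and cell count.
#'
#' @param reports named list of `eval_report`s (name = method).
#' @return a data frame with columns `method`, `zsi` (formatted
#'   `mean +/- std`), `mean_zsi`, `std_zsi`, `fno`, `tpp`, `fpp`,
#'   `n_cells`.
#' @export
method_table <- function(reports) {
  stopifnot(length(reports) > 0L, !is.null(names(reports)))
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm,
               zsi = sprintf("%.2f ± %.2f", r$mean_zsi, r$std_zsi),
               mean_zsi = r$mean_zsi, std_zsi = r$std_zsi,
               fno = r$fno, tpp = r$tpp, fpp = r$fpp,
               n_cells = r$n_true_cells)
  }))
}
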