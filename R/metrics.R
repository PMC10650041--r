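#' Binary segmentation mask
#'
#' A 2-D 0/1 matrix plus the physical pixel spacing in millimetres, used by
#' the overlap and distance metrics.
#'
#' @param values matrix (or 2-D array) containing only 0 and 1.
#' @param spacing length-2 positive numeric, (row_mm, col_mm).
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1)) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1)))
    stop("binary_mask: values must be exactly 0 or 1")
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("binary_mask: spacing must be two strictly positive numbers (mm)")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

mask_values <- function(m) if (inherits(m, "binary_mask")) m$values else as.matrix(m)
mask_spacing <- function(m) if (inherits(m, "binary_mask")) m$spacing else c(1, 1)

#' Soft dice loss
#'
#' Differentiable dice surrogate used for training:
#' `L = 1 - (2 * sum(p * t) + smooth) / (sum(p^2) + sum(t^2) + smooth)`,
#' with sums over all pixels of a case and the loss averaged over the batch
#' when `pred` is a 4-D array (4th dimension = batch).
#'
#' @param pred probability map in \[0, 1\]; matrix, 3-D or 4-D array.
#' @param target binary mask (same shape as `pred`, or a [binary_mask()]).
#' @param smooth positive smoothing constant (default 1).
#' @return scalar loss in \[0, 1).
#' @export
soft_dice_loss <- function(pred, target, smooth = 1) {
  if (inherits(target, "binary_mask")) target <- target$values
  pred <- as.array(pred)
  target <- as.array(target)
  if (!identical(dim_of(pred), dim_of(target)))
    stop("soft_dice_loss: pred and target shapes differ (",
         paste(dim_of(pred), collapse = "x"), " vs ",
         paste(dim_of(target), collapse = "x"), ")")
  if (any(pred < 0 | pred > 1)) stop("soft_dice_loss: pred must lie in [0, 1]")
  if (smooth <= 0) stop("soft_dice_loss: smooth must be positive")
  d <- dim_of(pred)
  n_batch <- if (length(d) == 4L) d[4] else 1L
  per <- length(pred) / n_batch
  pm <- matrix(pred, nrow = per)
  tm <- matrix(target, nrow = per)
  num <- 2 * .colSums(pm * tm, per, n_batch) + smooth
  den <- .colSums(pm * pm, per, n_batch) + .colSums(tm * tm, per, n_batch) + smooth
  mean(1 - num / den)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks.  When both
#' masks are empty the DSC is defined as 1 and the result carries the
#' attribute `both_empty = TRUE`.
#'
#' @param a,b binary masks ([binary_mask()] or plain 0/1 matrices) of equal
#'   shape.
#' @return scalar in \[0, 1\].
#' @export
dsc <- function(a, b) {
  av <- mask_values(a)
  bv <- mask_values(b)
  if (!identical(dim(av), dim(bv)))
    stop("dsc: mask shapes differ")
  sa <- sum(av)
  sb <- sum(bv)
  if (sa == 0 && sb == 0)
    return(structure(1, both_empty = TRUE))
  2 * sum(av * bv) / (sa + sb)
}

#' Symmetric Hausdorff distance between two masks (mm)
#'
#' The larger of the two directed farthest-nearest-point distances between
#' the foreground pixel sets, with pixel-centre coordinates scaled by the
#' per-axis spacing.  Computed over the full foreground sets (no boundary
#' extraction).  If either mask is empty the distance is undefined and
#' `NA_real_` is returned; [evaluate_dataset()] excludes such cases from the
#' aggregate.
#'
#' @param a,b binary masks of equal shape; spacings must agree.
#' @return non-negative scalar in millimetres, or `NA_real_`.
#' @export
hausdorff <- function(a, b) {
  av <- mask_values(a)
  bv <- mask_values(b)
  if (!identical(dim(av), dim(bv))) stop("hausdorff: mask shapes differ")
  sp <- mask_spacing(a)
  if (!isTRUE(all.equal(sp, mask_spacing(b))))
    stop("hausdorff: masks have different pixel spacings")
  pa <- which(av == 1, arr.ind = TRUE)
  pb <- which(bv == 1, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  ra <- pa[, 1] * sp[1]; ca <- pa[, 2] * sp[2]
  rb <- pb[, 1] * sp[1]; cb <- pb[, 2] * sp[2]
  # full pairwise squared distance matrix (|A| x |B|); foregrounds are tiny
  d2 <- outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

#' Evaluate a set of predictions against ground truth
#'
#' Computes per-case DSC and Hausdorff distance plus aggregate means.  Cases
#' where either mask is empty have no defined Hausdorff distance; they are
#' excluded from `mean_hd` and counted in `n_excluded_from_hd`.
#'
#' @param pred_masks,gt_masks aligned lists of binary masks.
#' @param case_ids optional character vector of case identifiers.
#' @return object of class `metrics_report` with elements `per_case`
#'   (data.frame: case_id, dsc, hd_mm, pred_empty, gt_empty), `mean_dsc`,
#'   `mean_hd` (`NA` if all cases excluded) and `n_excluded_from_hd`.
#' @export
evaluate_dataset <- function(pred_masks, gt_masks, case_ids = NULL) {
  if (length(pred_masks) != length(gt_masks))
    stop("evaluate_dataset: ", length(pred_masks), " predictions vs ",
         length(gt_masks), " ground-truth masks")
  n <- length(pred_masks)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    p <- pred_masks[[i]]; g <- gt_masks[[i]]
    data.frame(case_id = case_ids[i],
               dsc = as.numeric(dsc(p, g)),
               hd_mm = hausdorff(p, g),
               pred_empty = sum(mask_values(p)) == 0,
               gt_empty = sum(mask_values(g)) == 0,
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  hd_ok <- !is.na(per_case$hd_mm)
  structure(list(per_case = per_case,
                 mean_dsc = mean(per_case$dsc),
                 mean_hd = if (any(hd_ok)) mean(per_case$hd_mm[hd_ok]) else NA_real_,
                 n_excluded_from_hd = sum(!hd_ok)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("segmentation metrics over", nrow(x$per_case), "cases\n")
  cat(sprintf("  mean DSC: %.4f\n", x$mean_dsc))
  if (is.na(x$mean_hd)) cat("  mean HD : undefined (all cases excluded)\n")
  else cat(sprintf("  mean HD : %.4f mm (%d case(s) excluded)\n",
                   x$mean_hd, x$n_excluded_from_hd))
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One row per case plus an `aggregate` row holding the means.
#'
#' @param report a [evaluate_dataset()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- report$per_case
  agg <- data.frame(case_id = "aggregate", dsc = report$mean_dsc,
                    hd_mm = report$mean_hd, pred_empty = NA, gt_empty = NA)
  write.csv(rbind(df, agg), path, row.names = FALSE)
  invisible(path)
}
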