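#' Intersection over union of two pixel masks
#'
#' `IoU(A, B) = |A intersect B| / |A union B|`; 1 for a perfectly
#' recovered object, 0 for disjoint masks (and, by convention, when both
#' masks are empty).
#'
#' @param mask_a,mask_b logical matrices on the same grid
#' @return a value in `[0, 1]`
#' @export
iou <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  u <- sum(mask_a | mask_b)
  if (u == 0L) return(0)
  sum(mask_a & mask_b) / u
}

# areas and pairwise intersection table between two labelings
overlap_stats <- function(pred, gt) {
  pid <- label_ids(pred); gid <- label_ids(gt)
  both <- pred > 0L & gt > 0L
  inter <- NULL
  if (any(both)) {
    tab <- table(factor(pred[both], levels = pid),
                 factor(gt[both], levels = gid))
    inter <- unclass(tab)
  } else {
    inter <- matrix(0L, length(pid), length(gid), dimnames = list(pid, gid))
  }
  pa <- if (length(pid)) tabulate(pred[pred > 0L], nbins = max(pid))[pid]
        else integer(0)
  ga <- if (length(gid)) tabulate(gt[gt > 0L], nbins = max(gid))[gid]
        else integer(0)
  list(pid = pid, gid = gid, inter = inter, pa = pa, ga = ga)
}

#' Confusion counts at one IoU threshold
#'
#' A true positive is a (prediction, ground-truth) pair whose pixel IoU is
#' strictly above `t`; predictions left unmatched are false positives and
#' ground-truth objects left unmatched are false negatives. For
#' `t >= 0.5` a prediction can exceed the threshold with at most one
#' ground-truth object (two masks cannot each claim more than half of a
#' prediction's union), so no assignment problem arises; thresholds below
#' 0.5 are rejected.
#'
#' @param pred,gt label matrices on the same grid
#' @param t IoU threshold in `[0.5, 1)`
#' @return named integer vector `c(TP, FP, FN)`
#' @export
confusion_at_threshold <- function(pred, gt, t) {
  stopifnot(all(dim(pred) == dim(gt)))
  if (t < 0.5 || t >= 1) stop("IoU threshold must lie in [0.5, 1)")
  os <- overlap_stats(pred, gt)
  tp <- 0L
  if (length(os$pid) && length(os$gid)) {
    uni <- outer(os$pa, os$ga, `+`) - os$inter
    tp <- sum(os$inter / uni > t)
  }
  c(TP = tp, FP = length(os$pid) - tp, FN = length(os$gid) - tp)
}

# the fixed threshold grid of the metric
ap_thresholds <- function() seq(0.5, 0.95, by = 0.05)

#' Average precision of one image
#'
#' At each IoU threshold `t` in `{0.50, 0.55, ..., 0.95}` the precision is
#' `Q(t) = TP / (TP + FP + FN)`; the average precision is the mean of
#' `Q(t)` over the 10 thresholds. When both labelings are empty there is
#' nothing to find and nothing found, so `Q(t) = 1`.
#'
#' @param pred,gt label matrices on the same grid
#' @param detail when `TRUE`, also return the per-threshold table
#' @return the AP value, or (with `detail`) a list with `ap` and
#'   `per_threshold` (data.frame `t`, `Q`, `TP`, `FP`, `FN`)
#' @export
average_precision <- function(pred, gt, detail = FALSE) {
  ts <- ap_thresholds()
  rows <- lapply(ts, function(t) {
    cf <- confusion_at_threshold(pred, gt, t)
    denom <- sum(cf)
    q <- if (denom == 0L) 1 else cf[["TP"]] / denom
    data.frame(t = t, Q = q, TP = cf[["TP"]], FP = cf[["FP"]],
               FN = cf[["FN"]])
  })
  per_t <- do.call(rbind, rows)
  ap <- mean(per_t$Q)
  if (detail) list(ap = ap, per_threshold = per_t) else ap
}

#' Mean average precision over a set of images
#'
#' @param pairs non-empty list of `list(pred = , gt = )` label-matrix pairs
#' @return an `eval_report`: list with `per_image_ap`, `map` (their
#'   arithmetic mean) and `per_threshold_q` (one data.frame per image)
#' @export
mean_average_precision <- function(pairs) {
  if (length(pairs) == 0L) stop("at least one (pred, gt) pair is required")
  res <- lapply(pairs, function(p)
    average_precision(p$pred, p$gt, detail = TRUE))
  aps <- vapply(res, `[[`, numeric(1), "ap")
  structure(list(per_image_ap = aps, map = mean(aps),
                 per_threshold_q = lapply(res, `[[`, "per_threshold")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d image(s), mAP = %.4f\n",
              length(x$per_image_ap), x$map))
  cat("  per-image AP:", paste(sprintf("%.4f", x$per_image_ap),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of cells positive for both of two markers
#'
#' For a biologically mutually exclusive marker pair, the double-positive
#' fraction measures residual lateral spillover: gating each marker at its
#' threshold, true biology should yield (almost) no cells above both
#' gates, so a drop in this fraction after compensation quantifies how
#' much spillover was removed.
#'
#' @param table a `cell_table`
#' @param marker_a,marker_b channel names (or indices into the channel
#'   set)
#' @param gate_a,gate_b positivity gates (a cell is positive when its mean
#'   is strictly above the gate)
#' @param use_compensated gate on the compensated means instead of the raw
#'   means; errors when the table has no compensated columns
#' @return fraction of cells in `[0, 1]` positive for both markers
#' @export
double_positive_fraction <- function(table, marker_a, marker_b,
                                     gate_a, gate_b,
                                     use_compensated = FALSE) {
  stopifnot(gate_a >= 0, gate_b >= 0)
  channels <- attr(table, "channels")
  resolve <- function(m) {
    if (is.numeric(m)) m <- channels[m]
    if (!m %in% channels) stop("unknown marker: ", m)
    m
  }
  a <- resolve(marker_a); b <- resolve(marker_b)
  if (use_compensated) {
    a <- paste0(a, "_comp"); b <- paste0(b, "_comp")
    if (!all(c(a, b) %in% names(table)))
      stop("table has no compensated columns; run apply_compensation first")
  }
  if (nrow(table) == 0L) return(NaN)
  mean(table[[a]] > gate_a & table[[b]] > gate_b)
}

#' Evaluate a directory of predictions against ground truth
#'
#' Pairs files by name between the two directories; each file may be a
#' single-page label TIFF or a multi-page ROI stack (see
#' [read_label_tiff]).
#'
#' @param pred_dir,gt_dir directories of label TIFFs with matching names
#' @return list with `per_image` (data.frame `image`, `ap`) and `map`
#' @export
evaluate_label_dirs <- function(pred_dir, gt_dir) {
  pf <- sort(list.files(pred_dir, pattern = "\\.tiff?$", ignore.case = TRUE))
  gf <- sort(list.files(gt_dir, pattern = "\\.tiff?$", ignore.case = TRUE))
  common <- intersect(pf, gf)
  if (length(common) == 0L) stop("no matching label files between ",
                                 pred_dir, " and ", gt_dir)
  pairs <- lapply(common, function(f) list(
    pred = read_label_tiff(file.path(pred_dir, f)),
    gt = read_label_tiff(file.path(gt_dir, f))))
  rep <- mean_average_precision(pairs)
  list(per_image = data.frame(image = common, ap = rep$per_image_ap),
       map = rep$map)
}
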