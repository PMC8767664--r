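test_that("IoU matches hand-counted overlaps", {
  a <- matrix(FALSE, 8, 8); b <- a
  a[2:3, 1:4] <- TRUE            # 2x4 rectangle
  b[2:3, 3:6] <- TRUE            # 2x4 rectangle overlapping in a 2x2 block
  expect_equal(iou(a, b), 4 / 12)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, matrix(FALSE, 8, 8)), 0)
  expect_equal(iou(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8)), 0)
})

test_that("confusion counts behave at the boundary cases", {
  labels <- random_dense_labeling(1, H = 24, W = 24, n_cells = 4)
  n <- length(label_ids(labels))
  for (t in c(0.5, 0.75, 0.949)) {
    cf <- confusion_at_threshold(labels, labels, t)
    expect_equal(cf, c(TP = n, FP = 0L, FN = 0L))
  }
  # IoU 1/3 pair at t = 0.5: no match, one FP, one FN
  pred <- matrix(0L, 8, 8); gt <- matrix(0L, 8, 8)
  pred[2:3, 1:4] <- 1L; gt[2:3, 3:6] <- 1L
  expect_equal(confusion_at_threshold(pred, gt, 0.5),
               c(TP = 0L, FP = 1L, FN = 1L))
  expect_error(confusion_at_threshold(pred, gt, 0.4), "threshold")
  expect_error(confusion_at_threshold(pred, gt, 1), "threshold")
})

test_that("matching is unique: no object can pair twice at t >= 0.5", {
  set.seed(11)
  for (case in 1:60) {
    pred <- random_rect_labeling(16, 16, 5)
    gt <- random_rect_labeling(16, 16, 5)
    oracle <- brute_confusion(pred, gt, 0.5)
    expect_equal(oracle[["dup"]], 0L)
    got <- confusion_at_threshold(pred, gt, 0.5)
    expect_equal(got, oracle[c("TP", "FP", "FN")])
  }
})

test_that("average precision averages Q(t) over the 10-threshold grid", {
  labels <- random_dense_labeling(4, H = 24, W = 24, n_cells = 4)
  res <- average_precision(labels, labels, detail = TRUE)
  expect_equal(nrow(res$per_threshold), 10L)
  expect_equal(res$per_threshold$t, seq(0.5, 0.95, by = 0.05))
  expect_equal(res$ap, 1.0)
  # empty vs empty: nothing to find, nothing found -> AP = 1
  e <- matrix(0L, 24, 24)
  expect_equal(average_precision(matrix(0L, 6, 6), matrix(0L, 6, 6)), 1.0)
  # objects but no predictions: Q = 0/(0+0+FN) = 0 at every threshold
  expect_equal(average_precision(e, labels), 0.0)
})

test_that("a single pair at IoU 0.72 gives AP exactly 0.5", {
  # |A| = 20, |B| = 23, |intersection| = 18 -> IoU = 18/25 = 0.72:
  # Q = 1 for the 5 thresholds strictly below 0.72, else 0
  pred <- matrix(0L, 5, 10); gt <- matrix(0L, 5, 10)
  pred[seq_len(20)] <- 1L
  gt[3:25] <- 1L
  expect_equal(iou(pred == 1L, gt == 1L), 0.72)
  expect_equal(average_precision(pred, gt), 0.5)
})

test_that("mAP is the mean of per-image APs, invariant to ordering", {
  l1 <- random_dense_labeling(5, H = 24, W = 24, n_cells = 4)
  e <- matrix(0L, 24, 24)
  rep1 <- mean_average_precision(list(list(pred = l1, gt = l1)))
  expect_equal(rep1$map, 1.0)
  # one perfect image + one total miss -> mAP 0.5
  rep2 <- mean_average_precision(list(list(pred = l1, gt = l1),
                                      list(pred = e, gt = l1)))
  expect_equal(rep2$per_image_ap, c(1, 0))
  expect_equal(rep2$map, 0.5)
  perm <- mean_average_precision(list(list(pred = e, gt = l1),
                                      list(pred = l1, gt = l1)))
  expect_equal(perm$map, rep2$map)
  expect_error(mean_average_precision(list()), "at least one")
})

test_that("AP degrades when predictions are corrupted", {
  labels <- random_dense_labeling(6, H = 32, W = 32, n_cells = 5)
  ap0 <- average_precision(labels, labels)
  # spurious prediction
  spur <- labels
  stopifnot(spur[1, 1] == 0L, spur[1:2, 1:2] == 0L)
  spur[1:2, 1:2] <- max(labels) + 1L
  expect_lt(average_precision(spur, labels), ap0)
  # dropped true prediction
  drop1 <- labels; drop1[labels == label_ids(labels)[1]] <- 0L
  expect_lt(average_precision(drop1, labels), ap0)
})

test_that("double-positive fraction counts gated cells", {
  tab <- data.frame(cell_id = 1:10, x = 0, y = 0, size = 5,
                    cd4 = c(rep(100, 4), rep(1, 6)),
                    cd8 = c(50, 60, 1, 1, rep(80, 6)))
  attr(tab, "channels") <- c("cd4", "cd8")
  class(tab) <- c("cell_table", "data.frame")
  expect_equal(double_positive_fraction(tab, "cd4", "cd8", 20, 20), 0.2)
  expect_equal(double_positive_fraction(tab, "cd4", "cd8", 200, 200), 0)
  expect_error(double_positive_fraction(tab, "cd4", "cd8", 20, 20,
                                        use_compensated = TRUE),
               "compensated")
  expect_error(double_positive_fraction(tab, "cd19", "cd8", 20, 20),
               "unknown marker")
})

test_that("directory evaluation pairs files and reports mAP", {
  tmp <- withr::local_tempdir()
  pd <- file.path(tmp, "pred"); gd <- file.path(tmp, "gt")
  dir.create(pd); dir.create(gd)
  l1 <- random_dense_labeling(8, H = 32, W = 32, n_cells = 4)
  l2 <- random_dense_labeling(9, H = 32, W = 32, n_cells = 4)
  write_label_tiff(l1, file.path(pd, "a.tif"))
  write_label_tiff(l1, file.path(gd, "a.tif"))
  write_label_tiff(matrix(0L, 32, 32), file.path(pd, "b.tif"))
  write_label_tiff(l2, file.path(gd, "b.tif"))
  res <- evaluate_label_dirs(pd, gd)
  expect_equal(res$per_image$ap, c(1, 0))
  expect_equal(res$map, 0.5)
  # ground truth provided as an ROI stack reads equivalently
  export_roi_stack(l1, file.path(gd, "a.tif"))
  expect_equal(evaluate_label_dirs(pd, gd)$map, 0.5)
})
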