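test_that("nearest-centre expansion matches the per-pixel oracle", {
  # two 3x3 squares with a 2-pixel gap, expansion 2: contested column goes
  # to the nearer centroid, the equidistant column to the lower id
  labels <- matrix(0L, 9, 12)
  labels[4:6, 2:4] <- 1L
  labels[4:6, 7:9] <- 2L
  out <- expand_masks_nearest_center(labels, 2)
  expect_identical(out, brute_expand_nearest(labels, 2))
  # the gap columns 5 and 6 are both reachable from both masks;
  # column 5 is nearer centroid 1, column 6 nearer centroid 2
  expect_true(all(out[4:6, 5] == 1L))
  expect_true(all(out[4:6, 6] == 2L))
  # a symmetric mid-column tie goes to the lower id
  tie <- matrix(0L, 5, 11)
  tie[2:4, 2:4] <- 1L; tie[2:4, 8:10] <- 2L
  to <- expand_masks_nearest_center(tie, 2)
  expect_identical(to, brute_expand_nearest(tie, 2))
  expect_true(all(to[2:4, 6] == 1L))   # equidistant -> lower id
  # identity at n = 0
  expect_identical(expand_masks_nearest_center(labels, 0), labels)
})

test_that("both expansions agree with the oracle on dense random labelings", {
  for (seed in 1:10) {
    labels <- random_dense_labeling(seed)
    for (n in c(1, 2)) {
      expect_identical(expand_masks_nearest_center(labels, n),
                       brute_expand_nearest(labels, n))
    }
  }
})

test_that("iterative expansion splits contested bands at the front meeting", {
  # 10x10 mask (id 1) beside a 2x2 mask (id 2), 3 px apart, expansion 2:
  # the contested middle column goes to the small mask under the
  # nearest-centre rule (its centroid is much closer), but the iterative
  # rule assigns it where the growth fronts meet
  labels <- matrix(0L, 16, 22)
  labels[4:13, 2:11] <- 1L      # large 10x10
  labels[7:8, 15:16] <- 2L      # small 2x2, gap columns 12..14
  it <- expand_masks_iterative(labels, 2)
  expect_true(all(it[7:8, 12] == 1L))
  expect_true(all(it[7:8, 14] == 2L))
  expect_true(all(it[7:8, 13] == 1L))   # front collision, not centroid
  nc <- expand_masks_nearest_center(labels, 2)
  expect_identical(nc, brute_expand_nearest(labels, 2))
  expect_true(all(nc[7:8, 13] == 2L))   # small-mask centroid bias
  expect_identical(expand_masks_iterative(labels, 0), labels)
})

test_that("expansion algorithms agree exactly on well-separated masks", {
  for (seed in 1:8) {
    labels <- generate_nuclei(6, 64, 64, radius_range = c(2.5, 4.5),
                              ecc_range = c(1, 1.6), min_gap = 7,
                              noise_sd = 0, seed = seed)$labels
    n <- 2
    expect_gt(min_mask_separation(labels), 2 * n + 1)
    expect_identical(expand_masks_iterative(labels, n),
                     expand_masks_nearest_center(labels, n))
  }
})

test_that("expansion preserves nuclei, grows monotonically, stays bounded", {
  for (seed in 11:16) {
    labels <- random_dense_labeling(seed)
    fg <- labels > 0L
    for (algo in list(expand_masks_nearest_center, expand_masks_iterative)) {
      prev_area <- tabulate(labels[fg])
      for (n in 0:3) {
        out <- algo(labels, n)
        expect_identical(out[fg], labels[fg])  # nuclei never relabelled
        area <- tabulate(out[out > 0L], nbins = max(labels))
        expect_true(all(area >= prev_area[seq_along(area)] |
                          prev_area[seq_along(area)] == 0))
        prev_area <- area
        # every assigned pixel is within n growth steps of its source mask
        grown <- which(out > 0L & labels == 0L, arr.ind = TRUE)
        if (nrow(grown)) {
          src <- out[grown]
          d <- vapply(seq_len(nrow(grown)), function(k) {
            m <- which(labels == src[k], arr.ind = TRUE)
            min(pmax(abs(m[, 1] - grown[k, 1]), abs(m[, 2] - grown[k, 2])))
          }, numeric(1))
          expect_true(all(d <= n))
        }
      }
    }
  }
})

test_that("contact ratios match hand computation and the pixel-scan oracle", {
  # two isolated cells: identity matrix
  iso <- matrix(0L, 10, 10)
  iso[2:3, 2:3] <- 1L; iso[7:8, 7:8] <- 2L
  expect_equal(contact_ratios(iso)$A, diag(2), ignore_attr = TRUE)
  # two 3x1 bars sharing their full edge: every boundary pixel touches the
  # other bar, so both ratios are exactly 1
  bars <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 3, 2)
  A <- contact_ratios(bars)$A
  expect_equal(A, matrix(1, 2, 2), ignore_attr = TRUE)
  # pixel-scan oracle on random dense labelings (<= 32x32)
  for (seed in 21:28) {
    labels <- expand_masks_iterative(
      random_dense_labeling(seed, H = 32, W = 32, n_cells = 6), 2)
    cm <- contact_ratios(labels)
    expect_equal(cm$A, brute_contact(labels), ignore_attr = TRUE)
    expect_true(all(cm$A >= 0 & cm$A <= 1))
  }
  expect_error(contact_ratios(matrix(0L, 5, 5)), "no cells")
})

test_that("row sums of off-diagonal contact ratios stay within 1", {
  # expanded packings of elliptical cells: each boundary pixel touches at
  # most one neighbour except at rare triple junctions
  for (seed in 31:35) {
    labels <- expand_masks_iterative(
      random_dense_labeling(seed, H = 40, W = 40, n_cells = 7), 2)
    A <- contact_ratios(labels)$A
    expect_true(all(rowSums(A) - 1 <= 1 + 1e-12))
  }
})

test_that("compensation inverts the forward model exactly", {
  # identity contacts: output equals input
  iso <- matrix(0L, 10, 10); iso[2:3, 2:3] <- 1L; iso[7:8, 7:8] <- 2L
  cm <- contact_ratios(iso)
  raw <- matrix(c(5, 10, 1, 2), 2, 2)
  expect_equal(compensate(raw, cm), raw)
  # forward-model recovery on a labelled scene with real contacts
  labels <- expand_masks_iterative(
    random_dense_labeling(40, H = 48, W = 48, n_cells = 9), 2)
  cm <- contact_ratios(labels)
  set.seed(40)
  n <- length(cm$ids)
  s <- matrix(runif(n * 3, 0, 100), n, 3)
  obs <- cm$A %*% s
  expect_lt(max(abs(compensate(obs, cm) - s)), 1e-8)
  # flank attenuates the off-diagonal before inversion
  Mf <- diag(n) + 0.5 * (cm$A - diag(n))
  expect_lt(max(abs(compensate(Mf %*% s, cm, flank = 0.5) - s)), 1e-8)
  expect_error(compensate(obs, cm, flank = 2), "flank")
  expect_error(compensate(obs[-1, , drop = FALSE], cm), "one row per cell")
})

test_that("negative solutions clamp to zero, singular components pass through", {
  mk_cm <- function(A) structure(list(ids = seq_len(nrow(A)), A = A),
                                 class = "contact_matrix")
  # raw values below the spillover prediction force a negative solution
  A <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  raw <- matrix(c(1, 10), 2, 1)
  expect_true(all(compensate(raw, mk_cm(A)) >= 0))
  # a numerically singular component is left uncompensated with a warning
  As <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_warning(out <- compensate(raw, mk_cm(As)), "ill-conditioned")
  expect_equal(out, raw)
  # cells without contacts pass through even when others are compensated
  A3 <- diag(3); A3[1, 2] <- A3[2, 1] <- 0.4
  raw3 <- matrix(c(50, 60, 7), 3, 1)
  out3 <- compensate(raw3, mk_cm(A3))
  expect_equal(out3[3, 1], 7)
  expect_equal(A3 %*% out3, raw3, ignore_attr = TRUE)
})
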