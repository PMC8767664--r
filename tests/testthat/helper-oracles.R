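# Independent brute-force oracles. These deliberately share no code with
# the package internals: everything is computed by explicit per-pixel or
# per-pair loops so they stay slow, simple and obviously correct.

brute_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 0 else sum(a & b) / u
}

# enumerate every (pred, gt) object pair and count matches above t
brute_confusion <- function(pred, gt, t) {
  pid <- sort(unique(pred[pred > 0])); gid <- sort(unique(gt[gt > 0]))
  matched_p <- c(); matched_g <- c()
  for (p in pid) for (g in gid) {
    if (brute_iou(pred == p, gt == g) > t) {
      matched_p <- c(matched_p, p); matched_g <- c(matched_g, g)
    }
  }
  c(TP = length(matched_p), FP = length(pid) - length(matched_p),
    FN = length(gid) - length(matched_g),
    dup = anyDuplicated(matched_p) + anyDuplicated(matched_g))
}

# per-pixel scan for boundary pixels and contact counts
brute_contact <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  ids <- sort(unique(labels[labels > 0]))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  blen <- setNames(numeric(n), ids)
  touch <- list()
  at <- function(r, c) if (r < 1 || r > H || c < 1 || c > W) 0 else labels[r, c]
  for (r in 1:H) for (c in 1:W) {
    own <- labels[r, c]
    if (own == 0) next
    # boundary if any 4-neighbour (image border counts as background) differs
    nb <- c(at(r - 1, c), at(r + 1, c), at(r, c - 1), at(r, c + 1))
    if (any(nb != own)) {
      blen[as.character(own)] <- blen[as.character(own)] + 1
      for (j in unique(nb[nb > 0 & nb != own]))
        A[as.character(own), as.character(j)] <-
          A[as.character(own), as.character(j)] + 1
    }
  }
  for (i in seq_len(n)) A[i, ] <- A[i, ] / blen[i]
  diag(A) <- 1
  A
}

# per-pixel nearest-centre expansion: for every background pixel compute its
# chessboard distance to every mask, find the claimants within n growth
# steps, and assign by nearest centroid (Euclidean; ties to the lower id)
brute_expand_nearest <- function(labels, n) {
  H <- nrow(labels); W <- ncol(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0 || n == 0) return(labels)
  masks <- lapply(ids, function(id) which(labels == id, arr.ind = TRUE))
  cents <- lapply(masks, colMeans)
  out <- labels
  for (r in 1:H) for (c in 1:W) {
    if (labels[r, c] != 0) next
    dmask <- vapply(masks, function(m)
      min(pmax(abs(m[, 1] - r), abs(m[, 2] - c))), numeric(1))
    claim <- which(dmask <= n)
    if (length(claim) == 0) next
    if (length(claim) == 1) { out[r, c] <- ids[claim]; next }
    dcen <- vapply(cents[claim], function(ct)
      sqrt((ct[1] - r)^2 + (ct[2] - c)^2), numeric(1))
    best <- claim[order(dcen, ids[claim])][1]
    out[r, c] <- ids[best]
  }
  out
}

# minimum pairwise Euclidean distance between pixels of distinct masks
min_mask_separation <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 2) return(Inf)
  masks <- lapply(ids, function(id) which(labels == id, arr.ind = TRUE))
  best <- Inf
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- masks[[i]]; b <- masks[[j]]
    d <- sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
    best <- min(best, min(d))
  }
  best
}

# random labelling of axis-aligned rectangles (objects may touch or even
# overwrite each other; relabelled to whatever survives)
random_rect_labeling <- function(H, W, max_obj) {
  labels <- matrix(0L, H, W)
  n <- sample.int(max_obj + 1L, 1L) - 1L   # 0..max_obj
  for (id in seq_len(n)) {
    h <- sample.int(max(1L, H %/% 2L), 1L)
    w <- sample.int(max(1L, W %/% 2L), 1L)
    r0 <- sample.int(H - h + 1L, 1L); c0 <- sample.int(W - w + 1L, 1L)
    labels[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- id
  }
  # overwriting can disconnect or erase an id; keep only intact survivors
  keep <- sort(unique(labels[labels > 0L]))
  out <- matrix(0L, H, W)
  for (k in seq_along(keep)) out[labels == keep[k]] <- k
  out
}

# densely packed labelling for expansion stress tests
random_dense_labeling <- function(seed, H = 48, W = 48, n_cells = 8,
                                  min_gap = 1L) {
  generate_nuclei(n_cells, H, W, radius_range = c(2.5, 5),
                  ecc_range = c(1, 2), min_gap = min_gap, noise_sd = 0,
                  seed = seed)$labels
}
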