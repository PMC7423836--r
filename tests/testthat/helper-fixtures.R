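# Shared fixtures and independent oracles. Oracles are deliberately naive
# (exhaustive loops) and independent of the implementation they check.

# Binary matrix with filled disks at the given centers (0-based rows/cols).
disk_mask <- function(h, w, centers, radius) {
  m <- matrix(FALSE, h, w)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (i in seq_len(nrow(centers)))
    m <- m | ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2)
  m
}

# Exhaustive Otsu: maximize between-class variance by trying every
# threshold, computing class weights and means directly from the sample.
otsu_brute <- function(values, bit_depth = 8) {
  v <- as.integer(round(as.vector(values)))
  if (length(unique(v)) < 2) return(NA_integer_)
  L <- 2^bit_depth - 1
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:(L - 1)) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (!length(bg) || !length(fg)) next
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Brute-force transitive-closure merge oracle: pairwise "closer than one
# diameter" adjacency, boolean closure, component collapse; collapsed
# points have larger diameters, so the whole pass repeats to fixed point.
merge_brute <- function(centroids, areas, rule = "mean") {
  repeat {
    out <- merge_brute_once(centroids, areas, rule)
    if (nrow(out) == nrow(centroids)) return(out)
    centroids <- out[, c("row", "col"), drop = FALSE]
    areas <- out[, "area"]
  }
}

merge_brute_once <- function(centroids, areas, rule = "mean") {
  n <- nrow(centroids)
  d_equiv <- 2 * sqrt(areas / pi)
  adj <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
    lim <- switch(rule, mean = (d_equiv[i] + d_equiv[j]) / 2,
                  min = min(d_equiv[i], d_equiv[j]),
                  max = max(d_equiv[i], d_equiv[j]))
    if (d < lim) adj[i, j] <- TRUE
  }
  repeat {                                   # boolean transitive closure
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n); cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) { cid <- cid + 1; comp[which(adj[i, ])] <- cid }
  }
  out <- t(sapply(sort(unique(comp)), function(k) {
    ids <- which(comp == k)
    c(row = sum(centroids[ids, 1] * areas[ids]) / sum(areas[ids]),
      col = sum(centroids[ids, 2] * areas[ids]) / sum(areas[ids]),
      area = sum(areas[ids]))
  }))
  out[order(out[, "row"], out[, "col"]), , drop = FALSE]
}

# All-pairs concordance AUC oracle.
auc_brute <- function(scores, labels, positive = "CTC_POSITIVE") {
  pos <- which(labels == positive); neg <- which(labels != positive)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  s / (length(pos) * length(neg))
}

make_points <- function(centroids, areas, channel = "CEP8") {
  lapply(seq_len(nrow(centroids)), function(i)
    ctcscope:::signal_point(centroids[i, ], areas[i], channel, 255))
}

# Match ground-truth cells to called nuclei by nearest centroid.
match_calls <- function(truth, calls, max_dist = 12) {
  cents <- t(vapply(calls, function(x) x$nucleus$centroid, numeric(2)))
  vapply(truth, function(gt) {
    if (!length(calls)) return(NA_character_)
    d <- sqrt(colSums((t(cents) - gt$centroid)^2))
    if (min(d) > max_dist) return(NA_character_)
    calls[[which.min(d)]]$label
  }, character(1))
}

iou_best <- function(gt, regions) {
  best <- 0
  for (r in regions) {
    i <- length(intersect(gt$pixels, r$pixels))
    if (i == 0) next
    best <- max(best, i / length(union(gt$pixels, r$pixels)))
  }
  best
}
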