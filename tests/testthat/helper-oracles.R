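## Independent oracles and fixture builders used across the suite.

# Exhaustive Otsu: between-class variance computed directly (class weights and
# means from raw sums) for every split t in 0..254; smallest maximizer wins.
bruteOtsu <- function(counts) {
  n <- sum(counts)
  best <- -1
  bestT <- NA_integer_
  for (t in 0:254) {
    c0 <- counts[1:(t + 1)]
    c1 <- counts[(t + 2):256]
    w0 <- sum(c0) / n
    w1 <- sum(c1) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * c0) / sum(c0)
    mu1 <- sum(((t + 1):255) * c1) / sum(c1)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-9 * max(1, abs(best))) {
      best <- v
      bestT <- t
    }
  }
  bestT
}

# Brute-force transitive closure of the <= radius relation: BFS over the
# adjacency matrix. Returns an integer membership vector.
bfsClusters <- function(xy, radius) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  adj <- as.matrix(stats::dist(xy)) <= radius
  memb <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (memb[i] > 0L) next
    cl <- cl + 1L
    queue <- i
    memb[i] <- cl
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & memb == 0L)
      memb[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  memb
}

# Two memberships describe the same partition iff co-membership matrices agree.
samePartition <- function(m1, m2) {
  identical(outer(m1, m1, "=="), outer(m2, m2, "=="))
}

# Paint disks (centers/diameters in pixels) onto a zero matrix.
diskImage <- function(nr, nc, rows, cols, diamPx, intensity = 200) {
  img <- matrix(0, nr, nc)
  for (i in seq_along(rows)) {
    rad <- diamPx[i] / 2
    rr <- pmax(1, floor(rows[i] - rad)):pmin(nr, ceiling(rows[i] + rad))
    cc <- pmax(1, floor(cols[i] - rad)):pmin(nc, ceiling(cols[i] + rad))
    for (r in rr) for (c in cc)
      if ((r - rows[i])^2 + (c - cols[i])^2 <= rad^2) img[r, c] <- intensity
  }
  img
}

# Random 256-bin histogram with varied shapes (flat noise, spikes, bimodal).
randomHistogram <- function() {
  kind <- sample(3, 1)
  h <- switch(kind,
    rpois(256, 5),
    {h <- rpois(256, 1); h[sample(256, 2)] <- h[sample(256, 2)] + 500; h},
    {x <- c(rnorm(3000, 60, 15), rnorm(1500, 190, 20))
     tabulate(pmin(pmax(round(x), 0), 255) + 1L, 256)})
  if (sum(h > 0) < 2) h[c(3, 250)] <- h[c(3, 250)] + 1
  as.numeric(h)
}

# One detection whose pixel set is the first `componentSize` pixels of a
# 40x40 frame, with a marker mask covering the first `nMaskOverlap` of them.
overlapFixture <- function(nMaskOverlap, componentSize = 40L) {
  px <- seq_len(componentSize)
  mask <- matrix(FALSE, 40, 40)
  mask[px[seq_len(nMaskOverlap)]] <- TRUE
  tab <- data.frame(id = 1L, row_px = 0, col_px = 0, x_um = 0, y_um = 0,
                    area_um2 = componentSize, eq_diameter_um = 12,
                    zone = NA_character_, marker_positive = NA)
  det <- new("CellDetections", table = tab, pixels = list(px),
             dim = c(40L, 40L), pixelSize = 1, noSignal = FALSE)
  mm <- new("MarkerMask", mask = mask, threshold = 100, markerName = "aSMA")
  list(det = det, mm = mm)
}
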