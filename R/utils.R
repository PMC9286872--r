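## Internal helpers: seeded evaluation, connected components, disk rasters.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Connected-component labeling of a logical matrix with selectable 4/8
# connectivity. Works on the foreground pixel list (sparse images stay cheap);
# component graph solved by igraph. Returns a list of integer vectors of
# column-major linear indices, one per component, in first-pixel order.
componentPixelSets <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  # half the neighbourhood: each undirected adjacency generated once
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- match(nb, fg)
    keep <- !is.na(hit)
    from <- c(from, which(ok)[keep])
    to <- c(to, hit[keep])
  }
  if (length(from) == 0L) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  unname(split(fg, memb))
}

# Linear indices of a rasterized disk centred at (row0, col0) with radius in
# pixels: pixels whose centre lies within the radius (inclusive).
diskIndices <- function(row0, col0, radiusPx, nr, nc) {
  r1 <- max(1L, floor(row0 - radiusPx)); r2 <- min(nr, ceiling(row0 + radiusPx))
  c1 <- max(1L, floor(col0 - radiusPx)); c2 <- min(nc, ceiling(col0 + radiusPx))
  if (r1 > r2 || c1 > c2) return(integer(0))
  rows <- r1:r2; cols <- c1:c2
  dr2 <- (rows - row0)^2
  dc2 <- (cols - col0)^2
  inside <- outer(dr2, dc2, "+") <= radiusPx^2
  rr <- rows[row(inside)[inside]]
  cx <- cols[col(inside)[inside]]
  (cx - 1L) * nr + rr
}

# Clamp to [0, 255] and round half up (so 0.5 -> 1), returning numeric matrix.
clamp8bit <- function(x) {
  x <- pmin(pmax(x, 0), 255)
  floor(x + 0.5)
}

# Greedy one-to-one nearest matching between detected and true positions
# within maxDist (um). Returns recall/precision and the matched pairs.
matchPoints <- function(detXY, trueXY, maxDist) {
  nd <- nrow(detXY); nt <- nrow(trueXY)
  if (nd == 0L || nt == 0L)
    return(list(nMatched = 0L,
                recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0,
                pairs = cbind(det = integer(0), truth = integer(0))))
  dmat <- outer(detXY[, 1], trueXY[, 1], "-")^2 +
          outer(detXY[, 2], trueXY[, 2], "-")^2
  dmat <- sqrt(dmat)
  dmat[dmat > maxDist] <- Inf
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("det", "truth")))
  while (any(is.finite(dmat))) {
    k <- arrayInd(which.min(dmat), dim(dmat))
    pairs <- rbind(pairs, k)
    dmat[k[1], ] <- Inf
    dmat[, k[2]] <- Inf
  }
  list(nMatched = nrow(pairs), recall = nrow(pairs) / nt,
       precision = nrow(pairs) / nd, pairs = pairs)
}
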