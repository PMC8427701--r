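# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# breadth-first flood fill from a single 1-based seed; returns linear indices
bfs_flood <- function(data, seed, connectivity = 26) {
  d <- dim(data)
  offs <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$ds == 0 & offs$dr == 0 & offs$dc == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$ds) + abs(offs$dr) + abs(offs$dc) == 1, ]
  visited <- array(FALSE, d)
  queue <- matrix(seed, ncol = 3)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  out <- c((seed[3] - 1) * d[1] * d[2] + (seed[2] - 1) * d[1] + seed[1])
  while (nrow(queue)) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      nb <- cur + as.integer(offs[k, ])
      if (any(nb < 1) || any(nb > d)) next
      if (visited[nb[1], nb[2], nb[3]] || !data[nb[1], nb[2], nb[3]]) next
      visited[nb[1], nb[2], nb[3]] <- TRUE
      queue <- rbind(queue, nb)
      out <- c(out, (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1])
    }
  }
  sort(out)
}

# full BFS partition with labels assigned by first encounter in
# column-major scan order
bfs_partition <- function(data, connectivity = 26) {
  d <- dim(data)
  lab <- array(0L, d)
  nxt <- 0L
  for (lin in which(data)) {
    if (lab[lin] > 0L) next
    nxt <- nxt + 1L
    co <- arrayInd(lin, d)
    lab[bfs_flood(data, as.integer(co), connectivity)] <- nxt
  }
  lab
}

# exhaustive Kapur criterion scan over all splits of a histogram
kapur_bruteforce <- function(counts, edges) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf; best_t <- NA
  for (t in 1:(n - 1)) {
    P0 <- sum(p[1:t]); P1 <- sum(p[(t + 1):n])
    if (P0 <= 0 || P1 <= 0) next
    q0 <- p[1:t] / P0; q1 <- p[(t + 1):n] / P1
    H0 <- -sum(ifelse(q0 > 0, q0 * log(q0), 0))
    H1 <- -sum(ifelse(q1 > 0, q1 * log(q1), 0))
    if (H0 + H1 > best) { best <- H0 + H1; best_t <- t }
  }
  edges[best_t + 1]
}

# O(n^2) maximum pairwise distance over all corner points of all voxels
feret_bruteforce <- function(voxels, spacing) {
  corners <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5)))
  pts <- do.call(rbind, lapply(seq_len(8), function(i)
    sweep(voxels, 2, -corners[i, ]) %*% diag(spacing)))
  pts <- unique(pts)
  max(stats::dist(pts))
}
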