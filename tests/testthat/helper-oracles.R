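# Independent brute-force oracles. These deliberately use naive per-pixel
# loops and never call the package's own implementations.

random_mask <- function(nr = 16L, nc = 16L, p = 0.3, seed = 1L) {
  set.seed(seed)
  m <- matrix(as.integer(runif(nr * nc) < p), nr, nc)
  if (sum(m) == 0) m[ceiling(nr / 2), ceiling(nc / 2)] <- 1L
  binary_mask(m)
}

bf_confusion <- function(pred, gt) {
  p <- pred$values; g <- gt$values
  tp <- fp <- tn <- fn <- 0L
  for (r in seq_len(nrow(p))) for (cc in seq_len(ncol(p))) {
    if (p[r, cc] == 1L && g[r, cc] == 1L) tp <- tp + 1L
    else if (p[r, cc] == 1L) fp <- fp + 1L
    else if (g[r, cc] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

bf_overlap <- function(cc) {
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  den <- as.numeric(cc$tp + cc$fp) * (cc$tp + cc$fn) *
         (cc$tn + cc$fp) * (cc$tn + cc$fn)
  list(acc = (cc$tp + cc$tn) / n,
       sen = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
       jaccard = cc$tp / (cc$tp + cc$fp + cc$fn),
       dice = 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn),
       mcc = if (den > 0)
         (as.numeric(cc$tp) * cc$tn - as.numeric(cc$fp) * cc$fn) / sqrt(den)
       else 0)
}

# boundary pixels: foreground with a 4-neighbour outside the mask (or border)
bf_boundary <- function(m) {
  pts <- NULL
  nr <- nrow(m); nc <- ncol(m)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (m[r, cc] != 1L) next
    edge <- r == 1L || r == nr || cc == 1L || cc == nc ||
      m[r - 1L, cc] == 0L || m[r + 1L, cc] == 0L ||
      m[r, cc - 1L] == 0L || m[r, cc + 1L] == 0L
    if (edge) pts <- rbind(pts, c(r, cc))
  }
  pts
}

bf_hausdorff <- function(pred, gt) {
  A <- bf_boundary(pred$values); B <- bf_boundary(gt$values)
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q)))
        best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

# erosion by exact disc, per-pixel scan
bf_erode <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; ccc <- cc + offs$dc[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc || m[rr, ccc] == 0L) {
        keep <- FALSE
        break
      }
    }
    if (keep && m[r, cc] == 1L) out[r, cc] <- 1L
  }
  out
}

# a small, fast phantom spec for unit tests
tiny_spec <- function(seed = 1L, ...) phantom_spec(image_size = 96L, seed = seed, ...)
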