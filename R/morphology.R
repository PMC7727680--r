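# Binary morphology with an exact disc structuring element
# {(dr, dc) : dr^2 + dc^2 <= r^2}, implemented by shift-and-combine so the
# semantics are independent of any external library's brush approximation.
# Outside the image counts as background for both erosion and dilation.

disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

shift_matrix <- function(m, dr, dc, fill = 0L) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

mask_erode <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- disc_offsets(radius)
  out <- matrix(1L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift_matrix(m, -off$dr[i], -off$dc[i], 0L)
  out <- out * 1L
  dim(out) <- dim(m)
  out
}

mask_dilate <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- disc_offsets(radius)
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_matrix(m, off$dr[i], off$dc[i], 0L)
  out <- out * 1L
  dim(out) <- dim(m)
  out
}

# Pixels of m that touch the background 4-connectedly (or the image border).
mask_boundary <- function(m) {
  inner <- shift_matrix(m, 1, 0) & shift_matrix(m, -1, 0) &
           shift_matrix(m, 0, 1) & shift_matrix(m, 0, -1)
  (m == 1L) & !inner
}

# Does any 8-neighbour satisfy the mask? (used for frontier computation)
has_neighbor8 <- function(m) {
  acc <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc | (shift_matrix(m, dr, dc) == 1L)
  }
  acc
}
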