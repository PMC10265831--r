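# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# earliest time with three successive strict increases, by exhaustive scan
oracle_arrival <- function(times, values) {
  n <- length(values)
  for (i in seq_len(n - 3L)) {
    if (values[i + 1L] > values[i] && values[i + 2L] > values[i + 1L] &&
        values[i + 3L] > values[i + 2L]) {
      return(times[i])
    }
  }
  NA_real_
}

# 6-connected distance-to-background by breadth-first search; background
# (and out-of-volume) voxels have distance 0
oracle_bfs_distance <- function(mask) {
  d <- dim(mask)
  dist <- array(Inf, dim = d)
  frontier <- which(!mask, arr.ind = TRUE)
  dist[!mask] <- 0
  # also seed border voxels of the mask that touch the volume edge
  lvl <- 0
  repeat {
    nxt <- NULL
    for (r in seq_len(nrow(frontier))) {
      v <- frontier[r, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        w <- v; w[ax] <- w[ax] + s
        if (any(w < 1L) || any(w > d)) next
        if (dist[w[1], w[2], w[3]] > lvl + 1L) {
          dist[w[1], w[2], w[3]] <- lvl + 1L
          nxt <- rbind(nxt, w)
        }
      }
    }
    # voxels adjacent to out-of-volume count background at distance 0
    if (lvl == 0) {
      border <- which(mask, arr.ind = TRUE)
      border <- border[apply(border, 1, function(v) any(v == 1L) ||
                               any(v == d)), , drop = FALSE]
      for (r in seq_len(nrow(border))) {
        v <- border[r, ]
        if (dist[v[1], v[2], v[3]] > 1L) {
          dist[v[1], v[2], v[3]] <- 1L
          nxt <- rbind(nxt, v)
        }
      }
    }
    if (is.null(nxt)) break
    frontier <- nxt
    lvl <- lvl + 1
  }
  dist
}

# random blobby 3D mask: union of a few solid spheres, clipped to the volume
random_blob_mask <- function(d = c(12L, 12L, 12L), n_spheres = 3L) {
  mask <- array(FALSE, dim = d)
  ctr <- cbind(runif(n_spheres, 3, d[1] - 2), runif(n_spheres, 3, d[2] - 2),
               runif(n_spheres, 3, d[3] - 2))
  rad <- runif(n_spheres, 2, 4)
  ix <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                              z = seq_len(d[3])))
  for (s in seq_len(n_spheres)) {
    keep <- sqrt(colSums((t(ix) - ctr[s, ])^2)) <= rad[s]
    mask[ix[keep, , drop = FALSE]] <- TRUE
  }
  mask
}

# standard test grid and gamma-variate outer curve
test_grid <- function() seq(0, 360, length.out = 40)

test_outer <- function(times = test_grid(), A = 30) {
  gamma_variate_input(t0 = 20, A = A, alpha = 2, tau = 40, times = times)
}
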