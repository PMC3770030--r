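# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# shortest Euclidean distance from each grid pixel to any pixel in `pts`
# (n x 2 matrix, 1-based), by exhaustive minimization
brute_distance_field <- function(pts, shape) {
  out <- matrix(Inf, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
    }
  }
  out
}

# double-loop source-energy sum (Eq-style): sum over source pixels of
# exp(-dist/sigma) * g(source)
brute_source_energy <- function(r0, g, sigma) {
  src <- which(r0, arr.ind = TRUE)
  out <- matrix(0, nrow(g), ncol(g))
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      d <- sqrt((src[, 1] - i)^2 + (src[, 2] - j)^2)
      out[i, j] <- sum(exp(-d / sigma) * g[cbind(src[, 1], src[, 2])])
    }
  }
  out
}

# Dijkstra shortest-path oracle on the 8-connected grid: edge cost between
# neighbors p, q is the mean of their reciprocal speeds times the step length.
# O(V^2) scan, fine for <= 32 x 32 grids.
dijkstra_time_oracle <- function(energy, seeds) {
  nr <- nrow(energy); nc <- ncol(energy)
  n <- nr * nc
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  idx <- function(i, j) (j - 1L) * nr + i
  inv <- 1 / energy
  for (k in seq_len(nrow(seeds))) dist[idx(seeds[k, 1], seeds[k, 2])] <- 0
  nbr <- expand.grid(di = -1:1, dj = -1:1)
  nbr <- nbr[!(nbr$di == 0 & nbr$dj == 0), ]
  for (step in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    ui <- (u - 1L) %% nr + 1L; uj <- (u - 1L) %/% nr + 1L
    for (q in seq_len(nrow(nbr))) {
      vi <- ui + nbr$di[q]; vj <- uj + nbr$dj[q]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      v <- idx(vi, vj)
      if (done[v]) next
      len <- sqrt(nbr$di[q]^2 + nbr$dj[q]^2)
      w <- 0.5 * (inv[u] + inv[v]) * len
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc)
}

# pixel-counting metrics oracle via explicit set algebra on index sets
brute_metrics <- function(o, g) {
  O <- which(o); G <- which(g)
  OG <- intersect(O, G)
  OB <- setdiff(O, G)
  list(fpe = length(OB) / length(G),
       fne = (length(G) - length(OG)) / length(G),
       si = 2 * length(OG) / (length(O) + length(G)))
}

# small, fast phantom used by unit tests (full default phantom is reserved
# for the acceptance suite)
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(128L, 128L),
               organ_a = list(center = c(64, 46), semi_axes = c(29, 19)),
               organ_b = list(center = c(64, 88), semi_axes = c(30, 26)),
               ...)
}

# central-difference gradient norm with replicate edges (independent of the
# package's internal helper)
test_grad_norm <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- m[, pmin(seq_len(nc) + 1, nc)] - m[, pmax(seq_len(nc) - 1, 1)]
  yr <- m[pmin(seq_len(nr) + 1, nr), ] - m[pmax(seq_len(nr) - 1, 1), ]
  sqrt((xr / 2)^2 + (yr / 2)^2)
}
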