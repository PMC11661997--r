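# Independent oracles, deliberately implemented apart from the package
# code paths they check.

# Full-lattice discrete Frechet dynamic program over the complete
# coupling matrix (no rolling rows, plain R).
frechet_oracle <- function(a, b, time_scale = 0, value_scale = 1) {
  grid <- sort(unique(c(a$t, b$t)))
  va <- approx(a$t, a$v, grid, rule = 2)$y
  vb <- approx(b$t, b$v, grid, rule = 2)$y
  p <- length(grid); q <- length(grid)
  g <- function(i, j) sqrt(((grid[i] - grid[j]) * time_scale)^2 +
                           ((va[i] - vb[j]) * value_scale)^2)
  ca <- matrix(NA_real_, p, q)
  ca[1, 1] <- g(1, 1)
  for (j in 2:q) ca[1, j] <- max(ca[1, j - 1], g(1, j))
  for (i in 2:p) {
    ca[i, 1] <- max(ca[i - 1, 1], g(i, 1))
    for (j in 2:q)
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      g(i, j))
  }
  ca[p, q]
}

# EMD for integer-mass histograms of equal total: expand the masses into
# unit atoms and take the minimum-cost perfect matching by brute-force
# permutation enumeration (the transportation polytope has an integral
# optimum, which decomposes into such a matching).
emd_atom_oracle <- function(p, q, ground) {
  stopifnot(sum(p) == sum(q), sum(p) <= 8)
  atoms_p <- rep(seq_along(p), p)
  atoms_q <- rep(seq_along(q), q)
  n <- length(atoms_p)
  perms <- all_permutations(n)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    cost <- sum(ground[cbind(atoms_p, atoms_q[perms[r, ]])])
    if (cost < best) best <- cost
  }
  best / n
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# random metric ground distances: Euclidean distances of random points
random_ground <- function(n_clusters) {
  pts <- matrix(runif(2 * n_clusters, 0, 5), ncol = 2)
  as.matrix(dist(pts))
}
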