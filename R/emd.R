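#' Earth Mover's Distance between two histograms
#'
#' Solves the transportation problem between the two normalized
#' histograms exactly (two-phase simplex via [boot::simplex()]): minimize
#' `sum_ij ground[i, j] * x[i, j]` subject to row sums `p` and column
#' sums `q`, `x >= 0`.  After normalization the total flow is 1, so the
#' optimal cost already is the flow-normalized EMD.
#'
#' @param p,q Non-negative mass vectors over the same index set (e.g.
#'   cluster occurrence counts); each must carry positive total mass.
#'   They are normalized to sum to 1 internally.
#' @param ground Square matrix of ground distances between the indices.
#' @return The EMD, a non-negative number; 0 iff the normalized
#'   histograms are equal.
#' @export
emd <- function(p, q, ground) {
  p <- as.numeric(p); q <- as.numeric(q)
  n <- length(p)
  if (n == 0L || length(q) != n)
    stop("emd: histograms must be non-empty and of equal length",
         call. = FALSE)
  if (any(p < 0) || any(q < 0) || sum(p) <= 0 || sum(q) <= 0)
    stop("emd: histograms need non-negative masses and positive totals",
         call. = FALSE)
  ground <- as.matrix(ground)
  stopifnot(nrow(ground) == n, ncol(ground) == n)
  p <- p / sum(p)
  q <- q / sum(q)
  if (max(abs(p - q)) < 1e-12) return(0)
  if (n == 1L) return(0)

  # reduce to the supported rows (supplies) and columns (demands)
  rows <- which(p > 0)
  cols <- which(q > 0)
  C <- ground[rows, cols, drop = FALSE]
  ps <- p[rows]; qs <- q[cols]
  nr <- length(rows); nc <- length(cols)
  if (nr == 1L) return(sum(qs * C[1L, ]))
  if (nc == 1L) return(sum(ps * C[, 1L]))

  # transportation LP: variables x[i, j] laid out row-major, one
  # equality per supply and per demand (the last demand is implied by
  # the others and dropped to avoid a redundant constraint)
  A3 <- matrix(0, nr + nc - 1L, nr * nc)
  for (i in seq_len(nr)) A3[i, (i - 1L) * nc + seq_len(nc)] <- 1
  for (j in seq_len(nc - 1L)) A3[nr + j, (seq_len(nr) - 1L) * nc + j] <- 1
  b3 <- c(ps, qs[seq_len(nc - 1L)])
  sol <- boot::simplex(a = as.vector(t(C)), A3 = A3, b3 = b3, maxi = FALSE)
  if (sol$solved < 0)
    stop("emd: transportation LP did not converge", call. = FALSE)
  max(0, sol$value)
}
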