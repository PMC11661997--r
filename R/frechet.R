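#' Discrete Fréchet distance between two aligned curves
#'
#' The discrete Fréchet distance is the minimum, over monotone couplings
#' of the two sample sequences, of the maximum coupled point-pair
#' distance ("dog-leash" distance on the samples).  The ground distance is
#' Euclidean on the scaled plane `(t * time_scale, v * value_scale)`.
#'
#' Both curves must cover the same time span (use [align_dataset()]
#' first).  If their sampling grids differ they are linearly resampled
#' onto the union grid of the common frame before the dynamic program, so
#' the coupling walks over identical index sets.
#'
#' With the default `time_scale = 0` the distance is computed on the
#' values at coupled indices of the commonly framed, identically
#' resampled curves; time then enters only through the coupling order,
#' which sidesteps mixing seconds with signal units.  Set a positive
#' `time_scale` to trade the axes explicitly.
#'
#' @param a,b [curve] objects covering the same span.
#' @param time_scale,value_scale Non-negative axis weights of the ground
#'   distance.
#' @return A single non-negative number; 0 for identical curves.
#' @export
frechet_distance <- function(a, b, time_scale = 0, value_scale = 1) {
  stopifnot(is_curve(a), is_curve(b))
  sa <- range(a$t); sb <- range(b$t)
  if (max(abs(sa - sb)) > 1e-9)
    stop("frechet_distance: curves are not aligned to a common frame ",
         "(spans [", sa[1L], ", ", sa[2L], "] vs [", sb[1L], ", ", sb[2L],
         "]); use align_dataset() first", call. = FALSE)
  if (length(a$t) != length(b$t) || any(abs(a$t - b$t) > 1e-9)) {
    grid <- sort(unique(c(a$t, b$t)))
    va <- curve_values_at(a, grid)
    vb <- curve_values_at(b, grid)
    .frechet_dp(grid, va, grid, vb, time_scale, value_scale)
  } else {
    .frechet_dp(a$t, a$v, b$t, b$v, time_scale, value_scale)
  }
}

#' All pairwise Fréchet distances of a curve set
#'
#' Resamples every curve onto the union grid of the set's common frame
#' and runs the discrete Fréchet dynamic program for every pair.
#'
#' @param cs An aligned `curve_set`.
#' @param time_scale,value_scale Ground-distance axis weights, see
#'   [frechet_distance()].
#' @return A symmetric `n x n` matrix with zero diagonal, dimnames set to
#'   the curve ids.
#' @export
pairwise_distances <- function(cs, time_scale = 0, value_scale = 1) {
  stopifnot(is_curve_set(cs))
  grid <- set_union_grid(cs)
  V <- vapply(cs$curves, curve_values_at, numeric(length(grid)), at = grid)
  D <- .frechet_pairwise_grid(grid, V, time_scale, value_scale)
  dimnames(D) <- list(curve_ids(cs), curve_ids(cs))
  D
}

set_union_grid <- function(cs) {
  sort(unique(unlist(lapply(cs$curves, `[[`, "t"))))
}

#' Export a distance matrix as CSV (debugging aid)
#'
#' @param dm Matrix from [pairwise_distances()].
#' @param path Output path.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(dm, path, sep = ";", col.names = NA, quote = FALSE)
  invisible(path)
}
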