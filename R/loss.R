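#' Generalization loss (GLM) of a released hull
#'
#' The information loss of an equivalence class is the fraction of the
#' value domain spanned by its generalization: the mean, over the hull
#' grid, of `(upper - lower) / (v_max - v_min)`.  A class with a single
#' member loses nothing and scores 0 by definition.
#'
#' @param hull A `hull` (see [build_hull()]).
#' @param value_domain Length-2 numeric `(v_min, v_max)` of the dataset.
#' @param member_count Number of (non-dropped) members of the class.
#' @return A number in `[0, 1]`.
#' @export
glm_info_loss <- function(hull, value_domain, member_count) {
  stopifnot(inherits(hull, "hull"))
  if (member_count <= 1L) return(0)
  W <- value_domain[2L] - value_domain[1L]
  if (W <= 0) {
    warning("glm_info_loss: degenerate value domain; loss defined as 0")
    return(0)
  }
  mean((hull$upper - hull$lower) / W)
}

#' Median relative error of an equivalence class
#'
#' For every non-dropped member and every hull grid time, the relative
#' error is the distance from the member's (interpolated) value to the
#' nearer hull bound: `min(|v - lower|, |upper - v|)`.  The class MRE is
#' the median of all these errors, pooled over members and grid points.
#' It is computed at the hull's own resolution.
#'
#' @param members List of [curve] objects (the class's non-dropped
#'   members, aligned).
#' @param hull The class's `hull`.
#' @param interpolate Linear interpolation of member values at grid times
#'   (`TRUE`) or previous-sample hold (`FALSE`).
#' @return A non-negative number.
#' @export
median_relative_error <- function(members, hull, interpolate = TRUE) {
  stopifnot(inherits(hull, "hull"))
  if (length(members) == 0L)
    stop("median_relative_error: empty equivalence class", call. = FALSE)
  errs <- unlist(lapply(members, function(m) {
    v <- curve_values_at(m, hull$grid, interpolate = interpolate)
    pmin(abs(v - hull$lower), abs(hull$upper - v))
  }))
  median(errs)
}
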