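#' Build the released hull of an equivalence class
#'
#' The hull is the pointwise lower/upper envelope of the (non-dropped)
#' member curves on a regular grid: `grid = start + i * resolution`,
#' with the final point clamped to the segment end.  Member values at
#' grid times are interpolated (linearly, or by previous-sample hold if
#' the signal is not interpolable); the hull resolution is independent of
#' the members' sampling.
#'
#' @param members Non-empty list of aligned [curve] objects.
#' @param resolution Grid step in seconds (> 0).
#' @param frame Optional length-2 numeric time frame; defaults to the
#'   members' common span.
#' @param interpolate Linear interpolation (`TRUE`) or previous-sample
#'   hold (`FALSE`).
#' @return An object of class `hull` with fields `resolution`, `grid`,
#'   `lower`, `upper`.
#' @export
build_hull <- function(members, resolution, frame = NULL, interpolate = TRUE) {
  if (length(members) == 0L)
    stop("build_hull: empty member list", call. = FALSE)
  stopifnot(resolution > 0)
  if (is.null(frame)) {
    frame <- c(min(vapply(members, function(m) m$t[1L], numeric(1L))),
               max(vapply(members, function(m) m$t[length(m$t)], numeric(1L))))
  }
  grid <- hull_grid(frame, resolution)
  V <- vapply(members, curve_values_at, numeric(length(grid)),
              at = grid, interpolate = interpolate)
  V <- matrix(V, nrow = length(grid))
  structure(list(resolution = resolution, grid = grid,
                 lower = apply(V, 1L, min), upper = apply(V, 1L, max)),
            class = "hull")
}

hull_grid <- function(frame, resolution) {
  eps <- 1e-9
  grid <- seq(frame[1L], frame[2L] + eps, by = resolution)
  if (grid[length(grid)] < frame[2L] - eps) grid <- c(grid, frame[2L])
  grid[length(grid)] <- frame[2L]  # clamp
  unique(grid)
}

#' Merge two hulls (class merging along the ECS parenthood relation)
#'
#' The hull is additive: the hull of a merged equivalence class is the
#' pointwise `(min lower, max upper)` of the children's hulls.  Both
#' hulls must share the same grid.
#'
#' @param a,b `hull` objects on identical grids.
#' @return A `hull`.
#' @export
merge_hulls <- function(a, b) {
  stopifnot(inherits(a, "hull"), inherits(b, "hull"))
  if (length(a$grid) != length(b$grid) || any(abs(a$grid - b$grid) > 1e-9))
    stop("merge_hulls: grid mismatch", call. = FALSE)
  structure(list(resolution = a$resolution, grid = a$grid,
                 lower = pmin(a$lower, b$lower),
                 upper = pmax(a$upper, b$upper)),
            class = "hull")
}

#' @export
print.hull <- function(x, ...) {
  cat(sprintf("<hull> %d grid point(s) at %g s on [%g, %g] s\n",
              length(x$grid), x$resolution, x$grid[1L],
              x$grid[length(x$grid)]))
  invisible(x)
}

#' Plot a hull with optional member curves
#'
#' @param x A `hull`.
#' @param members Optional list of member [curve]s drawn inside the
#'   envelope.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hull <- function(x, members = NULL, ...) {
  graphics::plot(x$grid, x$upper, type = "n",
                 ylim = range(c(x$lower, x$upper)),
                 xlab = "time [s]", ylab = "value", ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$upper, rev(x$lower)),
                    col = "grey85", border = NA)
  graphics::lines(x$grid, x$lower); graphics::lines(x$grid, x$upper)
  if (!is.null(members))
    for (m in members) graphics::lines(m$t, m$v, col = "steelblue")
  invisible(x)
}

#' Write a hull in the curve CSV dialect
#'
#' Columns are `"Time [s];lower [<unit>];upper [<unit>]"` under the same
#' three-line header as the input curves.
#'
#' @param hull A `hull`.
#' @param path Output path.
#' @param quantity_name,unit Metadata for the header.
#' @param class_id Identifier written in place of the subject UUID (a
#'   released hull represents a class, not a subject).
#' @param start ISO datetime for the header.
#' @return Invisibly, `path`.
#' @export
write_hull_csv <- function(hull, path, quantity_name = "value", unit = "",
                           class_id = "eqc", start = "1970-01-01T00:00:00") {
  header <- c(class_id, start,
              sprintf("Time [s];lower [%s];upper [%s]", unit, unit))
  rows <- sprintf("%s;%s;%s", fmt_num(hull$grid), fmt_num(hull$lower),
                  fmt_num(hull$upper))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
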