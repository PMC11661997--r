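#' Restrict an aligned curve set to a time interval
#'
#' Keeps the samples inside `[t0, t1]` and adds linearly interpolated
#' samples at the interval boundaries, so every restriction has at least
#' two points per curve.  The value domain is recomputed over the
#' restricted samples.
#'
#' @param cs A `curve_set`.
#' @param interval Length-2 numeric `(t0, t1)` inside the common frame.
#' @return A `curve_set` whose common frame is `interval`.
#' @export
restrict_curve_set <- function(cs, interval) {
  stopifnot(is_curve_set(cs), length(interval) == 2L,
            interval[1L] < interval[2L])
  t0 <- interval[1L]; t1 <- interval[2L]
  eps <- 1e-9
  restricted <- lapply(cs$curves, function(c) {
    inside <- c$t > t0 + eps & c$t < t1 - eps
    c$v <- c(curve_values_at(c, t0), c$v[inside], curve_values_at(c, t1))
    c$t <- c(t0, c$t[inside], t1)  # absolute times kept for reporting
    c
  })
  vr <- range(unlist(lapply(restricted, `[[`, "v")))
  structure(
    list(curves = restricted, common_frame = c(t0, t1), value_domain = vr,
         quantity_name = cs$quantity_name, unit = cs$unit),
    class = "curve_set")
}

new_segment <- function(index, interval, cs) {
  structure(list(index = index, interval = interval,
                 curves = restrict_curve_set(cs, interval)),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment %d> [%g, %g) s, %d curve(s)\n",
              x$index, x$interval[1L], x$interval[2L], length(x$curves)))
  invisible(x)
}

#' Fixed-length time-axis splitting
#'
#' Splits the common frame into consecutive segments of
#' `segment_length` seconds.  A final remainder shorter than
#' `remainder_threshold` is added to the last segment; otherwise it
#' becomes its own segment.  Intervals are half-open `[start, end)`, the
#' final segment closed at the frame end.
#'
#' @param cs An aligned `curve_set`.
#' @param segment_length Segment length in seconds (> 0).
#' @param remainder_threshold Remainder merge threshold in seconds.
#' @return A list of `segment` objects partitioning the frame.
#' @export
split_fixed <- function(cs, segment_length, remainder_threshold = segment_length / 2) {
  stopifnot(is_curve_set(cs), segment_length > 0)
  t0 <- cs$common_frame[1L]; t1 <- cs$common_frame[2L]
  frame_len <- t1 - t0
  if (segment_length >= frame_len) {
    warning("split_fixed: segment length >= frame length; single segment")
    return(list(new_segment(1L, c(t0, t1), cs)))
  }
  eps <- 1e-9
  n_full <- floor((frame_len + eps) / segment_length)
  remainder <- frame_len - n_full * segment_length
  if (remainder < eps) remainder <- 0
  bounds <- t0 + segment_length * seq_len(n_full - 1L)
  if (remainder > 0 && remainder >= remainder_threshold - eps)
    bounds <- c(bounds, t0 + segment_length * n_full)
  edges <- c(t0, bounds, t1)
  lapply(seq_len(length(edges) - 1L), function(i)
    new_segment(i, c(edges[i], edges[i + 1L]), cs))
}

#' Manual (expert-chosen) time-axis splitting
#'
#' Each provided interval becomes one segment; every segment must start
#' at or after the previous one ends, and data between intervals is
#' simply omitted from the anonymization.
#'
#' @param cs An aligned `curve_set`.
#' @param boundaries List of length-2 numeric `[start, end)` intervals,
#'   ordered, non-overlapping, inside the common frame.
#' @return A list of `segment` objects (gaps allowed).
#' @export
split_manual <- function(cs, boundaries) {
  stopifnot(is_curve_set(cs), length(boundaries) >= 1L)
  iv <- do.call(rbind, lapply(boundaries, function(b) {
    if (length(b) != 2L || b[1L] >= b[2L])
      stop("split_manual: each boundary must be a [start, end) pair",
           call. = FALSE)
    as.numeric(b)
  }))
  eps <- 1e-9
  if (any(iv[, 1L] < cs$common_frame[1L] - eps) ||
      any(iv[, 2L] > cs$common_frame[2L] + eps))
    stop("split_manual: interval outside the common frame", call. = FALSE)
  if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L] - eps))
    stop("split_manual: intervals must be ordered and non-overlapping",
         call. = FALSE)
  lapply(seq_len(nrow(iv)), function(i)
    new_segment(i, iv[i, ], cs))
}

#' Windowed-Fréchet similarity splitting
#'
#' Slides a window of `window` seconds in steps of `step` seconds across
#' the common frame, computes the mean of all pairwise Fréchet distances
#' between the curve restrictions to each window, and places segment
#' boundaries at the starts of the `n_segments - 1` windows with the
#' lowest mean distance — segments then reach from one region of
#' similarity to the next.  Chosen boundaries must lie strictly inside
#' the frame and at least one window length apart (earliest offset wins
#' ties); the resulting segments partition the frame without gaps.
#'
#' @param cs An aligned `curve_set`.
#' @param window Window length in seconds (> 0).
#' @param step Step size in seconds (> 0, at most `window`).
#' @param n_segments Desired number of segments (>= 1).
#' @param time_scale,value_scale Ground-distance weights, see
#'   [frechet_distance()].
#' @return A list of `segment` objects partitioning the frame.
#' @export
split_windowed_frechet <- function(cs, window, step, n_segments,
                                   time_scale = 0, value_scale = 1) {
  stopifnot(is_curve_set(cs), window > 0, step > 0, n_segments >= 1)
  if (step > window)
    stop("split_windowed_frechet: step must not exceed window", call. = FALSE)
  t0 <- cs$common_frame[1L]; t1 <- cs$common_frame[2L]
  if (n_segments == 1L)
    return(list(new_segment(1L, c(t0, t1), cs)))

  eps <- 1e-9
  offsets <- seq(t0, t1 - window + eps, by = step)
  # boundary = window start; it must be strictly inside the frame
  cand <- offsets[offsets > t0 + eps & offsets < t1 - eps]
  if (length(cand) == 0L)
    stop("split_windowed_frechet: no admissible window offsets", call. = FALSE)
  means <- vapply(cand, function(off) {
    wcs <- restrict_curve_set(cs, c(off, off + window))
    D <- pairwise_distances(wcs, time_scale, value_scale)
    mean(D[upper.tri(D)])
  }, numeric(1L))

  ord <- order(means, cand)  # lowest mean first, earliest offset on ties
  chosen <- numeric(0)
  for (i in ord) {
    if (length(chosen) == n_segments - 1L) break
    if (all(abs(cand[i] - chosen) >= window - eps))
      chosen <- c(chosen, cand[i])
  }
  if (length(chosen) < n_segments - 1L)
    stop("split_windowed_frechet: only ", length(chosen) + 1L,
         " segment(s) achievable with window ", window, " and step ", step,
         call. = FALSE)
  edges <- c(t0, sort(chosen), t1)
  lapply(seq_len(length(edges) - 1L), function(i)
    new_segment(i, c(edges[i], edges[i + 1L]), cs))
}

#' Split a curve set according to a split configuration
#'
#' @param cs An aligned `curve_set`.
#' @param config A list with `mode` one of `"none"`, `"fixed"`,
#'   `"manual"`, `"windowed_frechet"` and the mode's parameters
#'   (`segment_length`, `remainder_threshold`; `boundaries`; `window`,
#'   `step`, `n_segments`).
#' @return A list of `segment` objects.
#' @export
split_dataset <- function(cs, config) {
  mode <- config$mode %||% "none"
  switch(mode,
    none = list(new_segment(1L, cs$common_frame, cs)),
    fixed = split_fixed(cs, config$segment_length,
                        config$remainder_threshold %||%
                          (config$segment_length / 2)),
    manual = split_manual(cs, config$boundaries),
    windowed_frechet = split_windowed_frechet(
      cs, config$window, config$step, config$n_segments,
      config$time_scale %||% 0, config$value_scale %||% 1),
    stop("split_dataset: unknown mode '", mode, "'", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
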