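#' Construct a waveform curve
#'
#' A curve is an ordered list of `(t, v)` samples of one physiological
#' signal for one subject, together with identity metadata.  Times are in
#' seconds since `start` and must be strictly increasing; a curve needs at
#' least two samples.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing,
#'   all `>= 0`.
#' @param v Numeric vector of measured values, same length as `t`.
#' @param curve_id Opaque identifier of the curve within a dataset.
#' @param subject_uuid Subject identifier (a UUID in the native file
#'   format; any string is accepted).
#' @param start Start of the recording as an ISO-8601 datetime string.
#' @param quantity_name Name of the measured quantity, e.g. `"AWF"`.
#' @param unit Unit of the measured values, e.g. `"L/min"`; may be `""`.
#' @return An object of class `curve`.
#' @export
curve <- function(t, v, curve_id = "c1",
                  subject_uuid = "00000000-0000-0000-0000-000000000000",
                  start = "1970-01-01T00:00:00",
                  quantity_name = "value", unit = "") {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v))
    stop("curve: t and v must have the same length", call. = FALSE)
  if (length(t) < 2L)
    stop("curve: at least 2 points are required", call. = FALSE)
  if (anyNA(t) || anyNA(v))
    stop("curve: NA samples are not allowed", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("curve: times must be strictly increasing", call. = FALSE)
  if (t[1L] < 0)
    stop("curve: times must be non-negative", call. = FALSE)
  structure(
    list(curve_id = as.character(curve_id),
         subject_uuid = as.character(subject_uuid),
         start = as.character(start),
         quantity_name = as.character(quantity_name),
         unit = as.character(unit),
         t = t, v = v),
    class = "curve")
}

#' @export
print.curve <- function(x, ...) {
  cat(sprintf("<curve %s> %s [%s], %d points on [%g, %g] s\n",
              x$curve_id, x$quantity_name, x$unit,
              length(x$t), x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' @export
length.curve <- function(x) length(x$t)

is_curve <- function(x) inherits(x, "curve")

#' Interpolate a curve at arbitrary times
#'
#' Values outside the sampled span are held constant at the first/last
#' sample.  With `interpolate = FALSE` the previous sample is carried
#' forward instead of interpolating linearly (for signals that are not
#' meaningfully interpolable).
#'
#' @param x A [curve].
#' @param at Numeric vector of query times (seconds).
#' @param interpolate Linear interpolation (`TRUE`, default) or
#'   previous-sample hold (`FALSE`).
#' @return Numeric vector of values at `at`.
#' @export
curve_values_at <- function(x, at, interpolate = TRUE) {
  method <- if (interpolate) "linear" else "constant"
  approx(x$t, x$v, xout = at, method = method, rule = 2, ties = "ordered")$y
}

#' Align a set of curves onto a common time frame
#'
#' All curves must measure the same quantity.  The common frame spans from
#' the earliest first sample to the latest last sample over the set.  A
#' curve that starts later than the frame start is padded by holding its
#' first value back to the frame start; one that ends earlier is padded by
#' holding its last value forward to the frame end.  Padding inserts at
#' most two explicit samples per curve and never produces values outside
#' the curve's own original range.  The value domain of the set is
#' computed over the original (unpadded) samples.
#'
#' Without this padding an equivalence class whose shortest member ends
#' early would only be (k-1)-anonymous for the remaining time; holding the
#' boundary values closes that alignment hazard.
#'
#' @param curves A list of [curve] objects (non-empty, same
#'   `quantity_name`).
#' @return An object of class `curve_set` with fields `curves` (named list
#'   by curve id), `common_frame` (length-2 numeric), `value_domain`
#'   (length-2 numeric), `quantity_name` and `unit`.
#' @export
align_dataset <- function(curves) {
  if (is_curve(curves)) curves <- list(curves)
  if (length(curves) == 0L)
    stop("align_dataset: empty curve list", call. = FALSE)
  stopifnot(all(vapply(curves, is_curve, logical(1L))))
  qn <- unique(vapply(curves, `[[`, character(1L), "quantity_name"))
  if (length(qn) != 1L)
    stop("align_dataset: mixed quantity names: ",
         paste(qn, collapse = ", "), call. = FALSE)
  ids <- vapply(curves, `[[`, character(1L), "curve_id")
  if (anyDuplicated(ids))
    stop("align_dataset: duplicated curve ids", call. = FALSE)

  t0 <- min(vapply(curves, function(c) c$t[1L], numeric(1L)))
  t1 <- max(vapply(curves, function(c) c$t[length(c$t)], numeric(1L)))
  vr <- range(unlist(lapply(curves, `[[`, "v")))

  padded <- lapply(curves, function(c) {
    if (c$t[1L] > t0) {
      c$t <- c(t0, c$t)
      c$v <- c(c$v[1L], c$v)
    }
    n <- length(c$t)
    if (c$t[n] < t1) {
      c$t <- c(c$t, t1)
      c$v <- c(c$v, c$v[n])
    }
    c
  })
  names(padded) <- ids

  structure(
    list(curves = padded,
         common_frame = c(t0, t1),
         value_domain = vr,
         quantity_name = qn,
         unit = curves[[1L]]$unit),
    class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> %d curve(s) of %s [%s], frame [%g, %g] s, values [%g, %g]\n",
              length(x$curves), x$quantity_name, x$unit,
              x$common_frame[1L], x$common_frame[2L],
              x$value_domain[1L], x$value_domain[2L]))
  invisible(x)
}

#' @export
length.curve_set <- function(x) length(x$curves)

is_curve_set <- function(x) inherits(x, "curve_set")

curve_ids <- function(cs) names(cs$curves)
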