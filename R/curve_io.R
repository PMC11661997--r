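#' Read a curve from a semicolon-delimited CSV file
#'
#' The file dialect has a three-line header followed by data rows:
#' \enumerate{
#'   \item the subject UUID,
#'   \item the recording start as an ISO-8601 datetime,
#'   \item the column labels with the unit in square brackets, fixed as
#'     `"Time [s];<quantity> [<unit>]"`.
#' }
#' Data rows are `<time in seconds>;<value>` with `"."` as decimal mark.
#' Only single-channel files (exactly two columns) are accepted.
#'
#' @param path Path to the file.
#' @param curve_id Curve id to assign; defaults to the file name without
#'   extension.
#' @return A [curve].
#' @export
read_curve_csv <- function(path, curve_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L)
    stop("read_curve_csv: '", path,
         "' needs a 3-line header and at least 2 data rows", call. = FALSE)
  uuid <- trimws(lines[1L])
  start <- trimws(lines[2L])
  if (uuid == "")
    stop("read_curve_csv: malformed header line 1 (empty subject UUID)",
         call. = FALSE)
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}", start))
    stop("read_curve_csv: malformed header line 2 (expected ISO datetime, got '",
         start, "')", call. = FALSE)
  cols <- strsplit(lines[3L], ";", fixed = TRUE)[[1L]]
  if (length(cols) != 2L)
    stop("read_curve_csv: malformed header line 3 ('", lines[3L],
         "'): expected exactly 2 semicolon-separated column labels",
         call. = FALSE)
  m <- regmatches(cols[2L], regexec("^\\s*(.*?)\\s*\\[(.*)\\]\\s*$", cols[2L]))[[1L]]
  if (length(m) != 3L)
    stop("read_curve_csv: malformed header line 3 ('", lines[3L],
         "'): value column must carry its unit in square brackets",
         call. = FALSE)
  quantity <- m[2L]
  unit <- m[3L]

  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ";", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("read_curve_csv: data row ", bad[1L] + 3L,
         " does not have exactly 2 fields", call. = FALSE)
  t <- as.numeric(vapply(parts, `[[`, character(1L), 1L))
  v <- as.numeric(vapply(parts, `[[`, character(1L), 2L))
  if (anyNA(t) || anyNA(v))
    stop("read_curve_csv: non-numeric data in '", path, "'", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("read_curve_csv: times are not strictly increasing in '", path, "'",
         call. = FALSE)
  if (is.null(curve_id))
    curve_id <- sub("\\.[^.]*$", "", basename(path))
  curve(t, v, curve_id = curve_id, subject_uuid = uuid, start = start,
        quantity_name = quantity, unit = unit)
}

#' Write a curve to the semicolon-delimited CSV dialect
#'
#' Inverse of [read_curve_csv()]: the output is re-readable and two writes
#' of the same curve are byte-identical (UTF-8, LF line endings, `"%.15g"`
#' number formatting).  An empty unit is still written as `"[]"` so that
#' the header shape is invariant.
#'
#' @param x A [curve].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve_csv <- function(x, path) {
  stopifnot(is_curve(x))
  header <- c(x$subject_uuid, x$start,
              sprintf("Time [s];%s [%s]", x$quantity_name, x$unit))
  rows <- sprintf("%s;%s", fmt_num(x$t), fmt_num(x$v))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Locale-independent shortest round-trip-safe formatting.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  # avoid "-0"
  out[out == "-0"] <- "0"
  out
}

#' Write all curves of a set to a directory
#'
#' One file per curve, named `<dataset>_<curve_id><suffix>.csv`; the
#' optional suffix mirrors the per-segment naming scheme of the native
#' data layout.
#'
#' @param cs A `curve_set`.
#' @param dir Output directory (created if missing).
#' @param dataset Dataset name used as the filename prefix.
#' @param suffix Optional segment suffix, e.g. `"_seg03"`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_curve_set <- function(cs, dir, dataset = cs$quantity_name, suffix = "") {
  stopifnot(is_curve_set(cs))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cs$curves, function(c) {
    p <- file.path(dir, sprintf("%s_%s%s.csv", dataset, c$curve_id, suffix))
    write_curve_csv(c, p)
    p
  }, character(1L))
  invisible(unname(paths))
}

#' Read a directory (or glob) of curve CSV files as an aligned set
#'
#' @param paths Either a directory containing `*.csv` files or an explicit
#'   character vector of file paths.
#' @return A `curve_set` (see [align_dataset()]).
#' @export
read_curve_set <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.csv$", full.names = TRUE))
  if (length(paths) == 0L)
    stop("read_curve_set: no CSV files found", call. = FALSE)
  align_dataset(lapply(paths, read_curve_csv))
}
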