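#' Exact t of finished equivalence classes
#'
#' For each class, the Earth Mover's Distance between the class's
#' cluster histogram (members attributed to the nearest cluster
#' reference) and the population histogram, with the Fréchet distance
#' between cluster references as the ground distance.  With
#' normalization the ground distances are divided by the maximum
#' pairwise reference distance, so t lies in `[0, 1]`.  The overall t is
#' the maximum over classes and is typically smaller than the
#' bucket-error bound of [estimate_t()].
#'
#' @param class_members List of character vectors: the non-dropped
#'   member ids per class.
#' @param d The population `distribution`.
#' @param dm Distance matrix covering members and cluster references.
#' @param normalizer Positive divisor for the ground distances (1 = raw).
#' @return List with `per_eqc` (numeric vector) and `t` (their max).
#' @export
exact_t <- function(class_members, d, dm, normalizer = 1) {
  stopifnot(inherits(d, "distribution"), normalizer > 0)
  refs <- distribution_refs(d)
  pop <- distribution_counts(d)
  ground <- dm[refs, refs, drop = FALSE] / normalizer
  per <- vapply(class_members, function(members) {
    emd(eqc_histogram(members, d, dm), pop, ground)
  }, numeric(1L))
  list(per_eqc = per, t = if (length(per)) max(per) else 0)
}

# Assemble the released per-class results of a finished builder state.
segment_result <- function(st, segment) {
  params <- st$params
  cs <- st$cs
  cids <- sort(st$marked)
  classes <- lapply(cids, function(cid) st$classes[[cid]])
  names(classes) <- cids

  sizes <- vapply(st$buckets, function(b) b$n, numeric(1L))
  errs <- vapply(st$buckets, function(b) b$err, numeric(1L))
  p <- sizes / sum(sizes)

  per_class <- lapply(classes, function(e) {
    members <- cs$curves[sort(e$member_ids)]
    hull <- build_hull(members, params$hull_resolution,
                       frame = segment$interval,
                       interpolate = params$interpolate)
    j <- e$taken > 0L
    list(id = e$id,
         member_ids = sort(e$member_ids),
         dropped_ids = sort(e$dropped_ids),
         n_members = length(e$member_ids),
         hull = hull,
         glm = glm_info_loss(hull, cs$value_domain, length(e$member_ids)),
         mre = median_relative_error(members, hull,
                                     interpolate = params$interpolate),
         t_bound = sum(errs[j] * p[j]) / st$normalizer)
  })

  et <- exact_t(lapply(per_class, `[[`, "member_ids"), st$dist,
                st$histo_dm, st$normalizer)
  for (i in seq_along(per_class)) per_class[[i]]$t_exact <- et$per_eqc[[i]]

  unassigned <- sort(unlist(lapply(st$unmarked, function(cid)
    c(st$classes[[cid]]$member_ids, st$classes[[cid]]$dropped_ids))))

  list(index = segment$index,
       interval = segment$interval,
       duration = diff(segment$interval),
       n_clusters = length(st$dist$clusters),
       usable_depth = st$tree$usable_depth,
       classes = per_class,
       dropped_ids = sort(unlist(lapply(per_class, `[[`, "dropped_ids"))),
       unanonymized_ids = unassigned,
       mean_glm = mean(vapply(per_class, `[[`, numeric(1L), "glm")),
       t_exact = et$t,
       t_bound = max(vapply(per_class, `[[`, numeric(1L), "t_bound")))
}

#' Anonymize a set of waveform curves
#'
#' Runs the full pipeline: optional time-axis splitting, then per
#' segment (independently — the semi-local decision) distance
#' computation, distribution clustering, Bucket and ECS tree
#' construction, the data distribution phase and the three
#' redistribution phases, hull construction and the privacy/utility
#' report.  The whole procedure is deterministic: identical inputs and
#' parameters yield identical results.
#'
#' @param cs Aligned `curve_set` (see [align_dataset()]).
#' @param params [anonymization_params()].
#' @param population Optional larger aligned `curve_set` for an external
#'   population distribution.
#' @return An `anonymization_result`: per-segment class lists with
#'   hulls, per-class GLM / MRE / exact and bound t, and the aggregate
#'   report of [evaluation_report()].
#' @export
anonymize <- function(cs, params, population = NULL) {
  stopifnot(is_curve_set(cs), inherits(params, "anon_params"))
  if (length(cs) < params$k)
    stop("database too small: ", length(cs), " curve(s) cannot satisfy k = ",
         params$k, call. = FALSE)
  segments <- split_dataset(cs, params$split)
  seg_results <- lapply(segments, function(seg) {
    pop <- if (!is.null(population))
      restrict_curve_set(population, seg$interval)
    st <- prepare_anonymization(seg$curves, params, population = pop)
    data_distribution_phase(st)
    unmarked_redistribution(st)
    marked_redistribution(st, "CONSTRAINED")
    marked_redistribution(st, "RELAXED")
    if (length(st$marked) == 0L)
      stop("no releasable equivalence class: segment ", seg$index,
           " cannot satisfy k = ", params$k, call. = FALSE)
    segment_result(st, seg)
  })
  evaluation_report(seg_results, params, cs)
}

#' Aggregate per-segment results into the run report
#'
#' The aggregate information loss weights each segment's mean GLM by its
#' temporal share of the dataset, so short segments do not dominate.  A
#' "cleaned" variant recomputes the aggregate after omitting segments
#' shorter than the hull resolution; it is suppressed when the omitted
#' segments would make up more than 25 % of the curves' duration.  The
#' dataset MRE is the median of the per-class MREs; dropped and
#' unanonymizable curves are enumerated.
#'
#' @param seg_results List of per-segment results (internal shape, as
#'   produced by [anonymize()]).
#' @param params The run's [anonymization_params()].
#' @param cs The aligned input `curve_set`.
#' @return An object of class `anonymization_result`.
#' @export
evaluation_report <- function(seg_results, params, cs) {
  durs <- vapply(seg_results, `[[`, numeric(1L), "duration")
  glms <- vapply(seg_results, `[[`, numeric(1L), "mean_glm")
  total <- sum(durs)
  agg <- sum(durs * glms) / total

  keep <- durs >= params$hull_resolution
  omitted_share <- sum(durs[!keep]) / total
  cleaned <- if (any(!keep) && omitted_share <= 0.25)
    sum(durs[keep] * glms[keep]) / sum(durs[keep])
  else NULL

  all_classes <- unlist(lapply(seg_results, `[[`, "classes"),
                        recursive = FALSE)
  mres <- vapply(all_classes, `[[`, numeric(1L), "mre")
  glms_class <- vapply(all_classes, `[[`, numeric(1L), "glm")

  structure(
    list(params = params,
         quantity_name = cs$quantity_name,
         unit = cs$unit,
         n_curves = length(cs),
         common_frame = cs$common_frame,
         value_domain = cs$value_domain,
         segments = seg_results,
         n_segments = length(seg_results),
         n_classes = length(all_classes),
         aggregate_glm = agg,
         aggregate_glm_cleaned = cleaned,
         cleaned_suppressed = any(!keep) && omitted_share > 0.25,
         omitted_share = omitted_share,
         median_glm = median(glms_class),
         median_mre = median(mres),
         t_exact = max(vapply(seg_results, `[[`, numeric(1L), "t_exact")),
         t_bound = max(vapply(seg_results, `[[`, numeric(1L), "t_bound")),
         dropped_ids = sort(unique(unlist(
           lapply(seg_results, `[[`, "dropped_ids")))),
         unanonymized_ids = sort(unique(unlist(
           lapply(seg_results, `[[`, "unanonymized_ids"))))),
    class = "anonymization_result")
}

#' @export
print.anonymization_result <- function(x, ...) {
  cat(sprintf("<anonymization_result> %s [%s]: %d curve(s), %d segment(s), %d class(es)\n",
              x$quantity_name, x$unit, x$n_curves, x$n_segments, x$n_classes))
  cat(sprintf("  aggregate GLM %.4f (median %.4f), median MRE %.4g\n",
              x$aggregate_glm, x$median_glm, x$median_mre))
  if (!is.null(x$aggregate_glm_cleaned))
    cat(sprintf("  cleaned aggregate GLM %.4f\n", x$aggregate_glm_cleaned))
  cat(sprintf("  t: exact %.4g <= bound %.4g\n", x$t_exact, x$t_bound))
  if (length(x$dropped_ids))
    cat("  dropped:", paste(x$dropped_ids, collapse = ", "), "\n")
  if (length(x$unanonymized_ids))
    cat("  unanonymized:", paste(x$unanonymized_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an anonymization report to JSON
#'
#' The JSON carries the resolved parameters, per-segment and per-class
#' quantities (members, dropped, GLM, MRE, exact and bound t) and the
#' aggregates; hull samples are stored alongside as CSVs by
#' [cmd_anonymize()], not inlined.  Serialization is deterministic, so
#' two identical runs produce byte-identical files.
#'
#' @param result An `anonymization_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(result, path) {
  stopifnot(inherits(result, "anonymization_result"))
  x <- unclass(result)
  x$params <- unclass(x$params)
  x$segments <- lapply(x$segments, function(s) {
    s$classes <- lapply(s$classes, function(cl) { cl$hull <- NULL; cl })
    s
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
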