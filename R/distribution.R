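#' Cluster a curve population into a surrogate distribution
#'
#' t-closeness needs a population distribution of the sensitive values.
#' For whole curves this is built by similarity clustering: scanning the
#' curves in ascending id order, each curve joins the first existing
#' cluster whose reference curve is within the distribution sensitivity
#' `s_d` (Fréchet distance), otherwise it founds a new cluster with
#' itself as the reference ("the first member added").  A cluster of `n`
#' members contributes `n` occurrences of its reference to the
#' distribution.  Singleton clusters are then eliminated by
#' [merge_singletons()], so every finalized cluster has at least 2
#' members (for populations of at least 2 curves).
#'
#' @param cs An aligned `curve_set`.
#' @param dm Distance matrix over `cs` from [pairwise_distances()].
#' @param s_d Distribution sensitivity: the join threshold, in the same
#'   units as the Fréchet distance.
#' @param source `"self"` when the distribution is built on the data to
#'   be anonymized, `"external"` for a separate/larger population.
#' @return An object of class `distribution`: a list of clusters (each
#'   with `reference_id` and `member_ids`), plus `s_d` and `source`.
#' @export
cluster_distribution <- function(cs, dm, s_d, source = "self") {
  stopifnot(is_curve_set(cs), s_d >= 0)
  ids <- sort(curve_ids(cs))
  if (length(ids) == 0L)
    stop("cluster_distribution: empty curve set", call. = FALSE)
  clusters <- list()
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (dm[id, clusters[[ci]]$reference_id] <= s_d) {
        clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, id)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <-
        list(reference_id = id, member_ids = id)
  }
  d <- structure(list(clusters = clusters, s_d = s_d, source = source),
                 class = "distribution")
  merge_singletons(d, dm)
}

#' Merge singleton clusters into their nearest cluster
#'
#' A cluster with a single element would force either merged equivalence
#' classes or a large t, and rarely represents the population; singletons
#' are therefore merged into the cluster whose reference curve is nearest
#' to them.  If only singletons exist they all collapse into the one with
#' the smallest id.  Merged members may end up farther than `s_d` from
#' their reference; the merge rule overrides the threshold.
#'
#' @param d A `distribution` (possibly with singletons).
#' @param dm Distance matrix covering all member ids.
#' @return A `distribution` without size-1 clusters.
#' @export
merge_singletons <- function(d, dm) {
  stopifnot(inherits(d, "distribution"))
  sizes <- vapply(d$clusters, function(cl) length(cl$member_ids), integer(1L))
  if (all(sizes > 1L) || length(d$clusters) == 1L) return(d)
  if (all(sizes == 1L)) {
    refs <- vapply(d$clusters, `[[`, character(1L), "reference_id")
    keep <- order(refs)[1L]
    d$clusters <- list(list(reference_id = refs[keep],
                            member_ids = sort(refs)))
    return(d)
  }
  repeat {
    sizes <- vapply(d$clusters, function(cl) length(cl$member_ids), integer(1L))
    s <- which(sizes == 1L)
    if (length(s) == 0L) break
    i <- s[1L]
    lone <- d$clusters[[i]]$member_ids
    others <- setdiff(seq_along(d$clusters), i)
    dist_to <- vapply(others, function(j)
      dm[lone, d$clusters[[j]]$reference_id], numeric(1L))
    j <- others[which.min(dist_to)]
    d$clusters[[j]]$member_ids <- sort(c(d$clusters[[j]]$member_ids, lone))
    d$clusters[[i]] <- NULL
  }
  d
}

#' @export
print.distribution <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$member_ids), integer(1L))
  cat(sprintf("<distribution> %d cluster(s) (%s source, s_d = %g), sizes: %s\n",
              length(x$clusters), x$source, x$s_d,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

distribution_counts <- function(d) {
  vapply(d$clusters, function(cl) length(cl$member_ids), integer(1L))
}

distribution_refs <- function(d) {
  vapply(d$clusters, `[[`, character(1L), "reference_id")
}

#' Histogram of an equivalence class over the distribution clusters
#'
#' Attributes each member to the cluster with the nearest reference curve
#' (ties broken toward the lower cluster index) and counts occurrences.
#' This is the class-side distribution whose EMD to the population
#' distribution is the class's exact t.
#'
#' @param member_ids Character vector of member curve ids (non-empty).
#' @param d A `distribution`.
#' @param dm Distance matrix covering the members and the cluster
#'   references.
#' @return Integer vector of counts, one per cluster of `d`.
#' @export
eqc_histogram <- function(member_ids, d, dm) {
  stopifnot(inherits(d, "distribution"))
  if (length(member_ids) == 0L)
    stop("eqc_histogram: empty member set", call. = FALSE)
  refs <- distribution_refs(d)
  counts <- integer(length(refs))
  for (id in member_ids) {
    j <- which.min(dm[id, refs])  # which.min takes the first (lowest) index
    counts[j] <- counts[j] + 1L
  }
  counts
}

#' Serialize / restore a distribution (JSON)
#'
#' Allows reusing an externally built population distribution across
#' runs.  Distances are always recomputed on the curves actually being
#' anonymized, so only the clustering itself is stored.
#'
#' @param d A `distribution`.
#' @param path JSON file path.
#' @return `write_distribution` invisibly returns `path`;
#'   `read_distribution` returns a `distribution`.
#' @export
write_distribution <- function(d, path) {
  stopifnot(inherits(d, "distribution"))
  jsonlite::write_json(
    list(s_d = d$s_d, source = d$source,
         clusters = lapply(d$clusters, function(cl)
           list(reference_id = cl$reference_id,
                member_ids = as.list(cl$member_ids)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(
    list(clusters = lapply(x$clusters, function(cl)
      list(reference_id = cl$reference_id,
           member_ids = unlist(cl$member_ids))),
      s_d = x$s_d, source = x$source),
    class = "distribution")
}
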