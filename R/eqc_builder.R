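# The multiphase distribution of curves from similarity buckets into
# equivalence classes.  State lives in an environment so the phases read
# like the imperative procedure they are.

#' Prepare a segment for anonymization
#'
#' Computes the distance matrix, the (self or external) population
#' distribution, the Bucket Tree at the chosen balancing factor, the
#' buckets at `depth_b`, the ECS tree with its target sizes, and the
#' initial empty equivalence classes with their per-bucket quotas.  When
#' a separate population is supplied, the distribution is clustered on
#' the population while the distances driving the bucketization are
#' recomputed on the curves actually being anonymized.
#'
#' @param cs Aligned `curve_set` to anonymize (the segment).
#' @param params [anonymization_params()].
#' @param population Optional larger aligned `curve_set` containing the
#'   curves of `cs`, used to build an external distribution.
#' @return A builder-state environment (internal structure; consumed by
#'   the phase functions and [anonymize()]).
#' @export
prepare_anonymization <- function(cs, params, population = NULL) {
  stopifnot(is_curve_set(cs), inherits(params, "anon_params"))
  if (length(cs) < params$k)
    stop("database too small: ", length(cs), " curve(s) cannot satisfy k = ",
         params$k, call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$cs <- cs
  st$params <- params
  st$dm <- pairwise_distances(cs, params$time_scale, params$value_scale)

  if (is.null(population)) {
    st$dist <- cluster_distribution(cs, st$dm, params$s_d, source = "self")
    st$histo_dm <- st$dm
  } else {
    stopifnot(is_curve_set(population))
    if (!all(curve_ids(cs) %in% curve_ids(population)))
      stop("prepare_anonymization: population must contain all curves ",
           "being anonymized", call. = FALSE)
    pop_dm <- pairwise_distances(population, params$time_scale,
                                 params$value_scale)
    st$dist <- cluster_distribution(population, pop_dm, params$s_d,
                                    source = "external")
    st$histo_dm <- pop_dm
  }
  refs <- distribution_refs(st$dist)
  ref_d <- st$histo_dm[refs, refs, drop = FALSE]
  st$normalizer <-
    if (params$normalize_t && max(ref_d) > 0) max(ref_d) else 1

  st$tree <- build_bucket_tree(cs, st$dm, params$f)
  st$buckets <- select_buckets(st$tree, params$depth_b)
  st$ecs <- build_ecs_tree(st$buckets, params$k)

  st$grid <- hull_grid(cs$common_frame, params$hull_resolution)
  st$V <- vapply(cs$curves, curve_values_at, numeric(length(st$grid)),
                 at = st$grid, interpolate = params$interpolate)
  st$V <- matrix(st$V, nrow = length(st$grid),
                 dimnames = list(NULL, curve_ids(cs)))
  st$W <- cs$value_domain[2L] - cs$value_domain[1L]

  st$remaining <- lapply(st$buckets, function(b) sort(b$member_ids))
  st$classes <- list()
  st$next_id <- 1L
  st$unmarked <- character(0)  # FIFO of class ids
  st$marked <- character(0)
  for (leaf in ecs_leaves(st$ecs)) enqueue_class(st, leaf)
  st
}

enqueue_class <- function(st, ecs_node, members = character(0),
                          source_bucket = integer(0),
                          dropped = character(0)) {
  id <- sprintf("eqc%03d", st$next_id)
  st$next_id <- st$next_id + 1L
  nb <- length(st$buckets)
  e <- list(id = id,
            quota = as.integer(ecs_node$vec),
            target = ecs_node$target,
            taken = integer(nb),
            member_ids = character(0),
            source_bucket = integer(0),   # named by member id
            dropped_ids = character(0),
            marked = FALSE,
            ecs_node = ecs_node,
            lower = NULL, upper = NULL)
  st$classes[[id]] <- e
  st$unmarked <- c(st$unmarked, id)
  for (i in seq_along(members))
    add_member(st, id, members[i], source_bucket[i])
  for (m in dropped) add_dropped(st, id, m)
  id
}

# --- class bookkeeping -------------------------------------------------

class_nd <- function(e) length(e$member_ids)

class_glm <- function(st, cid) {
  e <- st$classes[[cid]]
  if (class_nd(e) <= 1L) return(0)
  if (st$W <= 0) return(0)
  mean((e$upper - e$lower) / st$W)
}

# information loss of the class after hypothetically adding value row vc
post_insertion_glm <- function(st, e, vc) {
  if (class_nd(e) == 0L) return(0)  # single member spans nothing
  if (st$W <= 0) return(0)
  if (is.null(e$lower)) return(0)
  mean((pmax(e$upper, vc) - pmin(e$lower, vc)) / st$W)
}

add_member <- function(st, cid, m, bucket_j) {
  e <- st$classes[[cid]]
  vc <- st$V[, m]
  if (is.null(e$lower)) {
    e$lower <- vc; e$upper <- vc
  } else {
    e$lower <- pmin(e$lower, vc); e$upper <- pmax(e$upper, vc)
  }
  e$member_ids <- c(e$member_ids, m)
  e$source_bucket[m] <- bucket_j
  e$taken[bucket_j] <- e$taken[bucket_j] + 1L
  st$classes[[cid]] <- e
}

add_dropped <- function(st, cid, m) {
  e <- st$classes[[cid]]
  e$dropped_ids <- c(e$dropped_ids, m)
  st$classes[[cid]] <- e
}

remove_member <- function(st, cid, m) {
  e <- st$classes[[cid]]
  e$member_ids <- setdiff(e$member_ids, m)
  j <- e$source_bucket[[m]]
  e$source_bucket <- e$source_bucket[names(e$source_bucket) != m]
  e$taken[j] <- e$taken[j] - 1L
  if (length(e$member_ids) == 0L) {
    e$lower <- NULL; e$upper <- NULL
  } else {
    M <- st$V[, e$member_ids, drop = FALSE]
    e$lower <- apply(M, 1L, min); e$upper <- apply(M, 1L, max)
  }
  st$classes[[cid]] <- e
  j
}

# A class fulfills its constraints when it holds at least k non-dropped
# members and its per-bucket counts either meet the quota or stay within
# +/- 1 of the quota proportions scaled to its actual size.
class_fulfilled <- function(st, cid) {
  e <- st$classes[[cid]]
  nd <- class_nd(e)
  if (nd < st$params$k) return(FALSE)
  if (all(e$taken >= e$quota)) return(TRUE)
  ideal <- nd * e$quota / e$target
  all(abs(e$taken - ideal) <= 1 + 1e-9)
}

mark_class <- function(st, cid) {
  e <- st$classes[[cid]]
  e$marked <- TRUE
  st$classes[[cid]] <- e
  st$unmarked <- setdiff(st$unmarked, cid)
  st$marked <- c(st$marked, cid)
}

total_remaining <- function(st) sum(lengths(st$remaining))

# best remaining candidate of bucket j for class cid: the curve whose
# insertion increases the class hull loss least, ties by ascending id
best_candidate <- function(st, cid, j) {
  cand <- st$remaining[[j]]
  e <- st$classes[[cid]]
  losses <- vapply(cand, function(m) post_insertion_glm(st, e, st$V[, m]),
                   numeric(1L))
  i <- order(losses, cand)[1L]
  list(id = cand[i], loss = losses[i])
}

# --- phase 1: data distribution ---------------------------------------

#' Data distribution phase
#'
#' Dequeues one equivalence class at a time from the unmarked queue and
#' fills it greedily from the buckets, proportionally to its quota (the
#' proportionally most under-served bucket is served next).  Within a
#' bucket the pick is the remaining curve that raises the class's hull
#' information loss least.  A pick whose post-insertion loss exceeds the
#' drop threshold `d` is dropped from the dataset (it stays attached to
#' the class but contributes to no further computation); a loss in
#' `(s_eqc, d]` splits the class into its ECS children instead.  A class
#' that meets its constraints is marked; the phase ends when all classes
#' are marked or the buckets are empty.
#'
#' @param st Builder state from [prepare_anonymization()].
#' @return The state, invisibly (modified in place).
#' @export
data_distribution_phase <- function(st) {
  queue <- st$unmarked
  leftovers <- character(0)
  while (length(queue) > 0L) {
    cid <- queue[1L]; queue <- queue[-1L]
    res <- fill_class(st, cid)
    if (res == "marked") {
      mark_class(st, cid)
    } else if (res == "split") {
      kids <- split_class(st, cid)
      st$unmarked <- setdiff(st$unmarked, cid)
      queue <- c(queue, kids)
    } else {
      leftovers <- c(leftovers, cid)
    }
  }
  st$unmarked <- leftovers
  invisible(st)
}

# fill a single class; returns "marked", "split" or "stuck".  Buckets
# whose best pick would breach the maximum-cost constraint are blocked
# for this class; the drop threshold d overrides the block (a curve
# that ruins every class is removed from the dataset, not deferred).
fill_class <- function(st, cid) {
  blocked <- logical(length(st$buckets))
  repeat {
    e <- st$classes[[cid]]
    if (all(e$taken >= e$quota)) return("marked")
    avail <- which(e$taken < e$quota & lengths(st$remaining) > 0L & !blocked)
    if (length(avail) == 0L)
      return(if (class_fulfilled(st, cid)) "marked" else "stuck")
    # serve the proportionally most under-served bucket next
    behind <- e$taken[avail] / e$quota[avail]
    j <- avail[order(behind, -e$quota[avail], avail)[1L]]
    pick <- best_candidate(st, cid, j)
    if (pick$loss > st$params$d) {
      st$remaining[[j]] <- setdiff(st$remaining[[j]], pick$id)
      add_dropped(st, cid, pick$id)
    } else if (pick$loss > st$params$s_eqc &&
               !is.null(st$classes[[cid]]$ecs_node$children)) {
      return("split")
    } else if (pick$loss > st$params$max_cost) {
      blocked[j] <- TRUE
    } else {
      st$remaining[[j]] <- setdiff(st$remaining[[j]], pick$id)
      add_member(st, cid, pick$id, j)
    }
  }
}

# split a class into its two ECS children; current members are
# reassigned greedily (in id order) to the child whose loss grows least
split_class <- function(st, cid) {
  e <- st$classes[[cid]]
  kids <- vapply(e$ecs_node$children, function(child)
    enqueue_class(st, child), character(1L))
  for (m in sort(e$member_ids)) {
    j <- e$source_bucket[[m]]
    losses <- vapply(kids, function(kid)
      post_insertion_glm(st, st$classes[[kid]], st$V[, m]), numeric(1L))
    add_member(st, kids[order(losses, kids)[1L]], m, j)
  }
  for (m in e$dropped_ids) add_dropped(st, kids[1L], m)
  st$classes[[cid]] <- NULL
  kids
}

# --- phase 2: unmarked redistribution ---------------------------------

#' Unmarked redistribution phase
#'
#' Repeatedly dissolves the unmarked class with the fewest members and
#' offers its members to the other unmarked classes (greedy minimum-loss
#' insertion under the maximum-cost constraint).  Stops when all classes
#' are marked or a whole iteration moved no data.
#'
#' @param st Builder state after [data_distribution_phase()].
#' @return The state, invisibly.
#' @export
unmarked_redistribution <- function(st) {
  repeat {
    if (length(st$unmarked) <= 1L) break
    moved_any <- FALSE
    sizes <- vapply(st$unmarked, function(cid)
      class_nd(st$classes[[cid]]), integer(1L))
    donors <- st$unmarked[order(sizes, st$unmarked)]
    for (donor in donors) {
      if (!donor %in% st$unmarked) next
      if (length(st$unmarked) <= 1L) break
      moved_any <- redistribute_class(
        st, donor, get_recipients = function() setdiff(st$unmarked, donor),
        constrained = TRUE) || moved_any
    }
    if (!moved_any || length(st$unmarked) == 0L) break
  }
  invisible(st)
}

# Move the members of `donor` into `recipients` by greedy min-loss
# insertion.  Under the max-cost constraint members that fit nowhere
# stay with the donor.  Relaxed mode always finds a home but still
# drops members whose best loss exceeds d.  Returns TRUE if any data
# moved; dissolved donors are deleted and their dropped members are
# reattached to the least-loss recipient.
redistribute_class <- function(st, donor, get_recipients, constrained,
                               relaxed = FALSE) {
  moved <- FALSE
  for (m in sort(st$classes[[donor]]$member_ids)) {
    recipients <- setdiff(get_recipients(), donor)
    if (length(recipients) == 0L) break
    losses <- vapply(recipients, function(cid)
      post_insertion_glm(st, st$classes[[cid]], st$V[, m]), numeric(1L))
    best <- order(losses, recipients)[1L]
    if (constrained && losses[best] > st$params$max_cost) next
    j <- remove_member(st, donor, m)
    if (relaxed && losses[best] > st$params$d) {
      add_dropped(st, recipients[best], m)
    } else {
      add_member(st, recipients[best], m, j)
    }
    moved <- TRUE
    if (!st$classes[[recipients[best]]]$marked &&
        class_fulfilled(st, recipients[best]))
      mark_class(st, recipients[best])
  }
  e <- st$classes[[donor]]
  if (class_nd(e) == 0L) {
    # dissolve: dropped members follow to the best available class
    for (m in e$dropped_ids) {
      home <- setdiff(c(st$marked, st$unmarked), donor)
      if (length(home) == 0L) break
      losses <- vapply(home, function(cid)
        post_insertion_glm(st, st$classes[[cid]], st$V[, m]), numeric(1L))
      add_dropped(st, home[order(losses, home)[1L]], m)
    }
    st$unmarked <- setdiff(st$unmarked, donor)
    st$classes[[donor]] <- NULL
  }
  moved
}

# --- phases 3 & 4: marked redistribution ------------------------------

#' Marked redistribution phases (constrained / relaxed)
#'
#' Dissolves the remaining unmarked classes into the marked ones by
#' greedy minimum-loss insertion.  `CONSTRAINED` keeps the maximum-cost
#' constraint, so some members may find no home and their class stays
#' unmarked; `RELAXED` waives it (classes are no longer split) but the
#' drop threshold `d` remains in place, so the unmarked queue always
#' empties.  If no marked class exists the remaining curves are not
#' anonymizable and are reported as such by [anonymize()].
#'
#' @param st Builder state.
#' @param constrain `"CONSTRAINED"` or `"RELAXED"`.
#' @return The state, invisibly.
#' @export
marked_redistribution <- function(st, constrain = c("CONSTRAINED", "RELAXED")) {
  constrain <- match.arg(constrain)
  relaxed <- constrain == "RELAXED"
  if (length(st$marked) == 0L) return(invisible(st))
  repeat {
    if (length(st$unmarked) == 0L) break
    moved_any <- FALSE
    sizes <- vapply(st$unmarked, function(cid)
      class_nd(st$classes[[cid]]), integer(1L))
    for (donor in st$unmarked[order(sizes, st$unmarked)]) {
      if (!donor %in% st$unmarked) next
      moved_any <- redistribute_class(st, donor,
                                      get_recipients = function() st$marked,
                                      constrained = !relaxed,
                                      relaxed = relaxed) || moved_any
    }
    if (!moved_any) break
  }
  if (relaxed) flush_buckets(st)
  invisible(st)
}

# After the relaxed phase any curve still sitting in a bucket (stranded
# by early proportional marking) is placed into the least-loss marked
# class, or dropped there if the loss exceeds d.
flush_buckets <- function(st) {
  if (length(st$marked) == 0L) return(invisible(st))
  for (j in seq_along(st$remaining)) {
    for (m in st$remaining[[j]]) {
      losses <- vapply(st$marked, function(cid)
        post_insertion_glm(st, st$classes[[cid]], st$V[, m]), numeric(1L))
      best <- order(losses, st$marked)[1L]
      if (losses[best] > st$params$d) {
        add_dropped(st, st$marked[best], m)
      } else {
        add_member(st, st$marked[best], m, j)
      }
    }
    st$remaining[[j]] <- character(0)
  }
  invisible(st)
}
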