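#' Build a Bucket Tree over a curve set
#'
#' A Bucket Tree is a fully balanced binary tree of similarity buckets:
#' the root holds all curves and every node of size >= 2 is split into
#' two children.  A level of the tree partitions the dataset (child
#' sizes sum to the parent's), so selecting a depth yields a bucketization
#' with an implied maximum cost instead of an explicitly chosen one.
#'
#' Each split seeds the children with the node's two mutually farthest
#' members, assigns every other member to the nearer seed, and then
#' rebalances so that each child keeps at least `ceil(f * n_parent)`
#' members, moving the members whose assignment margin (distance to own
#' seed minus distance to the other seed) is smallest.  The child's
#' reference curve is its seed; ties are broken by ascending curve id.
#' Recursion stops at single-member nodes.  The usable depth is the
#' minimum leaf depth: beyond it some branch has died and the level no
#' longer partitions the dataset.
#'
#' @param cs An aligned `curve_set`.
#' @param dm Distance matrix over `cs`.
#' @param f Balancing factor in `(0, 0.5]`; the minimum child fraction of
#'   a split.  Values above 0.5 would make the constraint unfulfillable.
#' @return An object of class `bucket_tree` with fields `root`, `f` and
#'   `usable_depth`.
#' @export
build_bucket_tree <- function(cs, dm, f = 0.4) {
  stopifnot(is_curve_set(cs))
  if (!(f > 0 && f <= 0.5))
    stop("build_bucket_tree: f must be in (0, 0.5]", call. = FALSE)
  ids <- sort(curve_ids(cs))
  if (length(ids) == 0L)
    stop("build_bucket_tree: empty curve set", call. = FALSE)
  root <- grow_bucket_node(ids, reference = ids[1L], dm, f)
  structure(list(root = root, f = f,
                 usable_depth = min_leaf_depth(root)),
            class = "bucket_tree")
}

grow_bucket_node <- function(member_ids, reference, dm, f) {
  node <- list(member_ids = member_ids,
               reference_id = reference,
               n = length(member_ids),
               err = bucket_err(member_ids, reference, dm),
               children = NULL)
  if (node$n >= 2L) {
    halves <- split_bucket_members(member_ids, dm, f)
    node$children <- list(
      grow_bucket_node(halves[[1L]]$members, halves[[1L]]$seed, dm, f),
      grow_bucket_node(halves[[2L]]$members, halves[[2L]]$seed, dm, f))
  }
  node
}

bucket_err <- function(member_ids, reference, dm) {
  if (length(member_ids) <= 1L) return(0)
  max(dm[member_ids, reference])
}

# Farthest-pair seeding + nearest-seed assignment + margin rebalancing.
split_bucket_members <- function(ids, dm, f) {
  ids <- sort(ids)
  n <- length(ids)
  D <- dm[ids, ids, drop = FALSE]
  # farthest pair, ties by ascending (row, col) id order
  mx <- max(D)
  hit <- which(D == mx & upper.tri(D), arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  s1 <- ids[hit[1L, 1L]]; s2 <- ids[hit[1L, 2L]]
  rest <- setdiff(ids, c(s1, s2))
  d1 <- dm[rest, s1]; d2 <- dm[rest, s2]
  to1 <- d1 <= d2  # tie goes with the lower-id seed (s1 < s2)
  g1 <- c(s1, rest[to1]); g2 <- c(s2, rest[!to1])

  # feasibility cap: both children must exist, so the ceil'd minimum can
  # never exceed floor(n/2)
  min_size <- min(ceiling(f * n), floor(n / 2))
  move <- function(from, to, d_from, d_to) {
    # move lowest-margin members of `from` (excluding its seed) to `to`
    need <- min_size - length(to)
    cand <- setdiff(from, from[1L])
    margin <- dm[cand, d_to] - dm[cand, d_from]
    ord <- order(margin, cand)
    moved <- cand[ord][seq_len(need)]
    list(from = setdiff(from, moved), to = c(to, moved))
  }
  if (length(g1) < min_size && length(g2) > min_size) {
    r <- move(g2, g1, s2, s1); g2 <- r$from; g1 <- r$to
  } else if (length(g2) < min_size && length(g1) > min_size) {
    r <- move(g1, g2, s1, s2); g1 <- r$from; g2 <- r$to
  }
  list(list(seed = s1, members = sort(g1)),
       list(seed = s2, members = sort(g2)))
}

min_leaf_depth <- function(node, depth = 0L) {
  if (is.null(node$children)) return(depth)
  min(min_leaf_depth(node$children[[1L]], depth + 1L),
      min_leaf_depth(node$children[[2L]], depth + 1L))
}

#' Maximum member-to-reference distance of a bucket
#'
#' The error of a bucket is the distance from its reference curve to the
#' farthest member; it over-approximates the cost of treating every value
#' taken from the bucket as the reference.  Singleton buckets have error
#' 0.
#'
#' @param node A bucket node (element of [select_buckets()] output).
#' @param dm Distance matrix covering the members.
#' @return A non-negative number.
#' @export
bucket_error <- function(node, dm) {
  bucket_err(node$member_ids, node$reference_id, dm)
}

#' Select the buckets at a depth of a Bucket Tree
#'
#' The `2^depth_b` nodes at the chosen depth together partition the
#' dataset; deeper selections give a finer bucketization with smaller
#' bucket errors.
#'
#' @param tree A `bucket_tree`.
#' @param depth_b Depth to select, between 0 and the tree's
#'   `usable_depth`.
#' @return List of bucket nodes.
#' @export
select_buckets <- function(tree, depth_b) {
  stopifnot(inherits(tree, "bucket_tree"))
  if (depth_b < 0 || depth_b > tree$usable_depth)
    stop("select_buckets: depth ", depth_b, " not available; usable depth is ",
         tree$usable_depth, call. = FALSE)
  nodes_at_depth(tree$root, depth_b)
}

nodes_at_depth <- function(node, depth) {
  if (depth == 0L) return(list(node))
  c(nodes_at_depth(node$children[[1L]], depth - 1L),
    nodes_at_depth(node$children[[2L]], depth - 1L))
}

#' @export
print.bucket_tree <- function(x, ...) {
  cat(sprintf("<bucket_tree> %d curve(s), f = %g, usable depth %d\n",
              x$root$n, x$f, x$usable_depth))
  invisible(x)
}

#' Export a tree as a plain list (JSON-ready)
#'
#' @param tree A `bucket_tree` or `ecs_tree`.
#' @return A nested list of node sizes, references and errors.
#' @export
tree_as_list <- function(tree) {
  if (inherits(tree, "bucket_tree")) return(bucket_node_list(tree$root))
  if (inherits(tree, "ecs_tree")) return(ecs_node_list(tree$root))
  stop("tree_as_list: not a tree", call. = FALSE)
}

bucket_node_list <- function(node) {
  out <- list(n = node$n, reference_id = node$reference_id, err = node$err)
  if (!is.null(node$children))
    out$children <- lapply(node$children, bucket_node_list)
  out
}

ecs_node_list <- function(node) {
  out <- list(virtual_buckets = node$vec, target_size = node$target)
  if (!is.null(node$children))
    out$children <- lapply(node$children, ecs_node_list)
  out
}
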