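#' Build the Equivalence Class Size Tree
#'
#' Each node is a vector of virtual buckets: one integer per selected
#' bucket, giving how many curves the equivalence class should take from
#' that bucket; the node's target size is the vector sum.  The root holds
#' the full bucket sizes.  Every split halves the target size (+/- 1) and
#' divides each component with the largest-remainder method, so the
#' children preserve the population proportions and sum componentwise to
#' their parent.  Splitting stops where a component has reached 1 (it
#' cannot be split further) or where a child's target size would drop
#' below `k`; the leaves are the initial equivalence classes.
#'
#' @param buckets List of bucket nodes from [select_buckets()].
#' @param k Minimal equivalence class size (>= 1).
#' @return An object of class `ecs_tree` (fields `root`, `k`,
#'   `bucket_sizes`).
#' @export
build_ecs_tree <- function(buckets, k) {
  stopifnot(k >= 1)
  sizes <- vapply(buckets, function(b) b$n, integer(1L))
  if (sum(sizes) < k)
    stop("build_ecs_tree: database too small: ", sum(sizes),
         " curve(s) cannot fill an equivalence class of size k = ", k,
         call. = FALSE)
  structure(list(root = grow_ecs_node(sizes, k),
                 k = k, bucket_sizes = sizes),
            class = "ecs_tree")
}

grow_ecs_node <- function(vec, k) {
  node <- list(vec = vec, target = sum(vec), children = NULL)
  if (any(vec == 1L) || floor(sum(vec) / 2) < k) return(node)
  t1 <- floor(sum(vec) / 2)
  v1 <- largest_remainder(vec, t1)
  v2 <- vec - v1
  node$children <- list(grow_ecs_node(v1, k), grow_ecs_node(v2, k))
  node
}

# Apportion `target` units over `vec` proportionally (largest-remainder,
# ties toward the lower index), never exceeding vec componentwise.
largest_remainder <- function(vec, target) {
  ideal <- vec * target / sum(vec)
  base <- floor(ideal)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(-(ideal - base), seq_along(vec))
    ord <- ord[base[ord] < vec[ord]]  # cannot take more than the bucket has
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Leaves of an ECS tree (the initial equivalence class quotas)
#'
#' @param tree An `ecs_tree`.
#' @return List of ECS nodes in left-to-right order.
#' @export
ecs_leaves <- function(tree) {
  stopifnot(inherits(tree, "ecs_tree"))
  collect_leaves(tree$root)
}

collect_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  c(collect_leaves(node$children[[1L]]), collect_leaves(node$children[[2L]]))
}

#' @export
print.ecs_tree <- function(x, ...) {
  cat(sprintf("<ecs_tree> %d bucket(s), total %d, k = %d, %d leaf class(es)\n",
              length(x$bucket_sizes), sum(x$bucket_sizes), x$k,
              length(ecs_leaves(x))))
  invisible(x)
}

#' Over-approximate the achievable t from bucket errors
#'
#' Treating every curve taken from a bucket as that bucket's reference
#' introduces at most the bucket error `err_j` into the class
#' distribution.  With the proportionality coefficient
#' `p_j = n_j / sum(n)`, the class bound is `t_i = sum_j err_j * p_j`
#' over the buckets the class draws from, and the releasable target t is
#' the maximum over classes.  The exact t computed after the run (see
#' [exact_t()]) will typically be smaller.
#'
#' @param leaves List of ECS nodes (e.g. [ecs_leaves()] output).
#' @param buckets The selected bucket nodes, in the same order as the
#'   leaves' vector components.
#' @param normalizer Positive scale divisor applied to the bucket errors
#'   (use the maximum pairwise reference distance to express t on the
#'   same normalized scale as [exact_t()]; 1 for raw distances).
#' @return A list with `per_eqc` (numeric vector of class bounds), `t`
#'   (their maximum) and `p` (the proportionality coefficients).
#' @export
estimate_t <- function(leaves, buckets, normalizer = 1) {
  stopifnot(normalizer > 0)
  sizes <- vapply(buckets, function(b) b$n, numeric(1L))
  errs <- vapply(buckets, function(b) b$err, numeric(1L))
  p <- sizes / sum(sizes)
  per <- vapply(leaves, function(leaf) {
    j <- leaf$vec > 0
    sum(errs[j] * p[j]) / normalizer
  }, numeric(1L))
  list(per_eqc = per, t = if (length(per)) max(per) else 0, p = p)
}
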