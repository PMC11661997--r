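#' Anonymization parameters
#'
#' Bundles every knob of the anonymization pipeline.  Defaults follow the
#' package's evaluation defaults: `k = 3` (the smallest class size that
#' hides individual bounds), balancing factor `f = 0.4`, Bucket Tree
#' depth `depth_b = 1`, and `d = s_eqc = 1.0` so that neither dropping
#' nor class splitting occurs unless the user opts in.
#'
#' @param s_d Distribution sensitivity: similarity-cluster join threshold
#'   in Fréchet-distance units (data specific; no default).
#' @param k Minimal equivalence class size, `>= 1`.
#' @param f Bucket Tree balancing factor in `(0, 0.5]`.
#' @param depth_b Bucket Tree depth whose nodes become the buckets.
#' @param s_eqc Equivalence class sensitivity: information-loss threshold
#'   above which a class is split, in `[0, 1]`.
#' @param d Drop threshold: information-loss upper bound above which a
#'   curve is dropped rather than used, in `[s_eqc, 1]`.
#' @param max_cost Maximum-cost constraint for (re)insertions: a class's
#'   post-insertion information loss may not exceed it while the
#'   constraint is active.  Defaults to `s_eqc`, which ties the three
#'   loss knobs together (`max_cost <= d`) and is inactive at the
#'   default `s_eqc = 1`.
#' @param hull_resolution Hull grid step in seconds.
#' @param split Split configuration list, see [split_dataset()].
#' @param interpolate Are the curves meaningfully interpolable
#'   (linear interpolation) or held between samples?
#' @param normalize_t Normalize EMD ground distances by the maximum
#'   pairwise cluster-reference distance so that t lies in `[0, 1]`.
#' @param time_scale,value_scale Fréchet ground-distance axis weights,
#'   see [frechet_distance()].
#' @param greedy Take data greedily from the buckets (the only
#'   implemented strategy; kept as an explicit, checked flag).
#' @return A list of class `anon_params`.
#' @export
anonymization_params <- function(s_d,
                                 k = 3L,
                                 f = 0.4,
                                 depth_b = 1L,
                                 s_eqc = 1.0,
                                 d = 1.0,
                                 max_cost = s_eqc,
                                 hull_resolution = 0.05,
                                 split = list(mode = "none"),
                                 interpolate = TRUE,
                                 normalize_t = TRUE,
                                 time_scale = 0,
                                 value_scale = 1,
                                 greedy = TRUE) {
  if (missing(s_d) || !is.numeric(s_d) || s_d < 0)
    stop("anonymization_params: s_d (distribution sensitivity) is required ",
         "and must be >= 0", call. = FALSE)
  stopifnot(k >= 1, f > 0, f <= 0.5, depth_b >= 0,
            s_eqc >= 0, s_eqc <= d, d <= 1,
            max_cost >= 0, hull_resolution > 0, isTRUE(greedy))
  structure(list(s_d = s_d, k = as.integer(k), f = f,
                 depth_b = as.integer(depth_b),
                 s_eqc = s_eqc, d = d, max_cost = max_cost,
                 hull_resolution = hull_resolution, split = split,
                 interpolate = isTRUE(interpolate),
                 normalize_t = isTRUE(normalize_t),
                 time_scale = time_scale, value_scale = value_scale,
                 greedy = TRUE),
            class = "anon_params")
}

#' @export
print.anon_params <- function(x, ...) {
  cat("<anon_params>\n")
  cat(sprintf("  k = %d, s_d = %g, f = %g, depth_b = %d\n",
              x$k, x$s_d, x$f, x$depth_b))
  cat(sprintf("  s_eqc = %g, d = %g, max_cost = %g\n",
              x$s_eqc, x$d, x$max_cost))
  cat(sprintf("  hull_resolution = %g s, split mode = %s\n",
              x$hull_resolution, x$split$mode %||% "none"))
  invisible(x)
}
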