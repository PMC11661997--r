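# Small construction helpers shared across the suite.

constant_curve <- function(value, id, times = 0:10, quantity = "AWF",
                           unit = "L/min") {
  curve(times, rep(value, length(times)), curve_id = id,
        quantity_name = quantity, unit = unit)
}

constant_set <- function(values, times = 0:10) {
  align_dataset(lapply(seq_along(values), function(i)
    constant_curve(values[i], sprintf("c%02d", i), times)))
}

random_curve <- function(id, n = 25, times = NULL) {
  if (is.null(times)) times <- seq(0, 10, length.out = n)
  curve(times, rnorm(length(times)), curve_id = id)
}

random_set <- function(n_curves, n_points = 25) {
  align_dataset(lapply(seq_len(n_curves), function(i)
    random_curve(sprintf("c%02d", i), n = n_points)))
}

# a moderately noisy two-group population, the workhorse of the
# clustering and tree tests
two_group_set <- function(n_per = 6, gap = 10, spread = 0.5, seed = 1) {
  set.seed(seed)
  curves <- lapply(seq_len(2 * n_per), function(i) {
    base <- if (i <= n_per) 0 else gap
    constant_curve(base + runif(1, -spread, spread), sprintf("c%02d", i))
  })
  align_dataset(curves)
}
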