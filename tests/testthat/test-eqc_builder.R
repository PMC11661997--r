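default_params <- function(...) {
  args <- list(...)
  base <- list(s_d = 5, k = 3L, hull_resolution = 0.5)
  do.call(anonymization_params, utils::modifyList(base, args))
}

test_that("identical curves collapse into one perfect class", {
  cs <- constant_set(rep(2, 3))
  # identical members give a width-zero value domain; the degenerate-
  # domain warning is part of the contract, the loss is defined as 0
  res <- suppressWarnings(anonymize(cs, default_params()))
  expect_equal(res$n_classes, 1L)
  cls <- res$segments[[1]]$classes[[1]]
  expect_setequal(cls$member_ids, names(cs$curves))
  expect_equal(cls$glm, 0)
  expect_equal(cls$mre, 0)
  expect_equal(res$t_exact, 0)
  expect_length(res$dropped_ids, 0L)
})

test_that("too small a database is refused", {
  cs <- constant_set(c(1, 2))
  expect_error(anonymize(cs, default_params(k = 3)), "database too small")
  expect_error(prepare_anonymization(cs, default_params(k = 3)),
               "database too small")
})

test_that("preparation is deterministic and wires quotas to bucket sizes", {
  cs <- generate_breath_curves(n_curves = 8, n_clusters = 2,
                               respiratory_rate = c(20, 60),
                               amplitude_jitter = 0.4, noise_sd = 0.2,
                               seed = 5)
  p <- default_params()
  st1 <- prepare_anonymization(cs, p)
  st2 <- prepare_anonymization(cs, p)
  expect_identical(st1$dm, st2$dm)
  expect_identical(st1$classes, st2$classes)
  expect_identical(lapply(st1$buckets, `[[`, "member_ids"),
                   lapply(st2$buckets, `[[`, "member_ids"))
  # quota vectors sum to the bucket sizes
  quotas <- Reduce(`+`, lapply(st1$classes, `[[`, "quota"))
  expect_equal(quotas, vapply(st1$buckets, `[[`, integer(1), "n"))
})

test_that("default thresholds cause neither dropping nor splitting", {
  cs <- emulate_paper_shapes("AWF", seed = 9)
  p <- default_params(s_d = 6, hull_resolution = 0.1)
  expect_equal(p$d, 1.0)
  expect_equal(p$s_eqc, 1.0)
  st <- prepare_anonymization(cs, p)
  n_initial <- length(st$classes)
  res <- anonymize(cs, p)
  expect_length(res$dropped_ids, 0L)
  # no class was split: released classes descend from the initial set
  expect_lte(res$n_classes, n_initial)
})

test_that("curves are conserved across the phases", {
  cs <- emulate_paper_shapes("AWP", seed = 13)
  p <- default_params(s_d = 8, hull_resolution = 0.1, k = 4L, depth_b = 2L)
  st <- prepare_anonymization(cs, p)
  n <- length(cs)
  in_classes <- function(st)
    length(unlist(lapply(st$classes, function(e)
      c(e$member_ids, e$dropped_ids))))
  expect_equal(in_classes(st) + sum(lengths(st$remaining)), n)
  data_distribution_phase(st)
  expect_equal(in_classes(st) + sum(lengths(st$remaining)), n)
  n_marked <- length(st$marked)
  unmarked_redistribution(st)
  expect_equal(in_classes(st) + sum(lengths(st$remaining)), n)
  expect_gte(length(st$marked), n_marked)
  n_marked <- length(st$marked)
  marked_redistribution(st, "CONSTRAINED")
  marked_redistribution(st, "RELAXED")
  expect_equal(in_classes(st) + sum(lengths(st$remaining)), n)
  expect_gte(length(st$marked), n_marked)
  expect_length(st$unmarked, 0L)
  expect_equal(sum(lengths(st$remaining)), 0L)
})

test_that("leftover curves are merged into marked classes by redistribution", {
  # 7 curves, k = 3: one ECS class stays short and must be dissolved
  set.seed(19)
  vals <- c(rnorm(4, 0, 0.3), rnorm(3, 1.5, 0.3))
  cs <- constant_set(vals)
  res <- anonymize(cs, default_params(s_d = 5))
  sizes <- vapply(res$segments[[1]]$classes, `[[`, integer(1), "n_members")
  expect_true(all(sizes >= 3L))
  expect_equal(sum(sizes), 7L)
  expect_length(res$unanonymized_ids, 0L)
})

test_that("the maximum cost constraint shapes or blocks class formation", {
  cs <- two_group_set(n_per = 4, gap = 10, spread = 0.2, seed = 6)

  # a single root bucket (depth 0) with a tight cost cap: the greedy
  # fill forms two pure low-loss classes
  p0 <- default_params(s_d = 2, k = 4L, depth_b = 0L, max_cost = 0.3)
  res <- anonymize(cs, p0)
  expect_equal(res$n_classes, 2L)
  for (cls in res$segments[[1]]$classes) {
    expect_lte(cls$glm, 0.3)
    # members come from one value group only
    vals <- vapply(cls$member_ids, function(id) cs$curves[[id]]$v[1],
                   numeric(1))
    expect_lt(diff(range(vals)), 1)
  }

  # at depth 1 the per-bucket quotas demand mixed classes, which the
  # cost cap forbids: no releasable class can exist
  p1 <- default_params(s_d = 2, k = 4L, depth_b = 1L, max_cost = 0.3)
  expect_error(anonymize(cs, p1), "no releasable equivalence class")
})

test_that("identical reruns produce byte-identical reports", {
  cs <- emulate_paper_shapes("AWF", seed = 2)
  p <- default_params(s_d = 6, hull_resolution = 0.2,
                      split = list(mode = "fixed", segment_length = 2))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(anonymize(cs, p), f1)
  write_report_json(anonymize(cs, p), f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
})

test_that("segments are anonymized independently and classes may differ", {
  # similarity pairings flip mid-stream, so a curve can change
  # equivalence classes between segments
  times <- seq(0, 10, by = 0.1)
  mk <- function(id, a, b) {
    v <- ifelse(times < 5, a, b)
    curve(times, v + id / 100, curve_id = sprintf("c%02d", id))
  }
  curves <- list(mk(1, 0, 0), mk(2, 0, 8), mk(3, 8, 0), mk(4, 8, 8))
  cs <- align_dataset(curves)
  p <- default_params(s_d = 3, k = 2L,
                      split = list(mode = "manual",
                                   boundaries = list(c(0, 5), c(5, 10))))
  res <- anonymize(cs, p)
  expect_equal(res$n_segments, 2L)
  classes_of <- function(seg) {
    parts <- lapply(res$segments[[seg]]$classes, function(cl)
      sort(cl$member_ids))
    parts[order(vapply(parts, `[[`, "", 1L))]
  }
  # the class partition changes between the segments
  expect_false(identical(classes_of(1), classes_of(2)))
  for (seg in 1:2)
    for (m in classes_of(seg)) expect_gte(length(m), 2L)
})

test_that("external population distributions drive the clustering", {
  pop <- constant_set(c(0, 0.2, 0.4, 5, 5.2, 5.4, 10, 10.2))
  sub <- align_dataset(pop$curves[c(1, 2, 4, 5, 7, 8)])
  p <- default_params(s_d = 1, k = 3L)
  st <- prepare_anonymization(sub, p, population = pop)
  expect_equal(st$dist$source, "external")
  # clusters reflect the population (three groups), not just the subset
  expect_length(st$dist$clusters, 3L)
  # the anonymization-set distance matrix covers only the subset
  expect_equal(dim(st$dm), c(6L, 6L))
})
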