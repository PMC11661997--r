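test_that("hulls envelope their members on the resolution grid", {
  one <- constant_curve(4, "a")
  h1 <- build_hull(list(one), resolution = 1)
  expect_equal(h1$lower, h1$upper)
  expect_equal(h1$lower, rep(4, length(h1$grid)))

  cs <- constant_set(c(0, 2))
  h <- build_hull(cs$curves, resolution = 1)
  expect_equal(h$lower, rep(0, length(h$grid)))
  expect_equal(h$upper, rep(2, length(h$grid)))

  expect_error(build_hull(list(), 1), "empty")

  # containment against a dense-resample oracle
  set.seed(3)
  members <- lapply(1:5, function(i) random_curve(paste0("m", i)))
  members <- align_dataset(members)$curves
  h2 <- build_hull(members, resolution = 0.25)
  for (m in members) {
    vals <- approx(m$t, m$v, h2$grid, rule = 2)$y
    expect_true(all(vals >= h2$lower - 1e-12))
    expect_true(all(vals <= h2$upper + 1e-12))
  }
  # grid honors the resolution and clamps the last point to the frame end
  expect_equal(diff(h2$grid)[1], 0.25)
  expect_equal(h2$grid[length(h2$grid)], 10)
})

test_that("hull merging is idempotent, commutative, associative and pooled", {
  set.seed(4)
  curves <- align_dataset(lapply(1:6, function(i)
    random_curve(paste0("m", i))))$curves
  ha <- build_hull(curves[1:3], resolution = 0.5)
  hb <- build_hull(curves[4:6], resolution = 0.5)
  hc <- build_hull(curves[2:5], resolution = 0.5)

  expect_equal(merge_hulls(ha, ha), ha)
  expect_equal(merge_hulls(ha, hb), merge_hulls(hb, ha))
  expect_equal(merge_hulls(merge_hulls(ha, hb), hc),
               merge_hulls(ha, merge_hulls(hb, hc)))
  # merged hull equals the hull of the pooled members
  expect_equal(merge_hulls(ha, hb), build_hull(curves, resolution = 0.5))

  bad <- build_hull(curves[1:2], resolution = 1)
  expect_error(merge_hulls(ha, bad), "grid mismatch")
})

test_that("merging along the ECS parenthood never tightens the hull", {
  set.seed(9)
  curves <- align_dataset(lapply(1:6, function(i)
    random_curve(paste0("m", i))))$curves
  ha <- build_hull(curves[1:3], resolution = 0.5)
  hb <- build_hull(curves[4:6], resolution = 0.5)
  hm <- merge_hulls(ha, hb)
  dom <- range(unlist(lapply(curves, `[[`, "v")))
  expect_gte(glm_info_loss(hm, dom, 6),
             max(glm_info_loss(ha, dom, 3), glm_info_loss(hb, dom, 3)))
})

test_that("exact t vanishes for proportional classes and single-cluster populations", {
  cs <- constant_set(c(0, 0.2, 8, 8.2))
  dm <- pairwise_distances(cs)
  d <- cluster_distribution(cs, dm, s_d = 1)
  # class composed proportionally to the population (1 of each cluster,
  # population is 2 and 2)
  et <- exact_t(list(c("c01", "c03"), c("c02", "c04")), d, dm)
  expect_equal(et$t, 0)

  # single-cluster population: 0-closeness trivially
  d1 <- cluster_distribution(cs, dm, s_d = 100)
  et1 <- exact_t(list(c("c01", "c02"), c("c03", "c04")), d1, dm)
  expect_equal(et1$t, 0)

  # a homogeneous class in a mixed population is penalized
  et2 <- exact_t(list(c("c01", "c02")), d, dm, normalizer = max(dm))
  expect_gt(et2$t, 0)
})

test_that("the aggregate information loss is duration-weighted", {
  mk_seg <- function(index, dur, glm, mre = 0.1) {
    list(index = index, interval = c(0, dur), duration = dur,
         n_clusters = 1L, usable_depth = 1L,
         classes = list(list(id = "eqc001", member_ids = c("a", "b", "c"),
                             dropped_ids = character(0), n_members = 3L,
                             glm = glm, mre = mre, t_bound = 0.2,
                             t_exact = 0.1)),
         dropped_ids = character(0), unanonymized_ids = character(0),
         mean_glm = glm, t_exact = 0.1, t_bound = 0.2)
  }
  params <- anonymization_params(s_d = 1, hull_resolution = 0.5)
  cs <- constant_set(c(0, 1, 2))

  # unsplit: aggregate equals the single segment's mean
  r1 <- evaluation_report(list(mk_seg(1, 4, 0.4)), params, cs)
  expect_equal(r1$aggregate_glm, 0.4)
  expect_null(r1$aggregate_glm_cleaned)

  # durations 1 and 3 with losses 0.4 and 0.2
  r2 <- evaluation_report(list(mk_seg(1, 1, 0.4), mk_seg(2, 3, 0.2)),
                          params, cs)
  expect_equal(r2$aggregate_glm, 0.25)
  expect_equal(r2$t_exact, 0.1)
  expect_equal(r2$t_bound, 0.2)

  # a segment shorter than the hull resolution is omitted from the
  # cleaned aggregate
  r3 <- evaluation_report(list(mk_seg(1, 0.3, 0.9), mk_seg(2, 9.7, 0.2)),
                          params, cs)
  expect_equal(r3$aggregate_glm_cleaned, 0.2)
  expect_false(r3$cleaned_suppressed)

  # cleaning is suppressed when the omitted share exceeds 25 %
  r4 <- evaluation_report(list(mk_seg(1, 0.4, 0.9), mk_seg(2, 0.6, 0.2)),
                          params, cs)
  expect_null(r4$aggregate_glm_cleaned)
  expect_true(r4$cleaned_suppressed)
})

test_that("the exact t stays below the bucket-error bound across seeded runs", {
  for (seed in c(3, 14, 27)) {
    cs <- emulate_paper_shapes("AWF", seed = seed)
    res <- anonymize(cs, anonymization_params(s_d = 6, hull_resolution = 0.2))
    for (s in res$segments)
      for (cl in s$classes)
        expect_lte(cl$t_exact, cl$t_bound + 1e-9)
  }
})

test_that("hull CSVs carry lower and upper columns in the native dialect", {
  cs <- constant_set(c(0, 2))
  h <- build_hull(cs$curves, resolution = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_hull_csv(h, p, quantity_name = "AWF", unit = "L/min",
                 class_id = "eqc001")
  lines <- readLines(p)
  expect_equal(lines[1], "eqc001")
  expect_equal(lines[3], "Time [s];lower [L/min];upper [L/min]")
  expect_equal(length(lines), 3 + length(h$grid))
  expect_equal(strsplit(lines[4], ";")[[1]], c("0", "0", "2"))
})
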