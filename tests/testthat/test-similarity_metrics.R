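test_that("Frechet distance: identity and parallel constant curves", {
  a <- constant_curve(3, "a")
  expect_equal(frechet_distance(a, a), 0)
  b <- constant_curve(3 + 2.5, "b")
  expect_equal(frechet_distance(a, b), 2.5)
  expect_equal(frechet_distance(a, b, value_scale = 2), 5)
  # time axis enters only when weighted in
  expect_equal(frechet_distance(a, b, time_scale = 1), 2.5)
  expect_error(frechet_distance(a, curve(0:5, rep(1, 6), curve_id = "u")),
               "not aligned")
})

test_that("Frechet distance matches the full-lattice DP oracle", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_curve("a", n = sample(10:40, 1))
    b <- random_curve("b", n = sample(10:40, 1))
    expect_equal(frechet_distance(a, b), frechet_oracle(a, b))
    expect_equal(frechet_distance(a, b, time_scale = 0.3, value_scale = 2),
                 frechet_oracle(a, b, time_scale = 0.3, value_scale = 2))
  }
  # curves on different grids are resampled onto the union grid
  set.seed(43)
  a <- random_curve("a", times = sort(c(0, 10, runif(15, 0, 10))))
  b <- random_curve("b", times = sort(c(0, 10, runif(22, 0, 10))))
  expect_equal(frechet_distance(a, b), frechet_oracle(a, b))
})

test_that("Frechet distance is a metric on random triples", {
  set.seed(7)
  for (i in 1:100) {
    tr <- lapply(c("a", "b", "c"), random_curve, n = 15)
    dab <- frechet_distance(tr[[1]], tr[[2]])
    dba <- frechet_distance(tr[[2]], tr[[1]])
    dac <- frechet_distance(tr[[1]], tr[[3]])
    dbc <- frechet_distance(tr[[2]], tr[[3]])
    expect_identical(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("pairwise_distances fills a symmetric zero-diagonal matrix", {
  cs <- constant_set(c(0, 1, 3))
  D <- pairwise_distances(cs)
  expect_equal(unname(D), rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)))

  csk <- constant_set(rep(4, 5))
  expect_true(all(pairwise_distances(csk) == 0))

  set.seed(11)
  cs2 <- random_set(6)
  D2 <- pairwise_distances(cs2)
  expect_identical(D2, t(D2))
  expect_true(all(diag(D2) == 0))
  expect_true(all(D2 >= 0))
  # matches the scalar route entry by entry
  ids <- colnames(D2)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D2[i, j],
                 frechet_distance(cs2$curves[[ids[i]]], cs2$curves[[ids[j]]]))
})

test_that("EMD: coincidence, single-flow and degenerate inputs", {
  g <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  expect_equal(emd(c(1, 2, 3), c(2, 4, 6), g), 0)  # equal after normalizing
  expect_equal(emd(c(1, 0, 0), c(0, 0, 1), g), g[1, 3])
  expect_equal(emd(c(0, 1, 0), c(1, 0, 0), g), g[2, 1])
  expect_error(emd(numeric(0), numeric(0), g), "non-empty")
  expect_error(emd(c(0, 0, 0), c(1, 1, 1), g), "positive totals")
})

test_that("EMD matches the unit-atom matching oracle on 100 seeded pairs", {
  set.seed(99)
  for (i in 1:100) {
    nc <- sample(3:5, 1)
    total <- sample(4:6, 1)
    p <- as.vector(rmultinom(1, total, rep(1, nc)))
    q <- as.vector(rmultinom(1, total, rep(1, nc)))
    g <- random_ground(nc)
    expect_equal(emd(p, q, g), emd_atom_oracle(p, q, g), tolerance = 1e-9)
  }
})

test_that("EMD is symmetric and satisfies the triangle inequality", {
  set.seed(5)
  for (i in 1:30) {
    nc <- 4
    g <- random_ground(nc)
    p <- runif(nc); q <- runif(nc); r <- runif(nc)
    expect_equal(emd(p, q, g), emd(q, p, g), tolerance = 1e-10)
    expect_lte(emd(p, r, g), emd(p, q, g) + emd(q, r, g) + 1e-9)
  }
})

test_that("GLM information loss follows the hull width fraction", {
  cs <- constant_set(c(0, 2, 10))
  h <- build_hull(cs$curves[c("c01", "c02")], resolution = 1)
  # width 2 on domain width 10
  expect_equal(glm_info_loss(h, cs$value_domain, 2), 0.2)
  # a single leaf loses nothing
  expect_equal(glm_info_loss(h, cs$value_domain, 1), 0)
  # full-domain hull
  hf <- build_hull(cs$curves[c("c01", "c03")], resolution = 1)
  expect_equal(glm_info_loss(hf, cs$value_domain, 2), 1)
  # degenerate domain warns and returns 0
  expect_warning(res <- glm_info_loss(h, c(5, 5), 2), "degenerate")
  expect_equal(res, 0)
})

test_that("GLM is monotone under pointwise hull enlargement", {
  set.seed(13)
  cs <- random_set(5)
  h <- build_hull(cs$curves[1:3], resolution = 0.5)
  h2 <- h
  h2$upper <- h2$upper + runif(length(h2$upper), 0, 1)
  h2$lower <- h2$lower - runif(length(h2$lower), 0, 1)
  expect_gte(glm_info_loss(h2, cs$value_domain, 3),
             glm_info_loss(h, cs$value_domain, 3))
})

test_that("median relative error pools member-grid deviations", {
  cs <- constant_set(c(0, 2, 1))
  members <- cs$curves
  h <- build_hull(members[c("c01", "c02")], resolution = 1)
  # members on the bounds contribute zeros; middle contributes 1 per
  # grid point; the pooled median over {0, 0, 1} per point is 0
  errs <- c(rep(0, 2 * length(h$grid)), rep(1, length(h$grid)))
  expect_equal(median_relative_error(members, h), median(errs))
  # coinciding with a bound everywhere gives 0
  expect_equal(median_relative_error(members[c("c01", "c02")], h), 0)
  # adding a duplicate of a bound member only adds zeros
  more <- c(members, list(constant_curve(0, "dup")))
  expect_equal(median_relative_error(more, h),
               median(c(errs, rep(0, length(h$grid)))))
  expect_error(median_relative_error(list(), h), "empty")
})
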