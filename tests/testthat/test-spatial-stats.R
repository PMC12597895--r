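test_that("spatial index queries match brute-force search", {
  idx0 <- build_spatial_index(numeric(0), numeric(0), 20)
  expect_equal(query_spatial_index(idx0, c(0, 0), 100), integer(0))

  idx2 <- build_spatial_index(c(0, 5), c(0, 0), 20)
  expect_equal(query_spatial_index(idx2, c(0, 0), 10), c(1L, 2L))

  set.seed(17)
  x <- runif(500, -300, 300); y <- runif(500, -300, 300)
  idx <- build_spatial_index(x, y, 25)
  for (q in 1:50) {
    pt <- runif(2, -320, 320)
    r <- runif(1, 5, 120)
    got <- query_spatial_index(idx, pt, r)
    want <- which((x - pt[1])^2 + (y - pt[2])^2 <= r^2)
    expect_equal(got, want)
  }
})

test_that("cross-PCF reproduces the hand-evaluated single-pair value", {
  snap <- make_snapshot(x = c(0, 15), y = c(0, 0),
                        type = c("cancer", "CD8"))
  p <- cross_pcf(snap, "cancer", "CD8", bin_edges = c(10, 20),
                 domain_area = 1e6)
  # g = (1/1) * 1 / ((1/1e6) * pi * (400 - 100)) = 1e6 / (300 pi)
  expect_equal(p$g, 1e6 / (300 * pi))
  expect_false(p$empty)
})

test_that("cross-PCF contracts for empty populations hold", {
  snap <- make_snapshot(x = c(0, 10), y = c(0, 0),
                        type = c("cancer", "cancer"))
  expect_warning(p <- cross_pcf(snap, "cancer", "CD8"), "no cells")
  expect_true(all(p$g == 0))
  expect_true(p$targets_absent)
  expect_error(cross_pcf(snap, "CD8", "cancer"), "center type")
})

test_that("cross-PCF is 1 under complete spatial randomness", {
  # centers are kept one maximal bin radius away from the walls: without
  # boundary correction the estimator is unbiased only where annuli lie
  # fully inside the domain (the documented large-r edge bias)
  set.seed(23)
  reps <- 20L
  vals <- numeric(reps)
  bins <- seq(0, 120, by = 10)
  sel <- which(utils::head(bins, -1L) >= 20 & utils::tail(bins, -1L) <= 100)
  for (k in seq_len(reps)) {
    n <- 500L
    snap <- make_snapshot(x = c(runif(n, 120, 880), runif(n, 0, 1000)),
                          y = c(runif(n, 120, 880), runif(n, 0, 1000)),
                          type = rep(c("cancer", "CD8"), each = n),
                          domain = c(0, 1000, 0, 1000))
    vals[k] <- mean(cross_pcf(snap, "cancer", "CD8", bins)$g[sel])
  }
  se <- stats::sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("cross-PCF is scale-equivariant and multiplicity-invariant", {
  set.seed(29)
  n <- 150L
  x <- runif(2 * n, 0, 500); y <- runif(2 * n, 0, 500)
  ty <- rep(c("cancer", "CD8"), each = n)
  bins <- seq(0, 100, by = 20)
  snap <- make_snapshot(x, y, ty, domain = c(0, 500, 0, 500))
  g1 <- cross_pcf(snap, "cancer", "CD8", bins)$g
  # rescale space by c: same g with scaled bins and area
  cc <- 3.7
  snap_c <- make_snapshot(cc * x, cc * y, ty,
                          domain = c(0, 500 * cc, 0, 500 * cc))
  g2 <- cross_pcf(snap_c, "cancer", "CD8", cc * bins)$g
  expect_equal(g2, g1, tolerance = 1e-12)
  # duplicating every target doubles counts and the density: g unchanged
  ti <- which(ty == "CD8")
  snap_d <- make_snapshot(c(x, x[ti]), c(y, y[ti]), c(ty, ty[ti]),
                          domain = c(0, 500, 0, 500))
  g3 <- cross_pcf(snap_d, "cancer", "CD8", bins)$g
  expect_equal(g3, g1, tolerance = 1e-12)
})

test_that("cross-PCF time series mirrors per-snapshot values and masks", {
  cfg <- single_type_config(cell_type_params(), duration_min = 120,
                            save_interval_min = 60)
  init <- initial_state(x = c(-20, 20), y = c(0, 0),
                        type = rep("cancer", 2),
                        domain = c(-100, 100, -100, 100))
  tr <- simulate_abm(init, cfg, seed = 1)
  ser <- cross_pcf_timeseries(tr, "cancer", "cancer",
                              bin_edges = seq(0, 80, 20))
  expect_equal(nrow(ser$G), 3L)
  # frozen system: every row identical and equal to the direct computation
  direct <- cross_pcf(tr$snapshots[[1]], "cancer", "cancer",
                      seq(0, 80, 20))$g
  for (i in 1:3) expect_equal(ser$G[i, ], direct)

  ser2 <- cross_pcf_timeseries(tr, "CD8", "cancer", seq(0, 80, 20))
  expect_true(all(is.na(ser2$G)))  # no centers anywhere: masked
})

test_that("neighbor graphs equal all-pairs construction", {
  snap <- make_snapshot(x = c(0, 10), y = c(0, 0),
                        type = c("cancer", "cancer"), radius = 8)
  expect_equal(nrow(neighbor_graph(snap, 1.2)$edges), 1L)  # 10 <= 19.2
  snap2 <- make_snapshot(x = c(0, 25), y = c(0, 0),
                         type = c("cancer", "cancer"), radius = 8)
  expect_equal(nrow(neighbor_graph(snap2, 1.2)$edges), 0L)

  set.seed(31)
  for (rep in 1:5) {
    n <- 300L
    x <- runif(n, -400, 400); y <- runif(n, -400, 400)
    r <- sample(c(6, 8, 10), n, replace = TRUE)
    snap3 <- make_snapshot(x, y, rep("cancer", n), radius = r)
    got <- neighbor_graph(snap3, 1.25)$edges
    want <- brute_force_pairs(x, y, r, 1.25)
    ord <- order(got[, 1], got[, 2])
    expect_equal(got[ord, , drop = FALSE],
                 matrix(as.integer(want), ncol = 2),
                 ignore_attr = TRUE)
  }
})

test_that("cancer components match a breadth-first-search oracle", {
  empty <- make_snapshot(x = c(0, 10), y = c(0, 0),
                         type = c("healthy", "CD8"))
  expect_equal(cancer_components(neighbor_graph(empty)), integer(0))

  chain <- make_snapshot(x = seq(0, 72, by = 18), y = rep(0, 5),
                         type = rep("cancer", 5), radius = 8)
  expect_equal(cancer_components(neighbor_graph(chain, 1.25)), 5L)

  set.seed(37)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    x <- runif(n, 0, 400); y <- runif(n, 0, 400)
    ty <- sample(c("cancer", "healthy"), n, replace = TRUE)
    snap <- make_snapshot(x, y, ty, radius = 8)
    g <- neighbor_graph(snap, 1.25)
    sizes <- sort(cancer_components(g))
    keep <- which(ty == "cancer")
    sub_edges <- brute_force_pairs(x[keep], y[keep],
                                   rep(8, length(keep)), 1.25)
    want <- sort(bfs_component_sizes(length(keep), sub_edges))
    expect_equal(sizes, as.integer(want))
  }
})

test_that("full-graph component convention counts cancer members only", {
  # cancer - healthy - cancer bridge: one full-graph component with 2
  # cancer cells, but two singleton components on the induced subgraph
  snap <- make_snapshot(x = c(0, 18, 36), y = c(0, 0, 0),
                        type = c("cancer", "healthy", "cancer"), radius = 8)
  g <- neighbor_graph(snap, 1.25)
  expect_equal(sort(cancer_components(g)), c(1L, 1L))
  expect_equal(cancer_components(g, induced = FALSE), 2L)
})

test_that("component CDFs are cancer-cell-weighted cumulative fractions", {
  cdf <- component_cdf(c(1, 1, 3))
  expect_equal(cdf$sizes, c(1L, 3L))
  expect_equal(cdf$F, c(0.4, 1.0))

  expect_equal(component_cdf(7)$F, 1)

  set.seed(41)
  for (rep in 1:10) {
    sizes <- sample(1:50, sample(1:20, 1), replace = TRUE)
    cdf2 <- component_cdf(sizes)
    expect_true(all(diff(cdf2$F) > 0))
    expect_equal(cdf2$F[length(cdf2$F)], 1)
  }

  expect_true(component_cdf(integer(0))$empty)
  expect_error(component_cdf(c(2, 0)), ">= 1")
})

test_that("replicate aggregation gives pointwise mean and sample SD", {
  same <- aggregate_series(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$sd, c(0, 0))
  two <- aggregate_series(list(c(0, 1), c(2, 3)))
  expect_equal(two$mean, c(1, 2))
  expect_equal(two$sd, c(sqrt(2), sqrt(2)))
  one <- aggregate_series(list(c(5, 6)))
  expect_equal(one$mean, c(5, 6))
  expect_equal(one$sd, c(0, 0))
  expect_error(aggregate_series(list(1:2, 1:3)), "common grid")
})

test_that("component CDF aggregation interpolates as a right-continuous step", {
  a <- component_cdf(c(1, 3))      # F(1) = 0.25, F(3) = 1
  b <- component_cdf(c(2, 2))      # F(2) = 1
  agg <- aggregate_component_cdfs(list(a, b))
  expect_equal(agg$sizes, c(1L, 2L, 3L))
  # replicate a evaluated on the union: 0.25, 0.25, 1; replicate b: 0, 1, 1
  expect_equal(agg$F[1, ], c(0.25, 0.25, 1))
  expect_equal(agg$F[2, ], c(0, 1, 1))
  expect_equal(agg$F_mean, c(0.125, 0.625, 1))
  expect_equal(agg$F_sd, apply(agg$F, 2, sd))
})
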