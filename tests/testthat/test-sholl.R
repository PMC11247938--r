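test_that("a straight ray crosses each smaller sphere exactly once", {
  tr <- straight_trace(zs = seq(0, 95, length.out = 20))
  p <- sholl_profile(tr, step = 10)
  expect_equal(p$radii, 10 * (1:10))
  expect_equal(p$counts, c(rep(1L, 9), 0L))
  # root-only trace: all-zero profile
  p0 <- sholl_profile(make_trace(c(0, 0, 0), -1L))
  expect_true(all(p0$counts == 0L))
  expect_error(sholl_profile(tr, step = 0), "positive")
})

test_that("a Y-tree doubles its crossings beyond the bifurcation", {
  g <- gen_trace("y_tree", branch_radius = 50, tip_radius = 100, seed = 1)
  p <- sholl_profile(g$trace, step = 10)
  expect_equal(p$counts[1:4], rep(1L, 4))   # r = 10..40
  expect_equal(p$counts[6:9], rep(2L, 4))   # r = 60..90
  # node exactly on the 50 um shell: a single strict sign change
  expect_equal(p$counts[5], 1L)
  # leaf tips exactly on the 100 um shell: tangential touch, no change
  expect_equal(p$counts[10], 0L)
  expect_identical(p$counts, g$sholl_truth$counts)
})

test_that("re-entrant edges count two crossings, tangencies none", {
  # second edge dips inside r = 10 and exits again: 2 crossings on it
  tr <- make_trace(rbind(c(0, 0, 0), c(-12, 1, 0), c(12, 1, 0)),
                   c(-1L, 1L, 2L))
  p <- sholl_profile(tr, step = 10)
  expect_equal(p$counts[1], 3L)             # 1 on the stem + 2 re-entrant
  expect_equal(sholl_profile_dense(tr, step = 10)$counts[1], 3L)

  # edge tangent to r = 10 at (0, 10, 0): contributes nothing
  tg <- make_trace(rbind(c(0, 0, 0), c(-12, 10, 0), c(12, 10, 0)),
                   c(-1L, 1L, 2L))
  expect_equal(sholl_profile(tg, step = 10)$counts[1], 1L)
})

test_that("nodes lying exactly on a shell are counted once, not twice", {
  tr <- straight_trace(zs = c(0, 10, 20))
  p <- sholl_profile(tr, step = 10)
  expect_equal(p$counts, c(1L, 0L))         # crossing at the node at z=10
  # path ending exactly on the shell: no sign change at the leaf
  tr2 <- straight_trace(zs = c(0, 10))
  expect_equal(sholl_profile(tr2, step = 10)$counts, 0L)
})

test_that("profiles at step 10 equal step 5 restricted to even shells", {
  for (s in 1:5) {
    tr <- gen_trace("random_tree", seed = s, truth = FALSE)$trace
    p10 <- sholl_profile(tr, step = 10)
    p5 <- sholl_profile(tr, step = 5)
    shared <- match(p10$radii, p5$radii)
    ok <- !is.na(shared)
    expect_equal(p10$counts[ok], p5$counts[shared[ok]])
    # shells on the 10 um grid beyond the 5 um range hold no crossings
    expect_true(all(p10$counts[!ok] == 0L))
  }
})

test_that("profiles are invariant under rigid motion of trace and center", {
  set.seed(31)
  for (s in 1:5) {
    tr <- gen_trace("random_tree", seed = s + 40, truth = FALSE)$trace
    p <- sholl_profile(tr, step = 10)
    m <- random_rigid()
    p2 <- sholl_profile(transform_trace(tr, m$R, m$t), step = 10)
    expect_identical(p2$counts, p$counts)
    expect_identical(p2$radii, p$radii)
  }
})

test_that("appending radially outward edges never removes crossings", {
  for (s in 1:5) {
    g <- gen_trace("random_tree", n_edges = 20, seed = s, truth = FALSE)
    tr <- g$trace
    before <- sum(sholl_profile(tr, step = 10)$counts)
    nd <- tr$nodes
    d <- sqrt(nd$x^2 + nd$y^2 + nd$z^2)
    far <- which.max(d)
    new <- nd[far, ]
    new$node_id <- max(nd$node_id) + 1L
    new$parent_id <- nd$node_id[far]
    scale <- (d[far] + 25) / d[far]
    new$x <- nd$x[far] * scale; new$y <- nd$y[far] * scale
    new$z <- nd$z[far] * scale
    tr2 <- neurite_trace(rbind(nd, new), name = "ext")
    expect_gte(sum(sholl_profile(tr2, step = 10)$counts), before)
  }
})

test_that("polynomial fits are exact on polynomial profiles", {
  flat <- structure(list(radii = 10 * (1:10), counts = rep(1, 10),
                         center = c(0, 0, 0), step = 10, trace = "t",
                         group = "untagged", normalized = FALSE,
                         norm_length = NA_real_), class = "sholl_profile")
  f <- fit_profile(flat, degree = 5)
  expect_equal(f$coefficients, c(1, rep(0, 5)), tolerance = 1e-8)
  expect_equal(predict(f, c(15, 55)), c(1, 1), tolerance = 1e-8)

  # generate-then-fit: a known cubic is recovered to 1e-8
  beta <- c(2.5, -0.31, 0.042, -7e-4)
  r <- 10 * (1:12)
  cubic <- flat
  cubic$radii <- r
  cubic$counts <- drop(outer(r, 0:3, `^`) %*% beta)
  f3 <- fit_profile(cubic, degree = 3)
  expect_equal(f3$coefficients, beta, tolerance = 1e-8)

  short <- flat
  short$radii <- 10 * (1:5); short$counts <- rep(1, 5)
  expect_error(fit_profile(short, degree = 5), "degenerate")
})

test_that("radii normalize to the skin-reaching nerve and invert", {
  long <- straight_trace(zs = seq(0, 100, by = 10), name = "skin")
  long$reaches_skin <- TRUE
  short <- straight_trace(zs = seq(0, 50, by = 10), name = "short")
  ts <- trace_set(list(long, short))
  ps <- list(sholl_profile(long), sholl_profile(short))
  np <- normalize_profiles(ps, ts)
  expect_true(all(np[[2]]$radii <= 0.5 + 1e-12))
  expect_equal(max(np[[1]]$radii), 1)
  expect_equal(np[[1]]$norm_length, 100)
  back <- denormalize_profiles(np)
  expect_equal(back[[1]]$radii, ps[[1]]$radii)
  expect_equal(back[[2]]$radii, ps[[2]]$radii)

  # no reaches_skin flag: fall back to the longest nerve, with a warning
  ts2 <- trace_set(list(straight_trace(zs = c(0, 40), name = "a"),
                        straight_trace(zs = c(0, 80), name = "b")))
  ps2 <- lapply(ts2$traces, sholl_profile)
  expect_warning(np2 <- normalize_profiles(ps2, ts2), "reaches_skin")
  expect_equal(np2[[2]]$norm_length, 80)
})
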