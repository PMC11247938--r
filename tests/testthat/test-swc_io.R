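test_that("read_swc parses plain, tabbed, commented and unordered files", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# a comment", "",
               "1 0 0 0 0 1 -1", "2 0 0 0 5 1 1", "3 0 0 0 10 1 2"), f)
  tr <- read_swc(f)
  expect_s3_class(tr, "neurite_trace")
  expect_equal(nrow(tr$nodes), 3L)
  expect_equal(tr$nodes$node_id[tr$nodes$parent_id == -1L], 1L)
  expect_equal(path_length(tr), 10)

  # tab-delimited, child listed before parent, non-consecutive ids
  f2 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("7\t0\t0\t0\t10\t1\t4", "4\t0\t0\t0\t5\t1\t1",
               "1\t0\t0\t0\t0\t1\t-1"), f2)
  tr2 <- read_swc(f2, group = "ExA")
  expect_equal(path_length(tr2), 10)
  expect_equal(tr2$group, "ExA")
})

test_that("malformed and structurally invalid files fail with context", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1 -1", "2 0 0 0 5 1 9"), f)
  expect_error(read_swc(f), "node 2.*parent 9")

  writeLines(c("1 0 0 0 0 1 -1", "2 0 0 0 5 1"), f)
  expect_error(read_swc(f), "line 2")

  writeLines(c("1 0 0 0 0 1 -1", "2 0 0 zz 5 1 1"), f)
  expect_error(read_swc(f), "line 2")

  writeLines(c("1 0 0 0 0 1 -1", "2 0 0 0 5 1 -1"), f)
  expect_error(read_swc(f), "2 roots")

  writeLines(c("1 0 0 0 0 1 -1", "1 0 0 0 5 1 1"), f)
  expect_error(read_swc(f), "duplicate node_id 1")

  # two nodes pointing at each other: a cycle, unreachable from the root
  writeLines(c("1 0 0 0 0 1 -1", "2 0 0 0 5 1 3", "3 0 0 1 5 1 2"), f)
  expect_error(read_swc(f), "unreachable")
})

test_that("write_swc round-trips node tables exactly", {
  f <- withr::local_tempfile(fileext = ".swc")
  for (s in 1:5) {
    tr <- gen_trace("random_tree", n_edges = 15, seed = s,
                    truth = FALSE)$trace
    write_swc(tr, f)
    back <- read_swc(f, name = tr$name)
    expect_identical(back$nodes, tr$nodes)
  }
  # non-integer coordinates survive at full precision
  tr <- make_trace(rbind(c(0, 0, 0), c(1 / 3, sqrt(2), pi)), c(-1L, 1L))
  write_swc(tr, f)
  expect_identical(read_swc(f)$nodes[, c("x", "y", "z")],
                   tr$nodes[, c("x", "y", "z")])
  # root-only trace: a one-line body
  tr1 <- make_trace(c(1, 2, 3), -1L)
  write_swc(tr1, f)
  expect_length(grep("^[^#]", readLines(f)), 1L)
  expect_equal(path_length(read_swc(f)), 0)
})

test_that("path_length sums edge norms and is rigid-motion invariant", {
  expect_equal(path_length(straight_trace()), 10)
  expect_equal(path_length(y150_trace()), 150)  # 50 + 2 * sqrt(30^2+40^2)
  set.seed(11)
  tr <- gen_trace("random_tree", seed = 11, truth = FALSE)$trace
  L <- path_length(tr)
  for (i in 1:5) {
    m <- random_rigid()
    expect_equal(path_length(transform_trace(tr, m$R, m$t)), L,
                 tolerance = 1e-9)
  }
})

test_that("extract_tips returns labelled leaves matching a degree scan", {
  expect_equal(nrow(extract_tips(straight_trace())), 1L)
  expect_equal(nrow(extract_tips(y150_trace())), 2L)

  ts <- trace_set(list(
    make_trace(rbind(c(0, 0, 0), c(1, 0, 0)), c(-1L, 1L), name = "a",
               group = "ExA"),
    make_trace(rbind(c(0, 0, 0), c(0, 1, 0)), c(-1L, 1L), name = "b",
               group = "InA")))
  tips <- extract_tips(ts)
  expect_setequal(tips$group, c("ExA", "InA"))
  expect_equal(attr(tips, "projection_axis"), "z")

  set.seed(21)
  for (s in 1:10) {
    tr <- gen_trace("random_tree", n_edges = 25, seed = s,
                    truth = FALSE)$trace
    expect_equal(nrow(extract_tips(tr)), leaf_count_by_degree(tr))
  }
  empty <- trace_set(list())
  expect_equal(nrow(extract_tips(empty)), 0L)
})

test_that("sidecar labels attach groups and skin flags by trace name", {
  ts <- trace_set(list(
    make_trace(rbind(c(0, 0, 0), c(1, 0, 0)), c(-1L, 1L), name = "n1"),
    make_trace(rbind(c(0, 0, 0), c(0, 2, 0)), c(-1L, 1L), name = "n2")))
  lab <- data.frame(trace = c("n1", "n2", "ghost"),
                    group = c("ExA", "InA", "ExA"),
                    reaches_skin = c(FALSE, TRUE, FALSE))
  expect_warning(ts <- apply_labels(ts, lab), "ghost")
  expect_equal(ts$traces$n1$group, "ExA")
  expect_true(ts$traces$n2$reaches_skin)
})

test_that("validate_swc_files reports per-file diagnostics", {
  ok <- withr::local_tempfile(fileext = ".swc")
  bad <- withr::local_tempfile(fileext = ".swc")
  write_swc(straight_trace(), ok)
  writeLines("1 0 0 0 0 1 7", bad)
  rep <- validate_swc_files(c(ok, bad))
  expect_equal(rep$valid, c(TRUE, FALSE))
  expect_equal(rep$tips[1], 1L)
  expect_match(rep$message[2], "root")
})
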