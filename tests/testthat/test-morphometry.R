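test_that("segments_per_sucker averages the two sides then divides", {
  expect_equal(segments_per_sucker(45, 45, 6), 7.5)
  expect_equal(segments_per_sucker(44, 47, 6), 45.5 / 6)
  expect_equal(segments_per_sucker(0, 0, 6), 0)
  # symmetric in the two sides
  expect_equal(segments_per_sucker(40, 50, 6), segments_per_sucker(50, 40, 6))
  expect_error(segments_per_sucker(45, 45, 0), "at least 1")
  expect_error(segments_per_sucker(-1, 45, 6), "non-negative")
})

test_that("summarize_widths does the two-step ExA/InA averaging", {
  tb <- segment_table(
    arm_id = "a1", position = rep("proximal", 4),
    side = c("anterior", "posterior", "anterior", "posterior"),
    territory = c("ExA", "ExA", "InA", "InA"),
    width = c(10, 12, 6, 8))
  s <- summarize_widths(tb)
  expect_equal(s$mean[s$territory == "ExA"], 11)
  expect_equal(s$mean[s$territory == "InA"], 7)
  expect_equal(s$mean[s$territory == "total"], 9)

  # the total is the mean of the two territory means, not the pooled mean
  tb2 <- segment_table(
    arm_id = "a1", position = rep("distal", 4),
    side = "anterior", territory = c("ExA", "ExA", "ExA", "InA"),
    width = c(10, 12, 14, 6))
  s2 <- summarize_widths(tb2)
  expect_equal(s2$mean[s2$territory == "total"], 9)   # (12 + 6) / 2
  expect_false(isTRUE(all.equal(s2$mean[s2$territory == "total"], 10.5)))

  # identical values: sem is zero
  tb3 <- segment_table(arm_id = "a1", position = "proximal",
                       side = rep(c("anterior", "posterior"), 2),
                       territory = rep(c("ExA", "InA"), each = 2),
                       width = rep(5, 4))
  s3 <- summarize_widths(tb3)
  expect_true(all(s3$mean == 5))
  expect_true(all(s3$sem[s3$territory != "total"] == 0))

  # an empty cell is omitted with a warning and no total is formed
  tb4 <- segment_table(arm_id = "a1", position = "proximal",
                       side = "anterior", territory = c("ExA", "ExA"),
                       width = c(4, 6))
  expect_warning(s4 <- summarize_widths(tb4), "InA")
  expect_false("total" %in% s4$territory)
})

test_that("density and cross-sectional area follow their definitions", {
  expect_equal(cell_density(50, 1000), 0.05)
  expect_equal(cell_density(0, 1000), 0)
  expect_equal(cell_density(100, 2000), cell_density(50, 1000))
  expect_error(cell_density(5, 0), "positive")

  expect_equal(cross_sectional_area(20, 30), 600)
  expect_equal(cross_sectional_area(1, 1), 1)
  expect_equal(cross_sectional_area(7, 3), cross_sectional_area(3, 7))
  expect_error(cross_sectional_area(0, 3), "positive")
})

test_that("the factorial stage fits both factors and Tukey contrasts", {
  g <- gen_segment_table(replicates = 12, exa_offset = 12, noise_sd = 4,
                         seed = 42)
  res <- two_way_anova_tukey(g$segments, "width", "position", "territory")
  expect_setequal(res$table$term,
                  c("position", "territory", "position:territory"))
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
  # a 3-sigma territory offset and a strong taper must register
  expect_true(res$table$significant[res$table$term == "territory"])
  expect_true(res$table$significant[res$table$term == "position"])
  # Tukey covers every level pair of each main factor
  expect_equal(sum(res$tukey$factor == "position"), 3L)
  expect_equal(sum(res$tukey$factor == "territory"), 1L)

  # balanced design: Type II F equals the classical sequential ANOVA
  cl <- summary(stats::aov(width ~ position * territory,
                           data = g$segments))[[1]]
  expect_equal(res$table$F, cl$`F value`[1:3], tolerance = 1e-10)
})

test_that("single-replicate cells refuse the interaction term", {
  tb <- segment_table(arm_id = "a1",
                      position = c(rep(c("proximal", "distal"), each = 2),
                                   "proximal", "distal", "proximal"),
                      side = "anterior",
                      territory = c(rep(c("ExA", "InA"), 2),
                                    "ExA", "ExA", "InA"),
                      width = c(10, 6, 8, 5, 11, 9, 7))
  expect_warning(res <- two_way_anova_tukey(tb, "width", "position",
                                            "territory"),
                 "interaction term is refused")
  expect_false("position:territory" %in% res$table$term)
  expect_false(res$interaction_included)
})

test_that("generated cell-mean offsets are recovered within 2 sem", {
  for (s in 1:5) {
    g <- gen_segment_table(replicates = 12, exa_offset = 8, taper = 10,
                           noise_sd = 4, seed = s)
    s_ <- summarize_widths(g$segments)
    for (pos in POSITIONS) {
      ex <- s_[s_$position == pos & s_$territory == "ExA", ]
      inn <- s_[s_$position == pos & s_$territory == "InA", ]
      se <- sqrt(ex$sem^2 + inn$sem^2)
      expect_lt(abs((ex$mean - inn$mean) - 8), 2 * se + 1e-12)
    }
  }
})
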