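test_that("the default montage has the 10 sites and 21 categorized pairs", {
  m <- build_default_montage()
  expect_setequal(m$sites$electrode,
                  c("F3", "F4", "F7", "F8", "C3", "C4", "T5", "T6", "P3", "P4"))
  expect_equal(nrow(m$pairs), 21L)
  expect_equal(sum(m$pairs$category == "left-intra"), 8L)
  expect_equal(sum(m$pairs$category == "right-intra"), 8L)
  expect_equal(sum(m$pairs$category == "interhemispheric"), 5L)
  expect_false(anyDuplicated(m$pairs$pair) > 0)
  expect_true(all(m$pairs$el1 != m$pairs$el2))
  # region / hemisphere mapping is bijective with (region, hemisphere)
  expect_equal(nrow(unique(m$sites[, c("region", "hemisphere")])), 10L)
})

test_that("region lookup matches the montage definition", {
  expect_equal(unname(region_of("C3")), c("M1", "left"))
  expect_equal(unname(region_of("F3")), c("DLPFC", "left"))
  expect_equal(unname(region_of("T6")), c("SPT", "right"))
  expect_error(region_of("Cz"), "not in montage")
})

test_that("category subsets are stable and mirror-symmetric", {
  left <- pairs_for("left-intra")$pair
  expect_equal(left, c("F3-F7", "F3-P3", "F7-C3", "P3-F7", "P3-C3",
                       "T5-C3", "T5-P3", "T5-F7"))
  expect_equal(pairs_for("interhemispheric")$pair,
               c("F3-F4", "F7-F8", "C3-C4", "P3-P4", "T5-T6"))
  mirror <- c(F3 = "F4", F7 = "F8", C3 = "C4", T5 = "T6", P3 = "P4")
  mirrored <- vapply(strsplit(left, "-"), function(e)
    paste(mirror[e[1]], mirror[e[2]], sep = "-"), "")
  expect_setequal(mirrored, pairs_for("right-intra")$pair)
  expect_error(pairs_for("frontal"), "unknown category")
  m <- build_default_montage()
  expect_equal(category <- m$pairs$category[m$pairs$pair == "F3-F4"],
               "interhemispheric")
})
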