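test_that("ExG and ExR match their closed forms", {
  img <- image_from_pixels(list(
    c(0, 0, 0), c(50, 150, 50), c(255, 0, 255), c(100, 0, 0), c(0, 100, 0)
  ))
  expect_equal(as.vector(compute_exg(img)), c(0, 200, -510, -100, 200))
  expect_equal(as.vector(compute_exr(img)), c(0, 1.4 * 50 - 150, 1.4 * 255, 140, -100))
})

test_that("fun01 applies its three strict criteria", {
  img <- image_from_pixels(list(
    c(50, 150, 50),    # all criteria hold -> vegetation
    c(150, 150, 150),  # R/G = 1 fails P1
    c(0, 10, 0),       # 2G - R - B = 20, not > 20
    c(10, 0, 10)       # G = 0: ratios undefined -> background
  ))
  expect_equal(as.vector(segment_fun01(img)), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("shrinking fun01 thresholds shrinks the vegetation set", {
  set.seed(21)
  arr <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), dim = c(20, 20, 3))
  img <- rgb_image(arr)
  base <- segment_fun01(img, fun01_params())
  # raising P3 can only remove vegetation
  tighter_p3 <- segment_fun01(img, fun01_params(p3 = 60))
  expect_true(all(!tighter_p3 | base))
  # lowering P1 or P2 can only remove vegetation
  tighter_p1 <- segment_fun01(img, fun01_params(p1 = 0.5))
  expect_true(all(!tighter_p1 | base))
  tighter_p2 <- segment_fun01(img, fun01_params(p2 = 0.5))
  expect_true(all(!tighter_p2 | base))
  # and the containments are strict somewhere on a random image this size
  expect_lt(sum(tighter_p3), sum(base))
})

test_that("the decision tree classifies single pixels by its ordering rules", {
  cases <- list(
    list(px = c(100, 150, 50), rule = "r1", veg = TRUE),    # green leaves
    list(px = c(50, 150, 100), rule = "r2", veg = TRUE),
    list(px = c(50, 100, 150), rule = "r3", veg = FALSE),   # cyan/blue stones
    list(px = c(120, 115, 112), rule = "r4", veg = TRUE),   # yellow leaves
    list(px = c(200, 150, 100), rule = "r5", veg = FALSE),  # soil, dead material
    list(px = c(150, 50, 100), rule = "r6", veg = TRUE),    # red flowers
    list(px = c(120, 90, 100), rule = "r7", veg = FALSE),   # soil
    list(px = c(100, 50, 150), rule = "r8", veg = TRUE),    # blue/purple flowers
    # R > B > G but in neither the r6 nor the r7 clause: the rule gap
    list(px = c(120, 60, 110), rule = "unmatched", veg = FALSE),
    # any tie defeats every strict ordering
    list(px = c(100, 100, 100), rule = "unmatched", veg = FALSE)
  )
  for (case in cases) {
    got <- classify_fun02_pixel(case$px)
    expect_identical(got$rule_id, case$rule, label = paste(case$px, collapse = ","))
    expect_identical(got$is_vegetation, case$veg, label = paste(case$px, collapse = ","))
  }
})

test_that("fun02 segments whole images and reports rule counts", {
  expect_equal(
    compute_fvc(segment_fun02(uniform_image(c(100, 150, 50))))$value, 100
  )
  expect_equal(
    compute_fvc(segment_fun02(uniform_image(c(150, 100, 50))))$value, 0
  )
  mixed <- half_half_image(c(100, 150, 50), c(150, 100, 50), h = 4, w = 4)
  mask <- segment_fun02(mixed)
  expect_equal(compute_fvc(mask)$value, 50)
  counts <- attr(mask, "rule_counts")
  expect_equal(unname(counts[c("r1", "r5")]), c(8L, 8L))
  expect_equal(sum(counts), 16L)
})

test_that("fun03 is vegetation strictly above the ExG - ExR zero line", {
  img <- image_from_pixels(list(
    c(50, 150, 50),    # difference 280
    c(100, 100, 100),  # difference -40
    c(0, 0, 0)         # difference exactly 0 -> background
  ))
  expect_equal(as.vector(segment_fun03(img)), c(TRUE, FALSE, FALSE))
})

test_that("fun03 labels depend only on the combined index value", {
  # two pixels with equal 15G - 12R - 5B must share a label
  set.seed(22)
  px <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  key <- 15 * px[, 2] - 12 * px[, 1] - 5 * px[, 3]
  img <- rgb_image(array(t(px), dim = c(3, nrow(px), 1)) |>
                     aperm(c(3, 2, 1)))
  labels <- as.vector(segment_fun03(img))
  for (k in unique(key)) {
    expect_length(unique(labels[key == k]), 1)
  }
})

test_that("otsu_threshold matches hand-checked splits and rejects constants", {
  expect_equal(otsu_threshold(c(rep(0, 50), rep(100, 50))), 0)
  expect_equal(otsu_threshold(c(rep(0, 90), rep(200, 10))), 0)
  expect_error(otsu_threshold(c(10, 10, 10)), "degenerate")
})

test_that("fun04 thresholds the ExG image and absorbs constant frames", {
  img <- half_half_image(c(50, 150, 50), c(120, 100, 90), h = 4, w = 4)
  mask <- segment_fun04(img)
  expect_equal(compute_fvc(mask)$value, 50)
  expect_true(all(mask[, 1:2]) && !any(mask[, 3:4]))
  t <- attr(mask, "otsu_threshold")
  expect_true(t >= -10 && t < 200)

  uniform <- uniform_image(c(80, 90, 100))
  umask <- segment_fun04(uniform)
  expect_equal(compute_fvc(umask)$value, 0)
  expect_true(is.na(attr(umask, "otsu_threshold")))
})

test_that("every algorithm labels every pixel at the input dimensions", {
  set.seed(23)
  img <- rgb_image(array(sample(0:255, 7 * 11 * 3, replace = TRUE), dim = c(7, 11, 3)))
  for (alg in c("fun01", "fun02", "fun03", "fun04")) {
    mask <- segment_image(img, alg)
    expect_identical(dim(mask), c(7L, 11L))
    expect_false(anyNA(mask))
    expect_type(as.logical(mask), "logical")
  }
  expect_identical(
    as.logical(segment_image(img, "FUN03")),
    as.logical(segment_fun03(img))
  )
})
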