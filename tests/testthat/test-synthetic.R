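test_that("the default palette is separable under all four algorithms", {
  pal <- default_palette()
  leaves <- pal$leaf_colors
  bg <- pal$background_colors
  for (i in seq_len(nrow(leaves))) {
    px <- leaves[i, ]
    img <- uniform_image(px, 1, 1)
    expect_true(as.vector(segment_fun01(img)), label = paste("fun01 leaf", i))
    expect_true(classify_fun02_pixel(px)$is_vegetation, label = paste("fun02 leaf", i))
    expect_true(as.vector(segment_fun03(img)), label = paste("fun03 leaf", i))
  }
  for (i in seq_len(nrow(bg))) {
    px <- bg[i, ]
    img <- uniform_image(px, 1, 1)
    expect_false(as.vector(segment_fun01(img)), label = paste("fun01 bg", i))
    expect_false(classify_fun02_pixel(px)$is_vegetation, label = paste("fun02 bg", i))
    expect_false(as.vector(segment_fun03(img)), label = paste("fun03 bg", i))
  }
})

test_that("generate_scene hits its coverage target and is seed-deterministic", {
  p <- scene_params(target_coverage = 0.25, scenario = "overcast",
                    noise_sd = 0, seed = 7)
  sc1 <- generate_scene(p)
  expect_true(abs(sc1$true_coverage / 100 - 0.25) <= 0.02)
  expect_equal(sc1$true_coverage, compute_fvc(sc1$truth)$value)
  sc2 <- generate_scene(p)
  expect_identical(unclass(sc1$image), unclass(sc2$image))
  expect_identical(as.logical(sc1$truth), as.logical(sc2$truth))
})

test_that("noise-free overcast scenes use only palette colours, split by truth", {
  p <- scene_params(target_coverage = 0.3, scenario = "overcast",
                    noise_sd = 0, seed = 9)
  sc <- generate_scene(p)
  pal <- p$palette
  img <- unclass(sc$image)
  cols <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  key <- paste(cols[, 1], cols[, 2], cols[, 3])
  leaf_key <- paste(pal$leaf_colors[, 1], pal$leaf_colors[, 2], pal$leaf_colors[, 3])
  bg_key <- paste(pal$background_colors[, 1], pal$background_colors[, 2],
                  pal$background_colors[, 3])
  veg <- as.vector(unclass(sc$truth))
  expect_true(all(key[veg] %in% leaf_key))
  expect_true(all(key[!veg] %in% bg_key))
})

test_that("scene parameters enforce their domain", {
  expect_error(scene_params(target_coverage = 0), "between 0 and 1")
  expect_error(scene_params(target_coverage = 1), "between 0 and 1")
  # overcast forces zero highlight and shadow
  p <- scene_params(scenario = "overcast", highlight_fraction = 0.5,
                    shadow_fraction = 0.5)
  expect_equal(p$highlight_fraction, 0)
  expect_equal(p$shadow_fraction, 0)
  # an unreachable target errors instead of looping forever
  tiny <- scene_params(target_coverage = 0.9, leaf_count_range = c(1, 3),
                       leaf_size_range = c(1, 2), seed = 5)
  expect_error(generate_scene(tiny), "target coverage")
})

test_that("illumination is identity for overcast and for zero fractions", {
  p <- scene_params(scenario = "overcast", noise_sd = 0, seed = 3)
  sc <- generate_scene(p)
  expect_identical(
    unclass(apply_illumination(sc$image, sc$truth, p)),
    unclass(sc$image)
  )
  noon0 <- scene_params(scenario = "noon", highlight_fraction = 0,
                        shadow_fraction = 0, noise_sd = 0, seed = 3)
  expect_identical(
    unclass(apply_illumination(sc$image, sc$truth, noon0)),
    unclass(sc$image)
  )
})

test_that("the shadow transform scales channels by 0.35 with half-away rounding", {
  img <- uniform_image(c(100, 150, 50), 8, 8)
  truth <- binary_mask(matrix(FALSE, 8, 8))
  p <- scene_params(scenario = "noon", highlight_fraction = 0,
                    shadow_fraction = 0.95, noise_sd = 0, seed = 4)
  out <- unclass(apply_illumination(img, truth, p))
  shadowed <- out[, , 1] == 35
  expect_gt(mean(shadowed), 0.9)  # the region covers at least the target share
  expect_true(all(out[, , 2][shadowed] == 53))  # 150 * 0.35 = 52.5 -> 53
  expect_true(all(out[, , 3][shadowed] == 18))  # 50 * 0.35 = 17.5 -> 18
})

test_that("illumination never alters the truth mask, only the image", {
  p <- scene_params(target_coverage = 0.3, scenario = "noon", seed = 13)
  sc <- generate_scene(p)
  overcast_twin <- scene_params(target_coverage = 0.3, scenario = "overcast",
                                noise_sd = 0, seed = 13)
  sc_o <- generate_scene(overcast_twin)
  expect_identical(as.logical(sc$truth), as.logical(sc_o$truth))
  expect_false(identical(unclass(sc$image), unclass(sc_o$image)))
})

test_that("batches are deterministic and sweep the coverage range", {
  base <- scene_params(scenario = "overcast", noise_sd = 0)
  b1 <- generate_batch(5, base, seed = 17)
  b2 <- generate_batch(5, base, seed = 17)
  expect_length(b1, 5)
  for (i in 1:5) {
    expect_identical(unclass(b1[[i]]$image), unclass(b2[[i]]$image))
    expect_true(abs(b1[[i]]$true_coverage / 100 -
                      b1[[i]]$params$target_coverage) <= 0.02)
  }
  covs <- vapply(b1, function(s) s$true_coverage, numeric(1))
  expect_true(all(diff(covs) > 0))  # monotone in the swept target

  single <- generate_batch(1, base, seed = 17)
  p1 <- base
  p1$target_coverage <- 0.05
  p1$seed <- single[[1]]$params$seed
  expect_identical(unclass(single[[1]]$image), unclass(generate_scene(p1)$image))
})

test_that("write_scenes exports image/truth pairs with a manifest", {
  dir <- withr::local_tempdir()
  base <- scene_params(height = 32, width = 32, scenario = "overcast",
                       noise_sd = 0)
  scenes <- generate_batch(2, base, seed = 19)
  manifest <- write_scenes(scenes, dir)
  expect_true(all(file.exists(file.path(
    dir, c("scene_0001.png", "scene_0001_truth.png",
           "scene_0002.png", "scene_0002_truth.png", "manifest.csv")
  ))))
  back <- read_image(file.path(dir, "scene_0001.png"))
  expect_identical(unclass(back), unclass(scenes[[1]]$image))
  tback <- read_mask(file.path(dir, "scene_0002_truth.png"))
  expect_identical(as.logical(tback), as.logical(scenes[[2]]$truth))
  stored <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(stored$true_coverage, manifest$true_coverage)
})
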