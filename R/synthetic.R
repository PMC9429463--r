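#' Default scene palette
#'
#' Leaf greens and soil/rock/litter background colours chosen so that, in a
#' noise-free overcast rendering, every leaf colour is classified vegetation
#' and every background colour background by all four algorithms. That
#' separability is what makes the generator's ground truth exactly
#' recoverable, and it is asserted by the test suite. Two leaf tones are
#' deliberately placed so that a specular highlight pushes them across an
#' algorithm's decision boundary (one across the excess-green threshold of the
#' ratio algorithm, one onto a channel tie that the decision tree cannot
#' order), which is what degrades sunlit scenes.
#'
#' @return A list of class `"fvc_palette"` with matrices `leaf_colors` and
#'   `background_colors` (rows are RGB triples).
#' @export
default_palette <- function() {
  structure(
    list(
      leaf_colors = rbind(
        c(45, 120, 60),    # mid green
        c(70, 150, 55),    # grass green
        c(30, 100, 45),    # dark green
        c(90, 170, 80),    # bright green
        c(55, 135, 75),    # blue-green
        c(150, 175, 100),  # yellow-green: highlight pushes R/G past 0.95
        c(118, 180, 119)   # pale lime: highlight collapses R and B to a tie
      ),
      background_colors = rbind(
        c(140, 110, 85),   # soil brown
        c(90, 70, 55),     # dark soil
        c(180, 150, 115),  # straw litter
        c(165, 140, 110),  # warm grey stone
        c(130, 105, 75)    # dark taupe stone
      )
    ),
    class = "fvc_palette"
  )
}

#' Palette with a lichen-like confounder
#'
#' Adds a light, slightly greenish background patch colour whose excess-green
#' value sits between soil and foliage. The ratio algorithm rejects it
#' (`R/G >= 0.95`) but Otsu thresholding of the ExG histogram tends to absorb
#' it into the vegetation class, reproducing the characteristic failure of
#' automatic thresholding on pale green ground cover.
#'
#' @return A list of class `"fvc_palette"`.
#' @export
hard_palette <- function() {
  p <- default_palette()
  p$background_colors <- rbind(p$background_colors, c(130, 135, 75))
  p
}

#' Synthetic scene parameters
#'
#' Describes one rendered nadir scene: frame size, target coverage, the
#' illumination scenario, leaf-blob geometry, colour palette, sensor noise and
#' the scenario's highlight/shadow extent.
#'
#' Scenario defaults mirror the three field conditions: `overcast` is diffuse
#' light (no highlights, no shadows — the invariant of the scenario, so both
#' fractions are forced to zero); `forenoon` is low-angle sun (long cast
#' shadows, moderate specular highlight: defaults 0.25 / 0.10); `noon` is
#' high sun (smaller shadows, stronger highlight: defaults 0.15 / 0.20).
#'
#' @param height,width Frame size in pixels.
#' @param target_coverage True vegetation fraction to aim for, in (0, 1). The
#'   generator hits it within 2 percentage points.
#' @param scenario One of `"overcast"`, `"forenoon"`, `"noon"`.
#' @param leaf_count_range Soft lower bound and hard upper bound on the number
#'   of leaf blobs placed.
#' @param leaf_size_range Range of ellipse semi-axes, pixels.
#' @param palette A palette from [default_palette()] or [hard_palette()].
#' @param noise_sd Standard deviation of additive Gaussian channel noise, DN.
#' @param highlight_fraction Fraction of vegetation pixels receiving a
#'   specular highlight (sunlit scenarios only).
#' @param shadow_fraction Fraction of the frame covered by cast shadow
#'   (sunlit scenarios only).
#' @param seed Integer seed; every random draw in the scene derives from it.
#' @return A list of class `"scene_params"`.
#' @export
scene_params <- function(height = 256, width = 256,
                         target_coverage = 0.30,
                         scenario = c("overcast", "forenoon", "noon"),
                         leaf_count_range = c(10, 5000),
                         leaf_size_range = c(4, 22),
                         palette = default_palette(),
                         noise_sd = 2,
                         highlight_fraction = NULL,
                         shadow_fraction = NULL,
                         seed = 1L) {
  scenario <- match.arg(scenario)
  if (!(target_coverage > 0 && target_coverage < 1)) {
    stop("target_coverage must lie strictly between 0 and 1", call. = FALSE)
  }
  if (height < 1 || width < 1) stop("frame must be at least 1 x 1", call. = FALSE)
  if (is.null(highlight_fraction)) {
    highlight_fraction <- switch(scenario, overcast = 0, forenoon = 0.10, noon = 0.20)
  }
  if (is.null(shadow_fraction)) {
    shadow_fraction <- switch(scenario, overcast = 0, forenoon = 0.25, noon = 0.15)
  }
  if (scenario == "overcast") {
    highlight_fraction <- 0
    shadow_fraction <- 0
  }
  if (highlight_fraction < 0 || highlight_fraction >= 1 ||
      shadow_fraction < 0 || shadow_fraction >= 1) {
    stop("highlight_fraction and shadow_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      target_coverage = target_coverage, scenario = scenario,
      leaf_count_range = leaf_count_range, leaf_size_range = leaf_size_range,
      palette = palette, noise_sd = noise_sd,
      highlight_fraction = highlight_fraction,
      shadow_fraction = shadow_fraction,
      seed = as.integer(seed)
    ),
    class = "scene_params"
  )
}

# Linear indices of the pixels of a rotated ellipse clipped to an h x w frame.
ellipse_pixels <- function(h, w, cx, cy, ax, ay, theta) {
  r <- max(ax, ay)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1
  ys <- y0:y1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, length(ys), length(xs)) - cy
  ct <- cos(theta); st <- sin(theta)
  U <- X * ct + Y * st
  V <- -X * st + Y * ct
  inside <- (U / ax)^2 + (V / ay)^2 <= 1
  rows <- matrix(ys, length(ys), length(xs))[inside]
  cols <- matrix(xs, length(ys), length(xs), byrow = TRUE)[inside]
  (cols - 1L) * h + rows
}

# Paint an RGB triple at linear pixel indices of an h x w x 3 array.
paint <- function(img, idx, color) {
  hw <- dim(img)[1] * dim(img)[2]
  img[idx] <- color[1]
  img[idx + hw] <- color[2]
  img[idx + 2L * hw] <- color[3]
  img
}

#' Render one synthetic vegetation scene
#'
#' Paints a soil/rock/litter background mosaic, overlays elliptical leaf blobs
#' until the ground-truth coverage first reaches the target (shrinking the
#' final blob if it would overshoot by more than 2 percentage points), applies
#' the scenario's illumination transform, and adds Gaussian channel noise.
#' The truth mask records exactly the painted leaf pixels and is never touched
#' by illumination or noise. The whole scene is a deterministic function of
#' `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `"synthetic_scene"` with elements `image`
#'   ([rgb_image()]), `truth` ([binary_mask()]), `params`, and `true_coverage`
#'   (percent).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$height; w <- params$width
  total <- h * w
  pal <- params$palette

  withr::with_seed(derive_seed(params$seed, 1L), {
    # background mosaic: base soil plus random patches of the other colours
    img <- array(0, dim = c(h, w, 3))
    img <- paint(img, seq_len(total), pal$background_colors[1, ])
    n_patch <- max(8L, round(total / 2000))
    for (k in seq_len(n_patch)) {
      col <- pal$background_colors[sample.int(nrow(pal$background_colors), 1L), ]
      idx <- ellipse_pixels(
        h, w,
        cx = stats::runif(1, 1, w), cy = stats::runif(1, 1, h),
        ax = stats::runif(1, 8, max(12, w / 6)),
        ay = stats::runif(1, 8, max(12, h / 6)),
        theta = stats::runif(1, 0, pi)
      )
      if (length(idx)) img <- paint(img, idx, col)
    }

    # leaf blobs until the truth mask first reaches the target coverage
    truth <- matrix(FALSE, h, w)
    target <- params$target_coverage
    max_blobs <- params$leaf_count_range[2]
    blobs <- 0L
    while (sum(truth) / total < target) {
      blobs <- blobs + 1L
      if (blobs > max_blobs) {
        stop(sprintf(
          "could not reach target coverage %.2f within %d leaf blobs; widen leaf_size_range or leaf_count_range",
          target, max_blobs
        ), call. = FALSE)
      }
      col <- pal$leaf_colors[sample.int(nrow(pal$leaf_colors), 1L), ]
      cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
      ax <- stats::runif(1, params$leaf_size_range[1], params$leaf_size_range[2])
      ay <- stats::runif(1, params$leaf_size_range[1], params$leaf_size_range[2])
      theta <- stats::runif(1, 0, pi)
      idx <- ellipse_pixels(h, w, cx, cy, ax, ay, theta)
      if (!length(idx)) next
      # shrink the final blob rather than overshoot the 2-point tolerance
      repeat {
        new_cov <- sum(truth[idx] == FALSE) + sum(truth)
        if (new_cov / total <= target + 0.02 || ax <= 1 || ay <= 1) break
        ax <- ax * 0.85
        ay <- ay * 0.85
        idx <- ellipse_pixels(h, w, cx, cy, ax, ay, theta)
        if (!length(idx)) break
      }
      if (!length(idx)) next
      img <- paint(img, idx, col)
      truth[idx] <- TRUE
    }
  })

  truth <- binary_mask(truth)
  image <- rgb_image(img)
  image <- apply_illumination(image, truth, params)

  if (params$noise_sd > 0) {
    withr::with_seed(derive_seed(params$seed, 3L), {
      noisy <- unclass(image) + stats::rnorm(length(image), 0, params$noise_sd)
      image <- rgb_image(clip_dn(round_half_away(noisy)))
    })
  }

  structure(
    list(
      image = image,
      truth = truth,
      params = params,
      true_coverage = compute_fvc(truth)$value
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d, scenario %s, true coverage %.2f%%, seed %d\n",
    x$params$height, x$params$width, x$params$scenario, x$true_coverage,
    x$params$seed
  ))
  invisible(x)
}

#' Apply the scenario's illumination transform
#'
#' Overcast scenes pass through unchanged (diffuse light). Sunlit scenarios
#' apply, in order: (a) a specular highlight — a random subset of vegetation
#' pixels of size `highlight_fraction * vegetation count` has each channel
#' moved 70% of the way to 255, emulating sunlit leaves washing out toward
#' the brightness of pale soil; (b) a cast shadow — a union of random
#' elongated blobs covering `shadow_fraction` of the frame has every channel
#' scaled by 0.35, emulating leaves and background lost in mutual-occlusion
#' shadow. Fractional results are rounded half away from zero and clipped to
#' `[0, 255]`. The truth mask is never modified. Draws are keyed off
#' `params$seed`, so the transform is deterministic.
#'
#' @param image An [rgb_image()].
#' @param truth The scene's ground-truth [binary_mask()] (highlights apply
#'   only to vegetation pixels).
#' @param params A [scene_params()] object.
#' @return The transformed [rgb_image()].
#' @export
apply_illumination <- function(image, truth, params) {
  stopifnot(inherits(image, "rgb_image"), inherits(params, "scene_params"))
  if (!all(dim(truth) == dim(image)[1:2])) {
    stop("truth mask and image dimensions must agree", call. = FALSE)
  }
  if (params$scenario == "overcast") return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  hw <- h * w
  img <- unclass(image) * 1.0  # numeric copy

  withr::with_seed(derive_seed(params$seed, 2L), {
    veg_idx <- which(unclass(truth))
    n_high <- round(params$highlight_fraction * length(veg_idx))
    if (n_high > 0) {
      hi <- sample(veg_idx, n_high)
      for (ch in 0:2) {
        at <- hi + ch * hw
        img[at] <- clip_dn(round_half_away(img[at] + 0.7 * (255 - img[at])))
      }
    }
    if (params$shadow_fraction > 0) {
      shadow <- matrix(FALSE, h, w)
      attempts <- 0L
      while (sum(shadow) / hw < params$shadow_fraction && attempts < 500L) {
        attempts <- attempts + 1L
        idx <- ellipse_pixels(
          h, w,
          cx = stats::runif(1, 1, w), cy = stats::runif(1, 1, h),
          ax = stats::runif(1, max(4, w / 8), max(8, w / 2)),
          ay = stats::runif(1, 2, max(4, h / 10)),
          theta = stats::runif(1, 0, pi)
        )
        shadow[idx] <- TRUE
      }
      sh <- which(shadow)
      for (ch in 0:2) {
        at <- sh + ch * hw
        img[at] <- clip_dn(round_half_away(img[at] * 0.35))
      }
    }
  })

  rgb_image(img)
}

#' Generate a batch of scenes
#'
#' Renders `n` scenes whose target coverages are spread evenly across
#' `coverage_range`, each with a per-scene seed derived deterministically from
#' the batch seed. This is the synthetic counterpart of a field campaign's
#' photo set for one illumination scenario.
#'
#' @param n Number of scenes.
#' @param base_params A [scene_params()] template; its coverage and seed are
#'   overridden per scene.
#' @param seed Batch seed.
#' @param coverage_range Range of target coverages (default 0.05 to 0.60,
#'   spanning sparse to dense herbaceous cover).
#' @return A list of [generate_scene()] results.
#' @export
generate_batch <- function(n, base_params, seed, coverage_range = c(0.05, 0.60)) {
  stopifnot(inherits(base_params, "scene_params"), n >= 1)
  coverages <- seq(coverage_range[1], coverage_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    p <- base_params
    p$target_coverage <- coverages[i]
    p$seed <- derive_seed(seed, i)
    generate_scene(p)
  })
}

#' Export scenes as paired image/truth PNG files with a manifest
#'
#' Writes `scene_0001.png` / `scene_0001_truth.png` pairs plus
#' `manifest.csv` (columns `scene_id`, `scenario`, `seed`, `true_coverage`).
#'
#' @param scenes A list of scenes from [generate_batch()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_scenes <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    scene_id = sprintf("scene_%04d", seq_along(scenes)),
    scenario = vapply(scenes, function(s) s$params$scenario, character(1)),
    seed = vapply(scenes, function(s) s$params$seed, integer(1)),
    true_coverage = vapply(scenes, function(s) s$true_coverage, numeric(1))
  )
  for (i in seq_along(scenes)) {
    png::writePNG(
      unclass(scenes[[i]]$image) / 255,
      file.path(dir, paste0(manifest$scene_id[i], ".png"))
    )
    write_mask(scenes[[i]]$truth, file.path(dir, paste0(manifest$scene_id[i], "_truth.png")))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
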