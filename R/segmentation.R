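#' Excess green index (ExG)
#'
#' `ExG = 2G - B - R`, computed per pixel in integer arithmetic. Green foliage
#' scores high; soil, rock and litter score near zero or negative. Values lie
#' in `[-510, 510]`.
#'
#' @param image An [rgb_image()].
#' @return An integer matrix of index values.
#' @export
compute_exg <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  x <- unclass(image)
  2L * channel(x, 2) - channel(x, 3) - channel(x, 1)
}

#' Excess red index (ExR)
#'
#' `ExR = 1.4R - G`, high for reddish soil and litter. The value is evaluated
#' exactly as the rational `(7R - 5G) / 5` so that downstream sign tests do not
#' depend on binary floating-point representation of 1.4.
#'
#' @param image An [rgb_image()].
#' @return A numeric matrix of index values.
#' @export
compute_exr <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  x <- unclass(image)
  (7L * channel(x, 1) - 5L * channel(x, 2)) / 5
}

#' Parameters for the ratio/excess-green algorithm
#'
#' @param p1 Threshold on `R/G` (unitless, default 0.95).
#' @param p2 Threshold on `B/G` (unitless, default 0.95).
#' @param p3 Threshold on `2G - R - B` (DN units, default 20).
#' @return A list of class `"fun01_params"`.
#' @export
fun01_params <- function(p1 = 0.95, p2 = 0.95, p3 = 20) {
  if (p1 <= 0 || p2 <= 0) stop("p1 and p2 must be positive", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, p3 = p3), class = "fun01_params")
}

#' Fun01: ratio and excess-green thresholding
#'
#' A pixel is vegetation iff `R/G < P1`, `B/G < P2` and `2G - R - B > P3`
#' (all strict, as the criteria are written). Pixels with `G = 0` have
#' undefined ratios and are labelled background: a pixel with no green signal
#' cannot be green vegetation.
#'
#' @param image An [rgb_image()].
#' @param params A [fun01_params()] object.
#' @return A [binary_mask()].
#' @export
segment_fun01 <- function(image, params = fun01_params()) {
  stopifnot(inherits(image, "rgb_image"), inherits(params, "fun01_params"))
  x <- unclass(image)
  R <- channel(x, 1); G <- channel(x, 2); B <- channel(x, 3)
  veg <- G > 0L & R / G < params$p1 & B / G < params$p2 &
    (2L * G - R - B) > params$p3
  binary_mask(veg)
}

# Fun02 decision-tree rule table: id, plain-language class, vegetation flag.
fun02_rules <- data.frame(
  rule_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "r8", "unmatched"),
  semantic = c(
    "green leaves (incl. peak-green and olivine leaves)",
    "blackish-green, reflective or light-coloured leaves",
    "cyan or blue stones",
    "yellow leaves",
    "soil, dead wood or dead leaves",
    "red flowers or red leaves",
    "soil",
    "blue or purple flowers",
    "no strict channel ordering matched"
  ),
  is_vegetation = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

# Vectorised first-match rule assignment over channel matrices.
# Returns an integer matrix of rule indices (1..8, 9 = unmatched).
fun02_rule_index <- function(R, G, B) {
  idx <- array(9L, dim = dim(R))
  idx[G > R & R > B] <- 1L                                  # r1
  idx[G > B & B > R] <- 2L                                  # r2
  idx[B > G & G > R] <- 3L                                  # r3
  rgb_ord <- R > G & G > B
  idx[rgb_ord & abs(R - B) <= 10L] <- 4L                    # r4
  idx[rgb_ord & abs(R - B) > 10L] <- 5L                     # r5
  rbg_ord <- R > B & B > G
  idx[rbg_ord & (R - B) > 40L & (R - G) > 40L] <- 6L        # r6
  idx[rbg_ord & abs(R - B) < 40L & abs(R - G) < 40L] <- 7L  # r7
  idx[B > R & R > G] <- 8L                                  # r8
  idx
}

#' Classify one pixel with the RGB decision tree
#'
#' Applies the eight strict-ordering colour rules of the decision-tree
#' algorithm to a single `(R, G, B)` triple. Pixels matching no rule (any two
#' channels tied, or an `R > B > G` pixel falling in the gap between the
#' red-flower and soil clauses) are labelled `unmatched` and treated as
#' background.
#'
#' @param pixel Numeric vector `c(R, G, B)` with values in 0..255.
#' @return A list with `rule_id` (one of `r1`..`r8`, `unmatched`), a
#'   human-readable `semantic`, and the `is_vegetation` flag.
#' @examples
#' classify_fun02_pixel(c(100, 150, 50))  # r1, green leaves
#' classify_fun02_pixel(c(200, 150, 100)) # r5, soil / dead material
#' @export
classify_fun02_pixel <- function(pixel) {
  if (length(pixel) != 3L || anyNA(pixel) || any(pixel < 0 | pixel > 255)) {
    stop("pixel must be an (R, G, B) triple with values in [0, 255]", call. = FALSE)
  }
  i <- fun02_rule_index(
    matrix(pixel[1], 1, 1), matrix(pixel[2], 1, 1), matrix(pixel[3], 1, 1)
  )[1, 1]
  as.list(fun02_rules[i, ])
}

#' Fun02: RGB decision-tree segmentation
#'
#' Labels each pixel by the first matching channel-ordering rule and maps the
#' leaf-and-flower rules (`r1`, `r2`, `r4`, `r6`, `r8`) to vegetation, the
#' stone/soil rules (`r3`, `r5`, `r7`) and unmatched pixels to background.
#' Per-rule pixel counts are attached as attribute `"rule_counts"` for
#' diagnostics.
#'
#' @param image An [rgb_image()].
#' @return A [binary_mask()] with a `"rule_counts"` attribute (named integer
#'   vector over `r1`..`r8`, `unmatched`).
#' @export
segment_fun02 <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  x <- unclass(image)
  idx <- fun02_rule_index(channel(x, 1), channel(x, 2), channel(x, 3))
  veg_rule <- fun02_rules$is_vegetation
  mask <- binary_mask(array(veg_rule[idx], dim = dim(idx)))
  counts <- tabulate(idx, nbins = 9L)
  names(counts) <- fun02_rules$rule_id
  attr(mask, "rule_counts") <- counts
  mask
}

#' Fun03: excess-green minus excess-red segmentation
#'
#' A pixel is vegetation iff `ExG - ExR > 0` strictly; the index is
#' self-thresholding at zero. The sign test is carried out on the integer
#' `5 * (ExG - ExR) = 15G - 12R - 5B`, which is exact for 8-bit inputs.
#'
#' @param image An [rgb_image()].
#' @return A [binary_mask()].
#' @export
segment_fun03 <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  x <- unclass(image)
  R <- channel(x, 1); G <- channel(x, 2); B <- channel(x, 3)
  binary_mask(15L * G - 12L * R - 5L * B > 0L)
}

#' Otsu's threshold over an index-value collection
#'
#' Returns the threshold `t` maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split `{v <= t}` vs `{v > t}`, with `t`
#' ranging over the observed distinct values and ties broken by the smallest
#' `t`. The histogram is taken over the exact observed values (for ExG, up to
#' 1021 integer levels), not a rebinned 256-level version.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return The maximising threshold (one of the observed values).
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  if (anyNA(v)) stop("values must not contain NA", call. = FALSE)
  vs <- sort(unique(v))
  if (length(vs) < 2L) {
    stop("degenerate input: Otsu thresholding needs at least two distinct values",
         call. = FALSE)
  }
  counts <- tabulate(match(v, vs), nbins = length(vs))
  n <- length(v)
  S <- sum(v)
  n0 <- cumsum(counts)
  S0 <- cumsum(vs * counts)
  # between-class variance, up to the constant factor 1/n^2:
  # w0 w1 (mu0 - mu1)^2 = (n S0 - n0 S)^2 / (n0 (n - n0) n^2)
  D <- n * S0 - n0 * S
  bcv <- D^2 / (n0 * (n - n0))
  bcv <- bcv[-length(bcv)]  # split with an empty upper class is no split
  vs[which.max(bcv)]
}

#' Fun04: excess-green with Otsu thresholding
#'
#' Computes the ExG image, finds the Otsu threshold `t` over its exact value
#' histogram, and labels pixels with `ExG > t` as vegetation. A constant-ExG
#' image carries no separable vegetation signal and yields an all-background
#' mask instead of an error, so batch runs never abort on degenerate frames.
#'
#' @param image An [rgb_image()].
#' @return A [binary_mask()] with the threshold attached as attribute
#'   `"otsu_threshold"` (`NA` for a constant-ExG image).
#' @export
segment_fun04 <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  exg <- compute_exg(image)
  if (length(unique(as.vector(exg))) < 2L) {
    mask <- binary_mask(array(FALSE, dim = dim(exg)))
    attr(mask, "otsu_threshold") <- NA_real_
    return(mask)
  }
  t <- otsu_threshold(as.vector(exg))
  mask <- binary_mask(exg > t)
  attr(mask, "otsu_threshold") <- t
  mask
}

#' Run a segmentation algorithm by identifier
#'
#' Dispatches to one of the four algorithms by its case-insensitive identifier
#' `fun01`, `fun02`, `fun03` or `fun04`.
#'
#' @param image An [rgb_image()].
#' @param algorithm Algorithm identifier.
#' @param params [fun01_params()] used when `algorithm = "fun01"`.
#' @return A [binary_mask()].
#' @export
segment_image <- function(image, algorithm, params = fun01_params()) {
  alg <- match.arg(tolower(algorithm), c("fun01", "fun02", "fun03", "fun04"))
  switch(alg,
    fun01 = segment_fun01(image, params),
    fun02 = segment_fun02(image),
    fun03 = segment_fun03(image),
    fun04 = segment_fun04(image)
  )
}
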