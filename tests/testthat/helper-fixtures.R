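# Shared fixture builders: tiny images built in code, no stored binaries.

# An image from an explicit list of RGB triples, recycled over h x w pixels.
image_from_pixels <- function(triples, h = 1, w = length(triples)) {
  stopifnot(length(triples) == h * w)
  arr <- array(0, dim = c(h, w, 3))
  for (i in seq_along(triples)) {
    row <- ((i - 1) %% h) + 1
    col <- ((i - 1) %/% h) + 1
    arr[row, col, ] <- triples[[i]]
  }
  rgb_image(arr)
}

# A uniform h x w image of a single colour.
uniform_image <- function(rgb, h = 4, w = 4) {
  arr <- array(rep(rgb, each = h * w), dim = c(h, w, 3))
  rgb_image(arr)
}

# An image whose left half is one colour and right half another.
half_half_image <- function(rgb_left, rgb_right, h = 4, w = 4) {
  stopifnot(w %% 2 == 0)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    arr[, 1:(w / 2), ch] <- rgb_left[ch]
    arr[, (w / 2 + 1):w, ch] <- rgb_right[ch]
  }
  rgb_image(arr)
}

# Brute-force Otsu oracle: for every candidate split, compute the
# between-class variance w0 * w1 * (mu0 - mu1)^2 from scratch by subsetting;
# smallest maximiser wins. Independent of the cumulative-histogram code path.
otsu_brute_force <- function(v) {
  v <- as.numeric(v)
  vs <- sort(unique(v))
  n <- length(v)
  S <- sum(v)
  cand <- vs[-length(vs)]
  best_t <- NA_real_
  best <- -Inf
  for (t in cand) {
    lo <- v[v <= t]
    n0 <- length(lo)
    D <- n * sum(lo) - n0 * S
    bcv <- D^2 / (n0 * (n - n0))
    if (bcv > best) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}
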