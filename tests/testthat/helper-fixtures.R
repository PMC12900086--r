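# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures are stored.

# image with every pixel the same RGB triplet
uniform_image <- function(rgb, h = 2L, w = 2L) {
  rgb_image(array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3L)))
}

# image from an explicit list of (r, g, b) rows laid out along one row
pixel_strip <- function(triplets) {
  n <- length(triplets)
  arr <- array(0L, dim = c(1L, n, 3L))
  for (i in seq_len(n)) arr[1L, i, ] <- as.integer(triplets[[i]])
  rgb_image(arr)
}

# scalar reference implementation of the discriminant classification:
# plain loop, no vectorization, independent of the package's code path
oracle_classify <- function(r, g, threshold = 134) {
  n <- length(r)
  out <- logical(n)
  for (i in seq_len(n)) {
    s <- r[i] + g[i]
    idx <- if (s == 0) 128 else 128 + 128 * (g[i] - r[i]) / s
    out[i] <- idx >= threshold
  }
  out
}

# element-wise loop reference for the agreement statistics
oracle_accuracy <- function(e, o) {
  n <- length(e)
  se <- 0; sa <- 0; sb <- 0
  for (i in seq_len(n)) {
    d <- e[i] - o[i]
    se <- se + d^2; sa <- sa + abs(d); sb <- sb + d
  }
  me <- sum(e) / n; mo <- sum(o) / n
  ve <- 0; vo <- 0; cv <- 0
  for (i in seq_len(n)) {
    ve <- ve + (e[i] - me)^2
    vo <- vo + (o[i] - mo)^2
    cv <- cv + (e[i] - me) * (o[i] - mo)
  }
  ve <- ve / n; vo <- vo / n; cv <- cv / n
  list(rmse = sqrt(se / n), mae = sa / n, bias = sb / n,
       r_squared = cv^2 / (ve * vo),
       ccc = 2 * cv / (ve + vo + (me - mo)^2))
}
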