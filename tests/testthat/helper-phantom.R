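# Shared fixture builders. Everything is generated in code; no binary files.

straight_params <- function(seed = 1, jitter_px = 0L, speck_rate = 0L, ...) {
  phantom_params(curve_coeffs = c(256, 0, 0, 0, 0), jitter_px = jitter_px,
                 speck_rate = speck_rate, seed = seed, ...)
}

# Quick synthetic binary vector: bodies of the given run lengths separated by
# the given gap widths, padded with background.
profile_vector <- function(bodies, gaps, lead = 100L) {
  v <- integer(0)
  for (i in seq_along(bodies)) {
    v <- c(v, rep(1L, bodies[i]))
    if (i <= length(gaps)) v <- c(v, rep(0L, gaps[i]))
  }
  c(rep(0L, lead), v, rep(0L, 1024L - lead - length(v)))
}

# Plain polynomial evaluation, independent of the package internals.
polyval_test <- function(coeffs, y) {
  out <- 0
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * y^(k - 1)
  out
}

# Brute-force AUC: count positive-negative score pairs (ties weigh 1/2).
auc_brute <- function(ratios, truth) {
  pos <- -ratios[truth]
  neg <- -ratios[!truth]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
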