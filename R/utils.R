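#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed clinical tables round half
#' away from zero (81.55 -> 81.6). Used everywhere a value is compared against
#' a printed figure.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Evaluate a polynomial with coefficients c0..c_n at y (Horner).
polyval <- function(coeffs, y) {
  out <- rep(coeffs[length(coeffs)], length(y))
  for (k in seq(length(coeffs) - 1L, 1L)) out <- out * y + coeffs[k]
  out
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# md5 of the canonical JSON serialization of a config list (no digest pkg here)
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
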