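#' Parameters for the synthetic spine phantom
#'
#' The phantom emulates the segmentation masks the pipeline consumes: a chain
#' of `n_vertebrae` quadrilateral vertebral bodies laid out down a 1024 x 512
#' canvas (rows = the spine axis) along a gently curved 4th-order polynomial
#' centerline, separated by inter-body gaps (the intervertebral disc spaces).
#' A stated fraction of gaps is narrowed by a multiplicative factor; optional
#' boundary jitter and small spurious foreground specks exercise the
#' downstream filters.
#'
#' Defaults describe a mid-size small-breed lateral study: ~10 vertebral
#' bodies of 60-90 rows with normal disc spaces of 8-18 rows (the paper-scale
#' quantified widths span roughly 2-20 px), a narrowed prevalence of 0.25
#' (the clinical validation set carried 65/294 = 22% narrowed sites) and a
#' narrowing factor drawn from 0.3-0.7.
#'
#' @param n_vertebrae integer number of vertebral bodies (6-16).
#' @param body_length_px length-2 range (rows) of vertebral body extent along
#'   the spine axis.
#' @param body_height_px length-2 range (columns) of body extent perpendicular
#'   to the axis.
#' @param gap_width_px length-2 range (rows) of normal gap widths.
#' @param narrowed_fraction probability in `[0,1]` that a gap is narrowed.
#' @param narrowing_factor multiplier in (0,1) applied to a narrowed gap's
#'   width; a scalar or a length-2 range sampled per gap.
#' @param curve_coeffs optional fixed centerline coefficients `c0..c4` of
#'   `x(y) = sum c_k y^k` (row `y` in 0..1023); random gentle curvature when
#'   `NULL`.
#' @param jitter_px integer boundary noise amplitude (columns).
#' @param speck_rate number of small (1-9 px) spurious foreground components.
#' @param annotate paint gap rows with training labels 2 (normal) / 3
#'   (narrowed) in the rendered mask.
#' @param seed RNG seed; identical seed and parameters give bit-identical
#'   output.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(n_vertebrae = 10L,
                           body_length_px = c(60, 90),
                           body_height_px = c(120, 180),
                           gap_width_px = c(8, 18),
                           narrowed_fraction = 0.25,
                           narrowing_factor = c(0.3, 0.7),
                           curve_coeffs = NULL,
                           jitter_px = 1L,
                           speck_rate = 2L,
                           annotate = TRUE,
                           seed = NULL) {
  chk_range <- function(x, name) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || any(!is.finite(x)) || any(x <= 0) || x[1] > x[2])
      stop(sprintf("'%s' must be a strictly positive range c(lo, hi)", name),
           call. = FALSE)
    x
  }
  n_vertebrae <- stopifnot_scalar_count(n_vertebrae, "n_vertebrae", min = 2L)
  body_length_px <- chk_range(body_length_px, "body_length_px")
  body_height_px <- chk_range(body_height_px, "body_height_px")
  gap_width_px <- chk_range(gap_width_px, "gap_width_px")
  if (!is.numeric(narrowed_fraction) || length(narrowed_fraction) != 1L ||
      narrowed_fraction < 0 || narrowed_fraction > 1)
    stop("'narrowed_fraction' must be in [0,1]", call. = FALSE)
  nf <- narrowing_factor
  if (length(nf) == 1L) nf <- c(nf, nf)
  if (length(nf) != 2L || any(nf <= 0) || any(nf >= 1) || nf[1] > nf[2])
    stop("'narrowing_factor' must lie in (0,1)", call. = FALSE)
  if (!is.null(curve_coeffs) && length(curve_coeffs) != 5L)
    stop("'curve_coeffs' must be five coefficients c0..c4", call. = FALSE)
  structure(list(
    n_vertebrae = n_vertebrae,
    body_length_px = body_length_px,
    body_height_px = body_height_px,
    gap_width_px = gap_width_px,
    narrowed_fraction = narrowed_fraction,
    narrowing_factor = nf,
    curve_coeffs = curve_coeffs,
    jitter_px = as.integer(jitter_px),
    speck_rate = as.integer(speck_rate),
    annotate = isTRUE(annotate),
    seed = seed
  ), class = "phantom_params")
}

PHANTOM_H <- 1024L
PHANTOM_W <- 512L
PHANTOM_MARGIN <- 12L

# Draw body/gap row layout from the current RNG stream. Rows are 0-based,
# intervals half-open.
draw_layout <- function(p) {
  n <- p$n_vertebrae
  L <- sample(seq(p$body_length_px[1], p$body_length_px[2]), n, replace = TRUE)
  hgt <- sample(seq(p$body_height_px[1], p$body_height_px[2]), n, replace = TRUE)
  g <- sample(seq(p$gap_width_px[1], p$gap_width_px[2]), n - 1L, replace = TRUE)
  narrowed <- runif(n - 1L) < p$narrowed_fraction
  if (any(narrowed)) {
    f <- runif(sum(narrowed), p$narrowing_factor[1], p$narrowing_factor[2])
    g[narrowed] <- pmax(1L, as.integer(round_half_up(g[narrowed] * f)))
  }
  total <- sum(L) + sum(g)
  max_start <- PHANTOM_H - PHANTOM_MARGIN - total
  if (max_start < PHANTOM_MARGIN)
    stop(sprintf(
      "infeasible phantom geometry: %d body+gap rows exceed the %d-row canvas",
      total, PHANTOM_H), call. = FALSE)
  start <- sample(seq(PHANTOM_MARGIN, max_start), 1L)
  body_start <- integer(n)
  gap_start <- integer(n - 1L)
  pos <- start
  for (i in seq_len(n)) {
    body_start[i] <- pos
    pos <- pos + L[i]
    if (i < n) {
      gap_start[i] <- pos
      pos <- pos + g[i]
    }
  }
  list(
    bodies = data.frame(body_index = seq_len(n), start_row = body_start,
                        end_row = body_start + L, height_px = hgt),
    gaps = data.frame(gap_index = seq_len(n - 1L), start_row = gap_start,
                      end_row = gap_start + g, width_px = g,
                      label = ifelse(narrowed, "narrowed", "normal"),
                      stringsAsFactors = FALSE)
  )
}

# Random gentle 4th-order centerline: exact quartic through five jittered
# control points, rejected (rarely) if it wanders more than 120 px off-centre.
draw_curve_coeffs <- function() {
  tgrid <- seq(0, 1, length.out = 256)
  for (trial in 1:50) {
    tc <- c(0, 0.25, 0.5, 0.75, 1)
    xc <- PHANTOM_W / 2 + runif(5, -45, 45)
    b <- solve(outer(tc, 0:4, `^`), xc)
    if (max(abs(polyval(b, tgrid) - PHANTOM_W / 2)) <= 120)
      return(b / 1023^(0:4))
  }
  c(PHANTOM_W / 2, 0, 0, 0, 0)  # unreachable in practice
}

position_labels_from_gaps <- function(gaps) {
  lab <- integer(PHANTOM_H)
  for (i in seq_len(nrow(gaps))) {
    rows <- seq(gaps$start_row[i] + 1L, gaps$end_row[i])
    lab[rows] <- if (gaps$label[i] == "narrowed") 2L else 1L
  }
  lab
}

#' Generate a synthetic spine segmentation mask with ground truth
#'
#' Renders a 1024 x 512 integer label mask (0 background, 1 vertebral body,
#' and, when `annotate = TRUE`, 2/3 for normal/narrowed disc-space rows) plus
#' the exact ground truth used by the validation suites.
#'
#' @param params a [phantom_params()] object.
#' @return a list of class `ivd_phantom` with elements `mask` (integer
#'   matrix) and `truth` (gap table, body table, centerline coefficients, and
#'   the length-1024 per-position class vector: 0 no disc space, 1 normal,
#'   2 narrowed).
#' @export
generate_spine_mask <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    lay <- draw_layout(params)
    coeffs <- params$curve_coeffs %||% draw_curve_coeffs()
    mask <- matrix(0L, PHANTOM_H, PHANTOM_W)
    yall <- 0:(PHANTOM_H - 1L)
    xc_all <- as.integer(round_half_up(polyval(coeffs, yall)))
    for (i in seq_len(nrow(lay$bodies))) {
      rows <- seq(lay$bodies$start_row[i], lay$bodies$end_row[i] - 1L)
      h <- lay$bodies$height_px[i]
      half_l <- (h - 1L) %/% 2L
      half_r <- h - 1L - half_l
      jl <- jr <- integer(length(rows))
      if (params$jitter_px > 0) {
        jl <- sample(seq(-params$jitter_px, params$jitter_px), length(rows),
                     replace = TRUE)
        jr <- sample(seq(-params$jitter_px, params$jitter_px), length(rows),
                     replace = TRUE)
      }
      for (k in seq_along(rows)) {
        y <- rows[k]
        lo <- max(0L, xc_all[y + 1L] - half_l + jl[k])
        hi <- min(PHANTOM_W - 1L, xc_all[y + 1L] + half_r + jr[k])
        if (lo <= hi) mask[y + 1L, (lo:hi) + 1L] <- 1L
      }
    }
    if (params$annotate) {
      band <- as.integer(round_half_up(0.6 * mean(lay$bodies$height_px)))
      half <- band %/% 2L
      for (i in seq_len(nrow(lay$gaps))) {
        code <- if (lay$gaps$label[i] == "narrowed") 3L else 2L
        rows <- seq(lay$gaps$start_row[i], lay$gaps$end_row[i] - 1L)
        for (y in rows) {
          lo <- max(0L, xc_all[y + 1L] - half)
          hi <- min(PHANTOM_W - 1L, xc_all[y + 1L] + half)
          cols <- (lo:hi) + 1L
          free <- mask[y + 1L, cols] == 0L
          mask[y + 1L, cols[free]] <- code
        }
      }
    }
    if (params$speck_rate > 0) {
      for (s in seq_len(params$speck_rate)) {
        sh <- sample(1:3, 1L)
        sw <- sample(1:3, 1L)
        r0 <- sample(seq(2L, PHANTOM_H - sh), 1L)
        c0 <- sample(seq(2L, PHANTOM_W - sw), 1L)
        # keep a clear 1-px halo so specks never merge with a body component
        halo <- mask[(r0 - 1L):(r0 + sh), (c0 - 1L):(c0 + sw)]
        if (all(halo == 0L))
          mask[r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)] <- 1L
      }
    }
    truth <- list(gaps = lay$gaps, bodies = lay$bodies,
                  curve_coeffs = coeffs,
                  labels = position_labels_from_gaps(lay$gaps))
    structure(list(mask = mask, truth = truth, params = params),
              class = "ivd_phantom")
  })
}

#' Generate a dataset of quantified vectors with per-position labels
#'
#' Bypasses mask rendering: each item is the binary spine profile implied by
#' a drawn layout (1 on vertebral-body rows, 0 elsewhere) together with its
#' three-class per-position truth, the form consumed by the sequence
#' labeller during training.
#'
#' @param params a [phantom_params()] object (`seed` drives the whole
#'   dataset).
#' @param n_images number of items to generate.
#' @return an object of class `ivd_vector_dataset`: a list with `items` (each
#'   `list(vector, labels, gaps, curve_coeffs)`) and `params`.
#' @export
generate_vector_dataset <- function(params, n_images) {
  stopifnot(inherits(params, "phantom_params"))
  n_images <- stopifnot_scalar_count(n_images, "n_images", min = 0L)
  with_seed(params$seed, {
    items <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      lay <- draw_layout(params)
      coeffs <- params$curve_coeffs %||% draw_curve_coeffs()
      v <- integer(PHANTOM_H)
      for (b in seq_len(nrow(lay$bodies)))
        v[seq(lay$bodies$start_row[b] + 1L, lay$bodies$end_row[b])] <- 1L
      items[[i]] <- list(vector = v,
                         labels = position_labels_from_gaps(lay$gaps),
                         gaps = lay$gaps,
                         curve_coeffs = coeffs)
    }
    structure(list(items = items, params = params),
              class = "ivd_vector_dataset")
  })
}

# Stack a vector dataset into training matrices (n x 1024 each).
dataset_matrices <- function(dataset) {
  stopifnot(inherits(dataset, "ivd_vector_dataset"))
  n <- length(dataset$items)
  X <- matrix(0, n, PHANTOM_H)
  Y <- matrix(0L, n, PHANTOM_H)
  for (i in seq_len(n)) {
    X[i, ] <- dataset$items[[i]]$vector
    Y[i, ] <- dataset$items[[i]]$labels
  }
  list(X = X, Y = Y)
}

#' Write / read a vector dataset as a plain-text bundle
#'
#' The bundle is a directory holding `vectors.csv` (one row per image, 1024
#' columns), `labels.csv` (same shape, classes 0/1/2), `gaps.csv` (the pooled
#' ground-truth gap table with an `image` column) and `manifest.json`
#' recording the item count and generator parameters.
#'
#' @param dataset an `ivd_vector_dataset`.
#' @param dir bundle directory (created if needed).
#' @return `read_vector_dataset` returns the reconstructed
#'   `ivd_vector_dataset`.
#' @export
write_vector_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ivd_vector_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- dataset_matrices(dataset)
  utils::write.table(mats$X, file.path(dir, "vectors.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(mats$Y, file.path(dir, "labels.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  gaps <- do.call(rbind, lapply(seq_along(dataset$items), function(i) {
    g <- dataset$items[[i]]$gaps
    g$image <- i
    g
  }))
  write.csv(gaps, file.path(dir, "gaps.csv"), row.names = FALSE, quote = FALSE)
  params <- unclass(dataset$params)
  jsonlite::write_json(
    list(n_images = length(dataset$items), input_length = PHANTOM_H,
         params = params),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_vector_dataset
#' @export
read_vector_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  X <- as.matrix(read.csv(file.path(dir, "vectors.csv"), header = FALSE))
  Y <- as.matrix(read.csv(file.path(dir, "labels.csv"), header = FALSE))
  gaps <- read.csv(file.path(dir, "gaps.csv"), stringsAsFactors = FALSE)
  stopifnot(nrow(X) == man$n_images, ncol(X) == man$input_length)
  items <- lapply(seq_len(man$n_images), function(i) {
    g <- gaps[gaps$image == i, setdiff(names(gaps), "image"), drop = FALSE]
    rownames(g) <- NULL
    list(vector = as.integer(X[i, ]), labels = as.integer(Y[i, ]), gaps = g)
  })
  p <- man$params
  params <- phantom_params(
    n_vertebrae = p$n_vertebrae, body_length_px = p$body_length_px,
    body_height_px = p$body_height_px, gap_width_px = p$gap_width_px,
    narrowed_fraction = p$narrowed_fraction,
    narrowing_factor = p$narrowing_factor, curve_coeffs = p$curve_coeffs,
    jitter_px = p$jitter_px, speck_rate = p$speck_rate,
    annotate = p$annotate, seed = p$seed)
  structure(list(items = items, params = params),
            class = "ivd_vector_dataset")
}

#' Write / read a label mask as 8-bit indexed PNG
#'
#' The palette follows the labelling convention of the field: background
#' black, vertebral body sky blue, normal disc space white, narrowed disc
#' space purple.
#'
#' @param mask integer matrix with values 0..255 (labels 0..3 for masks).
#' @param path file path.
#' @return `read_mask_png` returns an integer label matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  palette <- rbind(c(0L, 0L, 0L), c(135L, 206L, 235L),
                   c(255L, 255L, 255L), c(128L, 0L, 128L))
  mx <- max(mask)
  if (mx > 3L) {
    extra <- matrix(rep(seq(4L, mx), each = 3L) %% 256L, ncol = 3L, byrow = TRUE)
    palette <- rbind(palette, extra)
  }
  cpp_png_write_indexed(path.expand(path), mask, palette)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  cpp_png_read(path.expand(path))
}
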