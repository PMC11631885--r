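#' Validate a segmentation label mask
#'
#' Masks use the labelling convention 0 = background, 1 = vertebral body,
#' 2 = normal disc space, 3 = narrowed disc space (2/3 optional, training
#' annotation only). Any other value is a hard error naming the offenders.
#'
#' @param mask integer matrix.
#' @return the mask, invisibly.
#' @export
validate_label_mask <- function(mask) {
  if (!is.matrix(mask) || length(dim(mask)) != 2L || any(dim(mask) == 0L))
    stop("mask must be a non-empty 2D integer matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(mask)), 0:3)
  if (length(bad))
    stop(sprintf("mask contains invalid labels: %s (allowed: 0,1,2,3)",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  invisible(mask)
}

#' Resize a label mask to the canonical 1024 x 512 frame
#'
#' Nearest-neighbour resampling, so the integer label alphabet is preserved
#' exactly; no interpolated labels can appear. Already-canonical masks are
#' returned unchanged.
#'
#' @param mask integer label matrix (any size).
#' @return a 1024 x 512 integer matrix.
#' @export
resize_mask <- function(mask) {
  if (!is.matrix(mask) || length(dim(mask)) != 2L || any(dim(mask) == 0L))
    stop("mask must be a non-empty 2D integer matrix", call. = FALSE)
  storage.mode(mask) <- "integer"
  if (nrow(mask) == PHANTOM_H && ncol(mask) == PHANTOM_W) return(mask)
  src_r <- pmin(nrow(mask), pmax(1L, floor((seq_len(PHANTOM_H) - 0.5) *
                                             nrow(mask) / PHANTOM_H) + 1L))
  src_c <- pmin(ncol(mask), pmax(1L, floor((seq_len(PHANTOM_W) - 0.5) *
                                             ncol(mask) / PHANTOM_W) + 1L))
  mask[src_r, src_c, drop = FALSE]
}

#' Skeletonize vertebral-body components
#'
#' Only label 1 is foreground. 8-connected components smaller than
#' `min_area_px` (segmentation specks) are discarded; the survivors are
#' thinned to their morphological skeleton (Zhang-Suen), locating the
#' shape-independent centre of each vertebral body.
#'
#' @param mask resized integer label mask.
#' @param min_area_px minimum component area kept (default 50).
#' @return integer matrix with columns `row`, `col` (0-based pixel
#'   coordinates) of pooled skeleton points.
#' @export
skeletonize_components <- function(mask, min_area_px = 50) {
  kept <- filter_components(mask, min_area_px)
  skel <- cpp_skeletonize(kept)
  pts <- which(skel, arr.ind = TRUE)
  out <- cbind(row = pts[, 1L] - 1L, col = pts[, 2L] - 1L)
  out[order(out[, "row"], out[, "col"]), , drop = FALSE]
}

# Logical mask of label-1 pixels in 8-connected components of area >=
# min_area_px; errors when nothing survives.
filter_components <- function(mask, min_area_px) {
  stopifnot(is.matrix(mask))
  fg <- matrix(as.integer(mask == 1L), nrow(mask), ncol(mask))
  lab <- cpp_label_components(fg)
  keep <- integer(0)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(areas >= min_area_px)
  }
  if (!length(keep))
    stop("no vertebrae detected (no foreground component >= min_area_px)",
         call. = FALSE)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Fit the 4th-order polynomial spine centerline
#'
#' Least-squares fit of column as a function of row, `x(y) = sum c_k y^k`,
#' through the pooled skeleton points: the curve through the vertebral-body
#' centres along which the spine profile is sampled. The fit runs on the
#' scaled ordinate `y/1023` (QR decomposition) for numerical conditioning and
#' reports coefficients on the raw row scale.
#'
#' @param points matrix with columns `row`, `col` (0-based), as returned by
#'   [skeletonize_components()].
#' @return an object of class `spine_curve`: `coeffs` (c0..c4), `rss`
#'   (residual sum of squares), `n_points`.
#' @export
fit_spine_curve <- function(points) {
  y <- points[, "row"]
  x <- points[, "col"]
  if (length(unique(y)) < 5L)
    stop("degenerate fit: need skeleton points on at least 5 distinct rows",
         call. = FALSE)
  tt <- y / 1023
  A <- outer(tt, 0:4, `^`)
  fit <- stats::lm.fit(A, x)
  coeffs <- unname(fit$coefficients) / 1023^(0:4)
  structure(list(coeffs = coeffs, rss = sum(fit$residuals^2),
                 n_points = length(y)), class = "spine_curve")
}

#' Evaluate a spine curve at given rows
#' @param curve a `spine_curve` or a length-5 coefficient vector.
#' @param y rows (0-based), defaults to the full 0..1023 frame.
#' @return columns `x(y)`.
#' @export
eval_spine_curve <- function(curve, y = 0:(PHANTOM_H - 1L)) {
  coeffs <- if (inherits(curve, "spine_curve")) curve$coeffs else curve
  polyval(coeffs, y)
}

#' Sample the length-1024 binary spine profile along the centerline
#'
#' For each row `y`, the mask is probed at the nearest pixel to the curve,
#' `(y, round(x(y)))` (ties round half away from zero); the profile is 1 iff
#' that pixel is vertebral body (label 1). Samples falling outside the
#' 512-column frame read as background. Annotation labels 2/3 are treated as
#' background here: they mark disc space, not bone.
#'
#' @param mask resized 1024 x 512 integer mask.
#' @param curve a `spine_curve` (finite over rows 0..1023).
#' @return integer vector of length 1024 with values 0/1.
#' @export
quantify_vector <- function(mask, curve) {
  stopifnot(nrow(mask) == PHANTOM_H, ncol(mask) == PHANTOM_W)
  xs <- eval_spine_curve(curve)
  if (any(!is.finite(xs))) stop("curve is not finite over rows 0..1023", call. = FALSE)
  xi <- as.integer(round_half_up(xs))
  v <- integer(PHANTOM_H)
  inside <- xi >= 0L & xi < PHANTOM_W
  idx <- which(inside)
  v[idx] <- as.integer(mask[cbind(idx, xi[idx] + 1L)] == 1L)
  v
}

#' Measure inter-vertebral gaps on a quantified vector
#'
#' A gap is a maximal zero-run flanked on both sides by one-runs of length at
#' least `min_run_px` (vertebral bodies; shorter one-runs are label noise and
#' cannot delimit a gap). Leading and trailing zero-runs are background, never
#' gaps. Width is the pixel count of the zero-run; each gap also carries its
#' ratio to the image's mean gap width, the scale-free narrowing score.
#'
#' @param vector integer/numeric 0-1 vector of length 1024.
#' @param min_run_px minimum one-run length that counts as a vertebral body.
#' @return a data frame of gap records: `gap_index`, `start_row`,
#'   `end_row` (half-open, 0-based), `width_px`, `ratio_to_mean`, `label`
#'   (all `"unassigned"`). Zero rows when fewer than two qualifying bodies.
#' @export
measure_gaps <- function(vector, min_run_px = 5) {
  v <- as.integer(vector)
  if (length(v) != PHANTOM_H || any(!v %in% c(0L, 1L)))
    stop("vector must be binary of length 1024", call. = FALSE)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based start of each run
  is_body <- r$values == 1L & r$lengths >= min_run_px
  gap_idx <- which(r$values == 0L &
                     seq_along(r$values) > 1L &
                     seq_along(r$values) < length(r$values))
  gap_idx <- gap_idx[is_body[gap_idx - 1L] & is_body[gap_idx + 1L]]
  if (!length(gap_idx))
    return(data.frame(gap_index = integer(0), start_row = integer(0),
                      end_row = integer(0), width_px = integer(0),
                      ratio_to_mean = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  w <- r$lengths[gap_idx]
  data.frame(gap_index = seq_along(gap_idx),
             start_row = starts[gap_idx],
             end_row = ends[gap_idx],
             width_px = w,
             ratio_to_mean = w / mean(w),
             label = "unassigned",
             stringsAsFactors = FALSE)
}

#' Label gaps as narrowed by thresholding the ratio-to-mean score
#'
#' A gap is narrowed iff its width ratio to the image mean falls at or below
#' `threshold`; the operating threshold is typically chosen by the Youden
#' index on a labelled set (see [roc_youden()]).
#'
#' @param gaps gap table from [measure_gaps()].
#' @param threshold positive ratio cut.
#' @return the gap table with `label` set to `"narrowed"`/`"normal"`.
#' @export
classify_by_ratio <- function(gaps, threshold) {
  stopifnot(is.data.frame(gaps), is.numeric(threshold), threshold > 0)
  gaps$label <- ifelse(gaps$ratio_to_mean <= threshold, "narrowed", "normal")
  gaps
}

#' Run the full quantification pipeline on a mask
#'
#' Resize to 1024 x 512, skeletonize vertebral bodies, fit the 4th-order
#' centerline, sample the binary profile, and measure gaps.
#'
#' @param mask integer label mask (any size).
#' @param min_area_px component filter passed to [skeletonize_components()].
#' @param min_run_px body-run filter passed to [measure_gaps()].
#' @return list of class `ivd_quant`: `curve`, `vector`, `gaps`, `mask`
#'   (resized).
#' @export
quantify_mask <- function(mask, min_area_px = 50, min_run_px = 5) {
  validate_label_mask(mask)
  m <- resize_mask(mask)
  pts <- skeletonize_components(m, min_area_px = min_area_px)
  curve <- fit_spine_curve(pts)
  # sample only surviving components, so sub-threshold specks cannot leak
  # into the profile
  clean <- matrix(0L, nrow(m), ncol(m))
  clean[filter_components(m, min_area_px)] <- 1L
  v <- quantify_vector(clean, curve)
  gaps <- measure_gaps(v, min_run_px = min_run_px)
  structure(list(curve = curve, vector = v, gaps = gaps, mask = m),
            class = "ivd_quant")
}

#' Write a quantification overlay PNG
#'
#' The resized mask with the fitted centerline painted on top (label 4) and
#' each measured gap's rows tinted along the curve: label 5 for
#' normal/unassigned gaps, label 6 for narrowed ones. Purely a visual QC
#' artifact.
#'
#' @param quant an `ivd_quant` from [quantify_mask()].
#' @param path output PNG path.
#' @export
write_overlay_png <- function(quant, path) {
  stopifnot(inherits(quant, "ivd_quant"))
  ov <- quant$mask
  xs <- as.integer(round_half_up(eval_spine_curve(quant$curve)))
  half <- 20L
  for (i in seq_len(nrow(quant$gaps))) {
    code <- if (identical(quant$gaps$label[i], "narrowed")) 6L else 5L
    for (y in seq(quant$gaps$start_row[i], quant$gaps$end_row[i] - 1L)) {
      cols <- seq(max(0L, xs[y + 1L] - half),
                  min(PHANTOM_W - 1L, xs[y + 1L] + half)) + 1L
      ov[y + 1L, cols] <- code
    }
  }
  ok <- xs >= 0L & xs < PHANTOM_W
  ov[cbind(which(ok), xs[ok] + 1L)] <- 4L
  palette <- rbind(c(0L, 0L, 0L), c(135L, 206L, 235L), c(255L, 255L, 255L),
                   c(128L, 0L, 128L), c(0L, 200L, 0L), c(144L, 238L, 144L),
                   c(255L, 0L, 0L))
  cpp_png_write_indexed(path.expand(path), ov, palette)
  invisible(path)
}

#' @export
print.spine_curve <- function(x, ...) {
  cat("4th-order spine centerline x(y) = c0 + c1*y + ... + c4*y^4\n")
  cat("  coeffs:", format(x$coeffs, digits = 6), "\n")
  cat(sprintf("  rss: %.4g over %d skeleton points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
print.ivd_quant <- function(x, ...) {
  cat(sprintf("quantified spine profile: %d vertebral-body rows, %d gaps\n",
              sum(x$vector), nrow(x$gaps)))
  if (nrow(x$gaps)) print(x$gaps, row.names = FALSE)
  invisible(x)
}
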