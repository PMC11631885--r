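test_that("resize_mask is nearest-neighbour and idempotent at target shape", {
  m <- matrix(0L, 1024, 512)
  expect_identical(resize_mask(m), m)
  big <- matrix(0L, 2048, 1024)
  expect_identical(resize_mask(big), m)
  expect_error(resize_mask(matrix(integer(0), 0, 0)), "non-empty")
  # 512x256 with a solid label-1 block on rows 100-199 upscales to ~200-399
  sm <- matrix(0L, 512, 256)
  sm[100:199, ] <- 1L
  r <- resize_mask(sm)
  rows <- which(rowSums(r) > 0)
  expect_setequal(unique(as.vector(r)), c(0L, 1L))
  expect_lt(abs(min(rows) - 200), 3)
  expect_lt(abs(max(rows) - 399), 3)
  # independent oracle: every output pixel equals its nearest source pixel
  src_r <- floor((seq_len(1024) - 0.5) * 512 / 1024) + 1L
  src_c <- floor((seq_len(512) - 0.5) * 256 / 512) + 1L
  expect_identical(r, sm[src_r, src_c])
})

test_that("label validation names offenders", {
  m <- matrix(0L, 10, 10)
  m[3, 3] <- 7L
  expect_error(validate_label_mask(m), "7")
  expect_silent(validate_label_mask(matrix(c(0L, 1L, 2L, 3L), 2, 2)))
})

test_that("skeletonization keeps thin structures and filters specks", {
  m <- matrix(0L, 1024, 512)
  m[100:400, 256] <- 1L  # 1-px vertical line: already its own skeleton
  pts <- skeletonize_components(m, min_area_px = 50)
  expect_identical(unname(pts[, "col"]), rep(255L, 301))
  expect_identical(unname(pts[, "row"]), 99:399)
  # a 3x3 speck alone is filtered out entirely
  s <- matrix(0L, 1024, 512)
  s[10:12, 10:12] <- 1L
  expect_error(skeletonize_components(s, min_area_px = 25), "no vertebrae")
  # speck next to a real body leaves the body's skeleton untouched
  m2 <- m
  m2[700:702, 40:42] <- 1L
  pts2 <- skeletonize_components(m2, min_area_px = 50)
  expect_identical(pts2, pts)
})

test_that("rectangle skeleton runs down the central column, off the boundary", {
  m <- matrix(0L, 1024, 512)
  m[200:300, 230:270] <- 1L  # 41 wide x 101 tall, centre column 250 (0-based 249)
  pts <- skeletonize_components(m, min_area_px = 50)
  expect_true(all(pts[, "row"] >= 200 & pts[, "row"] <= 298))
  expect_true(all(pts[, "col"] >= 230 & pts[, "col"] <= 268))
  centred <- mean(pts[, "col"] == 249)
  expect_gt(centred, 0.5)
})

test_that("fit_spine_curve recovers exact polynomials", {
  pts <- cbind(row = 0:1023, col = 256)
  cv <- fit_spine_curve(pts)
  expect_equal(cv$coeffs, c(256, 0, 0, 0, 0), tolerance = 1e-8)
  expect_lt(cv$rss, 1e-12)
  y <- seq(0, 1023, by = 3)
  pts2 <- cbind(row = y, col = 200 + 1e-4 * y^2)
  cv2 <- fit_spine_curve(pts2)
  expect_equal(cv2$coeffs, c(200, 0, 1e-4, 0, 0), tolerance = 1e-6)
  expect_lt(cv2$rss, 1e-10)
  expect_error(fit_spine_curve(cbind(row = rep(1:4, 5), col = 1:20)),
               "degenerate")
})

test_that("fit matches a brute-force normal-equations oracle", {
  withr::local_seed(42)
  for (rep in 1:5) {
    y <- sort(sample(0:1023, 500, replace = TRUE))
    truec <- c(250, 0.05, -1e-4, 9e-8, -4e-11)
    x <- polyval_test(truec, y) + rnorm(500, sd = 2)
    cv <- fit_spine_curve(cbind(row = y, col = x))
    tt <- y / 1023
    A <- outer(tt, 0:4, `^`)
    b_or <- solve(crossprod(A), crossprod(A, x))
    c_or <- as.numeric(b_or) / 1023^(0:4)
    expect_equal(cv$coeffs, c_or, tolerance = 1e-6)
    # least-squares optimality: nudging any coefficient never lowers rss
    rss_of <- function(cf) sum((x - polyval_test(cf, y))^2)
    expect_equal(cv$rss, rss_of(cv$coeffs), tolerance = 1e-6)
    for (k in 1:5) {
      for (d in c(-1e-3, 1e-3)) {
        cf <- cv$coeffs
        cf[k] <- cf[k] + d / 1023^(k - 1)  # perturb on the scaled basis
        expect_gte(rss_of(cf), cv$rss - 1e-9)
      }
    }
  }
})

test_that("quantify_vector samples the mask at the rounded curve", {
  m0 <- matrix(0L, 1024, 512)
  curve <- structure(list(coeffs = c(256, 0, 0, 0, 0), rss = 0, n_points = 10),
                     class = "spine_curve")
  expect_identical(quantify_vector(m0, curve), integer(1024))
  m1 <- m0
  m1[, 257] <- 1L  # 0-based column 256
  expect_identical(quantify_vector(m1, curve), rep(1L, 1024))
  # out-of-frame samples read as background
  off <- structure(list(coeffs = c(600, 0, 0, 0, 0), rss = 0, n_points = 10),
                   class = "spine_curve")
  expect_identical(quantify_vector(m1, off), integer(1024))
  # annotation labels 2/3 are background for quantification
  m2 <- m1
  m2[100:110, 257] <- 2L
  m2[200:210, 257] <- 3L
  v <- quantify_vector(m2, curve)
  expect_identical(sum(v == 0L), 22L)
})

test_that("measure_gaps counts pixels between qualifying bodies", {
  expect_identical(nrow(measure_gaps(integer(1024))), 0L)
  v <- profile_vector(bodies = c(50, 50), gaps = 8)
  g <- measure_gaps(v, min_run_px = 5)
  expect_identical(g$start_row, 150L)
  expect_identical(g$end_row, 158L)
  expect_identical(g$width_px, 8L)
  expect_identical(g$ratio_to_mean, 1)
  # leading/trailing zero runs are never gaps; short one-runs cannot flank
  v2 <- profile_vector(bodies = c(50, 3, 50), gaps = c(8, 8))
  expect_identical(nrow(measure_gaps(v2, min_run_px = 5)), 0L)
  # known width family
  v3 <- profile_vector(bodies = rep(60, 6), gaps = c(12, 11, 6, 12, 13))
  g3 <- measure_gaps(v3)
  expect_identical(g3$width_px, c(12L, 11L, 6L, 12L, 13L))
  expect_equal(g3$ratio_to_mean, c(12, 11, 6, 12, 13) / 10.8)
  expect_error(measure_gaps(c(v3, 0L)), "length 1024")
})

test_that("classify_by_ratio thresholds the ratio", {
  g <- data.frame(gap_index = 1:2, start_row = c(0, 20), end_row = c(10, 30),
                  width_px = c(10, 10), ratio_to_mean = c(1.0, 1.0),
                  label = "unassigned")
  expect_true(all(classify_by_ratio(g, 0.8)$label == "normal"))
  g$ratio_to_mean <- c(0.5, 1.25)
  expect_identical(classify_by_ratio(g, 0.8)$label, c("narrowed", "normal"))
})

test_that("noiseless phantom round trip recovers exact widths", {
  for (seed in 1:20) {
    ph <- generate_spine_mask(straight_params(seed = seed))
    q <- quantify_mask(ph$mask)
    expect_identical(q$gaps$width_px, ph$truth$gaps$width_px)
    expect_identical(q$gaps$start_row, ph$truth$gaps$start_row)
  }
})

test_that("curved noiseless phantoms stay within one pixel of truth", {
  n_ok <- 0L
  n_tot <- 0L
  for (seed in 1:25) {
    ph <- generate_spine_mask(phantom_params(jitter_px = 0L, speck_rate = 0L,
                                             seed = 100 + seed))
    q <- quantify_mask(ph$mask)
    expect_identical(nrow(q$gaps), nrow(ph$truth$gaps))
    d <- abs(q$gaps$width_px - ph$truth$gaps$width_px)
    n_ok <- n_ok + sum(d <= 1L)
    n_tot <- n_tot + length(d)
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("specks below the area filter never change the vector", {
  ph <- generate_spine_mask(straight_params(seed = 31))
  q0 <- quantify_mask(ph$mask)
  expect_identical(sum(q0$vector), as.integer(sum(ph$mask[, 257] == 1L)))
  ph2 <- generate_spine_mask(straight_params(seed = 31, speck_rate = 12L))
  q2 <- quantify_mask(ph2$mask)
  expect_identical(q2$vector, q0$vector)
})
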