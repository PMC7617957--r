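# Straightening geometry, barrel detection, soma index, dendritic overlap,
# and intensity quantification.

test_that("straightening a horizontal reference is the identity (up to sign)", {
  ref <- data.frame(x = c(0, 100), y = c(0, 0))
  pts <- data.frame(x = c(10, 50, 99), y = c(-5, 3, 0))
  st <- straighten(pts, ref)
  expect_equal(st$s, pts$x)
  # deep (+y, below the reference in image coordinates) side is positive d
  expect_equal(st$d, pts$y)
})

test_that("straightening preserves distances under rotation", {
  base <- data.frame(x = seq(0, 100, by = 10), y = 0)
  pts <- data.frame(x = c(20, 45, 80), y = c(-12, 8, -3))
  for (theta in seq(0, 2 * pi, length.out = 9)[-9]) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    rot <- function(df) {
      m <- as.matrix(df) %*% t(R)
      data.frame(x = m[, 1], y = m[, 2])
    }
    st <- straighten(rot(pts), rot(base))
    expect_equal(abs(st$d), abs(pts$y), tolerance = 1e-9)
    expect_equal(st$s, pts$x, tolerance = 1e-9)
  }
})

test_that("point-to-polyline distances are preserved exactly on random clouds", {
  set.seed(5)
  ref <- data.frame(x = seq(0, 200, by = 20),
                    y = cumsum(rnorm(11, 0, 4)))
  pts <- data.frame(x = runif(200, 5, 195), y = runif(200, -60, 60))
  st <- straighten(pts, ref)
  # oracle: dense sampling of the polyline
  tt <- seq(0, 1, length.out = 4001)
  dense <- do.call(rbind, lapply(seq_len(nrow(ref) - 1), function(i)
    cbind(ref$x[i] + tt * (ref$x[i + 1] - ref$x[i]),
          ref$y[i] + tt * (ref$y[i + 1] - ref$y[i]))))
  for (i in seq_len(50)) {
    d_oracle <- min(sqrt((dense[, 1] - pts$x[i])^2 +
                         (dense[, 2] - pts$y[i])^2))
    expect_lt(abs(abs(st$d[i]) - d_oracle), 1e-6)
  }
})

test_that("a curved synthetic band is flat after image straightening", {
  b <- gen_barrel_image(barrel_image_params(curvature = 5e-4, noise_sd = 0,
                                            seed = 4))
  st <- straighten(b$image, b$truth$reference_polyline,
                   d_range = c(b$truth$l4_band[1] - 40, 40))
  # detect the deep band edge per column: last row above background
  span <- st$s > 100 & st$s < max(st$s) - 100
  edge <- apply(st$image[, span], 2, function(col) {
    i <- which(col > 3000)
    if (!length(i)) NA_real_ else st$d[max(i)]
  })
  edge <- edge[!is.na(edge)]
  expect_lt(sqrt(mean((edge - mean(edge))^2)), 1)   # flat within 1 px RMS
})

test_that("detect_barrels finds rectangular plateaus at their edges", {
  s <- 0:499
  prof <- rep(10, 500)
  for (st in c(50, 200, 350)) prof[s >= st & s < st + 100] <- 100
  det <- detect_barrels(prof, s, sigma = 0, min_width = 30)
  expect_equal(nrow(det), 3)
  expect_lt(max(abs(det$s_start - c(50, 200, 350))), 1)
  expect_lt(max(abs(det$s_end - c(150, 300, 450))), 1)
  expect_error(detect_barrels(rep(5, 100)), "flat profile")
})

test_that("detect_barrels is invariant to affine intensity rescaling", {
  b <- gen_barrel_image(barrel_image_params(noise_sd = 200, seed = 9))
  st <- straighten(b$image, b$truth$reference_polyline,
                   d_range = c(b$truth$l4_band[1] - 30, 30))
  band <- st$d >= b$truth$l4_band[1] + 5 & st$d < b$truth$l4_band[2] - 5
  prof <- colMeans(st$image[band, , drop = FALSE], na.rm = TRUE)
  d1 <- detect_barrels(prof, st$s)
  d2 <- detect_barrels(3.7 * prof + 1200, st$s)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("soma index anchors and symmetry under layout reflection", {
  barrels <- data.frame(s_start = c(0, 150, 300), s_end = c(100, 250, 400))
  barrels$s_center <- (barrels$s_start + barrels$s_end) / 2
  expect_equal(soma_position_index(200, barrels)$index, 1)   # centre
  expect_equal(soma_position_index(125, barrels)$index, 0)   # septal midpoint
  expect_equal(soma_position_index(162.5, barrels)$index, 0.5)
  # reflection s -> 400 - s maps the layout onto itself
  for (s in c(10, 60, 120, 190, 260, 330)) {
    expect_equal(soma_position_index(s, barrels)$index,
                 soma_position_index(400 - s, barrels)$index,
                 tolerance = 1e-12)
  }
  # outside the mirrored span is flagged
  expect_false(soma_position_index(-500, barrels)$in_span)
})

test_that("dendritic overlap: trivial cases and exclusion rule", {
  barrels <- data.frame(s_start = c(0, 150), s_end = c(100, 250))
  barrels$s_center <- (barrels$s_start + barrels$s_end) / 2
  band <- c(-100, 0)
  inside <- data.frame(id = 1:2, type = c(1, 3), x = c(20, 80),
                       y = -50, z = 0, radius = 1, parent = c(-1, 1))
  res <- dendritic_overlap(inside, barrels, band)
  expect_equal(res$pct_principal, 100)
  expect_equal(res$pct_adjacent, 0)
  expect_equal(res$pct_outside, 0, tolerance = 1e-9)
  # a 200 um dendrite crossing both barrels: 30..100 in b1 (70), 150..230 in
  # b2 (80), 50 outside
  m3 <- data.frame(id = 1:2, type = c(1, 3), x = c(30, 230), y = -50,
                   z = 0, radius = 1, parent = c(-1, 1))
  r3 <- dendritic_overlap(m3, barrels, band)
  expect_equal(r3$per_barrel_pct, c(35, 40))
  expect_equal(r3$pct_outside, 25, tolerance = 1e-9)
  expect_equal(r3$principal_barrel, 2)
  # a soma-only morphology has no measurable dendrite
  expect_error(dendritic_overlap(m3[1, ], barrels, band), "zero total")
  # max per-barrel overlap ~1% (< 5%): exclusion flag set
  long3 <- data.frame(id = 1:3, type = c(1, 3, 3), x = c(98, 102, 98),
                      y = c(-50, -50, 150), z = 0, radius = 1,
                      parent = c(-1, 1, 2))
  r4 <- dendritic_overlap(long3, barrels, band)
  expect_lt(max(r4$per_barrel_pct), 5)
  expect_true(r4$excluded)
})

test_that("overlap percentages sum to 100 for generated morphologies", {
  b <- gen_barrel_image(barrel_image_params(seed = 10))
  for (m in b$truth$morphologies) {
    res <- dendritic_overlap(m, b$truth$barrels, b$truth$l4_band)
    expect_equal(sum(res$per_barrel_pct) + res$pct_outside, 100,
                 tolerance = 1e-6)
    tr <- attr(m, "truth")
    expect_equal(res$pct_principal,
                 100 * tr$len_inside / (tr$len_inside + tr$len_outside),
                 tolerance = 1e-6)
    expect_equal(res$principal_barrel, tr$barrel)
  }
})

test_that("exact segment clipping agrees with the dense-sampling oracle", {
  set.seed(77)
  for (i in 1:20) {
    x1 <- runif(1, -50, 150); y1 <- runif(1, -150, 50)
    x2 <- runif(1, -50, 150); y2 <- runif(1, -150, 50)
    got <- barrelcircuit:::.seg_len_in_rect(x1, y1, x2, y2, 0, 100, -100, 0)
    want <- oracle_len_in_rect(x1, y1, x2, y2, c(0, 100), c(-100, 0))
    expect_lt(abs(got - want), 0.01 * max(1, want))
  }
})

test_that("lhx2_ratio and soma MPI recover planted intensity contrasts", {
  expect_equal(lhx2_ratio(100, c(100, 100, 100)), 1)
  expect_equal(lhx2_ratio(50, c(100, 100, 100)), 0.5)
  expect_error(lhx2_ratio(50, c(100, 100)), "exactly 3")
  set.seed(3)
  img <- matrix(1000, 200, 200)
  put_disk <- function(img, x, y, r, val) {
    for (cc in max(1, floor(x - r)):min(200, ceiling(x + r) + 1))
      for (rr in max(1, floor(y - r)):min(200, ceiling(y + r) + 1))
        if ((cc - 0.5 - x)^2 + (rr - 0.5 - y)^2 <= r^2) img[rr, cc] <- val
    img
  }
  img <- put_disk(img, 50, 50, 6, 3500)     # IP cell, ratio 0.7 vs 5000
  for (p in list(c(80, 50), c(50, 80), c(80, 80)))
    img <- put_disk(img, p[1], p[2], 6, 5000)
  img <- img + matrix(rnorm(length(img), 0, 50), 200)
  cell <- soma_mpi(img, 50, 50, 5)
  nb <- c(soma_mpi(img, 80, 50, 5), soma_mpi(img, 50, 80, 5),
          soma_mpi(img, 80, 80, 5))
  expect_lt(abs(lhx2_ratio(cell, nb) - 0.7), 0.05)
})

test_that("roi_expression_fraction counts suprathreshold pixels in the ROI", {
  img <- matrix(100, 100, 100)
  img[20:40, 20:40] <- 5000                 # expression blob
  roi <- matrix(FALSE, 100, 100)
  roi[10:50, 10:50] <- TRUE                 # blob strictly inside
  expect_equal(roi_expression_fraction(img, roi)$mean, 1)
  # ROI covering 25% of a uniform suprathreshold area
  img2 <- matrix(100, 100, 100)
  img2[1:40, 1:40] <- 5000
  roi2 <- matrix(FALSE, 100, 100)
  roi2[1:20, 1:20] <- TRUE
  expect_equal(roi_expression_fraction(img2, roi2)$mean, 0.25)
  expect_error(roi_expression_fraction(matrix(5, 10, 10),
                                       matrix(TRUE, 10, 10)), "constant")
})

test_that("planted in-ROI fraction is recovered from a noisy blob image", {
  set.seed(99)
  img <- matrix(rnorm(300 * 300, 500, 50), 300)
  blob <- function(cx, cy, r) {
    m <- matrix(FALSE, 300, 300)
    for (cc in (cx - r):(cx + r)) for (rr in (cy - r):(cy + r))
      if ((cc - cx)^2 + (rr - cy)^2 <= r^2) m[rr, cc] <- TRUE
    m
  }
  expr_in <- blob(100, 100, 40)             # inside ROI
  expr_out <- blob(230, 230, 20)            # outside
  img[expr_in | expr_out] <- rnorm(sum(expr_in | expr_out), 8000, 100)
  roi <- matrix(FALSE, 300, 300); roi[1:170, 1:170] <- TRUE
  want <- sum(expr_in) / sum(expr_in | expr_out)
  got <- roi_expression_fraction(img, roi)$mean
  expect_lt(abs(got - want), 0.02)
})
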