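# Image-domain quantification of the barrel field: layer straightening,
# barrel detection, soma position index, dendritic overlap, and intensity
# ratios. Coordinates are in um (1 um/px by default); arc length s is
# measured from the first polyline vertex; the signed normal distance d is
# negative on the pia side when the polyline runs left to right with the pia
# above (smaller y).

# Project points onto a piecewise-linear reference. Returns, per point, the
# arc length of the foot, the signed normal distance, and an ambiguity flag
# (two non-adjacent segments nearly equidistant).
.project_polyline <- function(px, py, ref) {
  rx <- ref$x; ry <- ref$y
  ns <- length(rx) - 1L
  if (ns < 1L) stop("reference polyline needs >= 2 points", call. = FALSE)
  seg_dx <- diff(rx); seg_dy <- diff(ry)
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  if (any(seg_len == 0)) stop("degenerate polyline segment", call. = FALSE)
  cum <- c(0, cumsum(seg_len))
  n <- length(px)
  s <- d <- dist <- numeric(n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    # parameter of the foot on each segment, clamped to [0, 1]
    t <- ((px[i] - rx[-length(rx)]) * seg_dx +
          (py[i] - ry[-length(ry)]) * seg_dy) / seg_len^2
    t <- pmin(pmax(t, 0), 1)
    fx <- rx[-length(rx)] + t * seg_dx
    fy <- ry[-length(ry)] + t * seg_dy
    dd <- sqrt((px[i] - fx)^2 + (py[i] - fy)^2)
    j <- which.min(dd)
    near <- which(dd - dd[j] < 1e-9 * max(1, dd[j]))
    ambiguous[i] <- any(abs(near - j) > 1L)
    # signed distance: positive on the left of the travel direction
    crossz <- seg_dx[j] * (py[i] - fy[j]) - seg_dy[j] * (px[i] - fx[j])
    s[i] <- cum[j] + t[j] * seg_len[j]
    d[i] <- sign(crossz) * dd[j]
    dist[i] <- dd[j]
  }
  list(s = s, d = d, dist = dist, ambiguous = ambiguous,
       cum = cum, seg_dx = seg_dx, seg_dy = seg_dy, seg_len = seg_len)
}

#' Straighten points or an image with respect to a reference polyline
#'
#' Maps each point to `(s, d)`: the arc length of its foot on the reference
#' polyline (drawn along the L4/L5 boundary) and its signed normal distance.
#' `|d|` equals the Euclidean distance to the polyline exactly, so relative
#' soma positions are preserved while the cortical layers are flattened. The
#' sign of `d` is positive on the left of the polyline's travel direction
#' (for a left-to-right reference with the pia above in image coordinates,
#' the pia side is negative).
#'
#' For an image, the straightened frame is sampled on a regular `(s, d)`
#' grid by inverse mapping (`point = foot(s) + d * normal(s)`) with bilinear
#' interpolation.
#'
#' @param x data.frame with `x`, `y` (um), or an intensity matrix
#'   (rows = y, cols = x, 1 um/px).
#' @param reference data.frame with `x`, `y`: the ordered reference polyline.
#' @param d_range for the image variant, range of normal offsets to sample
#'   (um), default c(-300, 100).
#' @param step grid step for the image variant (um, default 1).
#' @return for points: data.frame with `s`, `d`, `ambiguous`. For an image:
#'   list with `image` (d x s matrix), `s` and `d` axis vectors.
#' @export
straighten <- function(x, reference, d_range = c(-300, 100), step = 1) {
  stopifnot(is.data.frame(reference), nrow(reference) >= 2)
  if (is.data.frame(x)) {
    pr <- .project_polyline(x$x, x$y, reference)
    return(data.frame(s = pr$s, d = pr$d, ambiguous = pr$ambiguous))
  }
  stopifnot(is.matrix(x))
  rx <- reference$x; ry <- reference$y
  seg_dx <- diff(rx); seg_dy <- diff(ry)
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  cum <- c(0, cumsum(seg_len))
  s_axis <- seq(0, cum[length(cum)], by = step)
  d_axis <- seq(d_range[1], d_range[2], by = step)
  seg_of <- pmin(findInterval(s_axis, cum, rightmost.closed = TRUE),
                 length(seg_len))
  t_of <- (s_axis - cum[seg_of]) / seg_len[seg_of]
  fx <- rx[seg_of] + t_of * seg_dx[seg_of]
  fy <- ry[seg_of] + t_of * seg_dy[seg_of]
  # unit normal pointing to the positive-d (left-of-direction) side
  nx <- -seg_dy[seg_of] / seg_len[seg_of]
  ny <- seg_dx[seg_of] / seg_len[seg_of]
  out <- matrix(NA_real_, nrow = length(d_axis), ncol = length(s_axis))
  for (k in seq_along(d_axis)) {
    qx <- fx + d_axis[k] * nx
    qy <- fy + d_axis[k] * ny
    out[k, ] <- .bilinear(x, qx, qy)
  }
  list(image = out, s = s_axis, d = d_axis)
}

# Bilinear sample of img at physical points (qx, qy) in um; pixel (r, c) has
# its centre at (c - 0.5, r - 0.5) um. Points outside are clamped to the edge.
.bilinear <- function(img, qx, qy) {
  cc <- pmin(pmax(qx + 0.5, 1), ncol(img))   # continuous col, centres integer
  rr <- pmin(pmax(qy + 0.5, 1), nrow(img))
  c0 <- pmin(floor(cc), ncol(img) - 1L); wx <- cc - c0
  r0 <- pmin(floor(rr), nrow(img) - 1L); wy <- rr - r0
  v00 <- img[cbind(r0, c0)];      v01 <- img[cbind(r0, c0 + 1L)]
  v10 <- img[cbind(r0 + 1L, c0)]; v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Detect barrel intervals from a straightened L4 intensity profile
#'
#' The profile (mean intensity over the normal direction of the L4 band,
#' as a function of arc length) is Gaussian-smoothed; the threshold is the
#' midpoint between a robust septal floor and barrel plateau (10th and 90th
#' percentiles); maximal runs above threshold wider than `min_width` are
#' barrels, with boundaries linearly interpolated at the threshold
#' crossings. Invariant to affine intensity rescaling `a * I + b`, `a > 0`.
#'
#' @param profile intensity versus arc length.
#' @param s arc-length coordinates (um), same length; default 1 um steps.
#' @param sigma smoothing SD (um, default 5); 0 disables smoothing.
#' @param min_width minimum barrel width (um, default 30).
#' @return data.frame with `s_start`, `s_end`, `s_center` per barrel.
#' @export
detect_barrels <- function(profile, s = seq_along(profile) - 1,
                           sigma = 5, min_width = 30) {
  stopifnot(length(profile) == length(s), length(profile) > 2)
  if (sigma > 0) {
    step <- mean(diff(s))
    half <- max(1L, ceiling(3 * sigma / step))
    kern <- stats::dnorm(seq(-half, half) * step, sd = sigma)
    kern <- kern / sum(kern)
    n <- length(profile)
    padded <- c(rep(profile[1], half), profile, rep(profile[n], half))
    profile <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
  }
  lo <- stats::quantile(profile, 0.10, names = FALSE)
  hi <- stats::quantile(profile, 0.90, names = FALSE)
  if (hi - lo <= 0) stop("no barrels detected: flat profile", call. = FALSE)
  thr <- (lo + hi) / 2
  above <- profile > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    s0 <- if (i0 > 1) {
      f <- (thr - profile[i0 - 1]) / (profile[i0] - profile[i0 - 1])
      s[i0 - 1] + f * (s[i0] - s[i0 - 1])
    } else s[i0]
    s1 <- if (i1 < length(s)) {
      f <- (thr - profile[i1]) / (profile[i1 + 1] - profile[i1])
      s[i1] + f * (s[i1 + 1] - s[i1])
    } else s[i1]
    if (s1 - s0 >= min_width)
      out[[length(out) + 1L]] <- c(s0, s1)
  }
  if (!length(out)) stop("no barrels detected: no run exceeds the minimum ",
                         "width", call. = FALSE)
  m <- do.call(rbind, out)
  data.frame(s_start = m[, 1], s_end = m[, 2],
             s_center = (m[, 1] + m[, 2]) / 2)
}

#' Soma barrel-position index
#'
#' 1 for a soma at a barrel centre, 0 at the midpoint between two barrel
#' boundaries (the septal midpoint), with a linear ramp in between:
#' `index = clip(|s - m| / |c - m|, 0, 1)` for the nearest barrel centre `c`
#' and nearest septal midpoint `m`. Beyond the outer barrels the outermost
#' half-gap is mirrored; somata beyond the mirrored span are flagged.
#'
#' @param s soma tangential (arc-length) coordinate (um).
#' @param barrels data.frame from [detect_barrels()] (or truth): `s_start`,
#'   `s_end`, `s_center`.
#' @param ramp "linear" (default) or "cosine".
#' @return list with `index` and `in_span` (logical flag).
#' @export
soma_position_index <- function(s, barrels, ramp = c("linear", "cosine")) {
  ramp <- match.arg(ramp)
  stopifnot(nrow(barrels) >= 1)
  centers <- barrels$s_center
  nb <- nrow(barrels)
  gaps_mid <- if (nb > 1)
    (barrels$s_end[-nb] + barrels$s_start[-1]) / 2 else numeric(0)
  half_gap <- if (nb > 1) (barrels$s_start[2] - barrels$s_end[1]) / 2
              else mean(barrels$s_end - barrels$s_start) / 2
  mids <- c(barrels$s_start[1] - half_gap, gaps_mid,
            barrels$s_end[nb] + half_gap)
  in_span <- s >= mids[1] && s <= mids[length(mids)]
  cn <- centers[which.min(abs(s - centers))]
  mn <- mids[which.min(abs(s - mids))]
  u <- min(max(abs(s - mn) / abs(cn - mn), 0), 1)
  idx <- if (ramp == "linear") u else (1 - cos(pi * u)) / 2
  list(index = idx, in_span = in_span)
}

# exact length of segment (x1,y1)-(x2,y2) inside the axis-aligned rectangle
# [sx0, sx1] x [dy0, dy1] (Liang-Barsky parametric clipping)
.seg_len_in_rect <- function(x1, y1, x2, y2, sx0, sx1, dy0, dy1) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(0)
  t0 <- 0; t1 <- 1
  for (pq in list(c(-dx, x1 - sx0), c(dx, sx1 - x1),
                  c(-dy, y1 - dy0), c(dy, dy1 - y1))) {
    p <- pq[1]; q <- pq[2]
    if (p == 0) { if (q < 0) return(0) }
    else {
      r <- q / p
      if (p < 0) { if (r > t1) return(0); if (r > t0) t0 <- r }
      else       { if (r < t0) return(0); if (r < t1) t1 <- r }
    }
  }
  max(0, t1 - t0) * len
}

#' Dendritic overlap with barrel territories
#'
#' Clips every dendritic segment of an SWC morphology (in the straightened
#' frame: x = arc length s, y = normal offset d) exactly against each barrel
#' region (tangential interval x L4 band) and reports per-barrel length as a
#' percentage of total dendritic length. The principal barrel is the one
#' holding the majority of dendrite; the adjacent barrel is, by default, the
#' non-principal barrel whose centre is nearest the soma
#' (`adjacent = "second_overlap"` selects the second-highest overlap
#' instead). Neurons with under 5% of their total dendritic length inside
#' any single barrel are flagged for exclusion.
#'
#' @param swc data.frame with SWC columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (parent -1 for the root/soma).
#' @param barrels data.frame: `s_start`, `s_end`, `s_center`.
#' @param l4_band numeric length-2: normal-offset interval of the L4 band.
#' @param adjacent "nearest_center" (default) or "second_overlap".
#' @param exclusion_pct exclusion threshold (default 5).
#' @return list with `total_length`, `per_barrel_pct`, `pct_principal`,
#'   `pct_adjacent`, `pct_outside`, `principal_barrel`, `adjacent_barrel`,
#'   `excluded`.
#' @export
dendritic_overlap <- function(swc, barrels, l4_band,
                              adjacent = c("nearest_center", "second_overlap"),
                              exclusion_pct = 5) {
  adjacent <- match.arg(adjacent)
  stopifnot(all(c("id", "x", "y", "parent") %in% names(swc)))
  idx <- match(swc$parent, swc$id)
  has_par <- !is.na(idx) & swc$parent != -1L
  x1 <- swc$x[has_par]; y1 <- swc$y[has_par]
  x2 <- swc$x[idx[has_par]]; y2 <- swc$y[idx[has_par]]
  seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  total <- sum(seg_len)
  if (total <= 0) stop("zero total dendritic length", call. = FALSE)
  nb <- nrow(barrels)
  in_len <- vapply(seq_len(nb), function(b)
    sum(vapply(seq_along(x1), function(i)
      .seg_len_in_rect(x1[i], y1[i], x2[i], y2[i],
                       barrels$s_start[b], barrels$s_end[b],
                       min(l4_band), max(l4_band)), numeric(1))),
    numeric(1))
  pct <- 100 * in_len / total
  principal <- which.max(in_len)
  soma_s <- swc$x[swc$parent == -1L][1]
  adj <- if (nb < 2) NA_integer_ else if (adjacent == "nearest_center") {
    others <- setdiff(seq_len(nb), principal)
    others[which.min(abs(barrels$s_center[others] - soma_s))]
  } else {
    order(in_len, decreasing = TRUE)[2]
  }
  list(total_length = total,
       per_barrel_pct = pct,
       pct_principal = pct[principal],
       pct_adjacent = if (is.na(adj)) 0 else pct[adj],
       pct_outside = 100 - sum(pct),
       principal_barrel = principal,
       adjacent_barrel = adj,
       excluded = max(pct) < exclusion_pct)
}

#' Mean pixel intensity over a disk-shaped soma mask
#'
#' @param image intensity matrix (rows = y, cols = x, 1 um/px).
#' @param x,y soma centroid (um).
#' @param radius disk radius (um, default 5).
#' @return mean intensity over pixels whose centres fall within the disk.
#' @export
soma_mpi <- function(image, x, y, radius = 5) {
  cols <- pmax(1L, floor(x - radius)):pmin(ncol(image), ceiling(x + radius) + 1L)
  rows <- pmax(1L, floor(y - radius)):pmin(nrow(image), ceiling(y + radius) + 1L)
  cx <- cols - 0.5; cy <- rows - 0.5
  m <- outer(cy, cx, function(yy, xx) (xx - x)^2 + (yy - y)^2 <= radius^2)
  vals <- image[rows, cols, drop = FALSE][m]
  if (!length(vals)) stop("soma mask covers no pixels", call. = FALSE)
  mean(vals)
}

#' Lhx2 mean-pixel-intensity ratio
#'
#' Ratio of a cell's soma MPI over the mean MPI of exactly three neighbouring
#' cells (same z-plane, within the 100 x 100 um region of interest —
#' validated upstream from coordinates). Fewer than three qualifying
#' neighbours is an error, not a fallback.
#'
#' @param cell_mpi MPI of the IP-derived cell.
#' @param neighbor_mpis MPIs of exactly 3 neighbouring OP-derived cells.
#' @return the ratio.
#' @export
lhx2_ratio <- function(cell_mpi, neighbor_mpis) {
  if (length(neighbor_mpis) != 3L)
    stop("exactly 3 qualifying neighbours required", call. = FALSE)
  if (any(neighbor_mpis <= 0)) stop("neighbour MPIs must be > 0", call. = FALSE)
  cell_mpi / mean(neighbor_mpis)
}

# Otsu's threshold on a [0, 65535]-range image
.otsu <- function(img, nbins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) stop("no suprathreshold pixels: constant image",
                           call. = FALSE)
  b <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(img, b, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  b[k + 1L]
}

#' Fraction of suprathreshold expression falling inside an ROI
#'
#' Per section, the fluorescence channel is thresholded (Otsu by default) and
#' the fraction is the number of suprathreshold pixels inside the ROI mask
#' over all suprathreshold pixels. Reports per-section values and their mean
#' (3 sections per brain by convention).
#'
#' @param images list of intensity matrices (or a single matrix).
#' @param roi_masks list of logical matrices congruent with `images`.
#' @param threshold fixed threshold, or `NULL` for Otsu per section.
#' @return list with `per_section` and `mean`.
#' @export
roi_expression_fraction <- function(images, roi_masks, threshold = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(roi_masks) || is.logical(roi_masks)) roi_masks <- list(roi_masks)
  stopifnot(length(images) == length(roi_masks))
  per <- mapply(function(img, roi) {
    stopifnot(all(dim(img) == dim(roi)))
    thr <- if (is.null(threshold)) .otsu(img) else threshold
    supra <- img > thr
    n <- sum(supra)
    if (n == 0) stop("no suprathreshold pixels in section", call. = FALSE)
    sum(supra & roi) / n
  }, images, roi_masks)
  list(per_section = per, mean = mean(per))
}
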