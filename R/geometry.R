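#' Calibrated area of a binary region mask
#'
#' Area is the foreground pixel count scaled by the squared calibration, the
#' raster analogue of the slide-viewer's region-area readout. Doubling
#' \code{um_per_px} quadruples the area (scale equivariance).
#'
#' @param mask binary matrix (any nonzero value is foreground), indexed
#'   \code{[y + 1, x + 1]}.
#' @param um_per_px isotropic calibration in micrometres per pixel.
#' @return Area in square micrometres.
#' @examples
#' m <- matrix(0, 20, 20); m[6:15, 6:15] <- 1
#' region_area(m, um_per_px = 1)  # 100 um^2
#' @export
region_area <- function(mask, um_per_px) {
  assert_scalar_pos(um_per_px, "um_per_px")
  m <- as_binary_mask(mask)
  n <- sum(m)
  if (n == 0L) stop("empty mask: area undefined", call. = FALSE)
  n * um_per_px^2
}

#' Calibrated perimeter of a binary region mask
#'
#' The boundary is traced as a sub-pixel iso-contour: the mask is lightly
#' smoothed with a Gaussian (default sigma 1 px) and the polygon at level 0.5
#' is extracted by marching squares; its length times the calibration is the
#' perimeter. This emulates the smooth vector outline a human traces in the
#' slide viewer, and is accurate to well under 2\% on rasterized disks
#' (pixel-edge counting, by contrast, overestimates circles by ~27\%). For
#' masks with holes only the outer contour is measured.
#'
#' @inheritParams region_area
#' @param smooth_sigma Gaussian pre-smoothing bandwidth in pixels.
#' @return Perimeter in micrometres.
#' @export
region_perimeter <- function(mask, um_per_px, smooth_sigma = 1) {
  assert_scalar_pos(um_per_px, "um_per_px")
  m <- as_binary_mask(mask)
  if (sum(m) == 0L) stop("empty mask: perimeter undefined", call. = FALSE)
  nc <- n_components(m)
  if (nc != 1L) {
    stop(sprintf("perimeter requires a single connected component (found %d)", nc),
         call. = FALSE)
  }
  pad <- max(4L, ceiling(3 * smooth_sigma) + 1L)
  mp <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  sm <- if (smooth_sigma > 0) {
    from_eb(EBImage::gblur(to_eb(mp), sigma = smooth_sigma))
  } else {
    mp
  }
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                                z = sm, levels = 0.5)
  if (length(cl) == 0L) stop("no iso-contour found (mask too small?)", call. = FALSE)
  closed_length <- function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  # outer contour of a single component is the longest closed loop
  max(vapply(cl, closed_length, numeric(1))) * um_per_px
}

#' The two longest perpendicular diameters of a region
#'
#' \code{diameter_1} is the maximum Feret (caliper) diameter, computed as the
#' largest pairwise distance between convex-hull vertices of the foreground
#' pixel centres. \code{diameter_2} is the caliper extent measured
#' perpendicular to \code{diameter_1}'s direction. When several directions tie
#' for the maximum (e.g. a disk), the smallest angle in \[0, pi) is used, so
#' the result is reproducible.
#'
#' @inheritParams region_area
#' @return Named numeric vector \code{c(diameter_1, diameter_2)} in
#'   micrometres, with \code{diameter_1 >= diameter_2}.
#' @export
perpendicular_diameters <- function(mask, um_per_px) {
  assert_scalar_pos(um_per_px, "um_per_px")
  m <- as_binary_mask(mask)
  if (sum(m) < 4L) {
    stop("degenerate mask (< 4 px): diameters undefined", call. = FALSE)
  }
  nc <- n_components(m)
  if (nc != 1L) {
    stop(sprintf("diameters require a single connected component (found %d)", nc),
         call. = FALSE)
  }
  xy <- mask_coords(m)
  hull <- xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE]
  d2 <- as.matrix(stats::dist(hull))
  dmax <- max(d2)
  cand <- which(d2 >= dmax - 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  # tie-break: smallest direction angle in [0, pi)
  ang <- apply(cand, 1, function(ij) {
    v <- hull[ij[2], ] - hull[ij[1], ]
    a <- atan2(v[2], v[1]) %% pi
    if (a >= pi - 1e-12) a <- 0
    a
  })
  pick <- cand[which.min(ang), ]
  u <- hull[pick[2], ] - hull[pick[1], ]
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])
  proj <- hull %*% v
  c(diameter_1 = dmax * um_per_px,
    diameter_2 = (max(proj) - min(proj)) * um_per_px)
}

#' Average of two perpendicular diameters
#'
#' The average-diameter summary used for the whole testis cross-section, for
#' individual tubules and for their lumina: \code{(d1 + d2) / 2}.
#'
#' @param d1,d2 the two perpendicular diameters in micrometres (> 0).
#' @return Average diameter in micrometres.
#' @examples
#' average_diameter(160, 80)  # 120
#' @export
average_diameter <- function(d1, d2) {
  assert_scalar_pos(d1, "d1")
  assert_scalar_pos(d2, "d2")
  (d1 + d2) / 2
}

#' Spermatogenic epithelium thickness at five random points
#'
#' Emulates the manual protocol of measuring the epithelium at five randomly
#' chosen points: five rays are cast from the lumen centroid at seeded
#' uniform-random angles; each thickness sample is the distance along a ray
#' between its lumen-boundary crossing and its outer (tubule) boundary
#' crossing, and the summary is their arithmetic mean. Identical seeds yield
#' identical samples. For strongly non-convex lumina a ray may exit and
#' re-enter; the first outward crossing pair is used and a warning is issued.
#'
#' @param tubule binary mask of the whole tubule (epithelium + lumen).
#' @param lumen binary mask of the lumen; must be contained in \code{tubule}.
#' @param um_per_px isotropic calibration in micrometres per pixel.
#' @param seed integer seed for the ray angles.
#' @param n_rays number of rays (the protocol uses 5).
#' @param step ray-marching step in pixels.
#' @param max_retries bound on angle resampling when a ray fails to cross both
#'   boundaries.
#' @return A list of class \code{thickness_sample} with elements
#'   \code{lengths} (micrometres, one per ray), \code{mean}, \code{angles}
#'   (radians) and \code{seed}.
#' @export
epithelium_thickness <- function(tubule, lumen, um_per_px, seed,
                                 n_rays = 5L, step = 0.1, max_retries = 50L) {
  assert_scalar_pos(um_per_px, "um_per_px")
  tm <- as_binary_mask(tubule)
  lm <- as_binary_mask(lumen)
  if (!identical(dim(tm), dim(lm))) stop("mask dimensions differ", call. = FALSE)
  if (sum(lm) == 0L) stop("empty lumen mask", call. = FALSE)
  if (any(lm > tm)) stop("lumen mask not contained in tubule mask", call. = FALSE)

  coords <- mask_coords(lm)
  cx <- mean(coords[, 1]); cy <- mean(coords[, 2])
  inside <- function(m, x, y) {
    r <- round(y) + 1; c <- round(x) + 1
    r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c] > 0
  }
  if (!inside(lm, cx, cy)) {
    warning("lumen centroid falls outside the lumen (non-convex lumen); ",
            "rays start from the nearest lumen pixel")
    i <- which.min((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2)
    cx <- coords[i, 1]; cy <- coords[i, 2]
  }
  tmax <- sqrt(nrow(tm)^2 + ncol(tm)^2)
  ts <- seq(0, tmax, by = step)

  # bilinear occupancy: interpolating the binary mask localises the boundary
  # crossing at sub-pixel precision (a nearest-neighbour lookup quantizes each
  # crossing to half a pixel)
  lookup <- function(m, xs, ys) {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    at <- function(r, c) {
      ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
      v <- numeric(length(r))
      v[ok] <- m[cbind(r[ok], c[ok])]
      v
    }
    val <- at(y0 + 1, x0 + 1) * (1 - fx) * (1 - fy) +
      at(y0 + 1, x0 + 2) * fx * (1 - fy) +
      at(y0 + 2, x0 + 1) * (1 - fx) * fy +
      at(y0 + 2, x0 + 2) * fx * fy
    val >= 0.5
  }

  cast <- function(theta) {
    xs <- cx + ts * cos(theta); ys <- cy + ts * sin(theta)
    in_lum <- lookup(lm, xs, ys)
    in_tub <- lookup(tm, xs, ys)
    exit_l <- which(!in_lum)[1]
    exit_t <- which(!in_tub)[1]
    if (is.na(exit_l) || is.na(exit_t) || exit_t <= exit_l) return(NA_real_)
    if (any(in_lum[exit_l:length(ts)])) {
      warning("ray re-enters the lumen; using first outward crossing pair")
    }
    # crossings at the midpoint between the last inside and first outside step
    t_l <- (ts[exit_l - 1] + ts[exit_l]) / 2
    t_t <- (ts[exit_t - 1] + ts[exit_t]) / 2
    (t_t - t_l) * um_per_px
  }

  angles0 <- with_seed(seed, runif(n_rays + max_retries, 0, 2 * pi))
  lengths <- numeric(0); used <- numeric(0); k <- 0L
  for (a in angles0) {
    k <- k + 1L
    len <- cast(a)
    if (!is.na(len) && len > 0) {
      lengths <- c(lengths, len); used <- c(used, a)
      if (length(lengths) == n_rays) break
    }
  }
  if (length(lengths) < n_rays) {
    stop(sprintf("could not place %d valid rays after %d attempts", n_rays, k),
         call. = FALSE)
  }
  structure(list(lengths = lengths, mean = mean(lengths),
                 angles = used, seed = seed),
            class = "thickness_sample")
}

#' @export
print.thickness_sample <- function(x, ...) {
  cat(sprintf("<thickness_sample> n=%d, mean=%.3f um (seed %d)\n",
              length(x$lengths), x$mean, x$seed))
  invisible(x)
}

#' Full shape metrics for one region
#'
#' Convenience wrapper bundling [region_area()], [region_perimeter()],
#' [perpendicular_diameters()] and [average_diameter()] into one record.
#'
#' @inheritParams region_perimeter
#' @return A one-row data.frame: \code{area}, \code{perimeter},
#'   \code{diameter_1}, \code{diameter_2}, \code{diameter_avg}.
#' @export
shape_metrics <- function(mask, um_per_px, smooth_sigma = 1) {
  d <- perpendicular_diameters(mask, um_per_px)
  data.frame(
    area = region_area(mask, um_per_px),
    perimeter = region_perimeter(mask, um_per_px, smooth_sigma = smooth_sigma),
    diameter_1 = unname(d[1]),
    diameter_2 = unname(d[2]),
    diameter_avg = average_diameter(d[1], d[2])
  )
}
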