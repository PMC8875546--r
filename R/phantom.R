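# H&E-like rendering palette (RGB, 0-255). Epithelium is the dark ring the
# tubule segmenter keys on; speckles are darker still so the spermatid
# detector can separate them from epithelium by intensity alone.
HE_PALETTE <- list(
  background   = c(255, 255, 255),
  interstitium = c(244, 214, 223),
  epithelium   = c(150,  90, 150),
  lumen        = c(240, 236, 244),
  speckle      = c( 45,  30,  60)
)

#' Specification of a synthetic testis-section phantom
#'
#' Parametric description of a roughly circular testis cross-section packed
#' with non-overlapping elliptical seminiferous tubules, each an annulus of
#' spermatogenic epithelium around a lumen. A configurable minority of tubules
#' is longitudinally sectioned (high-aspect ellipses) and a configurable
#' fraction of the cross-sectioned tubules carries the elongated-spermatid
#' marker (dark elongated speckles at the lumen border). The defaults describe
#' a rodent-scale section at a density where tubules occupy roughly a third of
#' the tissue; they are rendering conventions, not measured morphology.
#'
#' @param section_radius_um radius of the circular tissue section (um).
#' @param n_tubules number of tubules to pack.
#' @param tubule_radius_um length-2 vector: mean and sd of the equivalent
#'   tubule radius (um).
#' @param lumen_fraction ratio of lumen semi-axes to tubule semi-axes, in
#'   (0, 1) (epithelium thickness strictly positive).
#' @param longitudinal_fraction fraction of tubules rendered as longitudinal
#'   sections (aspect ratio >= 2.5), in \[0, 1).
#' @param spermatid_positive_fraction fraction of the cross-sectioned tubules
#'   flagged elongated-spermatid-positive, in \[0, 1\].
#' @param calibration_um_per_px isotropic calibration of the rendered rasters.
#' @param seed integer seed; identical specs render identical phantoms.
#' @param ihc_dab_od optical density of DAB on positive structures in the IHC
#'   rendering.
#' @param ihc_hema_od optical density of the hematoxylin counterstain over all
#'   tissue (0 = no counterstain).
#' @return An object of class \code{phantom_spec}.
#' @examples
#' spec <- phantom_spec(n_tubules = 10, seed = 7)
#' @export
phantom_spec <- function(section_radius_um = 450,
                         n_tubules = 30,
                         tubule_radius_um = c(45, 5),
                         lumen_fraction = 0.55,
                         longitudinal_fraction = 0.1,
                         spermatid_positive_fraction = 0.7,
                         calibration_um_per_px = 1,
                         seed = 1L,
                         ihc_dab_od = 0.8,
                         ihc_hema_od = 0.3) {
  assert_scalar_pos(section_radius_um, "section_radius_um")
  stopifnot(length(tubule_radius_um) == 2L, tubule_radius_um[1] > 0,
            tubule_radius_um[2] >= 0)
  if (!is.numeric(n_tubules) || n_tubules < 1) stop("n_tubules must be >= 1", call. = FALSE)
  assert_fraction(lumen_fraction, "lumen_fraction", open_left = TRUE, open_right = TRUE)
  assert_fraction(longitudinal_fraction, "longitudinal_fraction", open_right = TRUE)
  assert_fraction(spermatid_positive_fraction, "spermatid_positive_fraction")
  assert_scalar_pos(calibration_um_per_px, "calibration_um_per_px")
  if (ihc_dab_od < 0 || ihc_hema_od < 0) stop("stain ODs must be >= 0", call. = FALSE)
  structure(list(
    section_radius_um = section_radius_um,
    n_tubules = as.integer(n_tubules),
    tubule_radius_um = tubule_radius_um,
    lumen_fraction = lumen_fraction,
    longitudinal_fraction = longitudinal_fraction,
    spermatid_positive_fraction = spermatid_positive_fraction,
    calibration_um_per_px = calibration_um_per_px,
    seed = as.integer(seed),
    ihc_dab_od = ihc_dab_od,
    ihc_hema_od = ihc_hema_od
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d tubules in a %.0f um section (%.4g um/px, seed %d)\n",
    x$n_tubules, x$section_radius_um, x$calibration_um_per_px, x$seed))
  invisible(x)
}

#' Generate a phantom scene by seeded rejection packing
#'
#' Samples tubule sizes, shapes and flags from the spec, then places the
#' tubules largest-first by rejection sampling inside the section circle with
#' a minimum 2 px gap between bounding circles, which guarantees the rendered
#' tubules are pairwise disjoint and separable by the segmenter. Exactly
#' \code{round(n_tubules * longitudinal_fraction)} tubules are flagged
#' longitudinal and exactly
#' \code{round(n_tubules * spermatid_positive_fraction)} of the
#' non-longitudinal tubules are flagged spermatid-positive. Identical specs
#' give identical scenes.
#'
#' @param spec a [phantom_spec()].
#' @param max_attempts total rejection-sampling attempts per tubule before the
#'   packing is declared infeasible.
#' @param gap_px minimum gap between tubule bounding circles, pixels.
#' @return An object of class \code{phantom_scene}: the per-tubule table
#'   (centre, semi-axes, orientation, lumen semi-axes, flags, all in pixel
#'   units), the section circle, speckle slots and the raster dimensions.
#' @export
generate_scene <- function(spec, max_attempts = 20000L, gap_px = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  cal <- spec$calibration_um_per_px
  R <- spec$section_radius_um / cal
  n <- spec$n_tubules
  margin <- 6
  side <- ceiling(2 * (R + margin))
  c0 <- (side - 1) / 2

  with_seed(spec$seed, {
    r_mean <- spec$tubule_radius_um[1] / cal
    r_sd <- spec$tubule_radius_um[2] / cal
    radii <- rnorm(n, r_mean, r_sd)
    radii <- pmax(radii, 0.5 * r_mean)

    n_long <- round(n * spec$longitudinal_fraction)
    is_long <- rep(FALSE, n)
    if (n_long > 0) is_long[sample.int(n, n_long)] <- TRUE
    cross_ids <- which(!is_long)
    n_pos <- round(n * spec$spermatid_positive_fraction)
    if (n_pos > length(cross_ids)) {
      stop("spermatid_positive_fraction requires more positive tubules than ",
           "there are cross-sectioned tubules", call. = FALSE)
    }
    is_pos <- rep(FALSE, n)
    if (n_pos > 0) is_pos[sample(cross_ids, n_pos)] <- TRUE

    aspect <- ifelse(is_long, runif(n, 2.5, 3.2), runif(n, 1.0, 1.25))
    a <- radii * sqrt(aspect)
    b <- radii / sqrt(aspect)
    theta <- runif(n, 0, pi)

    # place largest bounding circles first; rejection sampling with min gap
    ord <- order(a, decreasing = TRUE)
    cx <- cy <- rep(NA_real_, n)
    placed <- integer(0)
    for (k in ord) {
      rmax <- R - a[k] - 1
      if (rmax <= 0) {
        stop(sprintf("packing infeasible: tubule radius %.1f px exceeds section", a[k]),
             call. = FALSE)
      }
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        rr <- rmax * sqrt(runif(1)); ph <- runif(1, 0, 2 * pi)
        x <- c0 + rr * cos(ph); y <- c0 + rr * sin(ph)
        if (length(placed) == 0L ||
            all(sqrt((cx[placed] - x)^2 + (cy[placed] - y)^2) >=
                a[placed] + a[k] + gap_px)) {
          cx[k] <- x; cy[k] <- y; placed <- c(placed, k); ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "packing infeasible: could not place tubule after %d attempts (limit)",
          max_attempts), call. = FALSE)
      }
    }

    lf <- spec$lumen_fraction
    tub <- data.frame(
      label = seq_len(n),
      center_x_px = cx, center_y_px = cy,
      semi_major_px = a, semi_minor_px = b,
      orientation_rad = theta,
      lumen_semi_major_px = lf * a, lumen_semi_minor_px = lf * b,
      is_longitudinal = is_long,
      is_spermatid_positive = is_pos
    )

    # speckle slots: 6 of 12 evenly spaced parametric angles per positive tubule
    spk <- do.call(rbind, lapply(which(is_pos), function(i) {
      slots <- sort(sample.int(12L, 6L))
      data.frame(label = i,
                 phi = (slots - 1) * pi / 6 + runif(6, -0.08, 0.08))
    }))
    if (is.null(spk)) spk <- data.frame(label = integer(0), phi = numeric(0))

    structure(list(
      spec = spec,
      tubules = tub,
      section = list(cx = c0, cy = c0, r = R),
      speckles = spk,
      dim = c(side, side)
    ), class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d tubules (%d longitudinal, %d spermatid+), %d x %d px\n",
              nrow(x$tubules), sum(x$tubules$is_longitudinal),
              sum(x$tubules$is_spermatid_positive), x$dim[2], x$dim[1]))
  invisible(x)
}

# Rasterize an ellipse on an h x w grid: pixel centres (0-based) satisfying
# the implicit equation after rotation by -theta. Returns a logical matrix.
rasterize_ellipse <- function(h, w, cx, cy, a, b, theta = 0) {
  i0 <- max(1L, floor(cy - a) + 1L); i1 <- min(h, ceiling(cy + a) + 1L)
  j0 <- max(1L, floor(cx - a) + 1L); j1 <- min(w, ceiling(cx + a) + 1L)
  m <- matrix(FALSE, h, w)
  if (i0 > i1 || j0 > j1) return(m)
  ys <- (i0:i1) - 1 - cy
  xs <- (j0:j1) - 1 - cx
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  m[i0:i1, j0:j1] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Rasterize a rotated rectangle (speckle) centred at (cx, cy) with unit
# direction (dx, dy), half-length hl and half-width hw.
rasterize_bar <- function(h, w, cx, cy, dx, dy, hl, hw) {
  ext <- hl + hw + 1
  i0 <- max(1L, floor(cy - ext) + 1L); i1 <- min(h, ceiling(cy + ext) + 1L)
  j0 <- max(1L, floor(cx - ext) + 1L); j1 <- min(w, ceiling(cx + ext) + 1L)
  m <- matrix(FALSE, h, w)
  if (i0 > i1 || j0 > j1) return(m)
  ys <- (i0:i1) - 1 - cy
  xs <- (j0:j1) - 1 - cx
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  t_ <- X * dx + Y * dy
  n_ <- -X * dy + Y * dx
  m[i0:i1, j0:j1] <- abs(t_) <= hl & abs(n_) <= hw
  m
}

# Per-tubule ground-truth masks from the scene, same rasterizer as render_he.
scene_masks <- function(scene) {
  h <- scene$dim[1]; w <- scene$dim[2]
  section <- rasterize_ellipse(h, w, scene$section$cx, scene$section$cy,
                               scene$section$r, scene$section$r)
  tubule_labels <- matrix(0L, h, w)
  lumen_labels <- matrix(0L, h, w)
  for (i in seq_len(nrow(scene$tubules))) {
    t <- scene$tubules[i, ]
    om <- rasterize_ellipse(h, w, t$center_x_px, t$center_y_px,
                            t$semi_major_px, t$semi_minor_px, t$orientation_rad)
    lmm <- rasterize_ellipse(h, w, t$center_x_px, t$center_y_px,
                             t$lumen_semi_major_px, t$lumen_semi_minor_px,
                             t$orientation_rad)
    tubule_labels[om] <- t$label
    lumen_labels[lmm] <- t$label
  }
  list(section = matrix(as.integer(section), h, w),
       tubule_labels = tubule_labels, lumen_labels = lumen_labels)
}

# Speckle mask for one tubule: bars placed just inside the lumen boundary
# (parametric radius 0.85), oriented along the local tangent, clipped to the
# lumen so ground-truth containment is exact by construction.
speckle_mask_for <- function(scene, label, lumen_mask) {
  h <- scene$dim[1]; w <- scene$dim[2]
  t <- scene$tubules[scene$tubules$label == label, ]
  phis <- scene$speckles$phi[scene$speckles$label == label]
  m <- matrix(FALSE, h, w)
  if (length(phis) == 0L) return(m)
  ct <- cos(t$orientation_rad); st <- sin(t$orientation_rad)
  la <- t$lumen_semi_major_px; lb <- t$lumen_semi_minor_px
  for (phi in phis) {
    px <- 0.85 * la * cos(phi); py <- 0.85 * lb * sin(phi)
    qx <- t$center_x_px + px * ct - py * st
    qy <- t$center_y_px + px * st + py * ct
    tx0 <- -la * sin(phi); ty0 <- lb * cos(phi)
    tn <- sqrt(tx0^2 + ty0^2); tx0 <- tx0 / tn; ty0 <- ty0 / tn
    dx <- tx0 * ct - ty0 * st
    dy <- tx0 * st + ty0 * ct
    m <- m | rasterize_bar(h, w, qx, qy, dx, dy, hl = 3.5, hw = 0.8)
  }
  m & (lumen_mask > 0)
}

#' Render a phantom scene as an H&E-like calibrated image
#'
#' Paints pale interstitium inside the section circle, a dark epithelium ring
#' and pale lumen per tubule, and - for spermatid-positive tubules - at least
#' five dark elongated speckles adjacent to the lumen boundary (the detection
#' substrate for [detect_spermatid_positive()]). Ground-truth label masks come
#' from the same rasterizer, so mask areas match rendered structures pixel for
#' pixel. Rendering is fully deterministic given the scene.
#'
#' @param scene a [generate_scene()] result.
#' @return A list: \code{image} (a [calibrated_image()]), \code{section_mask}
#'   (0/1), \code{tubule_labels} and \code{lumen_labels} (integer label
#'   matrices, background 0, label i's lumen inside label i's tubule), and
#'   \code{speckle_mask} (0/1).
#' @export
render_he <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  h <- scene$dim[1]; w <- scene$dim[2]
  gm <- scene_masks(scene)
  img <- array(0, dim = c(h, w, 3))
  paint <- function(img, mask, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask > 0] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, matrix(1, h, w), HE_PALETTE$background)
  img <- paint(img, gm$section, HE_PALETTE$interstitium)
  img <- paint(img, gm$tubule_labels, HE_PALETTE$epithelium)
  img <- paint(img, gm$lumen_labels, HE_PALETTE$lumen)
  spk <- matrix(FALSE, h, w)
  for (lab in unique(scene$speckles$label)) {
    spk <- spk | speckle_mask_for(scene, lab, gm$lumen_labels == lab)
  }
  img <- paint(img, spk, HE_PALETTE$speckle)
  list(image = calibrated_image(img, scene$spec$calibration_um_per_px),
       section_mask = gm$section,
       tubule_labels = gm$tubule_labels,
       lumen_labels = gm$lumen_labels,
       speckle_mask = matrix(as.integer(spk), h, w))
}

#' Beer-Lambert forward rendering of stain concentration fields
#'
#' Computes per-pixel transmitted RGB from optical-density concentration
#' fields: \code{RGB = round(255 * 10^(-M c))} clipped to \[0, 255\], where M
#' is the stain matrix and c the per-pixel concentration vector. Rounding is
#' round-half-to-even, making re-rendering bit-exact.
#'
#' @param conc numeric array \code{h x w x 3}: concentration (OD) fields in
#'   stain order matching the columns of \code{stains}.
#' @param stains a [stain_matrix()].
#' @return Integer RGB array \code{h x w x 3}.
#' @export
beer_lambert_render <- function(conc, stains) {
  stopifnot(inherits(stains, "stain_matrix"))
  stopifnot(is.array(conc), length(dim(conc)) == 3L, dim(conc)[3] == 3L)
  h <- dim(conc)[1]; w <- dim(conc)[2]
  cm <- matrix(conc, ncol = 3)          # npix x 3 (stain space)
  od <- cm %*% t(unclass(stains))       # npix x 3 (RGB absorbance)
  I <- round(255 * 10^(-od))
  I[I < 0] <- 0; I[I > 255] <- 255
  array(I, dim = c(h, w, 3))
}

#' Render a phantom scene as an IHC-like calibrated image
#'
#' Builds ground-truth concentration fields - DAB at \code{ihc_dab_od} on the
#' positive structures (by default the spermatogenic epithelium of
#' spermatid-positive tubules), hematoxylin counterstain at \code{ihc_hema_od}
#' over all tissue - and renders them with the Beer-Lambert forward model.
#' The concentration fields are returned losslessly alongside the 8-bit image,
#' so deconvolution round-trips can be checked against exact truth.
#'
#' @param scene a [generate_scene()] result.
#' @param stains a [stain_matrix()]; must be invertible.
#' @param dab_mask optional 0/1 matrix overriding the default positive
#'   structures.
#' @return A list: \code{image}, \code{conc} (h x w x 3 array in stain order
#'   hematoxylin, DAB, residual), \code{dab_mask}, \code{tissue_mask}.
#' @export
render_ihc <- function(scene, stains = stain_matrix("h-dab"), dab_mask = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  stopifnot(inherits(stains, "stain_matrix"))
  h <- scene$dim[1]; w <- scene$dim[2]
  gm <- scene_masks(scene)
  tissue <- gm$section
  if (is.null(dab_mask)) {
    pos <- scene$tubules$label[scene$tubules$is_spermatid_positive]
    dab_mask <- matrix(as.integer(
      gm$tubule_labels %in% pos & !(gm$lumen_labels %in% pos)), h, w)
    dab_mask[gm$tubule_labels == 0] <- 0L
  } else {
    dab_mask <- as_binary_mask(dab_mask)
  }
  conc <- array(0, dim = c(h, w, 3))
  conc[, , 1] <- scene$spec$ihc_hema_od * (tissue > 0)
  conc[, , 2] <- scene$spec$ihc_dab_od * (dab_mask > 0)
  img <- beer_lambert_render(conc, stains)
  list(image = calibrated_image(img, scene$spec$calibration_um_per_px),
       conc = conc, dab_mask = dab_mask, tissue_mask = tissue)
}

#' Write a phantom's ground truth to disk
#'
#' Writes the rendered images (PNG), the label masks (16-bit TIFF), the
#' per-tubule ground-truth table (CSV; pixel-unit geometry plus flags) and the
#' generating spec (YAML) into a directory.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory, created if missing.
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  he <- render_he(scene)
  write_image(he$image, file.path(dir, "he.png"))
  write_mask(he$section_mask, file.path(dir, "section_mask.tiff"))
  write_mask(he$tubule_labels, file.path(dir, "tubule_labels.tiff"))
  write_mask(he$lumen_labels, file.path(dir, "lumen_labels.tiff"))
  ihc <- render_ihc(scene)
  write_image(ihc$image, file.path(dir, "ihc.png"))
  write_mask(ihc$dab_mask, file.path(dir, "dab_mask.tiff"))
  write_report_csv(scene$tubules, file.path(dir, "scene_tubules.csv"))
  yaml::write_yaml(unclass(scene$spec), file.path(dir, "phantom_spec.yml"))
  invisible(dir)
}
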