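# Automated counterparts of the manual selection steps, validated against
# phantoms only: every threshold is a configurable convention, not a claim
# about real slides.

#' Delineate the tissue section
#'
#' Thresholds the image against the pale background (tissue pixels are darker
#' than \code{white_level} in gray), labels connected components, keeps the
#' largest and fills its holes. When several candidate components exist their
#' count is reported via a message.
#'
#' @param image a [calibrated_image()].
#' @param white_level gray level (0-255) above which a pixel counts as
#'   background.
#' @return Binary 0/1 section mask.
#' @export
segment_section <- function(image, white_level = 250) {
  stopifnot(inherits(image, "cathi_image"))
  gray <- image_gray(image)
  tissue <- gray < white_level
  if (!any(tissue)) stop("no tissue found (image is blank)", call. = FALSE)
  lab <- from_eb(EBImage::bwlabel(to_eb(matrix(as.integer(tissue), nrow(gray)))))
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) > 1L) {
    message(sprintf("segment_section: %d candidate components, keeping the largest",
                    length(sizes)))
  }
  keep <- which.max(sizes)
  m <- matrix(as.integer(lab == keep), nrow(gray))
  from_eb(EBImage::fillHull(to_eb(m)))
}

#' Label individual tubules and their lumina
#'
#' Detects the dark epithelium rings inside the section by a gray-level
#' threshold, closes small gaps, fills each ring to a full tubule region,
#' optionally splits touching tubules by a distance-transform watershed, and
#' removes regions below a minimum size. The lumen of each tubule is its
#' largest interior pale region (hole-filled, so intraluminal speckles belong
#' to the lumen). Labels are renumbered 1..n in raster-scan order; lumen
#' labels match tubule labels.
#'
#' @param image a [calibrated_image()].
#' @param section_mask binary section mask from [segment_section()].
#' @param epithelium_gray_max gray level at or below which a pixel counts as
#'   epithelium (or darker, e.g. spermatid speckles).
#' @param min_size_um2 minimum tubule area; smaller regions (debris, artifact
#'   blobs) are dropped.
#' @param split_touching run the watershed split.
#' @param watershed_tolerance minimum object-height difference (px) for the
#'   watershed to declare two tubules; large values avoid over-segmenting
#'   elongated profiles.
#' @return A list: \code{tubule_labels}, \code{lumen_labels} (integer
#'   matrices, label-matched, background 0), \code{missing_lumen} (labels
#'   without a detectable lumen), \code{params}.
#' @export
segment_tubules <- function(image, section_mask,
                            epithelium_gray_max = 180,
                            min_size_um2 = 500,
                            split_touching = TRUE,
                            watershed_tolerance = 10) {
  stopifnot(inherits(image, "cathi_image"))
  section_mask <- as_binary_mask(section_mask)
  gray <- image_gray(image)
  dark <- (gray <= epithelium_gray_max) & (section_mask > 0)
  m <- matrix(as.integer(dark), nrow(gray))
  kern <- EBImage::makeBrush(3, "diamond")
  closed <- EBImage::closing(to_eb(m), kern)
  filled <- EBImage::fillHull(closed)
  if (split_touching) {
    dm <- EBImage::distmap(filled)
    lab_eb <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  } else {
    lab_eb <- EBImage::bwlabel(filled)
  }
  lab <- from_eb(lab_eb)

  # minimum-size filter, then deterministic renumbering in raster-scan order
  px_area <- image$um_per_px^2
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes * px_area < min_size_um2)
  lab[lab %in% drop] <- 0L
  old <- unique(as.vector(t(lab))[as.vector(t(lab)) > 0])  # row-major scan
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(old)) relab[lab == old[i]] <- i

  # lumen: largest hole-filled pale region inside each tubule
  lumen <- matrix(0L, nrow(lab), ncol(lab))
  missing_lumen <- integer(0)
  pale <- gray > epithelium_gray_max
  for (i in seq_along(old)) {
    inside <- relab == i & pale
    if (!any(inside)) { missing_lumen <- c(missing_lumen, i); next }
    li <- from_eb(EBImage::bwlabel(to_eb(matrix(as.integer(inside), nrow(lab)))))
    ls <- tabulate(li[li > 0])
    if (length(ls) == 0L) { missing_lumen <- c(missing_lumen, i); next }
    big <- which.max(ls)
    lm <- matrix(as.integer(li == big), nrow(lab))
    lm <- from_eb(EBImage::fillHull(to_eb(lm)))
    # a real lumen is interior: it must not touch the tubule's outer boundary
    if (ls[big] * px_area < 0.01 * sum(relab == i) * px_area) {
      missing_lumen <- c(missing_lumen, i)
      next
    }
    lumen[lm > 0 & relab == i] <- i
  }
  if (length(missing_lumen) > 0) {
    message("segment_tubules: no lumen detected for label(s) ",
            paste(missing_lumen, collapse = ", "))
  }
  list(tubule_labels = relab, lumen_labels = lumen,
       missing_lumen = missing_lumen,
       params = list(epithelium_gray_max = epithelium_gray_max,
                     min_size_um2 = min_size_um2,
                     split_touching = split_touching,
                     watershed_tolerance = watershed_tolerance))
}

#' Classify a tubule profile as cross- or longitudinal-sectioned
#'
#' The aspect ratio of the best-fit ellipse (square root of the ratio of the
#' principal second moments of the pixel coordinates) decides the section
#' plane: profiles more elongated than \code{threshold} are longitudinal and
#' excluded from per-tubule geometric measurement.
#'
#' @param mask binary mask of a single tubule.
#' @param threshold aspect-ratio cutoff (default 1.8, a convention sitting
#'   between near-circular cross profiles and elongated longitudinal ones).
#' @return \code{"cross"} or \code{"longitudinal"}.
#' @export
classify_plane <- function(mask, threshold = 1.8) {
  m <- as_binary_mask(mask)
  if (sum(m) < 4L) stop("degenerate mask: plane undefined", call. = FALSE)
  if (mask_aspect_ratio(m) > threshold) "longitudinal" else "cross"
}

# Best-fit-ellipse aspect ratio from the coordinate covariance eigenvalues.
mask_aspect_ratio <- function(mask) {
  xy <- mask_coords(mask)
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-9)
  sqrt(ev[1] / ev[2])
}

#' Detect the elongated-spermatid marker in one tubule
#'
#' A tubule is elongated-spermatid-positive when at least \code{k} dark
#' elongated blobs (eccentricity >= \code{min_eccentricity}, length >=
#' \code{min_length_px}) lie in the peri-luminal band - the lumen dilated by
#' 10 percent of the tubule's equivalent radius. Deterministic given the image
#' and parameters. Without a lumen mask the whole tubule interior is searched
#' and a warning is issued.
#'
#' @param image a [calibrated_image()].
#' @param tubule_mask binary mask of the tubule.
#' @param lumen_mask binary mask of its lumen (or NULL).
#' @param dark_gray_max gray level at or below which a pixel belongs to a
#'   candidate spermatid (well below the epithelium gray).
#' @param k minimum number of qualifying blobs.
#' @param min_length_px minimum blob length (max Feret, px).
#' @param min_eccentricity minimum blob eccentricity.
#' @return Logical flag.
#' @export
detect_spermatid_positive <- function(image, tubule_mask, lumen_mask,
                                      dark_gray_max = 100, k = 3L,
                                      min_length_px = 3, min_eccentricity = 0.9) {
  stopifnot(inherits(image, "cathi_image"))
  tm <- as_binary_mask(tubule_mask)
  gray <- image_gray(image)
  if (is.null(lumen_mask) || sum(lumen_mask > 0) == 0L) {
    warning("no lumen mask: searching the whole tubule interior")
    band <- tm > 0
  } else {
    lm <- as_binary_mask(lumen_mask)
    eq_r <- sqrt(sum(tm) / pi)
    r <- max(1L, round(0.10 * eq_r))
    brush <- EBImage::makeBrush(2L * r + 1L, "disc")
    band <- from_eb(EBImage::dilate(to_eb(lm), brush)) > 0 & tm > 0
  }
  cand <- band & gray <= dark_gray_max
  if (!any(cand)) return(FALSE)
  lab <- from_eb(EBImage::bwlabel(to_eb(matrix(as.integer(cand), nrow(gray)))))
  n_ok <- 0L
  for (b in seq_len(max(lab))) {
    xy <- mask_coords(lab == b)
    if (nrow(xy) < 2L) next
    len <- max(stats::dist(xy))
    if (len < min_length_px) next
    ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 1e-9)
    ecc <- sqrt(1 - ev[2] / ev[1])
    if (ecc >= min_eccentricity) n_ok <- n_ok + 1L
    if (n_ok >= k) return(TRUE)
  }
  FALSE
}

#' Segment a full H&E image
#'
#' Convenience wrapper: [segment_section()], [segment_tubules()], per-label
#' [classify_plane()] and [detect_spermatid_positive()], assembled into one
#' result with a per-label flag table.
#'
#' @param image a [calibrated_image()].
#' @param params named list overriding segmentation parameters
#'   (\code{white_level}, \code{epithelium_gray_max}, \code{min_size_um2},
#'   \code{split_touching}, \code{watershed_tolerance},
#'   \code{aspect_threshold}, \code{dark_gray_max}, \code{k}).
#' @return A list of class \code{segmentation_result}: \code{section_mask},
#'   \code{tubule_labels}, \code{lumen_labels}, \code{flags} (data.frame:
#'   label, plane, is_longitudinal, is_spermatid_positive), \code{params}.
#' @export
segment_image <- function(image, params = list()) {
  p <- modifyList(list(white_level = 250, epithelium_gray_max = 180,
                       min_size_um2 = 500, split_touching = TRUE,
                       watershed_tolerance = 10, aspect_threshold = 1.8,
                       dark_gray_max = 100, k = 3L), params)
  section <- segment_section(image, white_level = p$white_level)
  seg <- segment_tubules(image, section,
                         epithelium_gray_max = p$epithelium_gray_max,
                         min_size_um2 = p$min_size_um2,
                         split_touching = p$split_touching,
                         watershed_tolerance = p$watershed_tolerance)
  labs <- sort(setdiff(unique(as.vector(seg$tubule_labels)), 0L))
  flags <- do.call(rbind, lapply(labs, function(lab) {
    tm <- matrix(as.integer(seg$tubule_labels == lab), nrow(seg$tubule_labels))
    lm <- matrix(as.integer(seg$lumen_labels == lab), nrow(seg$lumen_labels))
    plane <- classify_plane(tm, threshold = p$aspect_threshold)
    pos <- if (plane == "cross") {
      detect_spermatid_positive(image, tm, if (sum(lm) > 0) lm else NULL,
                                dark_gray_max = p$dark_gray_max, k = p$k)
    } else {
      FALSE
    }
    data.frame(label = lab, plane = plane,
               is_longitudinal = plane == "longitudinal",
               is_spermatid_positive = pos)
  }))
  if (is.null(flags)) {
    flags <- data.frame(label = integer(0), plane = character(0),
                        is_longitudinal = logical(0),
                        is_spermatid_positive = logical(0))
  }
  structure(list(section_mask = section,
                 tubule_labels = seg$tubule_labels,
                 lumen_labels = seg$lumen_labels,
                 missing_lumen = seg$missing_lumen,
                 flags = flags, params = p),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d tubules (%d longitudinal, %d spermatid+)\n",
              nrow(x$flags), sum(x$flags$is_longitudinal),
              sum(x$flags$is_spermatid_positive)))
  invisible(x)
}

#' Write a numbered overlay of labeled tubules
#'
#' Renders the image with each tubule's label number drawn at its centroid -
#' the internal control that lets a human verify the automated count against
#' the picture.
#'
#' @param image a [calibrated_image()].
#' @param tubule_labels integer label matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, tubule_labels, path) {
  stopifnot(inherits(image, "cathi_image"))
  h <- dim(image$rgb)[1]; w <- dim(image$rgb)[2]
  grDevices::png(path, width = w, height = h)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0), xaxs = "i", yaxs = "i")
  graphics::rasterImage(image$rgb / 255, 0, h, w, 0, interpolate = FALSE)
  for (lab in setdiff(unique(as.vector(tubule_labels)), 0L)) {
    xy <- mask_coords(tubule_labels == lab)
    graphics::text(mean(xy[, 1]), mean(xy[, 2]), labels = lab,
                   col = "red", cex = 1.2)
  }
  invisible(path)
}
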