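#' Stain matrix for colour deconvolution
#'
#' A 3x3 matrix whose columns are unit optical-density vectors (stain -> RGB
#' absorbance). The \code{"h-dab"} preset uses the standard published
#' hematoxylin/DAB pair (hematoxylin (0.650, 0.704, 0.286), DAB
#' (0.268, 0.570, 0.776), each normalised); when only two stains are given the
#' residual third column is the normalised cross product of the first two.
#' The condition number is stored as an attribute for audit.
#'
#' @param stains either the string \code{"h-dab"} or a 3x2 / 3x3 numeric
#'   matrix of column stain vectors.
#' @param names stain names for the columns.
#' @return An invertible matrix of class \code{stain_matrix}.
#' @examples
#' S <- stain_matrix("h-dab")
#' colnames(S)
#' @export
stain_matrix <- function(stains = "h-dab",
                         names = c("hematoxylin", "dab", "residual")) {
  if (is.character(stains)) {
    stains <- switch(tolower(stains),
      "h-dab" = ,
      "hdab" = cbind(c(0.650, 0.704, 0.286), c(0.268, 0.570, 0.776)),
      stop("unknown stain preset: ", stains, call. = FALSE)
    )
  }
  stains <- as.matrix(stains)
  if (nrow(stains) != 3L || !ncol(stains) %in% 2:3) {
    stop("stain matrix must be 3 x 2 or 3 x 3", call. = FALSE)
  }
  norms <- sqrt(colSums(stains^2))
  if (any(norms == 0)) stop("zero stain vector", call. = FALSE)
  stains <- sweep(stains, 2, norms, "/")
  if (ncol(stains) == 2L) {
    a <- stains[, 1]; b <- stains[, 2]
    r <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    rn <- sqrt(sum(r^2))
    if (rn < 1e-8) stop("stain vectors are collinear; matrix not invertible", call. = FALSE)
    stains <- cbind(stains, r / rn)
  }
  kap <- kappa(stains, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8 || abs(det(stains)) < 1e-8) {
    stop("stain matrix is not invertible", call. = FALSE)
  }
  colnames(stains) <- names[seq_len(ncol(stains))]
  rownames(stains) <- c("R", "G", "B")
  structure(stains, class = "stain_matrix", condition_number = kap)
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat(sprintf("<stain_matrix> %s (condition number %.3g)\n",
              paste(colnames(x), collapse = ", "),
              attr(x, "condition_number")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Clear the image outside a region of interest
#'
#' Sets every pixel outside the ROI to white (255, 255, 255), the raster
#' analogue of cutting a tubule out of its field before measurement. Cleared
#' pixels are excluded from all downstream statistics when the ROI is carried
#' along (see [measure_ihc()]).
#'
#' @param image a [calibrated_image()].
#' @param roi binary ROI mask of the same height/width.
#' @return A \code{cathi_image} with the outside cleared.
#' @export
clear_outside <- function(image, roi) {
  stopifnot(inherits(image, "cathi_image"))
  roi <- as_binary_mask(roi)
  if (!identical(dim(roi), dim(image$rgb)[1:2])) {
    stop("roi dimensions do not match the image", call. = FALSE)
  }
  if (sum(roi) == 0L) stop("empty roi", call. = FALSE)
  rgb <- image$rgb
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[roi == 0L] <- 255
    rgb[, , ch] <- plane
  }
  calibrated_image(rgb, image$um_per_px)
}

#' Colour deconvolution of an RGB image into stain channels
#'
#' Per channel the optical density is \code{-log10(max(I, 1) / 255)}; the
#' per-pixel concentration vector is the stain-matrix inverse applied to the
#' OD vector. Negative concentrations (noise outside the stain simplex) are
#' clipped to zero and the clipped fraction recorded. Each stain also gets an
#' 8-bit rendering \code{round(255 * 10^(-c))}, the gray-scale image on which
#' thresholds and mean pixel values are taken; 255 there corresponds to zero
#' concentration and values decrease monotonically with concentration.
#'
#' @param image a [calibrated_image()].
#' @param stains a [stain_matrix()].
#' @return A list of class \code{deconvolved_image}: \code{conc}
#'   (h x w x 3 concentration array, stain order = matrix columns),
#'   \code{eight_bit} (h x w x 3 integer array), \code{stains},
#'   \code{clipped_fraction}.
#' @export
color_deconvolve <- function(image, stains = stain_matrix("h-dab")) {
  stopifnot(inherits(image, "cathi_image"))
  stopifnot(inherits(stains, "stain_matrix"))
  h <- dim(image$rgb)[1]; w <- dim(image$rgb)[2]
  I <- matrix(image$rgb, ncol = 3)
  od <- -log10(pmax(I, 1) / 255)
  conc <- od %*% t(solve(unclass(stains)))
  clipped <- mean(conc < -1e-9)
  conc[conc < 0] <- 0
  eight <- round(255 * 10^(-conc))
  eight[eight < 0] <- 0; eight[eight > 255] <- 255
  structure(list(
    conc = array(conc, dim = c(h, w, 3),
                 dimnames = list(NULL, NULL, colnames(stains))),
    eight_bit = array(eight, dim = c(h, w, 3),
                      dimnames = list(NULL, NULL, colnames(stains))),
    stains = stains,
    clipped_fraction = clipped
  ), class = "deconvolved_image")
}

#' @export
print.deconvolved_image <- function(x, ...) {
  d <- dim(x$conc)
  cat(sprintf("<deconvolved_image> %d x %d px, stains: %s (%.2f%% clipped)\n",
              d[2], d[1], paste(colnames(x$stains), collapse = ", "),
              100 * x$clipped_fraction))
  invisible(x)
}

# Otsu threshold on an integer 0-255 sample: maximises between-class variance
# over the 256-bin histogram; ties resolved toward the lowest threshold.
# Hand-rolled (rather than a library call) so the histogram can be restricted
# to an arbitrary ROI pixel set.
otsu_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no pixels to threshold", call. = FALSE)
  if (min(values) == max(values)) {
    stop("constant channel: Otsu undefined, supply a manual threshold",
         call. = FALSE)
  }
  counts <- tabulate(as.integer(values) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  levels[which.max(bcv)]
}

#' Threshold an 8-bit stain channel
#'
#' Dark-pass thresholding of a deconvolved 8-bit channel: a pixel is positive
#' iff its value is less than or equal to the threshold. The threshold is
#' either supplied manually (0-255) or derived by Otsu's method on the
#' ROI-restricted histogram; the value actually used is always returned for
#' audit.
#'
#' @param channel numeric matrix of 8-bit values (0-255).
#' @param mode \code{"otsu"} or \code{"manual"}.
#' @param value manual threshold in \[0, 255\] (required for manual mode).
#' @param roi optional binary mask; pixels outside are excluded from both the
#'   histogram and the positive mask.
#' @return A list: \code{mask} (0/1 matrix), \code{threshold} (integer used).
#' @export
select_threshold <- function(channel, mode = c("otsu", "manual"), value = NULL,
                             roi = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(channel)) stop("channel must be a matrix", call. = FALSE)
  sel <- if (is.null(roi)) {
    matrix(TRUE, nrow(channel), ncol(channel))
  } else {
    as_binary_mask(roi) > 0
  }
  if (!any(sel)) stop("roi excludes every pixel", call. = FALSE)
  thr <- if (mode == "manual") {
    if (is.null(value) || value < 0 || value > 255) {
      stop("manual mode requires `value` in [0, 255]", call. = FALSE)
    }
    as.integer(value)
  } else {
    otsu_threshold(channel[sel])
  }
  mask <- matrix(0L, nrow(channel), ncol(channel))
  mask[sel & channel <= thr] <- 1L
  list(mask = mask, threshold = thr)
}

#' Positively-stained area percentage
#'
#' The positively-stained area (pixels passing the DAB threshold) expressed as
#' a percentage of the total stained area (pixels passing the counterstain
#' threshold): \code{100 * positive / total}. Undefined without a
#' counterstain, in which case an explicit error is raised rather than a
#' guessed denominator.
#'
#' @param positive_area positive pixel count (DAB channel).
#' @param total_stained_area total stained pixel count (counterstain channel).
#' @return Percentage in \[0, 100\].
#' @examples
#' positive_area_pct(2500, 10000)  # 25
#' @export
positive_area_pct <- function(positive_area, total_stained_area) {
  if (is.na(total_stained_area) || total_stained_area <= 0) {
    stop("positive area percentage undefined without counterstain ",
         "(total stained area must be > 0)", call. = FALSE)
  }
  if (positive_area < 0 || positive_area > total_stained_area) {
    stop("positive area must lie in [0, total stained area]", call. = FALSE)
  }
  100 * positive_area / total_stained_area
}

#' Uncalibrated optical density from a mean 8-bit pixel value
#'
#' \code{log10(255 / mean_pixel_value)}, the relative absorbance of the
#' threshold-selected DAB-stained structures. Zero iff the mean pixel value is
#' 255 (blank field); strictly decreasing in the mean pixel value.
#'
#' @param mean_pixel_value mean 8-bit value over the threshold-selected
#'   pixels, in (0, 255].
#' @return Optical density in arbitrary units (>= 0).
#' @examples
#' uncalibrated_od(25.5)  # 1
#' @export
uncalibrated_od <- function(mean_pixel_value) {
  if (!is.numeric(mean_pixel_value) || length(mean_pixel_value) != 1L ||
      is.na(mean_pixel_value) || mean_pixel_value <= 0) {
    stop("mean pixel value must be > 0 (OD would be infinite)", call. = FALSE)
  }
  if (mean_pixel_value > 255) stop("mean pixel value exceeds 255", call. = FALSE)
  log10(255 / mean_pixel_value)
}

#' Quantify IHC staining within one ROI
#'
#' The orchestrated per-ROI measurement: clear outside the ROI, deconvolve,
#' threshold the DAB channel (positive structures) and - if a counterstain is
#' present - the counterstain channel (total stained area), then derive the
#' positively-stained area percentage and the uncalibrated optical density of
#' the DAB-positive structures. The mean pixel value is taken over the
#' threshold-selected DAB pixels only, and cleared-background pixels
#' contribute to nothing.
#'
#' @param image a [calibrated_image()].
#' @param roi binary ROI mask.
#' @param stains a [stain_matrix()].
#' @param dab_threshold \code{"otsu"} or an integer 0-255.
#' @param counterstain_threshold \code{"otsu"} or an integer 0-255.
#' @param counterstain logical: is a counterstain present? Without one the
#'   area percentage is reported as NA with the reason in \code{note}.
#' @param roi_id identifier copied into the output row.
#' @return One-row data.frame: \code{roi_id}, \code{positive_area} (px),
#'   \code{total_stained_area} (px), \code{positive_pct} (%),
#'   \code{mean_pixel_value}, \code{od} (A.U.), \code{dab_threshold},
#'   \code{counterstain_threshold}, \code{note}.
#' @export
measure_ihc <- function(image, roi, stains = stain_matrix("h-dab"),
                        dab_threshold = "otsu",
                        counterstain_threshold = "otsu",
                        counterstain = TRUE, roi_id = 1L) {
  stopifnot(inherits(image, "cathi_image"))
  roi <- as_binary_mask(roi)
  cleared <- clear_outside(image, roi)
  dec <- color_deconvolve(cleared, stains)
  dab_i <- match("dab", colnames(stains), nomatch = 2L)
  ctr_i <- setdiff(seq_len(2L), dab_i)[1]

  thr_spec <- function(x) {
    if (identical(x, "otsu")) list(mode = "otsu", value = NULL)
    else list(mode = "manual", value = x)
  }
  ds <- thr_spec(dab_threshold)
  dab <- select_threshold(dec$eight_bit[, , dab_i], mode = ds$mode,
                          value = ds$value, roi = roi)
  positive_area <- sum(dab$mask)

  if (counterstain) {
    cs <- thr_spec(counterstain_threshold)
    ctr <- select_threshold(dec$eight_bit[, , ctr_i], mode = cs$mode,
                            value = cs$value, roi = roi)
    total_area <- sum(ctr$mask)
    pct <- positive_area_pct(positive_area, total_area)
    ctr_thr <- ctr$threshold
    note <- ""
  } else {
    total_area <- NA_integer_
    pct <- NA_real_
    ctr_thr <- NA_integer_
    note <- "no counterstain: positive area percentage undefined"
  }

  if (positive_area > 0) {
    mpv <- mean(dec$eight_bit[, , dab_i][dab$mask == 1L])
    od <- uncalibrated_od(mpv)
  } else {
    mpv <- NA_real_
    od <- NA_real_
    note <- paste0(note, if (nzchar(note)) "; ", "no DAB-positive pixels")
  }

  data.frame(roi_id = roi_id,
             positive_area = positive_area,
             total_stained_area = total_area,
             positive_pct = pct,
             mean_pixel_value = mpv,
             od = od,
             dab_threshold = dab$threshold,
             counterstain_threshold = ctr_thr,
             note = note,
             stringsAsFactors = FALSE)
}
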