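#' Count seminiferous tubules on a labeled mask
#'
#' The total tubule count (cross- and longitudinal-sectioned alike) is the
#' number of distinct nonzero labels. An empty mask is a valid count of 0.
#'
#' @param tubule_labels integer label matrix, background 0.
#' @return Number of tubules (pieces).
#' @export
count_tubules <- function(tubule_labels) {
  if (!is.matrix(tubule_labels)) stop("labeled mask must be a matrix", call. = FALSE)
  length(setdiff(unique(as.vector(tubule_labels)), 0L))
}

#' Histomorphometric Bergmann-Kliesch score
#'
#' The percentage of tubules containing elongated spermatids:
#' \code{100 * positive / total}.
#'
#' @param positive number of elongated-spermatid-positive tubules.
#' @param total total tubule count (> 0).
#' @return Score in percent, in \[0, 100\].
#' @examples
#' bergmann_kliesch(50, 100)  # 50
#' @export
bergmann_kliesch <- function(positive, total) {
  if (!is.numeric(total) || total <= 0) {
    stop("total tubule count must be > 0", call. = FALSE)
  }
  if (positive < 0 || positive > total) {
    stop("positive count must lie in [0, total]", call. = FALSE)
  }
  100 * positive / total
}

#' Spermatogenic epithelium area of one tubule
#'
#' Tubule area minus lumen area of the same tubule.
#'
#' @param tubule_area tubule cross-section area (um^2).
#' @param lumen_area lumen area of the same tubule (um^2), \code{<=
#'   tubule_area}.
#' @return Epithelium area in um^2.
#' @export
se_area <- function(tubule_area, lumen_area) {
  if (lumen_area > tubule_area) {
    stop("lumen area exceeds tubule area (mis-paired measurements?)", call. = FALSE)
  }
  if (lumen_area < 0) stop("lumen area must be >= 0", call. = FALSE)
  tubule_area - lumen_area
}

#' Spermatogenic epithelium area ratio
#'
#' \code{100 * se_area / tubule_area}, the percentage of a tubule's
#' cross-section occupied by epithelium.
#'
#' @param se_area epithelium area (um^2).
#' @param tubule_area tubule area of the same tubule (um^2, > 0).
#' @return Percentage in \[0, 100\].
#' @export
se_area_ratio <- function(se_area, tubule_area) {
  assert_scalar_pos(tubule_area, "tubule_area")
  if (se_area < 0 || se_area > tubule_area) {
    stop("se_area must lie in [0, tubule_area]", call. = FALSE)
  }
  100 * se_area / tubule_area
}

#' Total interstitial and other tissue area
#'
#' Total testis cross-section area minus the summed area of all countable
#' tubules (cross- and longitudinal-sectioned).
#'
#' @param total_testis_area total tissue cross-section area (um^2).
#' @param sum_all_tubule_areas summed area of all tubules (um^2), \code{<=
#'   total_testis_area}.
#' @return Interstitial area in um^2.
#' @export
interstitial_area <- function(total_testis_area, sum_all_tubule_areas) {
  if (sum_all_tubule_areas > total_testis_area) {
    stop("summed tubule area exceeds section area (inconsistent masks?)",
         call. = FALSE)
  }
  if (sum_all_tubule_areas < 0) stop("summed tubule area must be >= 0", call. = FALSE)
  total_testis_area - sum_all_tubule_areas
}

#' Total seminiferous tubule area ratio
#'
#' \code{100 * sum_all_tubule_areas / total_testis_area}; together with the
#' interstitial fraction it sums to exactly 100 percent.
#'
#' @inheritParams interstitial_area
#' @return Percentage in \[0, 100\].
#' @export
tubule_area_ratio <- function(sum_all_tubule_areas, total_testis_area) {
  assert_scalar_pos(total_testis_area, "total_testis_area")
  if (sum_all_tubule_areas < 0 || sum_all_tubule_areas > total_testis_area) {
    stop("summed tubule area must lie in [0, total_testis_area]", call. = FALSE)
  }
  100 * sum_all_tubule_areas / total_testis_area
}

#' Tubule number density
#'
#' Tubule count normalised by the section area, making different-sized
#' cross-sections comparable: \code{count / area} in pieces per um^2.
#'
#' @param total_tubule_count total tubule count (pieces).
#' @param total_testis_area section area (um^2, > 0).
#' @return Density in pieces/um^2.
#' @export
tubule_number_density <- function(total_tubule_count, total_testis_area) {
  assert_scalar_pos(total_testis_area, "total_testis_area")
  if (total_tubule_count < 0) stop("count must be >= 0", call. = FALSE)
  total_tubule_count / total_testis_area
}

#' Random sample of cross-sectioned tubules for detailed measurement
#'
#' Uniform sample without replacement from the non-longitudinal tubules
#' (longitudinal sections are unsuitable for the per-tubule geometric
#' measurements). If fewer cross-sections exist than requested, all of them
#' are returned with a warning - for small samples it is better to include
#' every available cross-section. Identical seeds give identical samples.
#'
#' @param tubule_records data.frame with columns \code{label} and
#'   \code{is_longitudinal}.
#' @param n_target requested sample size (the protocol suggests 75-100 per
#'   animal; the default takes the top of that range).
#' @param seed integer seed.
#' @return Integer vector of sampled tubule labels.
#' @export
sample_tubules <- function(tubule_records, n_target = 100L, seed = 1L) {
  stopifnot(is.data.frame(tubule_records),
            all(c("label", "is_longitudinal") %in% names(tubule_records)))
  if (n_target < 1) stop("n_target must be >= 1", call. = FALSE)
  cross <- tubule_records$label[!tubule_records$is_longitudinal]
  if (length(cross) == 0L) stop("no cross-sectioned tubules to sample", call. = FALSE)
  if (length(cross) <= n_target) {
    if (length(cross) < n_target) {
      warning(sprintf(
        "only %d cross-sectioned tubules available (requested %d): taking all",
        length(cross), n_target))
    }
    return(sort(cross))
  }
  with_seed(seed, sort(sample(cross, n_target)))
}

#' Measure one tubule: the full per-tubule geometric record
#'
#' Computes every per-tubule quantity - tubule and lumen area, perimeter and
#' perpendicular diameters, epithelium area and area ratio, and the
#' five-point epithelium thickness - from a tubule mask and its lumen mask.
#'
#' @param tubule_mask binary mask of the tubule (epithelium + lumen).
#' @param lumen_mask binary mask of the lumen, or NULL for a lumenless
#'   tubule.
#' @param um_per_px calibration (um per pixel).
#' @param tubule_id identifier copied into the record.
#' @param seed seed for the thickness rays.
#' @param is_longitudinal,is_spermatid_positive flags copied into the record.
#' @return One-row data.frame (see [measure_tubules()] for the schema).
#' @export
measure_tubule <- function(tubule_mask, lumen_mask, um_per_px, tubule_id = 1L,
                           seed = 1L, is_longitudinal = FALSE,
                           is_spermatid_positive = NA) {
  tm <- shape_metrics(tubule_mask, um_per_px)
  has_lumen <- !is.null(lumen_mask) && sum(lumen_mask > 0) > 0
  if (has_lumen) {
    lm <- shape_metrics(lumen_mask, um_per_px)
    th <- epithelium_thickness(tubule_mask, lumen_mask, um_per_px,
                               seed = seed)
    se_thick <- th$mean
  } else {
    lm <- data.frame(area = 0, perimeter = NA_real_, diameter_1 = NA_real_,
                     diameter_2 = NA_real_, diameter_avg = NA_real_)
    se_thick <- NA_real_
  }
  se <- se_area(tm$area, lm$area)
  data.frame(
    tubule_id = tubule_id,
    tubule_area = tm$area,
    tubule_perimeter = tm$perimeter,
    tubule_diameter_1 = tm$diameter_1,
    tubule_diameter_2 = tm$diameter_2,
    tubule_diameter_avg = tm$diameter_avg,
    lumen_area = lm$area,
    lumen_perimeter = lm$perimeter,
    lumen_diameter_1 = lm$diameter_1,
    lumen_diameter_2 = lm$diameter_2,
    lumen_diameter_avg = lm$diameter_avg,
    se_area = se,
    se_area_ratio = se_area_ratio(se, tm$area),
    se_thickness_mean = se_thick,
    is_longitudinal = is_longitudinal,
    is_spermatid_positive = is_spermatid_positive
  )
}

#' Measure a sample of tubules from labeled masks
#'
#' Applies [measure_tubule()] to each requested label of a labeled tubule /
#' lumen mask pair. Thickness-ray seeds are derived deterministically from the
#' base seed and the label, so the result is independent of processing order.
#'
#' @param tubule_labels,lumen_labels integer label matrices (label-matched;
#'   background 0).
#' @param um_per_px calibration.
#' @param ids labels to measure (default: all).
#' @param seed base seed for the thickness rays.
#' @param flags optional data.frame with columns \code{label},
#'   \code{is_longitudinal}, \code{is_spermatid_positive}.
#' @return data.frame, one row per measured tubule.
#' @export
measure_tubules <- function(tubule_labels, lumen_labels, um_per_px,
                            ids = NULL, seed = 1L, flags = NULL) {
  labs <- sort(setdiff(unique(as.vector(tubule_labels)), 0L))
  if (!is.null(ids)) {
    missing <- setdiff(ids, labs)
    if (length(missing) > 0) {
      stop("labels not present in mask: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    labs <- sort(ids)
  }
  rows <- lapply(labs, function(lab) {
    tm <- matrix(as.integer(tubule_labels == lab), nrow(tubule_labels))
    lmask <- matrix(as.integer(lumen_labels == lab), nrow(lumen_labels))
    il <- FALSE; ip <- NA
    if (!is.null(flags)) {
      fr <- flags[flags$label == lab, , drop = FALSE]
      if (nrow(fr) == 1L) {
        il <- isTRUE(fr$is_longitudinal)
        ip <- fr$is_spermatid_positive
      }
    }
    measure_tubule(tm, if (sum(lmask) > 0) lmask else NULL, um_per_px,
                   tubule_id = lab, seed = seed + lab,
                   is_longitudinal = il, is_spermatid_positive = ip)
  })
  do.call(rbind, rows)
}

#' Assemble the section-level morphometric report
#'
#' Aggregates the section-level quantities: total tissue area, perimeter and
#' perpendicular diameters; total tubule count and spermatid-positive count
#' with the Bergmann-Kliesch score; summed tubule area with the interstitial
#' area, tubule area ratio and tubule number density; plus the seeded sample
#' of cross-sectioned tubule ids selected for detailed measurement.
#'
#' The area sums (interstitial area, area ratio, number density) include every
#' countable tubule - cross- and longitudinal-sectioned - while the sampled
#' ids exclude longitudinal sections.
#'
#' @param section_mask binary mask of the whole tissue cross-section.
#' @param tubule_labels integer label matrix of all tubules.
#' @param um_per_px calibration.
#' @param flags data.frame with columns \code{label}, \code{is_longitudinal},
#'   \code{is_spermatid_positive}.
#' @param n_sample target size of the detailed-measurement sample.
#' @param seed seed for the sampling.
#' @return One-row data.frame of class \code{section_report}.
#' @export
build_section_report <- function(section_mask, tubule_labels, um_per_px,
                                 flags, n_sample = 100L, seed = 1L) {
  stopifnot(is.data.frame(flags),
            all(c("label", "is_longitudinal", "is_spermatid_positive") %in%
                  names(flags)))
  sm <- shape_metrics(section_mask, um_per_px)
  total <- count_tubules(tubule_labels)
  if (total != nrow(flags)) {
    stop("flag table rows do not match the tubule count", call. = FALSE)
  }
  n_pos <- sum(flags$is_spermatid_positive, na.rm = TRUE)
  sum_tub <- sum(tubule_labels > 0) * um_per_px^2
  inter <- interstitial_area(sm$area, sum_tub)
  sampled <- sample_tubules(flags, n_target = n_sample, seed = seed)
  rep <- data.frame(
    total_testis_area = sm$area,
    total_testis_perimeter = sm$perimeter,
    total_testis_diameter_1 = sm$diameter_1,
    total_testis_diameter_2 = sm$diameter_2,
    total_testis_diameter_avg = sm$diameter_avg,
    total_tubule_count = total,
    spermatid_positive_count = n_pos,
    bergmann_kliesch_pct = bergmann_kliesch(n_pos, total),
    sum_all_tubule_areas = sum_tub,
    interstitial_area = inter,
    tubule_area_ratio_pct = tubule_area_ratio(sum_tub, sm$area),
    tubule_number_density = tubule_number_density(total, sm$area),
    sampled_tubule_ids = paste(sampled, collapse = ";")
  )
  class(rep) <- c("section_report", "data.frame")
  rep
}
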