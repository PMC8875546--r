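#' Run configuration for the end-to-end pipeline
#'
#' Assembles and validates the configuration of a [run_pipeline()] call.
#' Either a phantom spec (synthetic mode) or an input image path must be
#' given; the calibration is mandatory for image input. The effective
#' configuration is serialised next to the outputs so every file is traceable
#' to its parameters and seed.
#'
#' @param out_dir output directory.
#' @param phantom a [phantom_spec()] for synthetic mode, or NULL.
#' @param image_path path to an H&E RGB raster (PNG/TIFF), or NULL.
#' @param um_per_px calibration for image input (ignored in phantom mode,
#'   which carries its own).
#' @param n_sample detailed-measurement sample size.
#' @param seed integer seed for all randomised steps.
#' @param segmentation named list of segmentation parameter overrides (see
#'   [segment_image()]).
#' @param ihc logical: also render/measure the IHC branch (phantom mode only).
#' @param dab_threshold,counterstain_threshold \code{"otsu"} or integer 0-255.
#'   The counterstain default is a manual near-white cutoff (240) rather than
#'   Otsu: the counterstain's role is to select the entire stained area, and
#'   on a uniformly counterstained field (as phantoms are) an Otsu split of
#'   the counterstain histogram is degenerate.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(out_dir, phantom = NULL, image_path = NULL,
                       um_per_px = NULL, n_sample = 100L, seed = 1L,
                       segmentation = list(), ihc = !is.null(phantom),
                       dab_threshold = "otsu", counterstain_threshold = 240) {
  if (is.null(phantom) && is.null(image_path)) {
    stop("config error: one of `phantom` or `image_path` is required", call. = FALSE)
  }
  if (!is.null(image_path) && is.null(um_per_px)) {
    stop("config error: `um_per_px` (calibration) is required for image input",
         call. = FALSE)
  }
  if (!is.null(phantom)) stopifnot(inherits(phantom, "phantom_spec"))
  structure(list(out_dir = out_dir, phantom = phantom,
                 image_path = image_path, um_per_px = um_per_px,
                 n_sample = as.integer(n_sample), seed = as.integer(seed),
                 segmentation = segmentation, ihc = isTRUE(ihc),
                 dab_threshold = dab_threshold,
                 counterstain_threshold = counterstain_threshold),
            class = "run_config")
}

#' Run the full phantom -> segment -> measure -> IHC pipeline
#'
#' Executes the end-to-end workflow and writes, into \code{config$out_dir}:
#' \code{tubules.csv} (per-tubule measurements of the sampled cross-sectioned
#' tubules), \code{section.csv} (the section report), \code{ihc.csv} (IHC
#' measurements, when enabled), \code{overlay.png} (numbered internal-control
#' overlay), \code{config.yml} and \code{run.log} (every parameter, threshold
#' and warning actually used). All randomness is seeded, so a repeated run
#' with the same configuration produces byte-identical CSV files.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the per-tubule table, section report, IHC
#'   table and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
  }
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$phantom)) {
      stage <- "phantom"
      scene <- generate_scene(config$phantom)
      he <- render_he(scene)
      image <- he$image
      note("phantom: %d tubules, seed %d", nrow(scene$tubules),
           config$phantom$seed)
    } else {
      scene <- NULL
      image <- read_image(config$image_path, config$um_per_px)
      note("input image: %s (%g um/px)", config$image_path, config$um_per_px)
    }

    stage <- "segmentation"
    seg <- withCallingHandlers(
      segment_image(image, params = config$segmentation),
      message = function(m) {
        note("segmentation: %s", trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    note("segmentation: %d tubules, params: %s", nrow(seg$flags),
         paste(names(seg$params), unlist(seg$params), sep = "=", collapse = " "))

    stage <- "morphometry"
    report <- withCallingHandlers(
      build_section_report(seg$section_mask, seg$tubule_labels,
                           image$um_per_px, seg$flags,
                           n_sample = config$n_sample, seed = config$seed),
      warning = function(w) {
        note("morphometry: %s", trimws(conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    sampled <- as.integer(strsplit(report$sampled_tubule_ids, ";")[[1]])
    tub <- measure_tubules(seg$tubule_labels, seg$lumen_labels,
                           image$um_per_px, ids = sampled,
                           seed = config$seed, flags = seg$flags)
    note("morphometry: measured %d sampled cross-sectioned tubules", nrow(tub))

    stage <- "ihc"
    ihc_tab <- NULL
    if (config$ihc && !is.null(scene)) {
      rendered <- render_ihc(scene)
      counterstain <- scene$spec$ihc_hema_od > 0
      ihc_tab <- measure_ihc(rendered$image, rendered$tissue_mask,
                             dab_threshold = config$dab_threshold,
                             counterstain_threshold = config$counterstain_threshold,
                             counterstain = counterstain, roi_id = 1L)
      note("ihc: dab threshold %d, counterstain threshold %s",
           ihc_tab$dab_threshold, as.character(ihc_tab$counterstain_threshold))
    }

    stage <- "output"
    write_report_csv(tub, file.path(config$out_dir, "tubules.csv"))
    write_report_csv(as.data.frame(report),
                     file.path(config$out_dir, "section.csv"))
    if (!is.null(ihc_tab)) {
      write_report_csv(ihc_tab, file.path(config$out_dir, "ihc.csv"))
    }
    write_overlay(image, seg$tubule_labels,
                  file.path(config$out_dir, "overlay.png"))
    cfg <- config
    cfg$phantom <- if (is.null(cfg$phantom)) NULL else unclass(cfg$phantom)
    yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yml"))
    list(tubules = tub, section = report, ihc = ihc_tab,
         out_dir = config$out_dir)
  }, error = function(e) {
    note("ERROR in stage %s: %s", stage, conditionMessage(e))
    writeLines(log_lines, logf)
    stop(sprintf("pipeline failed in stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), config$out_dir), call. = FALSE)
  })
  writeLines(log_lines, logf)
  invisible(result)
}
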