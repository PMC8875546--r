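# CSV report writers. Numbers are rendered with 6 significant digits so
# repeated runs produce byte-identical files; reading back recovers the values
# at stored precision.

#' Write and read CSV reports
#'
#' Deterministic CSV serialisation used for all package reports (per-tubule
#' table, section report, IHC table, phantom ground truth). Numeric columns
#' are rendered with 6 significant digits; writing the same data twice gives
#' byte-identical files, and a write/read round-trip is value-identical at the
#' stored precision.
#'
#' @param df data.frame to write.
#' @param path CSV file path.
#' @return `write_report_csv()` returns `path` invisibly; `read_report_csv()`
#'   returns a data.frame.
#' @export
write_report_csv <- function(df, path) {
  stopifnot(is.data.frame(df))
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "" else formatC(v, digits = 6, format = "g")
      }, character(1))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    stop("malformed CSV: empty or truncated header in ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a polygon ROI from CSV and rasterize it
#'
#' The CSV holds one vertex per row with columns \code{x}, \code{y} in 0-based
#' pixel coordinates. A pixel belongs to the ROI when its centre lies inside
#' the polygon (even-odd rule).
#'
#' @param path CSV path with columns \code{x}, \code{y}.
#' @param dim raster dimensions \code{c(height, width)}.
#' @return Binary 0/1 mask matrix.
#' @export
read_roi_polygon <- function(path, dim) {
  v <- read_report_csv(path)
  if (!all(c("x", "y") %in% names(v))) {
    stop("polygon CSV must have columns x, y", call. = FALSE)
  }
  polygon_mask(v$x, v$y, dim)
}

# Even-odd rasterization of a polygon given 0-based vertex coordinates.
polygon_mask <- function(px, py, dim) {
  h <- dim[1]; w <- dim[2]
  if (length(px) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  m <- matrix(0L, h, w)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  n <- length(px)
  inside <- rep(FALSE, length(xs))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  m[cbind(ys + 1L, xs + 1L)] <- as.integer(inside)
  m
}
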