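# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All seeded operations in the package go through
# this so that no call perturbs the global RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single strictly positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a fraction in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

# Coerce a mask-like input (logical/numeric matrix) to a 0/1 integer matrix.
as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- matrix(as.integer(mask > 0), nrow = nrow(mask))
  m
}

# 0-based (x, y) coordinates of foreground pixels; columns are x then y.
mask_coords <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Number of 8-connected foreground components (EBImage labels columns-first;
# count is orientation-independent).
n_components <- function(mask) {
  max(EBImage::bwlabel(t(as_binary_mask(mask))))
}

# EBImage stores images column-major as [x, y]; package masks are [y, x].
to_eb <- function(m) EBImage::Image(t(m))
from_eb <- function(img) t(as.matrix(EBImage::imageData(img)))
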