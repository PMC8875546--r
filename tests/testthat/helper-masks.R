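# Fixture builders and independent oracles shared across the test files.
# Masks are built by direct pixel-centre tests, independent of the package's
# internal rasterizer.

disk_mask <- function(r, pad = 5) {
  n <- 2 * ceiling(r) + 2 * pad + 1
  c0 <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
  matrix(as.integer(m), n, n)
}

ellipse_mask <- function(a, b, theta = 0, pad = 5) {
  n <- 2 * ceiling(max(a, b)) + 2 * pad + 1
  c0 <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n), function(i, j) {
    x <- j - c0; y <- i - c0
    u <- x * cos(theta) + y * sin(theta)
    v <- -x * sin(theta) + y * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
  matrix(as.integer(m), n, n)
}

# Brute-force rotating-caliper oracle over 1-degree steps: max Feret diameter
# and the caliper extent perpendicular to it, from foreground pixel centres.
feret_oracle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  hull <- xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE]
  best <- c(-Inf, NA)
  for (deg in 0:179) {
    th <- deg * pi / 180
    p <- hull[, 1] * cos(th) + hull[, 2] * sin(th)
    ext <- max(p) - min(p)
    if (ext > best[1]) best <- c(ext, th)
  }
  th2 <- best[2] + pi / 2
  p2 <- hull[, 1] * cos(th2) + hull[, 2] * sin(th2)
  c(d1 = best[1], d2 = max(p2) - min(p2))
}

# Ramanujan's second approximation to the ellipse circumference (error is
# negligible at the aspect ratios used here).
ellipse_perimeter_true <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Polar radius of an axis-aligned ellipse at parameter-free polar angle phi.
ellipse_radius <- function(a, b, phi) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

# Greedy overlap matching of segmented labels to ground-truth labels.
# Returns one row per segmented label with the best-overlap truth label and
# the IoU of the pair.
match_labels <- function(seg_labels, gt_labels) {
  segs <- setdiff(unique(as.vector(seg_labels)), 0L)
  out <- lapply(segs, function(s) {
    sm <- seg_labels == s
    cand <- gt_labels[sm]
    cand <- cand[cand > 0]
    if (length(cand) == 0L) {
      return(data.frame(seg = s, gt = NA_integer_, iou = 0))
    }
    g <- as.integer(names(which.max(table(cand))))
    gm <- gt_labels == g
    data.frame(seg = s, gt = g,
               iou = sum(sm & gm) / sum(sm | gm))
  })
  do.call(rbind, out)
}

# Small default phantom used by segmentation/pipeline tests (kept light so
# the suite stays fast).
small_phantom_spec <- function(seed = 11) {
  phantom_spec(section_radius_um = 280, n_tubules = 12,
               tubule_radius_um = c(40, 4), longitudinal_fraction = 0.25,
               spermatid_positive_fraction = 0.5, seed = seed)
}
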