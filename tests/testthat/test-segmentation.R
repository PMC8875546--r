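# Shared fixture: one small phantom segmented once per test run.
seg_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scene <- generate_scene(small_phantom_spec(seed = 11))
      he <- render_he(scene)
      seg <- suppressMessages(segment_image(he$image))
      cache <<- list(scene = scene, he = he, seg = seg)
    }
    cache
  }
})

test_that("the section mask recovers the tissue disk with high Dice", {
  fx <- seg_fixture()
  sec <- fx$seg$section_mask
  gt <- fx$he$section_mask
  dice <- 2 * sum(sec > 0 & gt > 0) / (sum(sec > 0) + sum(gt > 0))
  expect_gte(dice, 0.98)
})

test_that("a blank image raises a no-tissue error", {
  blank <- calibrated_image(array(255, dim = c(50, 50, 3)), 1)
  expect_error(segment_section(blank), "no tissue")
})

test_that("with two tissue pieces the largest is kept and candidates reported", {
  rgb <- array(255, dim = c(120, 240, 3))
  big <- disk_mask(40, pad = 9)     # 99 x 99
  sml <- disk_mask(15, pad = 10)    # 51 x 51
  for (ch in 1:3) {
    p <- rgb[, , ch]
    p[10:108, 10:108][big > 0] <- 120
    p[30:80, 170:220][sml > 0] <- 120
    rgb[, , ch] <- p
  }
  img <- calibrated_image(rgb, 1)
  expect_message(m <- segment_section(img), "2 candidate")
  expect_equal(sum(m), sum(big))
  expect_true(all(which(m > 0, arr.ind = TRUE)[, 2] <= 110))
})

test_that("tubule labelling recovers every phantom tubule with IoU >= 0.9", {
  fx <- seg_fixture()
  expect_identical(count_tubules(fx$seg$tubule_labels), 12L)
  mm <- match_labels(fx$seg$tubule_labels, fx$he$tubule_labels)
  expect_false(any(is.na(mm$gt)))
  expect_identical(sort(mm$gt), 1:12)  # bijective matching
  expect_true(all(mm$iou >= 0.9))
  # lumen labels are label-matched and contained
  ll <- fx$seg$lumen_labels; tl <- fx$seg$tubule_labels
  expect_true(all(tl[ll > 0] == ll[ll > 0]))
})

test_that("the minimum-size filter removes a planted small artifact blob", {
  fx <- seg_fixture()
  rgb <- fx$he$image$rgb
  # plant a dark ~300 um^2 blob (r = 9.8 px at 1 um/px) in the interstitium
  blob <- disk_mask(9.8, pad = 2)
  free <- fx$he$section_mask > 0 & fx$he$tubule_labels == 0
  # find a spot whose neighbourhood is entirely interstitium
  er <- cathi:::from_eb(EBImage::erode(cathi:::to_eb(matrix(as.integer(free), nrow(free))),
                                       EBImage::makeBrush(31, "disc")))
  pos <- which(er > 0, arr.ind = TRUE)[1, ]
  r0 <- pos[1] - (nrow(blob) - 1) %/% 2; c0 <- pos[2] - (ncol(blob) - 1) %/% 2
  for (ch in 1:3) {
    p <- rgb[, , ch]
    win <- p[r0:(r0 + nrow(blob) - 1), c0:(c0 + ncol(blob) - 1)]
    win[blob > 0] <- cathi:::HE_PALETTE$epithelium[ch]
    p[r0:(r0 + nrow(blob) - 1), c0:(c0 + ncol(blob) - 1)] <- win
    rgb[, , ch] <- p
  }
  img <- calibrated_image(rgb, 1)
  sec <- segment_section(img)
  with_filter <- suppressMessages(segment_tubules(img, sec, min_size_um2 = 500))
  expect_identical(count_tubules(with_filter$tubule_labels), 12L)
  without <- suppressMessages(segment_tubules(img, sec, min_size_um2 = 100))
  expect_identical(count_tubules(without$tubule_labels), 13L)
  # monotonicity: raising the filter never increases the label count
  sizes <- c(0, 100, 500, 2000)
  counts <- vapply(sizes, function(s) {
    count_tubules(suppressMessages(
      segment_tubules(img, sec, min_size_um2 = s))$tubule_labels)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("plane classification separates phantom cross and longitudinal tubules", {
  fx <- seg_fixture()
  mm <- match_labels(fx$seg$tubule_labels, fx$he$tubule_labels)
  truth <- fx$scene$tubules
  for (i in seq_len(nrow(mm))) {
    m <- matrix(as.integer(fx$seg$tubule_labels == mm$seg[i]),
                nrow(fx$seg$tubule_labels))
    got <- classify_plane(m)
    want <- if (truth$is_longitudinal[truth$label == mm$gt[i]])
      "longitudinal" else "cross"
    expect_identical(got, want)
  }
  expect_identical(classify_plane(disk_mask(30)), "cross")
  expect_error(classify_plane(matrix(0L, 5, 5)), "degenerate")
})

test_that("spermatid detection matches the planted flags exactly", {
  fx <- seg_fixture()
  mm <- match_labels(fx$seg$tubule_labels, fx$he$tubule_labels)
  truth <- fx$scene$tubules
  for (i in seq_len(nrow(mm))) {
    if (truth$is_longitudinal[truth$label == mm$gt[i]]) next
    tm <- matrix(as.integer(fx$seg$tubule_labels == mm$seg[i]),
                 nrow(fx$seg$tubule_labels))
    lm <- matrix(as.integer(fx$seg$lumen_labels == mm$seg[i]),
                 nrow(fx$seg$lumen_labels))
    got <- detect_spermatid_positive(fx$he$image, tm,
                                     if (sum(lm) > 0) lm else NULL)
    expect_identical(got,
                     truth$is_spermatid_positive[truth$label == mm$gt[i]],
                     label = sprintf("tubule %d", mm$gt[i]))
  }
})

test_that("a missing lumen falls back to the tubule interior with a warning", {
  fx <- seg_fixture()
  pos_lab <- fx$scene$tubules$label[fx$scene$tubules$is_spermatid_positive][1]
  mm <- match_labels(fx$seg$tubule_labels, fx$he$tubule_labels)
  seg_lab <- mm$seg[mm$gt == pos_lab]
  tm <- matrix(as.integer(fx$seg$tubule_labels == seg_lab),
               nrow(fx$seg$tubule_labels))
  expect_warning(got <- detect_spermatid_positive(fx$he$image, tm, NULL),
                 "no lumen")
  expect_true(got)
})

test_that("segmentation is deterministic", {
  fx <- seg_fixture()
  seg2 <- suppressMessages(segment_image(fx$he$image))
  expect_identical(fx$seg$tubule_labels, seg2$tubule_labels)
  expect_identical(fx$seg$lumen_labels, seg2$lumen_labels)
  expect_identical(fx$seg$flags, seg2$flags)
})

test_that("the full segmentation result reproduces all planted flags", {
  fx <- seg_fixture()
  mm <- match_labels(fx$seg$tubule_labels, fx$he$tubule_labels)
  truth <- fx$scene$tubules
  got <- fx$seg$flags
  for (i in seq_len(nrow(mm))) {
    tr <- truth[truth$label == mm$gt[i], ]
    fl <- got[got$label == mm$seg[i], ]
    expect_identical(fl$is_longitudinal, tr$is_longitudinal)
    expect_identical(fl$is_spermatid_positive, tr$is_spermatid_positive)
  }
})
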