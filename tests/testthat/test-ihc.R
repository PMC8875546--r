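test_that("stain matrices have unit columns and reject degenerate input", {
  S <- stain_matrix("h-dab")
  expect_equal(unname(colSums(unclass(S)^2)), rep(1, 3))
  expect_identical(colnames(S), c("hematoxylin", "dab", "residual"))
  expect_true(attr(S, "condition_number") < 10)
  # residual is orthogonal to both stains
  expect_lt(abs(sum(unclass(S)[, 1] * unclass(S)[, 3])), 1e-12)
  expect_lt(abs(sum(unclass(S)[, 2] * unclass(S)[, 3])), 1e-12)
  expect_error(stain_matrix(cbind(c(1, 0, 0), c(2, 0, 0))), "collinear")
  expect_error(stain_matrix("unknown-preset"), "preset")
})

test_that("clearing outside a ROI whitens only the outside", {
  rgb <- array(100, dim = c(10, 10, 3))
  img <- calibrated_image(rgb, 1)
  full <- matrix(1L, 10, 10)
  expect_identical(clear_outside(img, full)$rgb, img$rgb)
  expect_error(clear_outside(img, matrix(0L, 10, 10)), "empty roi")
  roi <- matrix(0L, 10, 10); roi[3:6, 3:6] <- 1L
  out <- clear_outside(img, roi)
  expect_true(all(out$rgb[, , 1][roi == 0L] == 255))
  expect_true(all(out$rgb[, , 1][roi == 1L] == 100))
})

test_that("ROI statistics are identical on cleared and roi-restricted images", {
  scene <- generate_scene(small_phantom_spec(seed = 41))
  out <- render_ihc(scene)
  lab <- scene$tubules$label[scene$tubules$is_spermatid_positive][1]
  he <- render_he(scene)
  roi <- matrix(as.integer(he$tubule_labels == lab), nrow(he$tubule_labels))
  m1 <- measure_ihc(out$image, roi, counterstain_threshold = 240)
  m2 <- measure_ihc(clear_outside(out$image, roi), roi,
                    counterstain_threshold = 240)
  expect_identical(m1, m2)
})

test_that("deconvolution handles blank pixels and the identity matrix", {
  white <- calibrated_image(array(255, dim = c(4, 4, 3)), 1)
  d <- color_deconvolve(white)
  expect_true(all(d$conc == 0))
  expect_true(all(d$eight_bit == 255))

  rgb <- array(0, dim = c(3, 3, 3))
  rgb[, , 1] <- 100; rgb[, , 2] <- 150; rgb[, , 3] <- 200
  img <- calibrated_image(rgb, 1)
  ident <- stain_matrix(diag(3), names = c("r", "g", "b"))
  d2 <- color_deconvolve(img, ident)
  for (ch in 1:3) {
    expect_equal(d2$conc[, , ch],
                 matrix(-log10(rgb[, , ch] / 255), 3, 3))
  }
})

test_that("the Beer-Lambert round-trip recovers planted concentrations", {
  S <- stain_matrix("h-dab")
  # single-pixel closed form: hema 0, DAB 0.5
  conc <- array(0, dim = c(1, 1, 3)); conc[1, 1, 2] <- 0.5
  img <- calibrated_image(beer_lambert_render(conc, S), 1)
  d <- color_deconvolve(img, S)
  expect_lt(abs(d$conc[1, 1, 2] - 0.5), 0.01)
  expect_lte(d$conc[1, 1, 1], 0.01)

  # grid of moderate ODs: 8-bit quantization keeps recovery within 0.02 here
  # (at higher combined ODs the transmitted intensities fall below ~11 counts
  # and the half-count quantization error alone exceeds that bound)
  vals <- seq(0, 1, by = 0.05)
  g <- expand.grid(h = vals, d = vals)
  conc <- array(0, dim = c(nrow(g), 1, 3))
  conc[, 1, 1] <- g$h; conc[, 1, 2] <- g$d
  img <- calibrated_image(beer_lambert_render(conc, S), 1)
  rec <- color_deconvolve(img, S)$conc
  expect_lt(max(abs(rec[, , 1] - g$h)), 0.02)
  expect_lt(max(abs(rec[, , 2] - g$d)), 0.02)
})

test_that("whole-phantom IHC fields deconvolve back to their ground truth", {
  scene <- generate_scene(small_phantom_spec(seed = 41))
  out <- render_ihc(scene)
  rec <- color_deconvolve(out$image)$conc
  expect_lt(max(abs(rec[, , 1] - out$conc[, , 1])), 0.02)
  expect_lt(max(abs(rec[, , 2] - out$conc[, , 2])), 0.02)
})

test_that("Otsu separates a bimodal channel exactly and fails on constants", {
  planted <- matrix(0L, 40, 40)
  planted[1:40, 1:12] <- 1L  # planted DAB class
  channel <- matrix(250, 40, 40)
  channel[planted == 1L] <- 40
  sel <- select_threshold(channel, mode = "otsu")
  expect_true(sel$threshold >= 40 && sel$threshold < 250)
  expect_identical(sel$mask, planted)

  expect_error(select_threshold(matrix(100, 5, 5), mode = "otsu"),
               "manual")
  # manual modes
  all_in <- select_threshold(matrix(100, 5, 5), mode = "manual", value = 128)
  expect_true(all(all_in$mask == 1L))
  none <- select_threshold(matrix(1, 5, 5), mode = "manual", value = 0)
  expect_true(all(none$mask == 0L))
  expect_error(select_threshold(channel, mode = "manual", value = 300), "255")
})

test_that("threshold ROI restriction confines both histogram and mask", {
  channel <- matrix(200, 20, 20)
  channel[1:10, ] <- 50
  roi <- matrix(0L, 20, 20); roi[1:10, ] <- 1L
  sel <- select_threshold(channel, mode = "manual", value = 128, roi = roi)
  expect_identical(sum(sel$mask), 200L)
  expect_true(all(sel$mask[roi == 0L] == 0L))
  expect_error(select_threshold(channel, roi = matrix(0L, 20, 20)),
               "excludes")
})

test_that("positive area percentage follows its formula and contracts", {
  expect_identical(positive_area_pct(2500, 10000), 25)
  expect_identical(positive_area_pct(4242, 4242), 100)
  expect_identical(positive_area_pct(0, 10), 0)
  expect_error(positive_area_pct(10, 0), "counterstain")
  expect_error(positive_area_pct(11, 10), "\\[0, total")
  # monotone in the DAB threshold: more permissive threshold, larger area
  channel <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  areas <- vapply(c(32, 64, 128, 255), function(t) {
    sum(select_threshold(channel, mode = "manual", value = t)$mask)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("uncalibrated OD inverts the 8-bit encoding", {
  expect_identical(uncalibrated_od(255), 0)
  expect_equal(uncalibrated_od(25.5), 1)
  expect_equal(uncalibrated_od(2.55), 2)
  expect_error(uncalibrated_od(0), "> 0")
  expect_error(uncalibrated_od(256), "exceeds")
  # strictly decreasing
  v <- vapply(c(10, 50, 100, 200, 255), uncalibrated_od, numeric(1))
  expect_true(all(diff(v) < 0))
  # exact inverse of the per-stain encoding on uniform fields
  for (od in c(0.15, 0.3, 0.6, 1.0)) {
    enc <- round(255 * 10^(-od))
    expect_identical(uncalibrated_od(enc), log10(255 / enc))
  }
})

test_that("measure_ihc is deterministic and honours the counterstain contract", {
  scene <- generate_scene(small_phantom_spec(seed = 41))
  out <- render_ihc(scene)
  m1 <- measure_ihc(out$image, out$tissue_mask, counterstain_threshold = 240)
  m2 <- measure_ihc(out$image, out$tissue_mask, counterstain_threshold = 240)
  expect_identical(m1, m2)
  expect_equal(m1$positive_pct,
               100 * sum(out$dab_mask) / sum(out$tissue_mask),
               tolerance = 0.01)
  expect_equal(m1$od, scene$spec$ihc_dab_od, tolerance = 0.01)

  # counterstain-free field (MAGE-A4-style): OD computed, percentage absent
  spec0 <- phantom_spec(section_radius_um = 280, n_tubules = 12,
                        tubule_radius_um = c(40, 4),
                        longitudinal_fraction = 0.25,
                        spermatid_positive_fraction = 0.5,
                        ihc_hema_od = 0, seed = 41)
  out0 <- render_ihc(generate_scene(spec0))
  m0 <- measure_ihc(out0$image, out0$tissue_mask, counterstain = FALSE)
  expect_true(is.na(m0$positive_pct))
  expect_match(m0$note, "counterstain")
  expect_equal(m0$od, spec0$ihc_dab_od, tolerance = 0.01)
})
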