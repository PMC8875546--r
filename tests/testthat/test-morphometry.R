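test_that("derived-quantity formulas satisfy their algebraic identities", {
  # randomized numeric fixtures: identities hold exactly
  set.seed(101)
  for (i in 1:50) {
    tub <- runif(1, 1e3, 1e5)
    lum <- runif(1, 0, tub)
    se <- se_area(tub, lum)
    expect_identical(se + lum, tub)
    expect_identical(se_area_ratio(se, tub), 100 * se / tub)

    total <- runif(1, 1e5, 1e7)
    sumt <- runif(1, 0, total)
    expect_identical(interstitial_area(total, sumt) + sumt, total)
    expect_equal(tubule_area_ratio(sumt, total) +
                   100 * interstitial_area(total, sumt) / total, 100)

    n <- sample(1:500, 1); p <- sample(0:n, 1)
    expect_identical(bergmann_kliesch(p, n), 100 * p / n)
    expect_identical(tubule_number_density(n, total), n / total)
  }
})

test_that("formula examples and error contracts hold", {
  expect_identical(se_area(5000, 1000), 4000)
  expect_identical(se_area(1234.5, 0), 1234.5)
  expect_error(se_area(1000, 2000), "exceeds")

  expect_identical(se_area_ratio(4000, 5000), 80)
  expect_identical(se_area_ratio(5000, 5000), 100)  # lumenless tubule
  expect_error(se_area_ratio(100, 0), "positive")

  expect_identical(bergmann_kliesch(50, 100), 50)
  expect_identical(bergmann_kliesch(73, 73), 100)
  expect_error(bergmann_kliesch(5, 0), "> 0")
  expect_error(bergmann_kliesch(11, 10), "\\[0, total\\]")

  expect_identical(interstitial_area(1e6, 6e5), 4e5)
  expect_identical(interstitial_area(777, 0), 777)
  expect_error(interstitial_area(100, 200), "exceeds")

  expect_identical(tubule_area_ratio(6e5, 1e6), 60)
  expect_identical(tubule_area_ratio(0, 42), 0)

  expect_identical(tubule_number_density(500, 1e6), 5e-4)
  expect_error(tubule_number_density(1, 0), "positive")
})

test_that("tubule number density follows the calibration scale law", {
  m <- disk_mask(60)
  a1 <- region_area(m, 1)
  a2 <- region_area(m, 2)  # doubling the calibration quadruples the area
  expect_identical(tubule_number_density(10, a2),
                   tubule_number_density(10, a1) / 4)
})

test_that("epithelium area of a rasterized annulus matches the closed form", {
  outer_m <- disk_mask(100)
  lumen_m <- disk_mask(60, pad = 45)
  se <- se_area(region_area(outer_m, 1), region_area(lumen_m, 1))
  expect_equal(se, pi * (100^2 - 60^2), tolerance = 0.01)
  expect_equal(se_area_ratio(se, region_area(outer_m, 1)), 64, tolerance = 0.01)
})

test_that("tubule counting is a pure label count", {
  he <- render_he(generate_scene(small_phantom_spec(seed = 31)))
  expect_identical(count_tubules(he$tubule_labels), 12L)
  expect_identical(count_tubules(matrix(0L, 10, 10)), 0L)
})

test_that("sampling draws only cross-sectioned tubules, deterministically", {
  rec <- data.frame(label = 1:250,
                    is_longitudinal = c(rep(FALSE, 200), rep(TRUE, 50)))
  s <- sample_tubules(rec, n_target = 100, seed = 7)
  expect_length(s, 100)
  expect_length(unique(s), 100)
  expect_true(all(s <= 200))
  expect_identical(s, sample_tubules(rec, n_target = 100, seed = 7))
  expect_false(identical(s, sample_tubules(rec, n_target = 100, seed = 8)))

  small <- data.frame(label = 1:60,
                      is_longitudinal = c(rep(FALSE, 40), rep(TRUE, 20)))
  expect_warning(s2 <- sample_tubules(small, n_target = 75, seed = 1),
                 "taking all")
  expect_identical(s2, 1:40)

  all_long <- data.frame(label = 1:5, is_longitudinal = rep(TRUE, 5))
  expect_error(sample_tubules(all_long, 10, 1), "no cross-sectioned")
})

test_that("per-tubule measurement records satisfy their invariants", {
  outer_m <- disk_mask(100)
  lumen_m <- disk_mask(60, pad = 45)
  rec <- measure_tubule(outer_m, lumen_m, um_per_px = 1, tubule_id = 7L,
                        seed = 2)
  expect_identical(rec$tubule_id, 7L)
  expect_identical(rec$se_area, rec$tubule_area - rec$lumen_area)
  expect_identical(rec$se_area_ratio, 100 * rec$se_area / rec$tubule_area)
  expect_lt(rec$lumen_area, rec$tubule_area)
  expect_lte(rec$lumen_diameter_1, rec$tubule_diameter_1)
  expect_lte(rec$lumen_diameter_2, rec$tubule_diameter_2)
  expect_equal(rec$se_thickness_mean, 40, tolerance = 0.03)

  lumenless <- measure_tubule(outer_m, NULL, 1, tubule_id = 1L)
  expect_identical(lumenless$lumen_area, 0)
  expect_identical(lumenless$se_area_ratio, 100)
})

test_that("the section report aggregates ground truth and round-trips CSV", {
  scene <- generate_scene(small_phantom_spec(seed = 31))
  he <- render_he(scene)
  flags <- data.frame(label = scene$tubules$label,
                      is_longitudinal = scene$tubules$is_longitudinal,
                      is_spermatid_positive = scene$tubules$is_spermatid_positive)
  rep <- suppressWarnings(
    build_section_report(he$section_mask, he$tubule_labels,
                         scene$spec$calibration_um_per_px, flags,
                         n_sample = 100, seed = 5))
  expect_identical(rep$total_tubule_count, 12L)
  expect_identical(rep$spermatid_positive_count,
                   as.integer(sum(flags$is_spermatid_positive)))
  expect_identical(rep$bergmann_kliesch_pct,
                   100 * rep$spermatid_positive_count / 12)
  expect_identical(rep$interstitial_area,
                   rep$total_testis_area - rep$sum_all_tubule_areas)
  expect_equal(rep$tubule_area_ratio_pct +
                 100 * rep$interstitial_area / rep$total_testis_area, 100)
  expect_gte(rep$interstitial_area, 0)
  sampled <- as.integer(strsplit(rep$sampled_tubule_ids, ";")[[1]])
  expect_true(all(!flags$is_longitudinal[match(sampled, flags$label)]))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_report_csv(as.data.frame(rep), f1)
  back <- read_report_csv(f1)
  expect_identical(back$total_tubule_count, 12L)
  expect_equal(back$bergmann_kliesch_pct, rep$bergmann_kliesch_pct,
               tolerance = 1e-5)  # stored at 6 significant digits
  write_report_csv(back, f2)
  back2 <- read_report_csv(f2)
  expect_identical(back, back2)  # idempotent at stored precision

  write_report_csv(as.data.frame(rep), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))  # byte-identical writes
})
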