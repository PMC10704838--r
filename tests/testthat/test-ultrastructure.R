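test_that("aspect ratio recovers symmetry and elongation", {
  expect_equal(aspect_ratio(circle_polygon(1000, 96)), 1.0, tolerance = 0.01)
  expect_equal(aspect_ratio(ellipse_polygon(2000, 1000, 96)), 2.0, tolerance = 0.02)
  p <- make_tem_profile(obliqueness = 1.3, lumen_wobble = 0, seed = 2)
  expect_equal(aspect_ratio(p$bm_outer_contour), 1.3, tolerance = 0.02)
  expect_error(aspect_ratio(circle_polygon(1, 4)), "vertices")
})

test_that("profile filtering is strict at the cutoff and labels reasons", {
  at_cutoff <- make_tem_profile(obliqueness = 1.2, lumen_wobble = 0, seed = 3)
  oblique <- make_tem_profile(obliqueness = 1.5, lumen_wobble = 0, seed = 4)
  # exclusion is strict: a profile whose aspect ratio equals the cutoff
  # exactly ("more than 1.2") stays in
  cutoff <- aspect_ratio(at_cutoff$bm_outer_contour)
  flt <- filter_profiles(list(at_cutoff, oblique), max_aspect = cutoff)
  expect_length(flt$included, 1)
  expect_identical(flt$log$reason, c(NA_character_, "oblique"))

  big <- make_tem_profile(lumen_radius = 6000, obliqueness = 1, seed = 5)
  flt2 <- filter_profiles(list(big), large_vessel_nm = 5000)
  expect_identical(flt2$log$reason, "large_vessel")

  covered <- make_tem_profile(pericyte_coverage = 0.9, obliqueness = 1, seed = 6)
  flt3 <- filter_profiles(list(covered), max_pericyte_coverage_pct = 80)
  expect_identical(flt3$log$reason, "high_pericyte_coverage")
})

test_that("generator-labelled oblique profiles are exactly the ones excluded", {
  obl <- rep(c(1.05, 1.4), c(20, 10))
  profs <- lapply(seq_along(obl), function(i)
    make_tem_profile(obliqueness = obl[i], lumen_wobble = 0,
                     capillary_id = sprintf("c%02d", i), seed = i))
  flt <- filter_profiles(profs, max_aspect = 1.2)
  expect_identical(which(!flt$log$included), which(obl > 1.2))
})

test_that("raising the aspect cutoff never shrinks the included set", {
  set.seed(77)
  profs <- lapply(1:25, function(i)
    make_tem_profile(obliqueness = 1 + rexp(1, 8), capillary_id = paste0("c", i),
                     seed = 100 + i))
  inc <- lapply(c(1.1, 1.2, 1.4), function(mx)
    filter_profiles(profs, max_aspect = mx)$log$capillary_id[
      filter_profiles(profs, max_aspect = mx)$log$included])
  expect_true(all(inc[[1]] %in% inc[[2]]))
  expect_true(all(inc[[2]] %in% inc[[3]]))
})

test_that("six-site measurement recovers a constant membrane", {
  p <- make_tem_profile(cbm_mean = 300, cbm_sd = 0, obliqueness = 1, seed = 9)
  s <- measure_cbm(p, seed = 10)
  expect_length(s$site_thicknesses, 6)
  expect_true(all(abs(s$site_thicknesses - 300) < 3))
  expect_equal(s$capillary_mean, mean(s$site_thicknesses))
  expect_equal(s$capillary_mean, 300, tolerance = 3)
})

test_that("measurement sites avoid pericyte arcs by the configured margin", {
  for (sd in 1:20) {
    p <- make_tem_profile(pericyte_coverage = 0, obliqueness = 1, seed = sd)
    p$pericyte_arcs <- matrix(c(0, pi / 2), 1,
                              dimnames = list(NULL, c("start", "end")))
    s <- measure_cbm(p, margin_deg = 5, seed = 50 + sd)
    m <- 5 * pi / 180
    bad <- capimorph:::angle_in_arc(s$site_angles, 0, pi / 2, m)
    expect_false(any(bad), info = sprintf("seed %d", sd))
  }
})

test_that("overwhelming pericyte coverage raises the exclusion error", {
  p <- make_tem_profile(pericyte_coverage = 0, obliqueness = 1, seed = 1)
  p$pericyte_arcs <- matrix(c(0, 1.98 * pi), 1,
                            dimnames = list(NULL, c("start", "end")))
  expect_error(measure_cbm(p, seed = 2), "pericyte coverage too high")
})

test_that("constant-membrane round trip holds over many generated profiles", {
  set.seed(88)
  means <- vapply(1:1000, function(i) {
    p <- make_tem_profile(lumen_radius = rlnorm(1, log(1800), 0.25),
                          ec_thickness = rlnorm(1, log(300), 0.2),
                          cbm_mean = 300, cbm_sd = 0,
                          pericyte_coverage = runif(1, 0, 0.5),
                          obliqueness = 1, seed = 3000 + i)
    measure_cbm(p, seed = 4000 + i)$capillary_mean
  }, numeric(1))
  expect_lt(abs(mean(means) - 300) / 300, 0.01)
})

test_that("capillary mean is stable under rotation of the site offset", {
  p <- make_tem_profile(cbm_mean = 320, cbm_sd = 30, obliqueness = 1, seed = 12)
  means <- vapply(1:100, function(i) measure_cbm(p, seed = i)$capillary_mean,
                  numeric(1))
  expect_lt(abs(mean(means) - mean(p$true_cbm$thickness)) /
              mean(p$true_cbm$thickness), 0.02)
})

test_that("CBM aggregation reports both conventions and flags outliers", {
  mk_set <- function(id, th) structure(
    list(capillary_id = id, site_angles = seq(0, 2 * pi, length.out = 6),
         site_thicknesses = th, excluded_sites = numeric(0),
         capillary_mean = mean(th)), class = "cbm_measurement_set")
  one <- aggregate_cbm(list(mk_set("c1", rep(300, 6))))
  expect_equal(one$sample_means$cbm_mean_nm, 300)

  two <- aggregate_cbm(list(mk_set("c1", c(340, 360, rep(300, 4)))),
                       outlier_nm = 350)
  expect_identical(sum(two$measurements$outlier), 1L)
  expect_equal(two$mean_of_singles, mean(c(340, 360, rep(300, 4))))

  grp <- aggregate_cbm(list(mk_set("c1", rep(300, 6)), mk_set("c2", rep(320, 6)),
                            mk_set("c3", rep(400, 6))),
                       sample_ids = c("s1", "s1", "s2"))
  expect_equal(grp$mean_of_sample_means, mean(c(310, 400)))
  expect_equal(grp$mean_of_singles, mean(c(300, 320, 400) %*% t(rep(1, 6))))
  expect_error(aggregate_cbm(list()), "no CBM")
})

test_that("contour morphometry is exact on concentric circles", {
  prof <- profile_from_contours(circle_polygon(2000), circle_polygon(2200),
                                circle_polygon(2500))
  m <- tbia_morphometry(prof)
  expect_equal(m$lumen_radius, 2000, tolerance = 1)
  expect_equal(m$ec_thickness, 200, tolerance = 1)
  expect_equal(m$bm_thickness, 300, tolerance = 1)
  expect_equal(m$pericyte_coverage, 0)
})

test_that("pericyte coverage equals the fraction of abluminal circumference", {
  arcs <- rbind(c(0, pi / 2), c(pi, 3 * pi / 2))
  colnames(arcs) <- c("start", "end")
  prof <- profile_from_contours(circle_polygon(2000), circle_polygon(2200),
                                circle_polygon(2500), arcs = arcs)
  expect_equal(tbia_morphometry(prof)$pericyte_coverage, 50, tolerance = 0.5)
})

test_that("annulus thickness formula agrees with ray casting on ellipses", {
  lum <- ellipse_polygon(3000, 1500)
  ec <- ellipse_polygon(3200, 1700)
  bm <- ellipse_polygon(3500, 2000)
  m <- tbia_morphometry(profile_from_contours(lum, ec, bm))
  expect_equal(m$ec_thickness, raycast_mean_thickness(lum, ec),
               tolerance = 0.05 * m$ec_thickness)
  expect_equal(m$bm_thickness, raycast_mean_thickness(ec, bm),
               tolerance = 0.05 * m$bm_thickness)
  # within the inclusion regime (aspect <= 1.2) agreement also holds for
  # generated profiles
  p <- make_tem_profile(obliqueness = 1.15, cbm_sd = 0, cbm_mean = 300, seed = 31)
  mp <- tbia_morphometry(p)
  expect_equal(mp$bm_thickness,
               raycast_mean_thickness(p$ec_abluminal_contour, p$bm_outer_contour),
               tolerance = 0.05 * mp$bm_thickness)
})

test_that("non-nested contours are rejected naming the violated pair", {
  bad <- profile_from_contours(circle_polygon(2300), circle_polygon(2200),
                               circle_polygon(2500))
  expect_error(tbia_morphometry(bad), "lumen.*ec_abluminal")
})

test_that("pathology rubric maps feature flags to the published grades", {
  expect_identical(score_capillary_pathology(3, FALSE, "none", "normal",
                                             FALSE, FALSE), 0L)
  expect_identical(score_capillary_pathology(ec_necrosis_or_debris = TRUE,
                                             n_pericyte_processes = 9,
                                             ensheathment = "present"), 4L)
  expect_identical(score_capillary_pathology(5, FALSE, "present", "prominent",
                                             pericyte_irregular = TRUE), 2L)
  expect_identical(score_capillary_pathology(5, FALSE, "present", "prominent",
                                             pericyte_irregular = TRUE,
                                             pronounced = TRUE), 3L)
  expect_identical(score_capillary_pathology(5, FALSE, "single", "slight"), 1L)
  expect_identical(score_capillary_pathology(2, TRUE, "none", "normal"), 1L)
})
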