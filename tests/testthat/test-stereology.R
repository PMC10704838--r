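test_that("forbidden-line rule on canonical square configurations", {
  fr <- counting_frame(0, 0, 10, 10)
  inside <- list(unit_square_at(3, 3), unit_square_at(5, 7), unit_square_at(8, 2.5))
  crossing_left <- unit_square_at(0, 5)      # straddles x = 0 (forbidden)
  crossing_right <- unit_square_at(10, 5)    # straddles x = 10 (acceptance)
  expect_equal(count_with_forbidden_line(fr, c(inside, list(crossing_left, crossing_right))), 4L)
  expect_equal(count_with_forbidden_line(fr, list()), 0L)
})

test_that("forbidden-line extensions exclude out-of-frame touchers", {
  fr <- counting_frame(0, 0, 10, 10)
  # below the frame, straddling the downward extension of the right frame
  # line (x = 10, y < 0): excluded even though it meets nothing else
  below_right <- unit_square_at(10, -3)
  expect_equal(count_with_forbidden_line(fr, list(below_right)), 0L)
  # same square shifted up to also cross the frame's bottom edge: the bottom
  # edge is forbidden, still 0
  astride_bottom <- unit_square_at(9.4, 0)
  expect_equal(count_with_forbidden_line(fr, list(astride_bottom)), 0L)
  # polygon crossing the top edge and reaching across the upward extension
  # of the left edge (x = 0, y > 10): excluded
  wide_top <- cbind(c(-2, 4, 4, -2), c(9, 9, 12, 12))
  expect_equal(count_with_forbidden_line(fr, list(wide_top)), 0L)
  # polygon crossing the top edge only (acceptance): counted
  top_only <- unit_square_at(5, 10)
  expect_equal(count_with_forbidden_line(fr, list(top_only)), 1L)
})

test_that("tangency follows the strict-exclusion convention", {
  fr <- counting_frame(0, 0, 10, 10)
  tangent_right_outside <- cbind(c(10, 11, 11, 10), c(4, 4, 6, 6))
  expect_equal(count_with_forbidden_line(fr, list(tangent_right_outside)), 1L)
  tangent_left_outside <- cbind(c(-1, 0, 0, -1), c(4, 4, 6, 6))
  expect_equal(count_with_forbidden_line(fr, list(tangent_left_outside)), 0L)
  # points: half-open in both axes
  expect_equal(count_with_forbidden_line(fr, rbind(c(10, 5), c(0, 5), c(5, 10), c(5, 0))), 2L)
})

test_that("counting agrees with the brute-force rule classifier on random scenes", {
  fr <- counting_frame(0, 0, 6, 6)
  set.seed(401)
  for (scene in 1:50) {
    profiles <- lapply(1:12, function(i) {
      c0 <- runif(2, -3, 9)
      k <- sample(3:7, 1)
      th <- sort(runif(k, 0, 2 * pi))
      r <- runif(k, 0.3, 1.4)
      cbind(c0[1] + r * cos(th), c0[2] + r * sin(th))
    })
    pts <- lapply(1:8, function(i) runif(2, -2, 8))
    for (pr in c(profiles, pts)) {
      expect_equal(count_with_forbidden_line(fr, list(pr)),
                   as.integer(brute_force_counted(fr, pr)),
                   info = sprintf("scene %d", scene))
    }
  }
})

test_that("tiling a scene with counting frames counts every profile exactly once", {
  for (s in 1:8) {
    sc <- make_tissue_scene(n_fibers = 36, mcsfa = 4000, cf = 1.5,
                            seed = 300 + s, extent_pad = 250)
    polys <- lapply(sc$fibers, `[[`, "polygon")
    ext <- sc$scene_extent
    w <- 157.3; h <- 211.9  # deliberately not commensurate with the lattice
    xs <- seq(ext[1] - w, ext[3] + w, by = w)
    ys <- seq(ext[2] - h, ext[4] + h, by = h)
    tot_f <- 0L; tot_c <- 0L
    for (x0 in xs) for (y0 in ys) {
      fr <- counting_frame(x0, y0, x0 + w, y0 + h)
      tot_f <- tot_f + count_with_forbidden_line(fr, polys)
      tot_c <- tot_c + count_with_forbidden_line(fr, sc$capillaries)
    }
    expect_identical(tot_f, length(polys))
    expect_identical(tot_c, nrow(sc$capillaries))
  }
})

test_that("point-grid hits recover trivial and analytic area fractions", {
  g <- point_grid(spacing = 10, origin = c(0, 0))
  expect_equal(point_hits(g, list()), list(p_fiber = 0, p_total = 100))
  whole <- cbind(c(-1, 101, 101, -1), c(-1, -1, 101, 101))
  expect_equal(point_hits(g, list(whole))$p_fiber, 100)

  # striped plane with known area fraction 0.8: mean hit fraction over many
  # random grid placements approaches the fraction
  stripes <- lapply(0:19, function(k)
    cbind(c(20 * k, 20 * k + 16, 20 * k + 16, 20 * k),
          c(-10, -10, 410, 410)))
  set.seed(402)
  fr <- replicate(1000, {
    o <- runif(2, 0, 200)
    g <- point_grid(spacing = 20, origin = o)
    ph <- point_hits(g, stripes)
    ph$p_fiber / ph$p_total
  })
  expect_gte(mean(fr), 0.78)
  expect_lte(mean(fr), 0.82)
})

test_that("MCSFA, capillary density and C/F follow the counting formulas", {
  ct <- stereology_counts(0, 10, 100, 100, 10000)
  expect_equal(estimate_mcsfa(ct), 1000)
  ct2 <- stereology_counts(5, 9, 80, 100, 56250)
  expect_equal(estimate_mcsfa(ct2), 5000)
  # 5 capillaries over 12500 um^2 of fiber area -> 400 per mm^2
  ct3 <- stereology_counts(5, 9, 100, 100, 12500)
  expect_equal(estimate_capillary_density(ct3), 400)
  expect_equal(estimate_capillary_density(stereology_counts(0, 9, 50, 100, 1000)), 0)
  expect_equal(estimate_cf_ratio(stereology_counts(12, 8, 1, 100, 1)), 1.5)
  expect_equal(estimate_cf_ratio(stereology_counts(0, 8, 1, 100, 1)), 0)
  expect_error(estimate_cf_ratio(stereology_counts(3, 0, 1, 100, 1)), "fiber")
  expect_error(estimate_mcsfa(stereology_counts(3, 0, 1, 100, 1)), "fiber")
})

test_that("sample aggregation pools counts (ratio of sums, not mean of ratios)", {
  a <- stereology_counts(3, 1, 40, 100, 10000)
  b <- stereology_counts(1, 3, 60, 100, 10000)
  est <- aggregate_sample(list(a, b))
  expect_equal(est$cf_ratio, 1.0)   # mean of ratios would give 1.67
  expect_match(attr(est, "aggregation"), "ratio-of-sums")
  one <- aggregate_sample(list(a))
  expect_equal(one$cf_ratio, estimate_cf_ratio(a))
  expect_equal(one$mcsfa, estimate_mcsfa(a))
  expect_error(aggregate_sample(list()), "no fields")
})

test_that("density x MCSFA = C/F identity holds exactly on pooled counts", {
  sc <- make_tissue_scene(n_fibers = 100, seed = 21)
  st <- stereology_sample(sc, n_fov = 6, seed = 3)
  expect_equal(st$sample$capillary_density * 1e-6 * st$sample$mcsfa,
               st$sample$cf_ratio, tolerance = 1e-9)
})

test_that("counting-frame C/F estimator is unbiased over random placements", {
  sc <- make_tissue_scene(n_fibers = 150, mcsfa = 4200, cf = 1.7,
                          seed = 17, extent_pad = 320)
  polys <- lapply(sc$fibers, `[[`, "polygon")
  census <- nrow(sc$capillaries) / length(polys)
  fovs <- sample_fovs(sc, c(300, 300), 1000, seed = 99)
  counts <- vapply(seq_len(nrow(fovs)), function(i) {
    fr <- counting_frame(fovs[i, 1], fovs[i, 2], fovs[i, 3], fovs[i, 4])
    c(count_with_forbidden_line(fr, sc$capillaries),
      count_with_forbidden_line(fr, polys))
  }, numeric(2))
  r <- sum(counts[1, ]) / sum(counts[2, ])
  # ratio-estimator standard error
  e <- counts[1, ] - r * counts[2, ]
  sem <- sqrt(sum(e^2) * length(e) / (length(e) - 1)) / sum(counts[2, ])
  expect_lt(abs(r - census), 2 * sem)
})

test_that("MCSFA error shrinks as the test-point grid is refined", {
  sc <- make_tissue_scene(n_fibers = 49, mcsfa = 4000, cf = 1.5,
                          seed = 23, extent_pad = 5)
  polys <- lapply(sc$fibers, `[[`, "polygon")
  ext <- sc$scene_extent
  fr <- counting_frame(ext[1], ext[2], ext[3], ext[4])
  n_fib <- count_with_forbidden_line(fr, polys)
  true_total <- sum(vapply(sc$fibers, `[[`, numeric(1), "area"))
  truth <- true_total / n_fib
  L <- max(ext[3] - ext[1], ext[4] - ext[2])  # square grid covering the scene
  # point-count error depends on the grid phase, so compare the error
  # averaged over a 3 x 3 set of sub-spacing grid shifts at each density
  err <- vapply(c(10, 20, 40), function(m) {
    mean(vapply(0:8, function(k) {
      off <- c((k %% 3), (k %/% 3)) / 3 * L / m
      g <- point_grid(m, m, spacing = L / m, origin = ext[1:2] - off)
      ph <- point_hits(g, polys)
      abs((ph$p_fiber / ph$p_total) * g$total_area / n_fib - truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("stereology recovers generator ground truth on synthetic scenes", {
  # grand mean over many scenes approaches the configured MCSFA
  ests <- vapply(1:40, function(i) {
    sc <- make_tissue_scene(n_fibers = 150, mcsfa = 3500, cf = 1.6,
                            seed = 1000 + i)
    st <- stereology_sample(sc, n_fov = 10, seed = 2000 + i)
    c(st$sample$mcsfa, st$sample$cf_ratio)
  }, numeric(2))
  expect_lt(abs(mean(ests[1, ]) - 3500) / 3500, 0.03)
  expect_lt(abs(mean(ests[2, ]) - 1.6), 0.05)
})
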