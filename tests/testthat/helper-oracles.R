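# Independent oracles and small fixture builders used across tests.

# --- brute-force forbidden-line classifier -------------------------------
# Classifies a profile against the counting-frame rule using dense boundary
# sampling and pracma's point-in-polygon, sharing no geometry code with
# count_with_forbidden_line(). `eps` is the touch tolerance; boundary
# sampling is fine enough that any transversal crossing is detected.
brute_force_counted <- function(frame, profile, eps = 1e-3) {
  x0 <- frame$x0; y0 <- frame$y0; x1 <- frame$x1; y1 <- frame$y1
  reach <- 100 * max(x1 - x0, y1 - y0)

  if (is.null(dim(profile))) {
    p <- profile
    touches_forbidden <-
      (abs(p[1] - x0) <= eps && p[2] >= y0 - eps) ||
      (abs(p[2] - y0) <= eps && p[1] >= x0 - eps && p[1] <= x1 + eps) ||
      (abs(p[1] - x1) <= eps && p[2] <= y0 + eps)
    meets <- p[1] >= x0 - eps && p[1] <= x1 + eps &&
      p[2] >= y0 - eps && p[2] <= y1 + eps
    return(meets && !touches_forbidden)
  }

  poly <- rbind(profile)
  n <- nrow(poly)
  # dense boundary samples; the touch tolerance must exceed the sampling
  # step so that a transversal crossing is always detected
  n_per_edge <- 1000
  bp <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    t <- seq(0, 1, length.out = n_per_edge)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  max_step <- max(sqrt(rowSums((poly[c(2:n, 1), , drop = FALSE] - poly)^2))) /
    (n_per_edge - 1)
  eps <- max(eps, 1.5 * max_step)

  in_rect <- any(bp[, 1] >= x0 - eps & bp[, 1] <= x1 + eps &
                   bp[, 2] >= y0 - eps & bp[, 2] <= y1 + eps)
  corner_inside <- any(pracma::inpolygon(
    c(x0, x1, x1, x0), c(y0, y0, y1, y1), poly[, 1], poly[, 2],
    boundary = TRUE))
  meets <- in_rect || corner_inside

  touches <- any(abs(bp[, 1] - x0) <= eps & bp[, 2] >= y0 - eps) ||
    any(abs(bp[, 2] - y0) <= eps & bp[, 1] >= x0 - eps & bp[, 1] <= x1 + eps) ||
    any(abs(bp[, 1] - x1) <= eps & bp[, 2] <= y0 + eps)
  if (!touches) {
    # the polygon might swallow part of a forbidden ray without its boundary
    # coming near it: sample the forbidden line itself
    fl <- rbind(
      cbind(x0, seq(y0, y1 + reach, length.out = 2000)),
      cbind(seq(x0, x1, length.out = 500), y0),
      cbind(x1, seq(y0 - reach, y0, length.out = 2000))
    )
    keep <- fl[, 1] >= min(poly[, 1]) - eps & fl[, 1] <= max(poly[, 1]) + eps &
      fl[, 2] >= min(poly[, 2]) - eps & fl[, 2] <= max(poly[, 2]) + eps
    if (any(keep))
      touches <- any(pracma::inpolygon(fl[keep, 1], fl[keep, 2],
                                       poly[, 1], poly[, 2], boundary = TRUE))
  }
  meets && !touches
}

# --- dense ray-casting thickness oracle ----------------------------------
# Mean separation between two nested contours measured along the inner
# contour's outward normal at many angles; independent of the annulus
# area/circumference formula it is used to check.
raycast_mean_thickness <- function(inner, outer, n_rays = 720) {
  ctr <- colMeans(inner)
  th <- vapply(2 * pi * (seq_len(n_rays) - 1) / n_rays, function(a) {
    hit <- capimorph:::ray_polygon_intersection(ctr, c(cos(a), sin(a)), inner)
    if (is.null(hit)) return(NA_real_)
    nv <- capimorph:::edge_outward_normal(inner, hit$edge)
    out <- capimorph:::ray_polygon_intersection(hit$point, nv, outer)
    if (is.null(out)) return(NA_real_)
    out$t
  }, numeric(1))
  mean(th, na.rm = TRUE)
}

# --- fixture builders -----------------------------------------------------
unit_square_at <- function(cx, cy, half = 0.5) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

circle_polygon <- function(r, n = 720, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_polygon <- function(a, b, n = 720) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(a * cos(th), b * sin(th))
}

# Minimal TEM profile object from explicit contours.
profile_from_contours <- function(lumen, ec, bm, arcs = NULL, id = "fix") {
  if (is.null(arcs))
    arcs <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  structure(list(
    capillary_id = id, lumen_contour = lumen, ec_abluminal_contour = ec,
    bm_outer_contour = bm, pericyte_arcs = arcs, obliqueness = NA_real_,
    true_cbm = NULL
  ), class = "tem_capillary_profile")
}

# Fiber table with a given atrophic fraction among 2b fibers.
fiber_table_fixture <- function(n2b = 100, frac_atrophic = 0, frac_small = 0,
                                n_other = 50) {
  n_atr <- round(frac_atrophic * n2b)
  n_small <- round(frac_small * n2b)
  data.frame(
    fiber_id = paste0("f", seq_len(n2b + n_other)),
    fiber_type = c(rep("2b", n2b), rep("1", n_other)),
    area_um2 = c(rep(c(1500, 4000), c(n_atr, n2b - n_atr)), rep(4200, n_other)),
    min_diameter_um = c(rep(c(15, 60), c(n_small, n2b - n_small)),
                        rep(62, n_other)),
    atrophic = c(rep(c(TRUE, FALSE), c(n_atr, n2b - n_atr)),
                 rep(FALSE, n_other)),
    mhc1_sarcolemmal = FALSE,
    stringsAsFactors = FALSE
  )
}

# Raw vectors with exactly the requested mean and SD.
raw_with_summary <- function(mean, sd, n) {
  z <- scale(seq_len(n))[, 1]
  mean + sd * z
}
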