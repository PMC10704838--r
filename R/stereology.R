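# Stereological estimation of capillarity from fields of view: unbiased
# counting frame (forbidden-line rule), point-counting grid, and the
# capillary-to-fiber ratio / MCSFA / capillary density estimators.

#' Construct an unbiased counting frame
#'
#' The frame follows the classical convention: the top and right edges are
#' acceptance edges; the left and bottom edges, together with the infinite
#' extension of the left edge upward and of the right frame line downward
#' from the bottom-right corner, form the forbidden line. Profiles touching
#' the forbidden line are never counted; this makes counts over a tiling of
#' frames count every profile exactly once.
#'
#' @param x0,y0,x1,y1 Frame rectangle (x0 < x1, y0 < y1), um.
#' @return A `counting_frame` object.
#' @export
counting_frame <- function(x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1)) stop("need x0 < x1 and y0 < y1")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 acceptance_edges = c("top", "right"),
                 forbidden_edges = c("bottom", "left")),
            class = "counting_frame")
}

#' Construct a point-counting grid
#'
#' A regular `n_rows` x `n_cols` array of test points. The grid's counting
#' area is `(n_cols * spacing) * (n_rows * spacing)`, i.e. each test point
#' represents one `spacing^2` tile; points sit at tile centers, so the
#' bounding square of the tiles is the counting frame.
#'
#' @param n_rows,n_cols Grid dimensions (default 10 x 10 = 100 test points).
#' @param spacing Distance between neighbouring test points, um.
#' @param origin Lower-left corner of the grid's counting area (length-2).
#' @return A `point_grid` with `points` (n x 2 matrix) and `total_area`.
#' @export
point_grid <- function(n_rows = 10, n_cols = 10, spacing, origin = c(0, 0)) {
  if (spacing <= 0) stop("spacing must be > 0")
  xs <- origin[1] + spacing * (seq_len(n_cols) - 0.5)
  ys <- origin[2] + spacing * (seq_len(n_rows) - 0.5)
  pts <- cbind(rep(xs, times = n_rows), rep(ys, each = n_cols))
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 origin = origin, points = pts,
                 total_area = (n_cols * spacing) * (n_rows * spacing)),
            class = "point_grid")
}

# The three pieces of the forbidden line, as segments (rays truncated far
# beyond any profile): left edge extended upward, bottom edge, and the
# downward extension of the right frame line from the bottom-right corner.
forbidden_line_segments <- function(frame, reach = NULL) {
  if (is.null(reach)) reach <- 1e7 * max(1, abs(frame$x1 - frame$x0))
  list(
    left_up = rbind(c(frame$x0, frame$y0), c(frame$x0, frame$y1 + reach)),
    bottom = rbind(c(frame$x0, frame$y0), c(frame$x1, frame$y0)),
    right_down = rbind(c(frame$x1, frame$y0), c(frame$x1, frame$y0 - reach))
  )
}

# Does a point profile get counted? Half-open rule: in (x0, x1] x (y0, y1].
point_counted <- function(frame, p, tol = GEOM_TOL) {
  p[1] > frame$x0 + tol && p[1] <= frame$x1 + tol &&
    p[2] > frame$y0 + tol && p[2] <= frame$y1 + tol
}

# Does the polygon intersect the closed frame rectangle?
polygon_meets_rect <- function(poly, frame, tol = GEOM_TOL) {
  poly <- as_polygon(poly)
  inx <- poly[, 1] >= frame$x0 - tol & poly[, 1] <= frame$x1 + tol
  iny <- poly[, 2] >= frame$y0 - tol & poly[, 2] <= frame$y1 + tol
  if (any(inx & iny)) return(TRUE)
  corners <- rbind(c(frame$x0, frame$y0), c(frame$x1, frame$y0),
                   c(frame$x1, frame$y1), c(frame$x0, frame$y1))
  if (any(points_in_polygon_fast(corners[, 1], corners[, 2], poly))) return(TRUE)
  edges <- rbind(corners, corners[1, ])
  for (i in 1:4) {
    if (polygon_touches_segment(poly, edges[i, ], edges[i + 1, ], tol))
      return(TRUE)
  }
  FALSE
}

polygon_touches_forbidden <- function(poly, frame, tol = GEOM_TOL) {
  segs <- forbidden_line_segments(frame)
  for (s in segs) {
    if (polygon_touches_segment(poly, s[1, ], s[2, ], tol)) return(TRUE)
  }
  FALSE
}

#' Count profiles under the forbidden-line rule
#'
#' A profile is counted iff it intersects the frame (interior or acceptance
#' edges) and does not touch the forbidden line or its infinite extensions.
#' Point profiles (length-2 vectors or single-row matrices, and degenerate
#' zero-area polygons) are counted with the equivalent half-open rule.
#'
#' @param frame A [counting_frame()].
#' @param profiles List of profiles: each an n x 2 polygon matrix or a
#'   length-2 point. An n x 2 matrix of points also works for point profiles.
#' @return Integer count.
#' @export
count_with_forbidden_line <- function(frame, profiles) {
  stopifnot(inherits(frame, "counting_frame"))
  tol <- GEOM_TOL
  if (is.matrix(profiles) && ncol(profiles) == 2) {
    # matrix of point profiles: vectorized half-open rule
    x <- profiles[, 1]; y <- profiles[, 2]
    return(sum(x > frame$x0 + tol & x <= frame$x1 + tol &
                 y > frame$y0 + tol & y <= frame$y1 + tol))
  }
  if (length(profiles) == 0) return(0L)
  n <- 0L
  for (pr in profiles) {
    if (is.null(dim(pr)) || nrow(pr) < 2) {
      p <- if (is.null(dim(pr))) pr else pr[1, ]
      if (point_counted(frame, p)) n <- n + 1L
      next
    }
    # bounding-box screening: a profile wholly outside the closed frame
    # cannot be counted (touching only the forbidden extensions excludes
    # it anyway); a nondegenerate profile wholly inside the open frame is
    # always counted
    bb <- c(range(pr[, 1]), range(pr[, 2]))
    if (bb[2] < frame$x0 - tol || bb[1] > frame$x1 + tol ||
        bb[4] < frame$y0 - tol || bb[3] > frame$y1 + tol) next
    if (bb[1] > frame$x0 + tol && bb[2] < frame$x1 - tol &&
        bb[3] > frame$y0 + tol && bb[4] < frame$y1 - tol) {
      # wholly inside the open frame: counted whether degenerate or not
      n <- n + 1L
      next
    }
    if (nrow(pr) < 3 || abs(polygon_area_signed(pr)) < tol) {
      # degenerate polygon: treat as a point at its vertex mean
      if (point_counted(frame, colMeans(pr))) n <- n + 1L
      next
    }
    if (polygon_meets_rect(pr, frame) && !polygon_touches_forbidden(pr, frame))
      n <- n + 1L
  }
  n
}

#' Count test-point hits on fiber profiles
#'
#' A test point hits a fiber iff it lies inside or on the fiber polygon.
#'
#' @param grid A [point_grid()].
#' @param fibers List of fiber profiles (`polygon` element) or bare polygon
#'   matrices.
#' @return List with `p_fiber` and `p_total`.
#' @export
point_hits <- function(grid, fibers) {
  stopifnot(inherits(grid, "point_grid"))
  pts <- grid$points
  hit <- rep(FALSE, nrow(pts))
  for (f in fibers) {
    poly <- if (is.list(f)) f$polygon else f
    todo <- which(!hit)
    if (length(todo) == 0) break
    # bounding-box prefilter
    bb <- c(range(poly[, 1]), range(poly[, 2]))
    cand <- todo[pts[todo, 1] >= bb[1] & pts[todo, 1] <= bb[2] &
                   pts[todo, 2] >= bb[3] & pts[todo, 2] <= bb[4]]
    if (length(cand) == 0) next
    hit[cand] <- points_in_polygon(pts[cand, 1], pts[cand, 2], poly)
  }
  list(p_fiber = sum(hit), p_total = nrow(pts))
}

#' Bundle raw stereological counts
#'
#' @param n_capillary_profiles,n_fiber_profiles Profile counts under the
#'   forbidden-line rule.
#' @param p_fiber,p_total Test-point hits on fibers and total test points.
#' @param grid_area Counting-grid area, um^2.
#' @return A `stereology_counts` object; `fiber_profile_area_total` is the
#'   point-count estimate `(p_fiber / p_total) * grid_area`.
#' @export
stereology_counts <- function(n_capillary_profiles, n_fiber_profiles,
                              p_fiber, p_total, grid_area) {
  stopifnot(p_fiber >= 0, p_fiber <= p_total, n_capillary_profiles >= 0,
            n_fiber_profiles >= 0)
  structure(list(
    n_capillary_profiles = n_capillary_profiles,
    n_fiber_profiles = n_fiber_profiles,
    p_fiber = p_fiber, p_total = p_total, grid_area = grid_area,
    fiber_profile_area_total = (p_fiber / p_total) * grid_area
  ), class = "stereology_counts")
}

#' Estimate mean cross-sectional fiber area (MCSFA)
#'
#' Point-count estimator: the fraction of test points on fiber profiles
#' times the grid area gives the total fiber profile area, which is divided
#' by the number of fiber profiles counted in the frame.
#'
#' @param counts A [stereology_counts()].
#' @return MCSFA in um^2.
#' @export
estimate_mcsfa <- function(counts) {
  stopifnot(inherits(counts, "stereology_counts"))
  if (counts$p_total <= 0) stop("p_total must be > 0")
  if (counts$n_fiber_profiles == 0)
    stop("MCSFA undefined: no fiber profiles counted")
  counts$fiber_profile_area_total / counts$n_fiber_profiles
}

#' Estimate capillary density (capillaries per mm^2 of fiber area)
#'
#' @param counts A [stereology_counts()].
#' @return Capillary profiles per mm^2 of muscle-fiber profile area.
#' @export
estimate_capillary_density <- function(counts) {
  stopifnot(inherits(counts, "stereology_counts"))
  if (counts$fiber_profile_area_total <= 0)
    stop("capillary density undefined: zero fiber profile area")
  counts$n_capillary_profiles / (counts$fiber_profile_area_total * 1e-6)
}

#' Estimate the capillary-to-fiber (C/F) ratio
#'
#' @param counts A [stereology_counts()].
#' @return Dimensionless ratio of capillary to fiber profile counts.
#' @export
estimate_cf_ratio <- function(counts) {
  stopifnot(inherits(counts, "stereology_counts"))
  if (counts$n_fiber_profiles == 0)
    stop("C/F undefined: no fiber profiles counted")
  counts$n_capillary_profiles / counts$n_fiber_profiles
}

capillarity_estimate <- function(counts) {
  structure(list(
    cf_ratio = estimate_cf_ratio(counts),
    mcsfa = estimate_mcsfa(counts),
    capillary_density = estimate_capillary_density(counts),
    counts = counts
  ), class = "capillarity_estimate")
}

#' Run the counting protocol on one field of view
#'
#' The field rectangle serves as the unbiased counting frame; a point grid
#' spanning it provides the test points. Capillaries are counted as points
#' (their profile size is negligible at this magnification), fibers as
#' polygons, both under the forbidden-line rule.
#'
#' @param scene A `tissue_scene`.
#' @param fov Length-4 rectangle (x0, y0, x1, y1), um.
#' @param n_rows,n_cols Test-point grid dimensions.
#' @return A `stereology_counts` object.
#' @export
count_fov <- function(scene, fov, n_rows = 10, n_cols = 10) {
  frame <- counting_frame(fov[1], fov[2], fov[3], fov[4])
  spacing <- (fov[3] - fov[1]) / n_cols
  grid <- point_grid(n_rows, n_cols, spacing, origin = c(fov[1], fov[2]))

  caps <- scene$capillaries
  n_cap <- count_with_forbidden_line(frame, caps)

  polys <- lapply(scene$fibers, `[[`, "polygon")
  # keep only fibers whose bounding box can interact with the frame
  bb <- scene_fiber_bboxes(scene)
  sel <- which(bb[, 2] >= fov[1] - GEOM_TOL & bb[, 1] <= fov[3] + GEOM_TOL &
                 bb[, 4] >= fov[2] - GEOM_TOL & bb[, 3] <= fov[4] + GEOM_TOL)
  n_fib <- count_with_forbidden_line(frame, polys[sel])

  ph <- point_hits(grid, polys[sel])
  stereology_counts(n_cap, n_fib, ph$p_fiber, ph$p_total, grid$total_area)
}

# Per-fiber bounding boxes (xmin, xmax, ymin, ymax), cached on the scene.
scene_fiber_bboxes <- function(scene) {
  cached <- attr(scene, "fiber_bboxes")
  if (!is.null(cached)) return(cached)
  t(vapply(scene$fibers, function(f)
    c(range(f$polygon[, 1]), range(f$polygon[, 2])), numeric(4)))
}

#' Pool per-field estimates into a sample-level estimate
#'
#' Raw counts are pooled across fields before the ratios are formed
#' (ratio-of-sums), which is unbiased for ratio estimators and robust to
#' fields containing no fibers. Mean-of-ratios is *not* used.
#'
#' @param counts_list List of per-field [stereology_counts()].
#' @return A `capillarity_estimate` with `cf_ratio`, `mcsfa` (um^2),
#'   `capillary_density` (per mm^2) and the pooled counts. The attribute
#'   `aggregation` records the pooling rule.
#' @export
aggregate_sample <- function(counts_list) {
  if (length(counts_list) == 0) stop("no fields of view to aggregate")
  stopifnot(all(vapply(counts_list, inherits, logical(1), "stereology_counts")))
  pooled <- stereology_counts(
    n_capillary_profiles = sum(vapply(counts_list, `[[`, numeric(1), "n_capillary_profiles")),
    n_fiber_profiles = sum(vapply(counts_list, `[[`, numeric(1), "n_fiber_profiles")),
    p_fiber = sum(vapply(counts_list, `[[`, numeric(1), "p_fiber")),
    p_total = sum(vapply(counts_list, `[[`, numeric(1), "p_total")),
    grid_area = sum(vapply(counts_list, `[[`, numeric(1), "grid_area"))
  )
  # total fiber area must be the sum of per-field point-count areas
  pooled$fiber_profile_area_total <- sum(vapply(
    counts_list, `[[`, numeric(1), "fiber_profile_area_total"))
  est <- capillarity_estimate(pooled)
  attr(est, "aggregation") <- "ratio-of-sums (counts pooled across FOVs)"
  est
}

#' Stereology for one sample: sample fields, count, pool
#'
#' @param scene A `tissue_scene`.
#' @param n_fov Number of fields of view.
#' @param fov_size Field width/height (um); default 450 x 450 um, chosen so
#'   that ten fields sample enough fiber profiles for a per-sample C/F
#'   coefficient of error well below the between-subject variation.
#' @param seed Integer seed for field placement.
#' @return List with `sample` (the pooled `capillarity_estimate`) and
#'   `per_fov` (data frame of per-field counts and estimates).
#' @export
stereology_sample <- function(scene, n_fov = 10, fov_size = c(450, 450),
                              seed = 1L) {
  attr(scene, "fiber_bboxes") <- scene_fiber_bboxes(scene)
  fovs <- sample_fovs(scene, fov_size, n_fov, seed = seed)
  counts <- lapply(seq_len(nrow(fovs)), function(i) count_fov(scene, fovs[i, ]))
  per_fov <- do.call(rbind, lapply(seq_along(counts), function(i) {
    ct <- counts[[i]]
    data.frame(fov_id = i,
               n_cap = ct$n_capillary_profiles, n_fib = ct$n_fiber_profiles,
               p_fiber = ct$p_fiber, p_total = ct$p_total,
               cf_ratio = if (ct$n_fiber_profiles > 0)
                 ct$n_capillary_profiles / ct$n_fiber_profiles else NA_real_)
  }))
  list(sample = aggregate_sample(counts), per_fov = per_fov)
}
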