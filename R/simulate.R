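# Synthetic tissue scenes and TEM capillary profiles with known ground truth.

#' Generate a synthetic muscle tissue scene
#'
#' Builds a fiber mosaic as a jittered hexagonal tiling: hexagon vertices
#' shared between neighbouring cells are perturbed consistently, each cell is
#' shrunk slightly about its centroid (leaving interstitial endomysium), and
#' atrophic type-2b fibers are shrunk further by the atrophy factor. Capillary
#' points are placed at fiber-boundary junction points (snapped exactly onto a
#' fiber polygon boundary) until the target capillary-to-fiber ratio is met.
#'
#' @param n_fibers Approximate number of fibers (the hexagonal grid is sized
#'   to the nearest feasible count).
#' @param mcsfa Target mean cross-sectional fiber area (um^2) before atrophy.
#' @param cf Target capillary-to-fiber ratio.
#' @param fiber_type_props Named proportions for types 1 / 2a / 2b.
#' @param atrophy_factor Area multiplier in (0, 1] for atrophic 2b fibers.
#' @param atrophy_fraction Fraction of 2b fibers that are atrophic.
#' @param sample_id Label stored in the scene.
#' @param extent_pad Width of the empty rim around the fiber mosaic included
#'   in the scene extent (um). A rim of about one field-of-view width makes
#'   random field placement translation-invariant over the mosaic, so the
#'   counting-frame estimators are free of scene-border bias.
#' @param seed Integer seed (scene is deterministic given it).
#' @return A `tissue_scene`: list with `fibers` (list of fiber profiles:
#'   `polygon`, `fiber_type`, `area`, `min_diameter`, `atrophic`),
#'   `capillaries` (n x 2 matrix, um), `cell_markers`, and `scene_extent`
#'   (xmin, ymin, xmax, ymax).
#' @export
make_tissue_scene <- function(n_fibers = 260,
                              mcsfa = 4500,
                              cf = 1.8,
                              fiber_type_props = c(`1` = 0.4, `2a` = 0.35, `2b` = 0.25),
                              atrophy_factor = 1,
                              atrophy_fraction = 0,
                              sample_id = "scene",
                              extent_pad = 450,
                              seed = 1L) {
  with_seed(seed, {
    # per-fiber linear shrink u ~ U(0.85, 1); E[u^2] = 0.8575, so size the
    # hexagons such that the expected non-atrophic fiber area is `mcsfa`
    u_lo <- 0.85
    eu2 <- (1 - u_lo^3) / (3 * (1 - u_lo))
    hex_area <- mcsfa / eu2
    side <- sqrt(hex_area / (3 * sqrt(3) / 2))

    dims <- grid_dims_for(n_fibers)
    ncol_h <- dims[1]; nrow_h <- dims[2]
    centers <- hex_centers(ncol_h, nrow_h, side)
    n <- nrow(centers)

    # raw vertices: 6 per cell, flat-top hexagon
    ang <- (0:5) * pi / 3
    vx <- outer(centers[, 1], side * cos(ang), `+`)
    vy <- outer(centers[, 2], side * sin(ang), `+`)
    allv <- cbind(as.vector(t(vx)), as.vector(t(vy)))  # cell-major order

    # consistent jitter of shared vertices, keyed by rounded coordinates
    key <- paste(round(allv[, 1] / side, 6), round(allv[, 2] / side, 6))
    uk <- !duplicated(key)
    idx <- match(key, key[uk])
    nu <- sum(uk)
    jit <- matrix(pmin(pmax(stats::rnorm(2 * nu, sd = 0.10 * side),
                            -0.25 * side), 0.25 * side), ncol = 2)
    junctions <- allv[uk, , drop = FALSE] + jit
    vjit <- junctions[idx, , drop = FALSE]

    # assign fiber types and atrophy
    types <- sample(names(fiber_type_props), n, replace = TRUE,
                    prob = fiber_type_props)
    atrophic <- types == "2b" & stats::runif(n) < atrophy_fraction
    u <- stats::runif(n, u_lo, 1)
    scale_lin <- u * ifelse(atrophic, sqrt(atrophy_factor), 1)

    # vectorized construction of all scaled hexagons and their metrics
    X <- matrix(vjit[, 1], ncol = 6, byrow = TRUE)
    Y <- matrix(vjit[, 2], ncol = 6, byrow = TRUE)
    cx <- rowMeans(X); cy <- rowMeans(Y)
    X <- (X - cx) * scale_lin + cx
    Y <- (Y - cy) * scale_lin + cy
    nxt <- c(2:6, 1)
    areas <- abs(rowSums(X * Y[, nxt] - X[, nxt] * Y)) / 2
    # minimal caliper width over the six edge-normal directions
    widths <- matrix(Inf, n, 6)
    for (j in 1:6) {
      ex <- X[, nxt[j]] - X[, j]; ey <- Y[, nxt[j]] - Y[, j]
      el <- sqrt(ex^2 + ey^2)
      proj <- (-ey * X + ex * Y) / el  # recycles columns of X, Y
      widths[, j] <- do.call(pmax, as.data.frame(proj)) -
        do.call(pmin, as.data.frame(proj))
    }
    min_diam <- do.call(pmin, as.data.frame(widths))

    fibers <- vector("list", n)
    cents <- cbind(cx, cy)
    for (i in seq_len(n)) {
      fibers[[i]] <- list(
        fiber_id = sprintf("%s_f%04d", sample_id, i),
        polygon = cbind(X[i, ], Y[i, ]),
        fiber_type = types[i],
        area = areas[i],
        min_diameter = min_diam[i],
        atrophic = atrophic[i]
      )
    }

    # capillaries at junction points, snapped onto the nearest fiber boundary
    n_cap <- round(cf * n)
    if (n_cap > nrow(junctions)) {
      stop(sprintf(paste0(
        "infeasible capillary-to-fiber ratio: %d capillaries requested but ",
        "only %d fiber-boundary junction points available; reduce cf (%.2f) ",
        "or increase n_fibers"), n_cap, nrow(junctions), cf))
    }
    picks <- sample.int(nrow(junctions), n_cap)
    caps <- matrix(0, n_cap, 2)
    for (j in seq_along(picks)) {
      p <- junctions[picks[j], ]
      d2 <- (cents[, 1] - p[1])^2 + (cents[, 2] - p[2])^2
      fi <- which.min(d2)
      caps[j, ] <- closest_point_on_boundary(p, fibers[[fi]]$polygon)$point
    }

    extent <- c(min(vjit[, 1]) - extent_pad, min(vjit[, 2]) - extent_pad,
                max(vjit[, 1]) + extent_pad, max(vjit[, 2]) + extent_pad)

    structure(list(
      sample_id = sample_id,
      fibers = fibers,
      capillaries = caps,
      cell_markers = list(),
      scene_extent = extent
    ), class = "tissue_scene")
  })
}

# Hexagonal grid dimensions (cols, rows) giving roughly n cells.
grid_dims_for <- function(n) {
  side_cells <- max(2L, round(sqrt(n)))
  c(side_cells, ceiling(n / side_cells))
}

# Flat-top hexagon centers for a cols x rows grid with side length s.
hex_centers <- function(ncol_h, nrow_h, s) {
  cols <- rep(seq_len(ncol_h) - 1L, each = nrow_h)
  rows <- rep(seq_len(nrow_h) - 1L, times = ncol_h)
  x <- 1.5 * s * cols
  y <- sqrt(3) * s * (rows + 0.5 * (cols %% 2))
  cbind(x, y)
}

#' @export
print.tissue_scene <- function(x, ...) {
  cat(sprintf("Tissue scene '%s': %d fibers, %d capillaries, extent %.0f x %.0f um\n",
              x$sample_id, length(x$fibers), nrow(x$capillaries),
              x$scene_extent[3] - x$scene_extent[1],
              x$scene_extent[4] - x$scene_extent[2]))
  invisible(x)
}

#' Sample rectangular fields of view from a scene
#'
#' Positions are uniform over all placements that keep the field fully
#' inside the scene extent.
#'
#' @param scene A `tissue_scene`.
#' @param fov_size Length-2 numeric (width, height) in um.
#' @param n_fov Number of fields.
#' @param seed Integer seed.
#' @return An `n_fov` x 4 matrix of rectangles (x0, y0, x1, y1).
#' @export
sample_fovs <- function(scene, fov_size, n_fov, seed = 1L) {
  ext <- scene$scene_extent
  w <- fov_size[1]; h <- fov_size[2]
  if (w > ext[3] - ext[1] || h > ext[4] - ext[2])
    stop("field of view larger than the scene extent")
  if (n_fov == 0) return(matrix(numeric(0), 0, 4,
                                dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  with_seed(seed, {
    x0 <- stats::runif(n_fov, ext[1], ext[3] - w)
    y0 <- stats::runif(n_fov, ext[2], ext[4] - h)
    cbind(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
  })
}

#' Generate a synthetic TEM capillary profile
#'
#' Builds three nested closed contours in nm around the origin -- capillary
#' lumen (blood:endothelium transition), abluminal endothelial surface
#' (endothelium:basement-membrane transition) and outer basement membrane
#' (basement-membrane:endomysium transition) -- plus pericyte arcs on the
#' abluminal surface. The basement-membrane thickness varies smoothly around
#' the profile (low-order harmonics) with mean `cbm_mean` and angular SD
#' `cbm_sd`. Oblique sectioning is emulated by an area-preserving affine
#' stretch of factor `obliqueness` (major/minor axis ratio), so a caliper
#' aspect-ratio measurement on the outer contour recovers it.
#'
#' @param lumen_radius Lumen radius, nm.
#' @param ec_thickness Endothelial thickness, nm.
#' @param cbm_mean,cbm_sd Basement-membrane thickness mean and angular SD, nm.
#' @param pericyte_coverage Fraction of the abluminal circumference covered
#'   by pericyte processes, in [0, 1].
#' @param obliqueness Axis-stretch ratio >= 1 (1 = true cross-section).
#' @param n_vertices Vertices per contour.
#' @param lumen_wobble Relative amplitude of lumen-contour irregularity.
#' @param capillary_id Label.
#' @param seed Integer seed.
#' @return A `tem_capillary_profile`: contours (n x 2 matrices, nm),
#'   `pericyte_arcs` (k x 2 matrix of angular intervals, radians),
#'   `obliqueness`, and `true_cbm` (per-angle thickness table and its mean).
#' @export
make_tem_profile <- function(lumen_radius = 1800,
                             ec_thickness = 300,
                             cbm_mean = 300,
                             cbm_sd = 0,
                             pericyte_coverage = 0,
                             obliqueness = 1,
                             n_vertices = 96,
                             lumen_wobble = 0.02,
                             capillary_id = "cap",
                             seed = 1L) {
  if (lumen_radius <= 0 || ec_thickness <= 0 || cbm_mean <= 0)
    stop("all lengths must be > 0")
  if (cbm_sd < 0) stop("cbm_sd must be >= 0")
  if (obliqueness < 1) stop("obliqueness must be >= 1")
  if (pericyte_coverage < 0 || pericyte_coverage > 1)
    stop("pericyte_coverage must be in [0, 1]")

  with_seed(seed, {
    theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices

    # smooth CBM field: harmonics of order 2..4, variance over angle = cbm_sd^2
    if (cbm_sd > 0) {
      amp <- cbm_sd * sqrt(2 / 3)
      ph <- stats::runif(3, 0, 2 * pi)
      cbm <- cbm_mean +
        amp * (cos(2 * theta + ph[1]) + cos(3 * theta + ph[2]) + cos(4 * theta + ph[3]))
      cbm <- pmax(cbm, 0.1 * cbm_mean)
    } else {
      cbm <- rep(cbm_mean, n_vertices)
    }

    # slightly irregular lumen, parallel endothelium
    if (lumen_wobble > 0) {
      phl <- stats::runif(1, 0, 2 * pi)
      rl <- lumen_radius * (1 + lumen_wobble * cos(3 * theta + phl))
    } else {
      rl <- rep(lumen_radius, n_vertices)
    }
    re <- rl + ec_thickness
    rb <- re + cbm

    stretch <- function(r) {
      cbind(r * cos(theta) * sqrt(obliqueness),
            r * sin(theta) / sqrt(obliqueness))
    }

    arcs <- draw_pericyte_arcs(pericyte_coverage)
    if (nrow(arcs) > 0 && obliqueness > 1) {
      # map arc endpoints into the stretched angular coordinate
      arcs <- t(apply(arcs, 1, function(a) stretched_angles(a, obliqueness)))
      colnames(arcs) <- c("start", "end")
    }

    structure(list(
      capillary_id = capillary_id,
      lumen_contour = stretch(rl),
      ec_abluminal_contour = stretch(re),
      bm_outer_contour = stretch(rb),
      pericyte_arcs = arcs,
      obliqueness = obliqueness,
      true_cbm = list(theta = theta, thickness = cbm, mean = cbm_mean)
    ), class = "tem_capillary_profile")
  })
}

# Disjoint pericyte arcs with total angular coverage = coverage * 2*pi.
draw_pericyte_arcs <- function(coverage) {
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (coverage <= 0) return(empty)
  k <- if (coverage > 0.6) 2L else sample(2:4, 1)
  lens <- stats::runif(k, 0.5, 1.5)
  lens <- lens / sum(lens) * coverage * 2 * pi
  gaps <- stats::runif(k, 0.5, 1.5)
  gaps <- gaps / sum(gaps) * (1 - coverage) * 2 * pi
  start0 <- stats::runif(1, 0, 2 * pi)
  starts <- start0 + cumsum(c(0, (lens + gaps)[-k]))
  arcs <- cbind(start = starts %% (2 * pi), end = (starts %% (2 * pi)) + lens)
  colnames(arcs) <- c("start", "end")
  arcs
}

# Angle observed after the affine stretch x*sqrt(o), y/sqrt(o); monotone in
# the original angle, applied to an interval (start, end) preserving order.
stretched_angles <- function(interval, o) {
  f <- function(th) {
    k <- floor(th / (2 * pi))
    th0 <- th - k * 2 * pi
    a <- atan2(sin(th0) / sqrt(o), cos(th0) * sqrt(o)) %% (2 * pi)
    a + k * 2 * pi
  }
  s <- f(interval[1]); e <- f(interval[2])
  if (e < s) e <- e + 2 * pi
  c(s, e)
}

#' @export
print.tem_capillary_profile <- function(x, ...) {
  cat(sprintf("TEM capillary profile '%s': %d-vertex contours, obliqueness %.2f, %d pericyte arc(s)\n",
              x$capillary_id, nrow(x$lumen_contour), x$obliqueness,
              nrow(x$pericyte_arcs)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' For every sample in the design, builds a tissue scene (fiber mosaic +
#' capillary points), a set of TEM capillary profiles, per-marker immune-cell
#' field counts, and a ground-truth record. Each sample is generated from a
#' substream seed derived from the cohort seed and the sample id, so the
#' output is deterministic and samples can be regenerated in isolation.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `samples` (each: `sample_id`,
#'   `group`, `scene`, `profiles`, `cell_fields`, `truth`) and `truth` (one
#'   data frame row per sample).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  samples <- list()
  truth_rows <- list()
  markers <- rownames(spec$cells_per_10hpf_mean)

  for (g in seq_along(spec$group_names)) {
    grp <- spec$group_names[g]
    for (i in seq_len(spec$group_sizes[g])) {
      sid <- sprintf("%s-%d", grp, i)
      sseed <- substream_seed(spec$seed, sid)

      pars <- with_seed(sseed, {
        list(
          # truncated at +/- 3 SD and at the hexagonal mosaic's junction
          # capacity (about 2.15 capillary sites per fiber)
          cf_s = min(max(stats::rnorm(1, spec$cf_true[g], spec$cf_sample_sd),
                         spec$cf_true[g] - 3 * spec$cf_sample_sd, 0.2),
                     spec$cf_true[g] + 3 * spec$cf_sample_sd, 2.05),
          cbm_s = max(60, stats::rnorm(1, spec$cbm_mean[g], spec$cbm_sample_sd)),
          n_tem = {
            r <- spec$capillaries_per_sample_range
            if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
          },
          cell_tot = vapply(markers, function(mk) {
            m <- spec$cells_per_10hpf_mean[mk, g]
            s <- spec$cells_per_10hpf_sd[mk, g]
            if (s^2 > m + 1e-9) {
              shape <- m^2 / (s^2 - m)
              stats::rgamma(1, shape = shape, rate = shape / m)
            } else m
          }, numeric(1))
        )
      })

      scene <- make_tissue_scene(
        n_fibers = spec$scene_fibers,
        mcsfa = spec$mcsfa_true[g],
        cf = pars$cf_s,
        fiber_type_props = spec$fiber_type_props,
        atrophy_factor = spec$type2b_atrophy_factor[g],
        atrophy_fraction = spec$type2b_atrophy_fraction[g],
        sample_id = sid,
        seed = substream_seed(sseed, "scene")
      )

      profiles <- with_seed(substream_seed(sseed, "tem"), {
        lapply(seq_len(pars$n_tem), function(j) {
          cap_mean <- max(50, stats::rnorm(1, pars$cbm_s, spec$cbm_capillary_sd))
          make_tem_profile(
            lumen_radius = stats::rlnorm(1, log(1800), 0.25),
            ec_thickness = stats::rlnorm(1, log(300), 0.20),
            cbm_mean = cap_mean,
            cbm_sd = spec$cbm_sd,
            pericyte_coverage = min(0.95, stats::rbeta(1, 2.2, 6.5)),
            obliqueness = 1 + stats::rexp(1, rate = 1 / 0.08),
            capillary_id = sprintf("%s_c%02d", sid, j),
            seed = substream_seed(sseed, paste0("tem", j))
          )
        })
      })

      cell_fields <- with_seed(substream_seed(sseed, "cells"), {
        out <- lapply(markers, function(mk)
          stats::rpois(10, pars$cell_tot[[mk]] / 10))
        names(out) <- markers
        out
      })

      fib_areas <- vapply(scene$fibers, `[[`, numeric(1), "area")
      truth_rows[[sid]] <- data.frame(
        sample_id = sid, group = grp,
        cf_true = nrow(scene$capillaries) / length(scene$fibers),
        cf_target = pars$cf_s,
        mcsfa_true = mean(fib_areas),
        cbm_mean_true = pars$cbm_s,
        n_tem = pars$n_tem,
        stringsAsFactors = FALSE
      )
      for (mk in markers)
        truth_rows[[sid]][[paste0("cells_", mk, "_true")]] <- pars$cell_tot[[mk]]

      samples[[sid]] <- list(
        sample_id = sid, group = grp, scene = scene, profiles = profiles,
        cell_fields = cell_fields, truth = truth_rows[[sid]]
      )
    }
  }

  structure(list(
    samples = samples,
    truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples in %d groups (seed %d)\n",
              length(x$samples), length(x$spec$group_names), x$spec$seed))
  invisible(x)
}
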