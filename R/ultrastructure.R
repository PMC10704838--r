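# TEM capillary morphometry: obliqueness filtering, six-site basement
# membrane thickness measurement with pericyte exclusion, contour-based
# (TBIA) morphometry, and the subjective 0-4 capillary pathology score.

#' Caliper aspect ratio of a closed contour
#'
#' Largest over smallest caliper (Feret) diameter, always >= 1. Profiles
#' sectioned obliquely appear elongated; those with ratio above the cutoff
#' (conventionally 1.2) are excluded from morphometry. Note the field's
#' customary phrasing "ratio of the smallest to largest diameter > 1.2"
#' describes the same elongation criterion with the fraction inverted; the
#' implemented ratio is largest/smallest.
#'
#' @param contour n x 2 vertex matrix (n >= 8).
#' @return Aspect ratio >= 1.
#' @export
aspect_ratio <- function(contour) {
  contour <- as_polygon(contour)
  if (nrow(contour) < 8) stop("contour needs >= 8 vertices")
  caliper_aspect_ratio(contour)
}

#' Filter TEM capillary profiles before morphometry
#'
#' Excludes profiles that are too obliquely sectioned (aspect ratio of the
#' outer basement-membrane contour strictly greater than `max_aspect`),
#' abnormally large microvessels (equivalent-circle lumen radius above
#' `large_vessel_nm`), or profiles with very high pericyte coverage. Each
#' exclusion is tagged with its reason.
#'
#' @param profiles List of `tem_capillary_profile` objects.
#' @param max_aspect Aspect-ratio cutoff; a profile at exactly the cutoff is
#'   included (exclusion is strict).
#' @param large_vessel_nm Lumen-radius cutoff, nm.
#' @param max_pericyte_coverage_pct Pericyte-coverage cutoff, percent.
#' @return List with `included`, `excluded` (profile lists), `morphometry`
#'   (list of [tbia_morphometry()] results for the included profiles) and
#'   `log` (data frame: capillary_id, included, reason, aspect_ratio).
#' @export
filter_profiles <- function(profiles, max_aspect = 1.2,
                            large_vessel_nm = 5000,
                            max_pericyte_coverage_pct = 80) {
  morphs <- lapply(profiles, tbia_morphometry)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]; morph <- morphs[[i]]
    ar <- aspect_ratio(p$bm_outer_contour)
    reason <- NA_character_
    if (ar > max_aspect) reason <- "oblique"
    else if (morph$lumen_radius > large_vessel_nm) reason <- "large_vessel"
    else if (morph$pericyte_coverage > max_pericyte_coverage_pct)
      reason <- "high_pericyte_coverage"
    data.frame(capillary_id = p$capillary_id, included = is.na(reason),
               reason = reason, aspect_ratio = ar, stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, rows)
  list(included = profiles[log$included],
       excluded = profiles[!log$included],
       morphometry = morphs[log$included],
       log = log)
}

# Angular distance of angle a to the interval [s, e] (may wrap past 2*pi),
# on the circle.
angle_in_arc <- function(a, s, e, margin = 0) {
  width <- e - s
  rel <- (a - (s - margin)) %% (2 * pi)
  rel <= width + 2 * margin
}

# Total angular measure and a sampler for the set of angles outside all
# pericyte arcs (each widened by `margin`).
free_angle_domain <- function(arcs, margin) {
  if (nrow(arcs) == 0) {
    return(list(measure = 2 * pi,
                sample = function(u) (u * 2 * pi)))
  }
  blocked <- cbind((arcs[, 1] - margin) %% (2 * pi),
                   (arcs[, 1] - margin) %% (2 * pi) + (arcs[, 2] - arcs[, 1]) + 2 * margin)
  # merge on the circle: cut at 2*pi, build union of intervals on [0, 4*pi)
  iv <- rbind(blocked, blocked - 2 * pi, blocked + 2 * pi)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(iv))) {
    if (length(merged) > 0 && iv[i, 1] <= merged[[length(merged)]][2]) {
      merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], iv[i, 2])
    } else merged[[length(merged) + 1]] <- iv[i, ]
  }
  # free intervals within [0, 2*pi)
  free <- list()
  cursor <- 0
  for (m in merged) {
    if (m[2] <= 0) next
    if (m[1] >= 2 * pi) break
    if (m[1] > cursor) free[[length(free) + 1]] <- c(cursor, min(m[1], 2 * pi))
    cursor <- max(cursor, min(m[2], 2 * pi))
    if (cursor >= 2 * pi) break
  }
  if (cursor < 2 * pi) free[[length(free) + 1]] <- c(cursor, 2 * pi)
  lens <- vapply(free, function(f) f[2] - f[1], numeric(1))
  total <- sum(lens)
  list(measure = total, sample = function(u) {
    # u in [0,1) -> angle in the free set, by inverse CDF over intervals
    x <- u * total
    for (i in seq_along(free)) {
      if (x <= lens[i]) return(free[[i]][1] + x)
      x <- x - lens[i]
    }
    free[[length(free)]][2]
  })
}

#' Measure basement-membrane thickness at six sites
#'
#' Sites are evenly spaced angles with a random rotation offset. Any site
#' falling within `margin_deg` of a pericyte arc (where the membrane is
#' irregular and typically thicker) is re-drawn from the pericyte-free
#' angular domain. At each accepted site the thickness is the length of the
#' segment from the abluminal endothelial contour to the outer basement
#' membrane contour along the local outward normal.
#'
#' @param profile A `tem_capillary_profile` (should have passed
#'   [filter_profiles()]).
#' @param n_sites Number of measurement sites (protocol: 6).
#' @param margin_deg Angular margin (degrees) kept clear around each
#'   pericyte arc.
#' @param seed Integer seed for the rotation offset and re-draws.
#' @return A `cbm_measurement_set`: `site_angles`, `site_thicknesses` (nm),
#'   `excluded_sites` (angles rejected for pericyte adjacency),
#'   `capillary_mean` (nm).
#' @export
measure_cbm <- function(profile, n_sites = 6, margin_deg = 5, seed = 1L) {
  stopifnot(inherits(profile, "tem_capillary_profile"))
  margin <- margin_deg * pi / 180
  dom <- free_angle_domain(profile$pericyte_arcs, margin)
  # need at least one margin-width of free membrane per site
  if (dom$measure < n_sites * margin) {
    stop(sprintf(
      "pericyte coverage too high on '%s': only %.2f rad free for %d sites; profile should have been excluded",
      profile$capillary_id, dom$measure, n_sites))
  }
  with_seed(seed, {
    offset <- stats::runif(1, 0, 2 * pi)
    angles <- (offset + 2 * pi * (seq_len(n_sites) - 1) / n_sites) %% (2 * pi)
    rejected <- numeric(0)
    arcs <- profile$pericyte_arcs
    in_any_arc <- function(a) {
      nrow(arcs) > 0 && any(vapply(seq_len(nrow(arcs)), function(i)
        angle_in_arc(a, arcs[i, 1], arcs[i, 2], margin), logical(1)))
    }
    for (i in seq_len(n_sites)) {
      if (in_any_arc(angles[i])) {
        rejected <- c(rejected, angles[i])
        repeat {
          cand <- dom$sample(stats::runif(1))
          if (!in_any_arc(cand)) break
        }
        angles[i] <- cand
      }
    }
    ctr <- polygon_centroid(profile$ec_abluminal_contour)
    th <- vapply(angles, function(a) cbm_thickness_at(profile, a, ctr), numeric(1))
    structure(list(
      capillary_id = profile$capillary_id,
      site_angles = angles,
      site_thicknesses = th,
      excluded_sites = rejected,
      capillary_mean = mean(th)
    ), class = "cbm_measurement_set")
  })
}

# Thickness of the basement membrane at angular position `a`: find the point
# of the abluminal (EC:BM) contour on the ray at angle `a` from the contour
# centroid, then cast along the local outward normal to the outer contour.
cbm_thickness_at <- function(profile, a, ctr = NULL) {
  ec <- profile$ec_abluminal_contour
  bm <- profile$bm_outer_contour
  if (is.null(ctr)) ctr <- polygon_centroid(ec)
  hit <- ray_polygon_intersection(ctr, c(cos(a), sin(a)), ec)
  if (is.null(hit)) stop("measurement ray missed the abluminal contour")
  nv <- edge_outward_normal(ec, hit$edge)
  out <- ray_polygon_intersection(hit$point, nv, bm)
  if (is.null(out)) stop("normal ray missed the outer basement membrane contour")
  out$t
}

#' Aggregate CBM measurement sets
#'
#' Returns the single measurements in long format, per-capillary means,
#' per-sample means (mean of capillary means) and, when `level = "group"`,
#' the group mean computed both over all single measurements and over
#' per-sample means (both conventions are reported because published work
#' rarely states which was used). Single measurements above `outlier_nm` are
#' flagged for display filtering but retained in all statistics.
#'
#' @param sets List of `cbm_measurement_set`.
#' @param sample_ids Optional character vector mapping each set to a sample;
#'   defaults to one pseudo-sample.
#' @param outlier_nm Display-outlier threshold, nm (default 350).
#' @return List with `measurements` (data frame: capillary_id, sample_id,
#'   site_index, thickness_nm, outlier), `capillary_means`, `sample_means`,
#'   `mean_of_singles`, `mean_of_sample_means`, `sd`, `n`.
#' @export
aggregate_cbm <- function(sets, sample_ids = NULL, outlier_nm = 350) {
  if (length(sets) == 0) stop("no CBM measurement sets to aggregate")
  if (is.null(sample_ids)) sample_ids <- rep("sample", length(sets))
  stopifnot(length(sample_ids) == length(sets))
  meas <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(capillary_id = s$capillary_id, sample_id = sample_ids[i],
               site_index = seq_along(s$site_thicknesses),
               thickness_nm = s$site_thicknesses,
               stringsAsFactors = FALSE)
  }))
  meas$outlier <- meas$thickness_nm > outlier_nm
  cap_means <- data.frame(
    capillary_id = vapply(sets, `[[`, character(1), "capillary_id"),
    sample_id = sample_ids,
    cbm_mean_nm = vapply(sets, `[[`, numeric(1), "capillary_mean"),
    stringsAsFactors = FALSE
  )
  smeans <- tapply(cap_means$cbm_mean_nm, cap_means$sample_id, mean)
  sample_means <- data.frame(sample_id = names(smeans),
                             cbm_mean_nm = as.numeric(smeans),
                             stringsAsFactors = FALSE)
  list(
    measurements = meas,
    capillary_means = cap_means,
    sample_means = sample_means,
    mean_of_singles = mean(meas$thickness_nm),
    mean_of_sample_means = mean(sample_means$cbm_mean_nm),
    sd = stats::sd(meas$thickness_nm),
    n = nrow(meas),
    outlier_nm = outlier_nm
  )
}

#' Contour-based (TBIA) capillary morphometry
#'
#' From the areas (shoelace formula) and circumferences (polyline length)
#' of the nested contours: lumen radius is the equivalent-circle radius
#' `C_lumen / 2 pi`; endothelial thickness is the annulus mean thickness
#' `2 (A_ec - A_lumen) / (C_lumen + C_ec)`; basement-membrane thickness is
#' `2 (A_bm - A_ec) / (C_ec + C_bm)`; pericyte coverage is the percentage of
#' the abluminal circumference lying under pericyte arcs.
#'
#' @param profile A `tem_capillary_profile`.
#' @return A `morphometry_result`: `lumen_radius`, `ec_thickness`,
#'   `bm_thickness` (nm), `pericyte_coverage` (percent), plus the raw areas
#'   (nm^2) and circumferences (nm).
#' @export
tbia_morphometry <- function(profile) {
  stopifnot(inherits(profile, "tem_capillary_profile"))
  lum <- profile$lumen_contour
  ec <- profile$ec_abluminal_contour
  bm <- profile$bm_outer_contour
  check_nested(lum, ec, "lumen", "ec_abluminal")
  check_nested(ec, bm, "ec_abluminal", "bm_outer")

  a_l <- polygon_area(lum); a_e <- polygon_area(ec); a_b <- polygon_area(bm)
  c_l <- polygon_perimeter(lum); c_e <- polygon_perimeter(ec)
  c_b <- polygon_perimeter(bm)

  structure(list(
    lumen_radius = c_l / (2 * pi),
    ec_thickness = 2 * (a_e - a_l) / (c_l + c_e),
    bm_thickness = 2 * (a_b - a_e) / (c_e + c_b),
    pericyte_coverage = 100 * pericyte_arc_length(ec, profile$pericyte_arcs) / c_e,
    areas = c(lumen = a_l, ec_abluminal = a_e, bm_outer = a_b),
    circumferences = c(lumen = c_l, ec_abluminal = c_e, bm_outer = c_b)
  ), class = "morphometry_result")
}

check_nested <- function(inner, outer, name_in, name_out) {
  inside <- points_in_polygon_fast(inner[, 1], inner[, 2], outer)
  if (!all(inside) || polygon_area(inner) >= polygon_area(outer))
    stop(sprintf("contours not nested: '%s' is not strictly inside '%s'",
                 name_in, name_out))
  invisible(TRUE)
}

# Length of the abluminal contour lying under pericyte arcs: edges whose
# midpoint angle (about the contour centroid) falls in an arc.
pericyte_arc_length <- function(ec, arcs) {
  if (nrow(arcs) == 0) return(0)
  ctr <- polygon_centroid(ec)
  n <- nrow(ec)
  nxt <- c(2:n, 1)
  mid <- (ec + ec[nxt, , drop = FALSE]) / 2
  len <- sqrt(rowSums((ec[nxt, , drop = FALSE] - ec)^2))
  ang <- atan2(mid[, 2] - ctr[2], mid[, 1] - ctr[1]) %% (2 * pi)
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(arcs)))
    covered <- covered | angle_in_arc(ang, arcs[i, 1], arcs[i, 2])
  sum(len[covered])
}

#' Subjective capillary pathology score (0-4)
#'
#' Deterministic implementation of the published per-capillary rubric,
#' checked in priority order 4 to 0 (first matching grade wins):
#' 4 = endothelial necrosis / capillary remnants / cellular debris;
#' 3 = grade-2 features, more pronounced (`pronounced = TRUE`);
#' 2 = prominent irregular pericytes with ensheathment and prominent
#' vesicles/mitochondria; 1 = any mild abnormality (>= 4 pericyte processes,
#' reduplication, single ensheathment, slightly increased vesicles);
#' 0 = < 4 pericyte processes, no reduplication, no ensheathment, vesicles
#' and mitochondria within normal range.
#'
#' @param n_pericyte_processes Integer count of pericyte processes.
#' @param reduplication Logical, basement-membrane reduplication.
#' @param ensheathment One of "none", "single", "present".
#' @param vesicle_mito_grade One of "normal", "slight", "prominent".
#' @param pericyte_irregular Logical, prominent pericytes with irregular
#'   structure.
#' @param ec_necrosis_or_debris Logical, endothelial necrosis, capillary
#'   remnants or cellular debris.
#' @param pronounced Logical severity flag separating grade 3 from grade 2.
#' @return Integer score in 0..4.
#' @export
score_capillary_pathology <- function(n_pericyte_processes = 0,
                                      reduplication = FALSE,
                                      ensheathment = c("none", "single", "present"),
                                      vesicle_mito_grade = c("normal", "slight", "prominent"),
                                      pericyte_irregular = FALSE,
                                      ec_necrosis_or_debris = FALSE,
                                      pronounced = FALSE) {
  ensheathment <- match.arg(ensheathment)
  vesicle_mito_grade <- match.arg(vesicle_mito_grade)
  if (ec_necrosis_or_debris) return(4L)
  grade2 <- pericyte_irregular && ensheathment == "present" &&
    vesicle_mito_grade == "prominent"
  if (grade2 && pronounced) return(3L)
  if (grade2) return(2L)
  abnormal <- n_pericyte_processes >= 4 || reduplication ||
    ensheathment != "none" || vesicle_mito_grade != "normal" ||
    pericyte_irregular
  if (abnormal) return(1L)
  0L
}
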