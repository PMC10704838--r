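# Plain-text serialization: one JSON document per sample (scene geometry,
# capillary contours and ground truth), TSV tables for fibers, cell counts
# and results. All writers are byte-stable for fixed inputs.

profile_to_list <- function(p) {
  list(
    capillary_id = p$capillary_id,
    lumen = unname(apply(p$lumen_contour, 1, c, simplify = FALSE)),
    ec_abluminal = unname(apply(p$ec_abluminal_contour, 1, c, simplify = FALSE)),
    bm_outer = unname(apply(p$bm_outer_contour, 1, c, simplify = FALSE)),
    pericyte_arcs = if (nrow(p$pericyte_arcs) == 0) list() else
      unname(apply(p$pericyte_arcs, 1, c, simplify = FALSE)),
    obliqueness = p$obliqueness
  )
}

list_to_profile <- function(x, where = "profile") {
  need <- c("capillary_id", "lumen", "ec_abluminal", "bm_outer", "pericyte_arcs")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop(sprintf("%s: missing required key(s): %s", where,
                 paste(miss, collapse = ", ")))
  to_mat <- function(v) {
    m <- do.call(rbind, lapply(v, as.numeric))
    if (is.null(m)) m <- matrix(numeric(0), 0, 2)
    m
  }
  arcs <- to_mat(x$pericyte_arcs)
  if (ncol(arcs) == 2) colnames(arcs) <- c("start", "end")
  structure(list(
    capillary_id = x$capillary_id,
    lumen_contour = to_mat(x$lumen),
    ec_abluminal_contour = to_mat(x$ec_abluminal),
    bm_outer_contour = to_mat(x$bm_outer),
    pericyte_arcs = arcs,
    obliqueness = if (is.null(x$obliqueness)) NA_real_ else x$obliqueness,
    true_cbm = x$true_cbm
  ), class = "tem_capillary_profile")
}

#' Write one sample (scene + TEM profiles + truth) as JSON
#'
#' @param sample One element of a `synthetic_cohort`'s `samples` list.
#' @param path Output file path (.json).
#' @return `path`, invisibly.
#' @export
write_sample_json <- function(sample, path) {
  sc <- sample$scene
  doc <- list(
    sample_id = sample$sample_id,
    group = sample$group,
    scene = list(
      scene_extent = sc$scene_extent,
      fibers = lapply(sc$fibers, function(f) list(
        fiber_id = f$fiber_id,
        polygon = unname(apply(f$polygon, 1, c, simplify = FALSE)),
        fiber_type = f$fiber_type, area = f$area,
        min_diameter = f$min_diameter, atrophic = f$atrophic)),
      capillaries = unname(apply(sc$capillaries, 1, c, simplify = FALSE))
    ),
    profiles = lapply(sample$profiles, profile_to_list),
    cell_fields = sample$cell_fields,
    truth = as.list(sample$truth)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a sample JSON back into scene + profiles
#'
#' @param path Path written by [write_sample_json()].
#' @return List with `sample_id`, `group`, `scene`, `profiles`,
#'   `cell_fields`, `truth`.
#' @export
read_sample_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("sample_id", "scene", "profiles"))
    if (is.null(doc[[key]]))
      stop(sprintf("%s: missing required key(s): %s", basename(path), key))
  sc <- doc$scene
  to_mat <- function(v) do.call(rbind, lapply(v, as.numeric))
  fibers <- lapply(sc$fibers, function(f) list(
    fiber_id = f$fiber_id, polygon = to_mat(f$polygon),
    fiber_type = f$fiber_type, area = f$area,
    min_diameter = f$min_diameter, atrophic = f$atrophic))
  scene <- structure(list(
    sample_id = doc$sample_id,
    fibers = fibers,
    capillaries = to_mat(sc$capillaries),
    cell_markers = list(),
    scene_extent = as.numeric(sc$scene_extent)
  ), class = "tissue_scene")
  profiles <- lapply(seq_along(doc$profiles), function(i)
    list_to_profile(doc$profiles[[i]],
                    where = sprintf("%s profile %d", basename(path), i)))
  list(sample_id = doc$sample_id, group = doc$group, scene = scene,
       profiles = profiles,
       cell_fields = lapply(doc$cell_fields, function(v) as.numeric(unlist(v))),
       truth = as.data.frame(doc$truth, stringsAsFactors = FALSE))
}

#' Read TEM capillary contours from a JSON file
#'
#' Accepts either a sample JSON (profiles under `profiles`) or a bare JSON
#' array of profile objects with keys `capillary_id`, `lumen`,
#' `ec_abluminal`, `bm_outer`, `pericyte_arcs`.
#'
#' @param path JSON file path.
#' @return List of `tem_capillary_profile` objects.
#' @export
read_contours <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- if (!is.null(doc$profiles)) doc$profiles else doc
  lapply(seq_along(items), function(i)
    list_to_profile(items[[i]], where = sprintf("%s profile %d", basename(path), i)))
}

#' Read and validate a fiber table TSV
#'
#' Expected header: fiber_id, fiber_type, area_um2, min_diameter_um, mhc1,
#' atrophic. Malformed rows are rejected with their line number.
#'
#' @param path TSV path.
#' @return Data frame with column `mhc1_sarcolemmal` (logical).
#' @export
read_fiber_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("fiber_id", "fiber_type", "area_um2", "min_diameter_um",
            "mhc1", "atrophic")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  check_rows <- function(bad, what) {
    if (any(bad)) {
      # +1 header line: file line = row index + 1
      stop(sprintf("%s: %s at line %d (column %s)",
                   basename(path), "invalid value",
                   which(bad)[1] + 1L, what))
    }
  }
  check_rows(!is.finite(tab$area_um2) | tab$area_um2 <= 0, "area_um2")
  check_rows(!is.finite(tab$min_diameter_um) | tab$min_diameter_um <= 0,
             "min_diameter_um")
  check_rows(!tab$fiber_type %in% c("1", "2a", "2b"), "fiber_type")
  tab$mhc1_sarcolemmal <- as.logical(tab$mhc1)
  tab$atrophic <- as.logical(tab$atrophic)
  check_rows(is.na(tab$mhc1_sarcolemmal), "mhc1")
  check_rows(is.na(tab$atrophic), "atrophic")
  tab
}

#' Read a cell-count TSV (sample_id, marker, field_index, count)
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_cell_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "marker", "field_index", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  bad <- !is.finite(tab$count) | tab$count < 0
  if (any(bad))
    stop(sprintf("%s: invalid value at line %d (column count)",
                 basename(path), which(bad)[1] + 1L))
  tab
}

#' Read a qPCR Ct table TSV (sample_id, group, gene, replicate, ct)
#'
#' @param path TSV path.
#' @return Data frame suitable for [ddct_fold_change()].
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  bad <- !is.finite(tab$ct) | tab$ct <= 0
  if (any(bad))
    stop(sprintf("%s: invalid value at line %d (column ct)",
                 basename(path), which(bad)[1] + 1L))
  tab
}

#' Read manually annotated profiles for stereology re-analysis
#'
#' TSV with columns `fov_id`, `object_type` (`fiber` or `capillary`) and
#' either `wkt` (a `POLYGON ((x y, x y, ...))` string, for fibers) or `x`,
#' `y` point coordinates (for capillaries).
#'
#' @param path TSV path.
#' @return Named list (one element per fov_id) with `fibers` (list of
#'   polygon matrices) and `capillaries` (n x 2 matrix).
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("fov_id", "object_type")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  bad <- !tab$object_type %in% c("fiber", "capillary")
  if (any(bad))
    stop(sprintf("%s: invalid value at line %d (column object_type)",
                 basename(path), which(bad)[1] + 1L))
  parse_wkt_polygon <- function(s, line) {
    m <- regmatches(s, regexec("^\\s*POLYGON\\s*\\(\\((.*)\\)\\)\\s*$", s))[[1]]
    if (length(m) < 2)
      stop(sprintf("%s: invalid value at line %d (column wkt)",
                   basename(path), line))
    xy <- do.call(rbind, lapply(strsplit(m[2], ",")[[1]], function(p) {
      as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    }))
    # WKT rings repeat the first vertex; drop the closing copy
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    xy
  }
  out <- lapply(split(seq_len(nrow(tab)), tab$fov_id), function(idx) {
    fibers <- lapply(idx[tab$object_type[idx] == "fiber"], function(i)
      parse_wkt_polygon(tab$wkt[i], i + 1L))
    ci <- idx[tab$object_type[idx] == "capillary"]
    caps <- if (length(ci) > 0) cbind(tab$x[ci], tab$y[ci])
    else matrix(numeric(0), 0, 2)
    if (any(!is.finite(caps)))
      stop(sprintf("%s: invalid value at line %d (column x/y)",
                   basename(path), ci[which(!is.finite(rowSums(caps)))[1]] + 1L))
    list(fibers = fibers, capillaries = caps)
  })
  out
}

#' Write a results report as JSON
#'
#' @param results Any list of result tables/values.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
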