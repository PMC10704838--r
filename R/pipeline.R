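# End-to-end orchestration: simulate -> stereology -> ultrastructure ->
# histology -> statistics -> report, with a reproducibility manifest.

#' Assemble a pipeline run configuration
#'
#' @param seed Global integer seed; every stage derives a substream from it.
#' @param cohort A [cohort_spec()] (its own seed is overridden by `seed`).
#' @param n_fov Fields of view per sample for stereology.
#' @param fov_size Field width/height in um.
#' @param max_aspect Obliqueness exclusion cutoff.
#' @param outlier_nm CBM display-outlier threshold, nm.
#' @param pericyte_margin_deg Angular margin around pericyte arcs, degrees.
#' @param large_vessel_nm Large-microvessel lumen-radius cutoff, nm.
#' @param max_pericyte_coverage_pct Pericyte-coverage exclusion cutoff.
#' @param alpha Significance level for the statistics stage.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_spec(seed = seed),
                       n_fov = 10,
                       fov_size = c(450, 450),
                       max_aspect = 1.2,
                       outlier_nm = 350,
                       pericyte_margin_deg = 5,
                       large_vessel_nm = 5000,
                       max_pericyte_coverage_pct = 80,
                       alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, max_aspect >= 1, outlier_nm > 0,
            n_fov >= 1, all(fov_size > 0))
  cohort$seed <- as.integer(seed)
  structure(list(
    seed = as.integer(seed), cohort = cohort, n_fov = n_fov,
    fov_size = fov_size, max_aspect = max_aspect, outlier_nm = outlier_nm,
    pericyte_margin_deg = pericyte_margin_deg,
    large_vessel_nm = large_vessel_nm,
    max_pericyte_coverage_pct = max_pericyte_coverage_pct,
    alpha = alpha
  ), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, stereology, ultrastructure, histology and statistics
#' in sequence and (optionally) writes per-stage TSVs, a combined per-sample
#' table, a JSON report and a manifest with file checksums. All stages are
#' pure functions of (config, seed); re-running with the same configuration
#' reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List with `per_sample` (combined table), `stats` (per-variable
#'   ANOVA + Tukey), `cbm` (pooled CBM aggregation), `exclusions`
#'   (exclusion log), and `manifest` (when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort)

  per_sample <- list()
  cbm_sets <- list(); cbm_sample_ids <- character(0)
  exclusions <- list()

  for (sid in names(cohort$samples)) {
    smp <- cohort$samples[[sid]]

    st <- stereology_sample(smp$scene, n_fov = config$n_fov,
                            fov_size = config$fov_size,
                            seed = substream_seed(config$seed, paste0("fov:", sid)))

    flt <- filter_profiles(smp$profiles, max_aspect = config$max_aspect,
                           large_vessel_nm = config$large_vessel_nm,
                           max_pericyte_coverage_pct = config$max_pericyte_coverage_pct)
    if (any(!flt$log$included)) {
      ex <- flt$log[!flt$log$included, c("capillary_id", "reason")]
      ex$stage <- "ultrastructure"
      exclusions[[sid]] <- ex
    }
    sets <- lapply(flt$included, function(p)
      measure_cbm(p, margin_deg = config$pericyte_margin_deg,
                  seed = substream_seed(config$seed, paste0("cbm:", p$capillary_id))))
    cbm_sets <- c(cbm_sets, sets)
    cbm_sample_ids <- c(cbm_sample_ids, rep(sid, length(sets)))

    morph <- flt$morphometry

    ftab <- scene_fiber_table(smp$scene)
    comp <- fiber_type_composition(ftab)
    atrophy <- if (any(ftab$fiber_type == "2b"))
      score_type2b_atrophy(ftab) else NA_integer_
    mhc <- score_mhc1(ftab)
    cells <- count_cells_per_10hpf(smp$cell_fields)

    row <- data.frame(
      sample_id = sid, group = smp$group,
      cf_ratio = st$sample$cf_ratio,
      mcsfa_um2 = st$sample$mcsfa,
      cap_density_per_mm2 = st$sample$capillary_density,
      cbm_mean_nm = if (length(sets) > 0)
        mean(vapply(sets, `[[`, numeric(1), "capillary_mean")) else NA_real_,
      n_tem_included = length(flt$included),
      n_tem_excluded = sum(!flt$log$included),
      ec_thickness_nm = mean(vapply(morph, `[[`, numeric(1), "ec_thickness")),
      lumen_radius_nm = mean(vapply(morph, `[[`, numeric(1), "lumen_radius")),
      pericyte_coverage_pct = mean(vapply(morph, `[[`, numeric(1), "pericyte_coverage")),
      atrophy_score = atrophy,
      mhc1_score = mhc$score,
      pct_type1 = comp$pct[["1"]],
      pct_type2a = comp$pct[["2a"]],
      pct_type2b = comp$pct[["2b"]],
      stringsAsFactors = FALSE
    )
    for (mk in cells$marker)
      row[[paste0("cells_", mk, "_per_10hpf")]] <-
        cells$total_per_10hpf[cells$marker == mk]
    per_sample[[sid]] <- row
  }

  per_sample <- do.call(rbind, c(per_sample, list(make.row.names = FALSE)))
  cbm <- aggregate_cbm(cbm_sets, cbm_sample_ids, outlier_nm = config$outlier_nm)

  vars <- c("cf_ratio", "mcsfa_um2", "cap_density_per_mm2", "cbm_mean_nm",
            grep("^cells_", names(per_sample), value = TRUE))
  stats_out <- lapply(vars, function(v) {
    vals <- split(per_sample[[v]], per_sample$group)
    vals <- vals[vapply(vals, function(x) sum(!is.na(x)) >= 2, logical(1))]
    anova_tukey(lapply(vals, stats::na.omit))
  })
  names(stats_out) <- vars

  exclusions <- if (length(exclusions) > 0)
    do.call(rbind, c(exclusions, list(make.row.names = FALSE)))
  else data.frame(capillary_id = character(0), reason = character(0),
                  stage = character(0))

  out <- list(per_sample = per_sample, stats = stats_out, cbm = cbm,
              exclusions = exclusions, truth = cohort$truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      per_sample = write_tsv(per_sample, file.path(out_dir, "per_sample.tsv")),
      cbm_measurements = write_tsv(cbm$measurements,
                                   file.path(out_dir, "cbm_measurements.tsv")),
      exclusions = write_tsv(out$exclusions, file.path(out_dir, "exclusions.tsv")),
      truth = write_tsv(cohort$truth, file.path(out_dir, "ground_truth.tsv")),
      report = write_report(report_list(stats_out),
                            file.path(out_dir, "report.json"))
    )
    manifest <- data.frame(
      file = basename(unlist(files)),
      md5 = unname(tools::md5sum(unlist(files))),
      stringsAsFactors = FALSE
    )
    manifest_path <- file.path(out_dir, "manifest.tsv")
    write_tsv(cbind(seed = config$seed, manifest), manifest_path)
    out$manifest <- manifest
  }
  out
}

report_list <- function(stats_out) {
  lapply(stats_out, function(s) list(
    F = s$F, p_omnibus = s$p_omnibus,
    pairs = s$tukey$pairs
  ))
}
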