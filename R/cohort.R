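#' Specify a synthetic study cohort
#'
#' Bundles the ground-truth parameters of a simulated three-group biopsy
#' study: per-group capillary-to-fiber ratios, mean cross-sectional fiber
#' areas, capillary basement membrane (CBM) thickness distributions,
#' immune-cell densities and the per-sample number of TEM capillary profiles.
#' Defaults emulate a case-control design with a healthy disease control
#' group (HDC, n = 8), a selective type-2b-atrophy control group (2BA,
#' n = 8) and a patient group (PCS, n = 11).
#'
#' Between-sample, between-capillary and within-capillary dispersions are
#' part of the ground truth: the CBM thickness of a single site is drawn
#' around its capillary's mean, which is drawn around its sample's mean,
#' which is drawn around the group mean.
#'
#' @param group_names Character vector of group labels.
#' @param group_sizes Integer vector, samples per group (each >= 2).
#' @param cf_true Per-group true capillary-to-fiber ratio (dimensionless).
#' @param cf_sample_sd Between-sample SD of the true C/F ratio.
#' @param mcsfa_true Per-group mean cross-sectional fiber area, um^2,
#'   before type-2b atrophy scaling.
#' @param type2b_atrophy_factor Per-group area multiplier in (0, 1] applied
#'   to atrophic type-2b fibers.
#' @param type2b_atrophy_fraction Per-group fraction of type-2b fibers that
#'   are atrophic.
#' @param fiber_type_props Proportions of fiber types 1 / 2a / 2b (sum 1).
#' @param cbm_mean,cbm_sd Per-group CBM thickness mean (nm) and the
#'   within-capillary site-to-site SD (nm).
#' @param cbm_sample_sd Between-sample SD of the sample-level CBM mean (nm).
#' @param cbm_capillary_sd Between-capillary SD within a sample (nm).
#' @param cells_per_10hpf_mean Numeric matrix (marker x group) of expected
#'   immune-cell counts per 10 high-power fields.
#' @param cells_per_10hpf_sd Matrix like `cells_per_10hpf_mean`: SD of the
#'   per-sample totals (negative-binomial overdispersion via gamma mixing).
#' @param capillaries_per_sample_range Integer interval, TEM capillary
#'   profiles photographed per sample (within [1, 100]).
#' @param scene_fibers Approximate number of fibers per tissue scene.
#' @param seed Integer RNG seed; all randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$group_sizes
cohort_spec <- function(group_names = c("HDC", "2BA", "PCS"),
                        group_sizes = c(8L, 8L, 11L),
                        cf_true = c(1.82, 1.80, 1.50),
                        cf_sample_sd = 0.12,
                        mcsfa_true = c(4400, 5000, 3500),
                        type2b_atrophy_factor = c(1, 0.45, 0.55),
                        type2b_atrophy_fraction = c(0, 0.75, 0.5),
                        fiber_type_props = c(`1` = 0.40, `2a` = 0.35, `2b` = 0.25),
                        cbm_mean = c(300, 301.5, 340),
                        cbm_sd = 30,
                        cbm_sample_sd = 15,
                        cbm_capillary_sd = 40,
                        cells_per_10hpf_mean = default_cell_means(),
                        cells_per_10hpf_sd = default_cell_sds(),
                        capillaries_per_sample_range = c(20L, 30L),
                        scene_fibers = 780L,
                        seed = 1L) {
  k <- length(group_names)
  rep_k <- function(x) if (length(x) == 1) rep(x, k) else x
  cf_true <- rep_k(cf_true); mcsfa_true <- rep_k(mcsfa_true)
  cbm_mean <- rep_k(cbm_mean)
  type2b_atrophy_factor <- rep_k(type2b_atrophy_factor)
  type2b_atrophy_fraction <- rep_k(type2b_atrophy_fraction)

  stopifnot(
    length(group_sizes) == k, length(cf_true) == k,
    length(mcsfa_true) == k, length(cbm_mean) == k
  )
  if (any(group_sizes < 2)) stop("all group sizes must be >= 2")
  if (abs(sum(fiber_type_props) - 1) > 1e-9)
    stop("fiber_type_props must sum to 1 (within 1e-9)")
  if (any(cbm_mean <= 0)) stop("cbm_mean must be > 0")
  if (cbm_sd < 0) stop("cbm_sd must be >= 0")
  if (any(type2b_atrophy_factor <= 0 | type2b_atrophy_factor > 1))
    stop("type2b_atrophy_factor must be in (0, 1]")
  r <- capillaries_per_sample_range
  if (length(r) != 2 || r[1] > r[2] || r[1] < 1 || r[2] > 100)
    stop("capillaries_per_sample_range must be an interval within [1, 100]")
  if (!is.matrix(cells_per_10hpf_mean) || ncol(cells_per_10hpf_mean) != k)
    stop("cells_per_10hpf_mean must be a marker x group matrix")

  structure(list(
    group_names = group_names,
    group_sizes = as.integer(group_sizes),
    cf_true = cf_true,
    cf_sample_sd = cf_sample_sd,
    mcsfa_true = mcsfa_true,
    type2b_atrophy_factor = type2b_atrophy_factor,
    type2b_atrophy_fraction = type2b_atrophy_fraction,
    fiber_type_props = fiber_type_props,
    cbm_mean = cbm_mean,
    cbm_sd = cbm_sd,
    cbm_sample_sd = cbm_sample_sd,
    cbm_capillary_sd = cbm_capillary_sd,
    cells_per_10hpf_mean = cells_per_10hpf_mean,
    cells_per_10hpf_sd = cells_per_10hpf_sd,
    capillaries_per_sample_range = as.integer(r),
    scene_fibers = as.integer(scene_fibers),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Expected immune-cell totals per 10 high-power fields (marker x group).
# CD68 and CD169 means/SDs follow the published group summaries; the
# non-significant markers (CD206, CD45, CD8) are given comparable means.
default_cell_means <- function() {
  m <- rbind(
    CD68  = c(32, 34, 58),
    CD169 = c(17, 22, 41),
    CD206 = c(12, 13, 15),
    CD45  = c(25, 26, 29),
    CD8   = c(8, 9, 11)
  )
  colnames(m) <- c("HDC", "2BA", "PCS")
  m
}

default_cell_sds <- function() {
  m <- rbind(
    CD68  = c(12, 15, 16),
    CD169 = c(10, 11, 13),
    CD206 = c(5, 5, 6),
    CD45  = c(9, 9, 10),
    CD8   = c(4, 4, 5)
  )
  colnames(m) <- c("HDC", "2BA", "PCS")
  m
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  groups: ", paste0(x$group_names, " (n=", x$group_sizes, ")", collapse = ", "), "\n")
  cat("  true C/F: ", paste(format(x$cf_true), collapse = " / "), "\n")
  cat("  true MCSFA (um^2): ", paste(format(x$mcsfa_true), collapse = " / "), "\n")
  cat("  true CBM mean (nm): ", paste(format(x$cbm_mean), collapse = " / "), "\n")
  cat("  TEM capillaries/sample: ", paste(x$capillaries_per_sample_range, collapse = "-"), "\n")
  cat("  seed: ", x$seed, "\n")
  invisible(x)
}
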