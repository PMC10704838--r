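# Immune-cell quantification per 10 high-power fields and semiquantitative
# histopathology rubrics (type-2b fiber atrophy, MHC class I, fiber typing).

#' Total immune cells per 10 high-power fields
#'
#' @param markers Named list: marker -> integer vector of exactly 10
#'   per-field counts.
#' @return Data frame (one row per marker): marker, total_per_10hpf and the
#'   per-field counts as a list column `per_field_counts`.
#' @export
count_cells_per_10hpf <- function(markers) {
  stopifnot(is.list(markers), length(markers) > 0, !is.null(names(markers)))
  rows <- lapply(names(markers), function(mk) {
    ct <- markers[[mk]]
    if (length(ct) != 10)
      stop(sprintf("marker '%s': expected exactly 10 field counts, got %d",
                   mk, length(ct)))
    if (any(ct < 0)) stop(sprintf("marker '%s': negative field count", mk))
    data.frame(marker = mk, total_per_10hpf = sum(ct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$per_field_counts <- unname(markers)
  out
}

#' Semiquantitative type-2b fiber atrophy score (0-3)
#'
#' Rubric: 0 = no atrophic 2b fibers; 1 = atrophy of < 15% of 2b fibers;
#' 2 = atrophy of 15-60% of 2b fibers (boundaries included); 3 = atrophy of
#' > 60% of 2b fibers *and* many fibers < `small_diameter_cutoff` um in
#' minimal diameter ("many" operationalized as a fraction of 2b fibers
#' exceeding `many_small_fraction`). An atrophic fraction > 60% without the
#' small-fiber criterion stays at grade 2.
#'
#' @param fibers Fiber table (data frame) with columns `fiber_type`,
#'   `min_diameter_um` and logical `atrophic`.
#' @param small_diameter_cutoff Diameter cutoff, um (default 20).
#' @param many_small_fraction Fraction of 2b fibers under the cutoff
#'   required for grade 3 (default 0.30).
#' @return Integer score 0-3.
#' @export
score_type2b_atrophy <- function(fibers, small_diameter_cutoff = 20,
                                 many_small_fraction = 0.30) {
  f2b <- fibers[fibers$fiber_type == "2b", , drop = FALSE]
  if (nrow(f2b) == 0) stop("atrophy score undefined: no type-2b fibers")
  f <- mean(f2b$atrophic)
  if (f == 0) return(0L)
  if (f < 0.15) return(1L)
  if (f <= 0.60) return(2L)
  small <- mean(f2b$min_diameter_um < small_diameter_cutoff)
  if (small > many_small_fraction) 3L else 2L
}

#' Semiquantitative MHC class I upregulation score
#'
#' Fraction of fibers with sarcolemmal MHC-class-I upregulation. Single
#' positive fibers (fraction below `significant_fraction`) are within the
#' normal range (score 1, not significant); upregulation in at least
#' `significant_fraction` of fibers is scored 2 and flagged significant.
#'
#' @param fibers Fiber table with logical column `mhc1_sarcolemmal`.
#' @param significant_fraction Significance threshold (default 0.20).
#' @return List with `score` (0/1/2), `significant` (logical), `fraction`.
#' @export
score_mhc1 <- function(fibers, significant_fraction = 0.20) {
  if (nrow(fibers) == 0) stop("MHC-I score undefined: empty fiber table")
  frac <- mean(fibers$mhc1_sarcolemmal)
  significant <- frac >= significant_fraction
  score <- if (frac == 0) 0L else if (significant) 2L else 1L
  list(score = score, significant = significant, fraction = frac)
}

#' Fiber type composition
#'
#' @param fibers Fiber table with column `fiber_type` in {"1", "2a", "2b"}.
#' @return Named list: `pct` (percentages for 1 / 2a / 2b, summing to 100)
#'   and `pct_type2_pooled` (2a + 2b).
#' @export
fiber_type_composition <- function(fibers) {
  if (nrow(fibers) == 0) stop("composition undefined: empty fiber table")
  lv <- c("1", "2a", "2b")
  tab <- table(factor(fibers$fiber_type, levels = lv))
  pct <- 100 * as.numeric(tab) / nrow(fibers)
  names(pct) <- lv
  list(pct = pct, pct_type2_pooled = pct[["2a"]] + pct[["2b"]])
}

#' Derive per-fiber atrophy flags from areas
#'
#' In re-analysis mode "atrophic" is an input flag; when absent it can be
#' derived as area below `factor` times the median area of same-type fibers.
#'
#' @param fibers Fiber table with `fiber_type` and `area_um2`.
#' @param factor Multiplier of the same-type median (default 0.5).
#' @return Logical vector, one element per fiber.
#' @export
derive_atrophic <- function(fibers, factor = 0.5) {
  med <- stats::ave(fibers$area_um2, fibers$fiber_type, FUN = stats::median)
  fibers$area_um2 < factor * med
}

# Convert a tissue scene's fiber list to the tabular fiber format.
scene_fiber_table <- function(scene, mhc1_positive_fraction = 0, seed = 1L) {
  fib <- scene$fibers
  tab <- data.frame(
    fiber_id = vapply(fib, `[[`, character(1), "fiber_id"),
    fiber_type = vapply(fib, `[[`, character(1), "fiber_type"),
    area_um2 = vapply(fib, `[[`, numeric(1), "area"),
    min_diameter_um = vapply(fib, `[[`, numeric(1), "min_diameter"),
    atrophic = vapply(fib, `[[`, logical(1), "atrophic"),
    stringsAsFactors = FALSE
  )
  tab$mhc1_sarcolemmal <- if (mhc1_positive_fraction > 0) {
    with_seed(seed, stats::runif(nrow(tab)) < mhc1_positive_fraction)
  } else rep(FALSE, nrow(tab))
  tab
}
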