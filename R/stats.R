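# Group statistics: one-way ANOVA with the Tukey-Kramer all-pairs test
# (from raw values or from printed summary statistics), Pearson correlation,
# and delta-delta-Ct fold changes.

#' Tukey-Kramer comparisons from group summary statistics
#'
#' Reconstructs the one-way ANOVA error term from per-group means, SDs and
#' sizes: `MSE = sum((n_i - 1) s_i^2) / sum(n_i - 1)` with
#' `df_error = sum(n_i - 1)`. For each pair the Tukey-Kramer standard error
#' is `sqrt(MSE / 2 * (1/n_i + 1/n_j))` (valid for unequal group sizes),
#' the studentized-range statistic is `q = |mean_i - mean_j| / SE`, and the
#' adjusted p-value comes from the studentized-range distribution with `k`
#' groups and `df_error` degrees of freedom. This lets published group
#' summaries be re-tested without the raw data; note that summaries printed
#' with rounding reproduce the original p-values only approximately.
#'
#' @param groups Data frame with columns `group`, `mean`, `sd`, `n`
#'   (each n >= 2).
#' @return A `tukey_result`: data frame `pairs` (group_i, group_j,
#'   mean_difference, standard_error, q_statistic, p_adjusted) with
#'   attributes `mse`, `df_error`, `k_groups`.
#' @export
#' @examples
#' cd68 <- data.frame(group = c("HDC", "2BA", "PCS"),
#'                    mean = c(32, 34, 58), sd = c(12, 15, 16), n = c(8, 8, 11))
#' tukey_from_summary(cd68)
tukey_from_summary <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("group", "mean", "sd", "n") %in% names(groups)))
  k <- nrow(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(groups$n < 2)) stop("every group needs n >= 2")
  if (any(groups$sd < 0)) stop("negative SD")

  df_error <- as.integer(sum(groups$n - 1))
  mse <- sum((groups$n - 1) * groups$sd^2) / df_error

  idx <- utils::combn(k, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(idx)), function(c0) {
    i <- idx[1, c0]; j <- idx[2, c0]
    diff <- groups$mean[i] - groups$mean[j]
    se <- sqrt(mse / 2 * (1 / groups$n[i] + 1 / groups$n[j]))
    if (se == 0) {
      if (abs(diff) > 0) {
        warning("zero pooled variance with a nonzero mean difference; p set to 0")
        p <- 0; q <- Inf
      } else {
        p <- 1; q <- 0
      }
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
    }
    data.frame(group_i = groups$group[i], group_j = groups$group[j],
               mean_difference = diff, standard_error = se,
               q_statistic = q, p_adjusted = p, stringsAsFactors = FALSE)
  }))
  structure(list(pairs = pairs, mse = mse, df_error = df_error, k_groups = k),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons (k = %d, MSE = %.4g, df = %d)\n",
              x$k_groups, x$mse, x$df_error))
  df <- x$pairs
  df$p_adjusted <- format_pvalue(df$p_adjusted)
  print(df, row.names = FALSE)
  invisible(x)
}

# Report-layer p formatting: one significant figure below 0.001, three
# decimals otherwise; full precision is kept in the result objects.
format_pvalue <- function(p) {
  ifelse(p < 0.001, signif(p, 1), round(p, 3))
}

#' One-way ANOVA with Tukey-Kramer comparisons from raw values
#'
#' The omnibus F comes from the standard one-way decomposition; the pairwise
#' comparisons equal [tukey_from_summary()] applied to the groups' computed
#' means, SDs and sizes (asserted internally).
#'
#' @param values Named list: group -> numeric vector (each length >= 2).
#' @return List with `F`, `p_omnibus`, `df` (c(k - 1, df_error)) and
#'   `tukey` (a `tukey_result`).
#' @export
anova_tukey <- function(values) {
  stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)))
  n <- vapply(values, length, integer(1))
  if (any(n < 2)) stop("every group needs n >= 2")
  summ <- data.frame(
    group = names(values),
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, stats::sd, numeric(1)),
    n = n, stringsAsFactors = FALSE
  )
  tk <- tukey_from_summary(summ)

  grand <- sum(summ$n * summ$mean) / sum(summ$n)
  ssb <- sum(summ$n * (summ$mean - grand)^2)
  k <- nrow(summ)
  df1 <- k - 1
  df2 <- tk$df_error
  msb <- ssb / df1
  if (tk$mse == 0) {
    if (msb > 0) {
      warning("zero within-group variance with differing means; omnibus p set to 0")
      Fstat <- Inf; p <- 0
    } else {
      Fstat <- NaN; p <- 1
    }
  } else {
    Fstat <- msb / tk$mse
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(F = Fstat, p_omnibus = p, df = c(df1, df2), tukey = tk)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and the two-sided `p` (t transform, n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Delta-delta-Ct relative expression
#'
#' Triplicate Ct values are averaged per sample and gene after dropping
#' cycles above `max_ct` (values above 40 cycles are "not expressed"). Per
#' sample, `dCt = Ct_target - Ct_reference`; `ddCt` is the mean dCt of the
#' case group minus the mean dCt of the control group, and the fold change
#' is `2^-ddCt`.
#'
#' @param ct_table Data frame: `sample_id`, `group`, `gene`, `replicate`,
#'   `ct`.
#' @param case_group,control_group Group labels.
#' @param reference_gene Reference (housekeeping) gene, e.g. "GAPDH".
#' @param max_ct Expression cutoff in cycles (default 40).
#' @return Data frame, one row per target gene: `gene`, `delta_delta_ct`,
#'   `fold_change`, `expressed` (FALSE when all case- and control-group
#'   triplicates exceeded the cutoff).
#' @export
ddct_fold_change <- function(ct_table, case_group, control_group,
                             reference_gene = "GAPDH", max_ct = 40) {
  need <- c("sample_id", "group", "gene", "ct")
  stopifnot(all(need %in% names(ct_table)))
  ct_table <- ct_table[ct_table$group %in% c(case_group, control_group), ]
  if (!reference_gene %in% ct_table$gene)
    stop(sprintf("reference gene '%s' absent from the Ct table", reference_gene))

  mean_ct <- function(v) {
    keep <- v <= max_ct
    if (!any(keep)) return(NA_real_)
    mean(v[keep])
  }
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct_table,
                          FUN = mean_ct)
  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  if (any(is.na(ref$ct_ref)))
    stop(sprintf("reference gene '%s' not expressed (all replicates > %g cycles) in sample(s): %s",
                 reference_gene, max_ct,
                 paste(ref$sample_id[is.na(ref$ct_ref)], collapse = ", ")))

  targets <- setdiff(unique(agg$gene), reference_gene)
  rows <- lapply(targets, function(g) {
    d <- merge(agg[agg$gene == g, ], ref, by = "sample_id")
    d$delta_ct <- d$ct - d$ct_ref
    dc_case <- d$delta_ct[d$group == case_group]
    dc_ctrl <- d$delta_ct[d$group == control_group]
    expressed <- any(!is.na(dc_case)) && any(!is.na(dc_ctrl))
    if (!expressed) {
      return(data.frame(gene = g, delta_delta_ct = NA_real_,
                        fold_change = NA_real_, expressed = FALSE,
                        stringsAsFactors = FALSE))
    }
    ddct <- mean(dc_case, na.rm = TRUE) - mean(dc_ctrl, na.rm = TRUE)
    data.frame(gene = g, delta_delta_ct = ddct, fold_change = 2^(-ddct),
               expressed = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
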