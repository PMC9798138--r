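#' Normalize an abundance matrix
#'
#' The three normalization conventions used across MS acquisition types:
#' * `tmt_median_mean` — subtract each column's median, then each row's
#'   mean (log-scale data), damping batch variation across channels;
#' * `ratio_to_control` — express every column relative to a control
#'   column (division, or subtraction when `log = TRUE`);
#' * `phospho_over_proteome` — divide each phosphosite row by its
#'   protein's matched proteome row (row names matched; subtraction when
#'   `log = TRUE`).
#'
#' @param x sites x samples numeric matrix.
#' @param mode normalization mode.
#' @param control control column name or index (ratio mode).
#' @param proteome proteome matrix with rows matching `rownames(x)`
#'   (proteome mode).
#' @param log logical; data are log-scale, so ratios become differences.
#' @return The normalized matrix.
#' @export
normalize_matrix <- function(x, mode = c("tmt_median_mean",
                                         "ratio_to_control",
                                         "phospho_over_proteome"),
                             control = NULL, proteome = NULL, log = FALSE) {
  mode <- match.arg(mode)
  switch(mode,
    tmt_median_mean = {
      x <- sweep(x, 2, apply(x, 2, median, na.rm = TRUE))
      sweep(x, 1, rowMeans(x, na.rm = TRUE))
    },
    ratio_to_control = {
      if (is.null(control)) stop("ratio_to_control needs a control column")
      if (is.character(control) && !control %in% colnames(x)) {
        stop("control column not found")
      }
      ctrl <- x[, control]
      if (log) x - ctrl else x / ctrl
    },
    phospho_over_proteome = {
      if (is.null(proteome)) stop("phospho_over_proteome needs a proteome matrix")
      idx <- match(rownames(x), rownames(proteome))
      if (anyNA(idx)) stop("proteome rows missing for some phosphosites")
      prot <- proteome[idx, colnames(x), drop = FALSE]
      if (!log && any(prot == 0, na.rm = TRUE)) {
        stop("proteome rows contain zeros; cannot form ratios")
      }
      if (log) x - prot else x / prot
    })
}

filter_report <- function(rule_name, sites_in, sites_kept, thresholds) {
  tibble::tibble(rule_name = rule_name, sites_in = sites_in,
                 sites_kept = sites_kept,
                 thresholds = list(thresholds))
}

average_replicates <- function(x, replicate_groups) {
  groups <- split(seq_len(ncol(x)), replicate_groups)
  out <- vapply(groups, function(j) rowMeans(x[, j, drop = FALSE], na.rm = TRUE),
                numeric(nrow(x)))
  colnames(out) <- names(groups)
  out
}

#' Keep actively regulated phosphosites in a time-series matrix
#'
#' Sites pass when some timepoint shows `|log2FC|` strictly above
#' `fc_threshold` and, when per-site adjusted p-values are supplied, the
#' adjusted p-value is below `p_threshold`. Replicate columns (same
#' timepoint label in `replicate_groups`) are averaged first. Spline-based
#' differential-expression fitting is delegated upstream: this filter
#' consumes its adjusted p-values.
#'
#' @param x sites x samples matrix of log2 ratios to the baseline
#'   timepoint.
#' @param pvalues optional named numeric vector of per-site adjusted
#'   p-values.
#' @param fc_threshold log2 fold-change threshold, strict (default 2).
#' @param p_threshold adjusted p-value threshold (default 0.05).
#' @param replicate_groups optional vector assigning columns to
#'   timepoints for replicate averaging.
#' @return List: `values` (filtered matrix) and `report` (a one-row
#'   filter-report tibble).
#' @export
filter_timeseries <- function(x, pvalues = NULL, fc_threshold = 2,
                              p_threshold = 0.05, replicate_groups = NULL) {
  if (!is.null(replicate_groups)) x <- average_replicates(x, replicate_groups)
  keep <- apply(abs(x), 1, max, na.rm = TRUE) > fc_threshold
  if (!is.null(pvalues)) {
    p <- pvalues[rownames(x)]
    keep <- keep & !is.na(p) & p < p_threshold
  }
  if (!any(keep)) warning("no phosphosite passes the regulation filter")
  list(values = x[keep, , drop = FALSE],
       report = filter_report("timeseries_regulation", nrow(x), sum(keep),
                              list(fc = fc_threshold,
                                   p = if (is.null(pvalues)) NA else p_threshold)))
}

#' Keep regulated phosphosites in a perturbation panel
#'
#' A site passes when at least `p_frac` of its conditions have p-values
#' below `p_threshold` and at least `min_fc_conditions` conditions exceed
#' the fold-change threshold (both thresholds inclusive on the counts,
#' strict on the fold change).
#'
#' @param x sites x conditions matrix of log2 ratios to control.
#' @param pvalues matrix of per-site per-condition p-values, same shape
#'   as `x`.
#' @param p_threshold p-value threshold (default 0.05).
#' @param p_frac minimum fraction of significant conditions (default 0.2).
#' @param fc_threshold log2 fold-change threshold, strict (default 2).
#' @param min_fc_conditions minimum conditions beyond the fold-change
#'   threshold (default 2).
#' @return List: `values` and `report`, as [filter_timeseries()].
#' @export
filter_perturbation <- function(x, pvalues, p_threshold = 0.05, p_frac = 0.2,
                                fc_threshold = 2, min_fc_conditions = 2) {
  if (!identical(dim(x), dim(pvalues))) {
    stop("p-value table shape does not match the data matrix")
  }
  frac_sig <- rowMeans(pvalues < p_threshold, na.rm = TRUE)
  n_fc <- rowSums(abs(x) > fc_threshold, na.rm = TRUE)
  keep <- frac_sig >= p_frac & n_fc >= min_fc_conditions
  if (!any(keep)) warning("no phosphosite passes the regulation filter")
  list(values = x[keep, , drop = FALSE],
       report = filter_report("perturbation_regulation", nrow(x), sum(keep),
                              list(p = p_threshold, p_frac = p_frac,
                                   fc = fc_threshold,
                                   min_fc_conditions = min_fc_conditions)))
}
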