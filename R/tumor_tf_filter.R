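#' Across-cell-type variability of TF activity
#'
#' Averages the bias-corrected deviation score of every motif within each
#' cell type and returns the population standard deviation of those group
#' means across cell types — the variability statistic the tumor-specific TF
#' filter thresholds.
#'
#' @param dev a `deviation_matrix` from [compute_deviations()].
#' @param labels cell group labels.
#' @return data.frame: `motif`, one `mean_<group>` column per group, and
#'   `sd_across_groups`.
#' @export
tf_variability <- function(dev, labels) {
  mat <- dev$deviations
  stopifnot(length(labels) == nrow(mat))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) .stopf("variability needs at least two groups")
  gm <- t(vapply(colnames(mat), function(m) {
    vapply(groups, function(g) mean(mat[labels == g, m], na.rm = TRUE), numeric(1))
  }, numeric(length(groups))))
  colnames(gm) <- paste0("mean_", groups)
  pop_sd <- apply(gm, 1, function(x) sqrt(mean((x - mean(x))^2)))
  out <- data.frame(motif = colnames(mat), gm, sd_across_groups = pop_sd,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- groups
  out
}

#' Upper double-MAD outlier threshold
#'
#' The double-MAD scheme computes the median absolute deviation separately on
#' each side of the median so that asymmetric distributions are thresholded
#' on the relevant tail. Here the upper side is used: with
#' `m = median(values)` and `right-MAD = median(|x - m|)` over the points
#' `x >= m`, the threshold is `m + multiplier * right-MAD`. No
#' normal-consistency constant (1.4826) is applied: the rule is stated
#' directly as median plus a multiple of the MAD.
#'
#' @param values numeric vector (non-empty).
#' @param multiplier MAD multiplier (default 4).
#' @return the threshold, a single number.
#' @export
double_mad_threshold <- function(values, multiplier = 4) {
  values <- values[!is.na(values)]
  if (length(values) == 0) .stopf("values must be non-empty")
  m <- median(values)
  right_mad <- median(abs(values[values >= m] - m))
  m + multiplier * right_mad
}

#' Select cell-type-specific transcription factors
#'
#' Applies the three-gate filtering strategy for TFs restricted to one cell
#' type (the tumor population in the motivating analysis):
#' 1. variability gate — the motif's across-type SD of mean deviation scores
#'    exceeds the upper double-MAD threshold computed over ALL motifs' SDs;
#' 2. in-group gate — `activity_delta > fc_in` with `p_adj < alpha` in the
#'    target group;
#' 3. out-group gate — `activity_delta < fc_out_max` in every other group.
#'
#' @param diff output of [differential_tf_activity()] covering all groups.
#' @param variab output of [tf_variability()] covering all motifs.
#' @param target_group the group the TFs must be specific to.
#' @param fc_in,fc_out_max,alpha gate values (defaults 4, 1, 1e-4).
#' @param mad_multiplier passed to [double_mad_threshold()].
#' @return character vector of selected motif ids; attribute `table` holds
#'   the full per-motif gate audit (sd, threshold, deltas, p_adj, pass
#'   flags).
#' @export
select_specific_tfs <- function(diff, variab, target_group, fc_in = 4,
                                fc_out_max = 1, alpha = 1e-4,
                                mad_multiplier = 4) {
  if (!target_group %in% diff$group)
    .stopf("target group '%s' absent from the differential table", target_group)
  thr <- double_mad_threshold(variab$sd_across_groups, mad_multiplier)
  motifs <- variab$motif
  d_in <- diff[diff$group == target_group, ]
  delta_in <- setNames(d_in$activity_delta, d_in$motif)[motifs]
  padj_in <- setNames(d_in$p_adj, d_in$motif)[motifs]
  d_out <- diff[diff$group != target_group, ]
  max_out <- vapply(motifs, function(m) {
    v <- d_out$activity_delta[d_out$motif == m]
    if (length(v) == 0) -Inf else max(v)
  }, numeric(1))
  tab <- data.frame(
    motif = motifs,
    sd_across_groups = variab$sd_across_groups,
    sd_threshold = thr,
    delta_in = unname(delta_in),
    p_adj_in = unname(padj_in),
    max_delta_out = unname(max_out),
    pass_variability = variab$sd_across_groups > thr,
    pass_in = !is.na(delta_in) & delta_in > fc_in & !is.na(padj_in) & padj_in < alpha,
    pass_out = max_out < fc_out_max,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$selected <- tab$pass_variability & tab$pass_in & tab$pass_out
  structure(tab$motif[tab$selected], table = tab)
}

#' Screen perturbation profiles for drugs down-regulating a TF
#'
#' Returns the approved drugs whose differential-expression Z-score for the
#' TF gene is below `z_cut` (strictly), sorted by ascending Z (strongest
#' down-regulation first).
#'
#' @param z drugs x genes Z-score matrix.
#' @param tf_gene gene column to screen.
#' @param approved character vector of approved drug ids.
#' @param z_cut down-regulation gate (default -2, strict).
#' @return data.frame: `drug`, `z`, ordered by ascending Z.
#' @export
screen_drugs <- function(z, tf_gene, approved, z_cut = -2) {
  if (!tf_gene %in% colnames(z))
    .stopf("gene '%s' is not in the perturbation matrix", tf_gene)
  v <- z[, tf_gene]
  keep <- v < z_cut & rownames(z) %in% approved
  out <- data.frame(drug = rownames(z)[keep], z = unname(v[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$z), , drop = FALSE]
}
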