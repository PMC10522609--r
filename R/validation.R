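#' Relative expression by the 2^-dCt method
#'
#' rel = 2^-(Ct_target - Ct_housekeeping). Lower target Ct than housekeeping
#' means higher expression. When several housekeeping Ct values are supplied
#' per well they are first aggregated (arithmetic mean of Ct by default, or
#' geometric mean of expression, i.e. mean on the Ct scale after sign flip --
#' identical for Ct averaging, provided for symmetry with plate designs that
#' export per-gene housekeeping wells).
#'
#' @param ct_target target-gene crossing cycle(s).
#' @param ct_housekeeping housekeeping crossing cycle(s); a matrix/data.frame
#'   with one column per housekeeping gene is aggregated row-wise.
#' @param hk_aggregate "mean_ct" (arithmetic mean of Ct) or "geomean_expr"
#'   (geometric mean of 2^-Ct, equivalent to mean Ct).
#' @return relative expression, > 0.
#' @export
delta_ct <- function(ct_target, ct_housekeeping,
                     hk_aggregate = c("mean_ct", "geomean_expr")) {
  hk_aggregate <- match.arg(hk_aggregate)
  if (is.matrix(ct_housekeeping) || is.data.frame(ct_housekeeping))
    ct_housekeeping <- rowMeans(as.matrix(ct_housekeeping))
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_housekeeping)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_housekeeping)
}

#' Normalize relative expression to a reference group
#'
#' Divides each sample's relative expression by the arithmetic mean of the
#' reference group's relative expression, per gene, so the reference-group
#' mean becomes exactly 1.
#'
#' @param rel data.frame with columns sample_id, group, gene, rel_expr.
#' @param reference_group group whose per-gene mean becomes the unit.
#' @return `rel` with an added `rel_to_reference` column.
#' @export
normalize_to_group <- function(rel, reference_group) {
  if (!reference_group %in% rel$group)
    stop("reference group '", reference_group, "' not present")
  ref_mean <- tapply(rel$rel_expr[rel$group == reference_group],
                     rel$gene[rel$group == reference_group], mean)
  missing_ref <- setdiff(unique(rel$gene), names(ref_mean))
  if (length(missing_ref))
    stop("no reference-group samples for gene(s): ",
         paste(missing_ref, collapse = ", "))
  rel$rel_to_reference <- as.numeric(rel$rel_expr / ref_mean[rel$gene])
  rel
}

#' Per-gene group comparison of qPCR relative expression
#'
#' Computes 2^-dCt per well, normalizes to the reference group, and compares
#' the case group against the reference per gene with the normality-gated
#' two-sample machinery. Samples on the blacklist (e.g. excluded for
#' technical reasons) are dropped before any computation.
#'
#' @param ct data.frame sample_id, group, gene, ct_target, ct_housekeeping.
#' @param case_group,reference_group the two arms compared (direction is
#'   case relative to reference).
#' @param alpha significance threshold.
#' @param exclude_samples character vector of sample ids to drop.
#' @param method test method ("auto"/"t"/"wilcox").
#' @return list with `expression` (the normalized per-well table) and
#'   `comparison` (data.frame gene_id, mean_case, mean_reference, p_value,
#'   test, observed_direction in {up, down, none}).
#' @export
compare_qpcr <- function(ct, case_group, reference_group, alpha = 0.05,
                         exclude_samples = character(0), method = "auto") {
  need <- c("sample_id", "group", "gene", "ct_target", "ct_housekeeping")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table missing columns: ",
                         paste(miss, collapse = ", "))
  ct <- ct[!ct$sample_id %in% exclude_samples, , drop = FALSE]
  ct <- ct[ct$group %in% c(case_group, reference_group), , drop = FALSE]
  if (nrow(ct) == 0) stop("no samples left after filtering")
  rel <- data.frame(sample_id = ct$sample_id, group = ct$group,
                    gene = ct$gene,
                    rel_expr = delta_ct(ct$ct_target, ct$ct_housekeeping),
                    stringsAsFactors = FALSE)
  rel <- normalize_to_group(rel, reference_group)
  genes <- unique(rel$gene)
  cmp <- do.call(rbind, lapply(genes, function(g) {
    a <- rel$rel_to_reference[rel$gene == g & rel$group == reference_group]
    b <- rel$rel_to_reference[rel$gene == g & rel$group == case_group]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(gene_id = g, mean_case = NA_real_,
                        mean_reference = NA_real_, p_value = NA_real_,
                        test = "untestable", observed_direction = "none",
                        stringsAsFactors = FALSE))
    }
    tt <- two_group_test(a, b, method = method)
    dirn <- if (tt$p < alpha) {
      if (mean(b) > mean(a)) "up" else "down"
    } else "none"
    data.frame(gene_id = g, mean_case = mean(b), mean_reference = mean(a),
               p_value = tt$p, test = tt$method, observed_direction = dirn,
               stringsAsFactors = FALSE)
  }))
  rownames(cmp) <- NULL
  list(expression = rel, comparison = cmp)
}

#' Concordance between predicted and observed regulation
#'
#' Joins a node-strength table (predicted direction per gene) against qPCR
#' comparison results. A gene is `validated` when its observed change is
#' significant and in the predicted direction; `trend_only` when the point
#' estimate moves the predicted way without significance; `discordant` when
#' a significant change opposes the prediction; `unchanged` otherwise.
#' Genes with no usable qPCR data are `untestable`. The summary counts
#' partition the tested set.
#'
#' @param predicted a [node_strengths()] table (or subset).
#' @param comparison the `comparison` frame from [compare_qpcr()].
#' @param alpha significance threshold (already applied inside
#'   `compare_qpcr`; repeated here for the report header).
#' @return list with `report` (per-gene data.frame gene_id,
#'   predicted_direction, observed_direction, p_value, status, validated) and
#'   `summary` (named counts).
#' @export
concordance <- function(predicted, comparison, alpha = 0.05) {
  genes <- intersect(predicted$gene_id, comparison$gene_id)
  if (length(genes) == 0) stop("no overlap between predicted and tested genes")
  pred <- predicted[match(genes, predicted$gene_id), ]
  obs <- comparison[match(genes, comparison$gene_id), ]
  status <- vapply(seq_along(genes), function(i) {
    if (obs$test[i] == "untestable" || is.na(obs$p_value[i]))
      return("untestable")
    pd <- pred$predicted_direction[i]
    od <- obs$observed_direction[i]
    moved <- if (is.na(obs$mean_case[i]) || is.na(obs$mean_reference[i])) "none"
             else if (obs$mean_case[i] > obs$mean_reference[i]) "up" else "down"
    if (od != "none" && od == pd) "validated"
    else if (od != "none" && pd %in% c("up", "down")) "discordant"
    else if (od == "none" && moved == pd) "trend_only"
    else "unchanged"
  }, character(1))
  report <- data.frame(gene_id = genes,
                       predicted_direction = pred$predicted_direction,
                       node_strength = pred$node_strength,
                       observed_direction = obs$observed_direction,
                       p_value = obs$p_value,
                       status = status,
                       validated = status == "validated",
                       stringsAsFactors = FALSE)
  summary <- c(n_tested = sum(status != "untestable"),
               n_validated = sum(status == "validated"),
               n_trend_only = sum(status == "trend_only"),
               n_unchanged = sum(status == "unchanged"),
               n_discordant = sum(status == "discordant"),
               n_untestable = sum(status == "untestable"))
  list(report = report, summary = summary, alpha = alpha)
}
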