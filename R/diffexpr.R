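#' Counts-per-million normalization
#'
#' Scales each sample column of a non-negative count matrix to sum to 1e6.
#' Zero counts stay zero; an all-zero sample has no defined library size and
#' is rejected.
#'
#' @param counts numeric matrix, miRNA x sample, non-negative.
#' @return matrix of the same shape, columns summing to 1e6.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Per-miRNA two-group test on normalized values
#'
#' Thin wrapper over [two_group_test()]: two-sided p-value with the
#' normality-gated choice between Student's t and Mann-Whitney U (exact for
#' small samples). Identical groups give p = 1.
#'
#' @param values_a,values_b normalized expression values per group.
#' @param method "auto", "t" or "wilcox".
#' @return two-sided p-value in [0, 1].
#' @export
test_mirna <- function(values_a, values_b, method = "auto") {
  two_group_test(values_a, values_b, method = method)$p
}

#' Construct a signed miRNA set
#'
#' @param up,down character vectors of miRNA ids; must be disjoint.
#'   Duplicates within a list are dropped with a warning.
#' @return object of class `signed_mirna_set` (list with `up`, `down`).
#' @export
signed_mirna_set <- function(up = character(0), down = character(0)) {
  if (anyDuplicated(up) || anyDuplicated(down)) {
    warning("duplicate miRNA names within a direction list; deduplicated")
    up <- unique(up); down <- unique(down)
  }
  both <- intersect(up, down)
  if (length(both)) stop("miRNA(s) listed as both up and down: ",
                         paste(both, collapse = ", "))
  structure(list(up = up, down = down), class = "signed_mirna_set")
}

#' @export
print.signed_mirna_set <- function(x, ...) {
  cat("Signed miRNA set:", length(x$up), "up,", length(x$down), "down\n")
  invisible(x)
}

#' Call differentially expressed miRNAs between two arms
#'
#' Normalizes to CPM, computes the linear fold change of group-B over
#' group-A means (with a pseudocount to keep ratios finite), tests each
#' miRNA with the normality-gated two-sample machinery, and labels direction
#' by the dual threshold: up when p < alpha AND FC > fc_threshold, down when
#' p < alpha AND FC < 1/fc_threshold, none otherwise. Both inequalities are
#' strict. No multiplicity correction is applied by default (the stated
#' criterion is a raw p-value); set `p_adjust` to change that.
#'
#' @param counts count matrix, miRNA x sample.
#' @param groups group label per sample (named by sample or in column order).
#' @param group_a reference arm; @param group_b case arm (FC = B / A).
#' @param alpha significance threshold (strict `<`).
#' @param fc_threshold linear fold-change threshold (strict `>` and
#'   `< 1/fc_threshold`).
#' @param pseudocount CPM added to both group means before the ratio.
#' @param method test method per miRNA ("auto"/"t"/"wilcox").
#' @param p_adjust p.adjust method applied before thresholding ("none"
#'   matches the headline criterion).
#' @return list with `table` (data.frame mirna_id, mean_a, mean_b,
#'   fold_change, log2fc, p_value, neg_log10_p, direction) and `signed`
#'   (a [signed_mirna_set()]).
#' @export
call_de <- function(counts, groups, group_a, group_b,
                    alpha = 0.05, fc_threshold = 1.5, pseudocount = 0.5,
                    method = "auto", p_adjust = "none") {
  counts <- as.matrix(counts)
  if (anyDuplicated(rownames(counts))) stop("duplicate miRNA ids")
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("need one group label per sample column")
  for (g in c(group_a, group_b))
    if (sum(groups == g) < 2L)
      stop("group '", g, "' absent or has < 2 samples")
  cpm <- cpm_normalize(counts)
  a_idx <- groups == group_a
  b_idx <- groups == group_b
  mean_a <- rowMeans(cpm[, a_idx, drop = FALSE])
  mean_b <- rowMeans(cpm[, b_idx, drop = FALSE])
  fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
  p <- vapply(seq_len(nrow(cpm)), function(i) {
    test_mirna(cpm[i, a_idx], cpm[i, b_idx], method = method)
  }, numeric(1))
  p_eff <- stats::p.adjust(p, method = p_adjust)
  direction <- ifelse(p_eff < alpha & fc > fc_threshold, "up",
                      ifelse(p_eff < alpha & fc < 1 / fc_threshold,
                             "down", "none"))
  tab <- data.frame(mirna_id = rownames(counts),
                    mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, log2fc = log2(fc),
                    p_value = p, neg_log10_p = -log10(pmax(p, 1e-300)),
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       signed = signed_mirna_set(up = tab$mirna_id[direction == "up"],
                                 down = tab$mirna_id[direction == "down"]))
}

#' Parse printed up/down miRNA name lists into a signed set
#'
#' Accepts the abbreviated form such lists are printed in, where only the
#' first name carries the species/family prefix ("rno-miR-106b-5p, 125a-3p,
#' ...") and bare suffixes inherit it. Names are deduplicated; a name in
#' both lists is an error. The attached `counts` attribute reports sizes so
#' discrepancies against a stated total can be surfaced by the caller.
#'
#' @param up,down character vectors of names (possibly bare suffixes), or a
#'   single comma-separated string each.
#' @param prefix prefix applied to bare suffixes (those not starting with a
#'   species tag such as "rno-"/"mmu-"/"hsa-" or "miR"/"let").
#' @return a [signed_mirna_set()] with attribute `counts = c(up=, down=)`.
#' @export
parse_signed_list <- function(up = character(0), down = character(0),
                              prefix = "rno-miR-") {
  expand <- function(x) {
    if (length(x) == 1L && grepl(",", x))
      x <- strsplit(x, ",")[[1]]
    x <- trimws(x)
    x <- x[nzchar(x)]
    has_prefix <- grepl("^([a-z]{3}-)?(miR|let|mir)", x)
    ifelse(has_prefix, x, paste0(prefix, x))
  }
  s <- signed_mirna_set(up = expand(up), down = expand(down))
  attr(s, "counts") <- c(up = length(s$up), down = length(s$down))
  s
}

#' Published AB_HF vs AB_LVH signature lists
#'
#' Reads the printed up/down miRNA lists of the heart-failure vs compensated
#' hypertrophy comparison shipped with the package (plain text, one
#' abbreviated name per line) and parses them with [parse_signed_list()].
#' Note the printed up list contains 43 names although the stated count is
#' 44 (one name is missing from the printed text); the parser reports what
#' is printed.
#'
#' @return a [signed_mirna_set()].
#' @export
published_signature <- function() {
  f <- function(which) {
    readLines(system.file("extdata", "mir_lists",
                          paste0("ab_hf_vs_ab_lvh_", which, ".txt"),
                          package = "mitanet", mustWork = TRUE))
  }
  parse_signed_list(up = f("up"), down = f("down"))
}

#' Write the DE outputs (full table, signed set, volcano data) as TSVs
#'
#' @param de result of [call_de()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_de <- function(de, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "de_table.tsv"),
             signed = file.path(dir, "signed_set.tsv"),
             volcano = file.path(dir, "volcano.tsv"))
  utils::write.table(de$table, paths["table"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  signed_df <- data.frame(
    mirna_id = c(de$signed$up, de$signed$down),
    direction = c(rep("up", length(de$signed$up)),
                  rep("down", length(de$signed$down))),
    stringsAsFactors = FALSE)
  utils::write.table(signed_df, paths["signed"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(de$table[, c("mirna_id", "log2fc", "neg_log10_p",
                                  "direction")],
                     paths["volcano"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
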