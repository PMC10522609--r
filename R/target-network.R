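#' Read a miRNA-target interaction table in one of three source dialects
#'
#' Dialects mirror the three databases the prediction pipeline integrates:
#' \describe{
#'   \item{validated}{experimentally validated catalog; columns `mirna`,
#'     `gene`, optional `evidence`; all rows kept, no score.}
#'   \item{mirdb}{prediction database with a 0-100 confidence `score`; rows
#'     kept only when score > `mirdb_min` (strict).}
#'   \item{mirsvr}{prediction set with a negative `mirsvr_score` (more
#'     negative = stronger predicted repression); rows kept only when score <
#'     `mirsvr_max` (strict).}
#' }
#' Malformed rows (missing ids, missing score in a prediction dialect) are
#' skipped with a warning.
#'
#' @param path TSV file with a header row.
#' @param dialect one of "validated", "mirdb", "mirsvr".
#' @param mirdb_min,mirsvr_max inclusion thresholds for the prediction
#'   dialects.
#' @return data.frame with columns mirna, gene, source, score (NA for
#'   validated rows).
#' @export
read_interactions <- function(path, dialect = c("validated", "mirdb", "mirsvr"),
                              mirdb_min = 80, mirsvr_max = -1.2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(d)))
    stop("interaction table needs 'mirna' and 'gene' columns: ", path)
  score_col <- switch(dialect, validated = NA_character_,
                      mirdb = "score", mirsvr = "mirsvr_score")
  bad <- !nzchar(trimws(as.character(d$mirna))) |
         !nzchar(trimws(as.character(d$gene))) |
         is.na(d$mirna) | is.na(d$gene)
  if (!is.na(score_col)) {
    if (!score_col %in% names(d))
      stop("dialect '", dialect, "' needs a '", score_col, "' column")
    bad <- bad | !is.finite(suppressWarnings(as.numeric(d[[score_col]])))
  }
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped in ", basename(path))
    d <- d[!bad, , drop = FALSE]
  }
  score <- if (is.na(score_col)) rep(NA_real_, nrow(d))
           else as.numeric(d[[score_col]])
  keep <- switch(dialect,
                 validated = rep(TRUE, nrow(d)),
                 mirdb = score > mirdb_min,
                 mirsvr = score < mirsvr_max)
  data.frame(mirna = as.character(d$mirna[keep]),
             gene = as.character(d$gene[keep]),
             source = dialect, score = score[keep],
             stringsAsFactors = FALSE)
}

# case-insensitive, species-prefix-aware miRNA name normalization for
# matching; arm suffixes (-3p/-5p) are preserved and must match exactly.
normalize_mirna_id <- function(x, species = "rno") {
  x <- tolower(trimws(x))
  bare <- !grepl("^[a-z]{3}-", x)
  x[bare] <- paste0(tolower(species), "-", x[bare])
  x
}

#' Build the signed bipartite miRNA-target network
#'
#' Keeps only interactions whose miRNA is in the signed set; edges from an
#' upregulated miRNA get weight +1 and from a downregulated miRNA -1.
#' Duplicate (miRNA, gene) pairs -- whether within or across sources --
#' collapse to a single edge whose provenance is the union of supporting
#' sources, so a gene's node strength counts distinct regulating miRNAs.
#' Genes with no surviving edge do not appear. miRNA name matching is
#' case-insensitive and species-prefix-aware.
#'
#' @param signed a [signed_mirna_set()], non-empty.
#' @param interactions data.frame(s) as returned by [read_interactions()]
#'   (a single frame or a list of frames, concatenated).
#' @param mode "union" keeps a pair supported by any source; "intersection"
#'   keeps only pairs supported by every distinct source present in
#'   `interactions`.
#' @param species species prefix assumed for bare miRNA names.
#' @return object of class `target_network`: list with `edges` (data.frame
#'   mirna, gene, weight, sources), `mirna_direction` (named vector over the
#'   full signed set) and `genes`.
#' @export
build_network <- function(signed, interactions, mode = c("union", "intersection"),
                          species = "rno") {
  mode <- match.arg(mode)
  stopifnot(inherits(signed, "signed_mirna_set"))
  if (length(signed$up) + length(signed$down) == 0)
    stop("signed miRNA set is empty")
  if (is.data.frame(interactions)) interactions <- list(interactions)
  ia <- do.call(rbind, interactions)
  dir_map <- c(stats::setNames(rep("up", length(signed$up)),
                               normalize_mirna_id(signed$up, species)),
               stats::setNames(rep("down", length(signed$down)),
                               normalize_mirna_id(signed$down, species)))
  mirna_direction <- c(stats::setNames(rep("up", length(signed$up)), signed$up),
                       stats::setNames(rep("down", length(signed$down)),
                                       signed$down))
  if (is.null(ia) || nrow(ia) == 0) {
    edges <- data.frame(mirna = character(0), gene = character(0),
                        weight = integer(0), sources = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(edges = edges, mirna_direction = mirna_direction,
                          genes = character(0)), class = "target_network"))
  }
  ia$mirna_norm <- normalize_mirna_id(ia$mirna, species)
  ia <- ia[ia$mirna_norm %in% names(dir_map), , drop = FALSE]
  key <- paste(ia$mirna_norm, ia$gene, sep = "\r")
  prov <- lapply(split(ia$source, key), function(s) sort(unique(s)))
  if (mode == "intersection") {
    n_src <- length(unique(ia$source))
    prov <- prov[vapply(prov, length, 1L) == n_src]
  }
  if (length(prov) == 0) {
    edges <- data.frame(mirna = character(0), gene = character(0),
                        weight = integer(0), sources = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(edges = edges, mirna_direction = mirna_direction,
                          genes = character(0)), class = "target_network"))
  }
  parts <- strsplit(names(prov), "\r", fixed = TRUE)
  # report edges under the signed set's original spelling
  orig_map <- stats::setNames(c(signed$up, signed$down), names(dir_map))
  edges <- data.frame(
    mirna_norm = vapply(parts, `[`, "", 1L),
    gene = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
  edges$weight <- ifelse(dir_map[edges$mirna_norm] == "up", 1L, -1L)
  edges$mirna <- unname(orig_map[edges$mirna_norm])
  edges$mirna_norm <- NULL
  edges <- edges[, c("mirna", "gene", "weight")]
  edges$sources <- vapply(prov, paste, "", collapse = ",")
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, mirna_direction = mirna_direction,
                 genes = sort(unique(edges$gene))),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat("Signed bipartite miRNA-target network:",
      length(x$mirna_direction), "miRNAs,",
      length(x$genes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Node strengths of the target genes
#'
#' Per gene, the sum of incident signed edge weights: +1 per distinct
#' upregulated regulator, -1 per downregulated one. A positive strength
#' predicts target downregulation (repression by upregulated miRNAs), a
#' negative strength predicts upregulation, zero is ambiguous. A target is
#' unidirectional when all its regulators share one direction, in which case
#' |strength| equals the regulator count. The table is sorted by |strength|
#' descending, ties broken lexicographically by gene id.
#'
#' @param net a [build_network()] result.
#' @return data.frame gene_id, node_strength, n_up_regulators,
#'   n_down_regulators, predicted_direction, unidirectional.
#' @export
node_strengths <- function(net) {
  stopifnot(inherits(net, "target_network"))
  e <- net$edges
  if (nrow(e) == 0) {
    return(data.frame(gene_id = character(0), node_strength = integer(0),
                      n_up_regulators = integer(0),
                      n_down_regulators = integer(0),
                      predicted_direction = character(0),
                      unidirectional = logical(0), stringsAsFactors = FALSE))
  }
  n_up <- tapply(e$weight > 0, e$gene, sum)
  n_down <- tapply(e$weight < 0, e$gene, sum)
  s <- as.integer(n_up - n_down)
  out <- data.frame(gene_id = names(n_up),
                    node_strength = s,
                    n_up_regulators = as.integer(n_up),
                    n_down_regulators = as.integer(n_down),
                    predicted_direction = ifelse(s > 0, "down",
                                                 ifelse(s < 0, "up",
                                                        "ambiguous")),
                    unidirectional = as.integer(n_up) == 0L |
                                     as.integer(n_down) == 0L,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$node_strength), out$gene_id), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Select candidate targets for validation in three tiers
#'
#' Tier 1: every gene at the maximal absolute node strength. Tier 2: genes
#' that are unidirectionally modulated at absolute strength
#' `unidirectional_strength` (typically the next level below the maximum).
#' Tier 3: a seeded random sample of `n_random_strong` further genes with
#' absolute strength at least `strong_floor`. Tiers are disjoint.
#'
#' @param strengths a [node_strengths()] table, non-empty.
#' @param unidirectional_strength absolute strength for tier 2; values above
#'   the observed maximum yield an empty tier with a warning.
#' @param n_random_strong size of the random tier.
#' @param strong_floor minimal absolute strength eligible for tier 3.
#' @param seed RNG seed for the tier-3 sample.
#' @return data.frame gene_id, node_strength, tier (1/2/3), sorted by tier.
#' @export
select_targets <- function(strengths, unidirectional_strength = NULL,
                           n_random_strong = 0, strong_floor = 1,
                           seed = 1L) {
  if (nrow(strengths) == 0) stop("empty node-strength table")
  smax <- max(abs(strengths$node_strength))
  tier1 <- strengths$gene_id[abs(strengths$node_strength) == smax]
  tier2 <- character(0)
  if (!is.null(unidirectional_strength)) {
    if (unidirectional_strength > smax) {
      warning("unidirectional_strength exceeds the maximal |strength|; ",
              "tier 2 is empty")
    } else {
      tier2 <- strengths$gene_id[
        strengths$unidirectional &
        abs(strengths$node_strength) == unidirectional_strength &
        !strengths$gene_id %in% tier1]
    }
  }
  pool <- strengths$gene_id[abs(strengths$node_strength) >= strong_floor &
                            !strengths$gene_id %in% c(tier1, tier2)]
  tier3 <- character(0)
  if (n_random_strong > 0 && length(pool) > 0) {
    set.seed(seed)
    tier3 <- sort(sample(pool, min(n_random_strong, length(pool))))
  }
  sel <- data.frame(
    gene_id = c(sort(tier1), sort(tier2), tier3),
    tier = c(rep(1L, length(tier1)), rep(2L, length(tier2)),
             rep(3L, length(tier3))),
    stringsAsFactors = FALSE)
  sel$node_strength <- strengths$node_strength[
    match(sel$gene_id, strengths$gene_id)]
  sel[, c("gene_id", "node_strength", "tier")]
}

net_to_igraph <- function(net, strengths = NULL) {
  if (is.null(strengths)) strengths <- node_strengths(net)
  mir_nodes <- data.frame(name = names(net$mirna_direction),
                          type = "mirna",
                          direction = unname(net$mirna_direction),
                          strength = NA_integer_,
                          predicted_direction = NA_character_,
                          stringsAsFactors = FALSE)
  gene_nodes <- data.frame(name = strengths$gene_id, type = "gene",
                           direction = NA_character_,
                           strength = strengths$node_strength,
                           predicted_direction = strengths$predicted_direction,
                           stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene", "weight", "sources")],
    directed = TRUE, vertices = rbind(mir_nodes, gene_nodes))
}

#' Export the network as SIF, GraphML or edge-list TSV
#'
#' SIF lines are `mirna <weight> gene`. GraphML (via igraph) carries typed
#' node attributes: direction on miRNA nodes, strength and predicted
#' direction on gene nodes; edges carry the weight. The edge-list TSV
#' (mirna, gene, weight, sources) round-trips through
#' [import_network_edges()] to an identical network.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @param format "sif", "graphml" or "tsv".
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$mirna, e$weight, e$gene, sep = "\t")
               else character(0), path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- net_to_igraph(net)
    # igraph rejects NA attribute values in GraphML; blank them
    for (at in c("direction", "predicted_direction"))
      igraph::vertex_attr(g, at)[is.na(igraph::vertex_attr(g, at))] <- ""
    igraph::vertex_attr(g, "strength")[
      is.na(igraph::vertex_attr(g, "strength"))] <- 0L
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an edge-list TSV written by [export_network()]
#'
#' @param path edge-list TSV (mirna, gene, weight, sources).
#' @param signed the signed miRNA set the network was built from (node set
#'   and directions are not stored in the edge list).
#' @return a `target_network`.
#' @export
import_network_edges <- function(path, signed) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(e) == 0) {
    return(build_network(signed, data.frame(mirna = character(0),
                                            gene = character(0),
                                            source = character(0),
                                            score = numeric(0))))
  }
  # replay each edge's provenance as one interaction row per source
  src <- strsplit(e$sources, ",", fixed = TRUE)
  ia <- data.frame(mirna = rep(e$mirna, lengths(src)),
                   gene = rep(e$gene, lengths(src)),
                   source = unlist(src), score = NA_real_,
                   stringsAsFactors = FALSE)
  build_network(signed, ia)
}
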