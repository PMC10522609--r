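# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive quantities from first principles rather than
# calling the code paths they check.

# Recount node strengths from raw dialect tables: filter each prediction
# dialect by its threshold, deduplicate (mirna, gene) pairs, then add +1 per
# distinct up-regulator and -1 per distinct down-regulator.
oracle_strengths <- function(tables, up, down,
                             mirdb_min = 80, mirsvr_max = -1.2) {
  pairs <- list()
  add <- function(d) {
    if (!is.null(d) && nrow(d))
      pairs[[length(pairs) + 1L]] <<- d[, c("mirna", "gene")]
  }
  add(tables$validated)
  if (!is.null(tables$mirdb))
    add(tables$mirdb[tables$mirdb$score > mirdb_min, , drop = FALSE])
  if (!is.null(tables$mirsvr))
    add(tables$mirsvr[tables$mirsvr$mirsvr_score < mirsvr_max, , drop = FALSE])
  if (!length(pairs)) return(integer(0))
  p <- unique(do.call(rbind, pairs))
  res <- new.env()
  for (i in seq_len(nrow(p))) {
    w <- if (p$mirna[i] %in% up) 1L else if (p$mirna[i] %in% down) -1L else 0L
    if (w == 0L) next
    g <- p$gene[i]
    assign(g, (if (exists(g, res)) get(g, res) else 0L) + w, envir = res)
  }
  vals <- mget(ls(res), envir = res)
  stats::setNames(as.integer(unlist(vals)), names(vals))
}

# random interaction fixture with a known signed set, for oracle-equivalence
# sweeps: n_mirnas <= 50, n_genes <= 500
random_network_fixture <- function(seed, n_mirnas = 30, n_genes = 200,
                                   per_mirna = 6) {
  set.seed(seed)
  mir <- sprintf("rno-miR-f%03d", seq_len(n_mirnas))
  gen <- sprintf("Fg%04d", seq_len(n_genes))
  dirs <- sample(c("up", "down"), n_mirnas, replace = TRUE, prob = c(0.8, 0.2))
  rows <- do.call(rbind, lapply(seq_len(n_mirnas), function(i) {
    k <- stats::rpois(1, per_mirna)
    if (k == 0) return(NULL)
    data.frame(mirna = mir[i], gene = sample(gen, min(k, n_genes)),
               stringsAsFactors = FALSE)
  }))
  src <- sample(c("validated", "mirdb", "mirsvr"), nrow(rows), replace = TRUE)
  tables <- list(
    validated = cbind(rows[src == "validated", , drop = FALSE],
                      evidence = "assay"),
    mirdb = cbind(rows[src == "mirdb", , drop = FALSE],
                  score = stats::runif(sum(src == "mirdb"), 60, 100)),
    mirsvr = cbind(rows[src == "mirsvr", , drop = FALSE],
                   mirsvr_score = stats::runif(sum(src == "mirsvr"),
                                               -2.5, -0.5)))
  list(tables = tables,
       signed = signed_mirna_set(up = mir[dirs == "up"],
                                 down = mir[dirs == "down"]))
}

# interaction data.frames (read_interactions output shape) from raw tables,
# applying the dialect thresholds the same way the reader would
fixture_to_interactions <- function(tables, mirdb_min = 80,
                                    mirsvr_max = -1.2) {
  v <- tables$validated
  m <- tables$mirdb[tables$mirdb$score > mirdb_min, , drop = FALSE]
  s <- tables$mirsvr[tables$mirsvr$mirsvr_score < mirsvr_max, , drop = FALSE]
  list(
    data.frame(mirna = v$mirna, gene = v$gene, source = "validated",
               score = NA_real_, stringsAsFactors = FALSE),
    data.frame(mirna = m$mirna, gene = m$gene, source = "mirdb",
               score = m$score, stringsAsFactors = FALSE),
    data.frame(mirna = s$mirna, gene = s$gene, source = "mirsvr",
               score = s$mirsvr_score, stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# golden pipeline configuration: noise-free world with planted selection
# tiers (4 genes at +7, 10 unidirectional at +6) and 5 planted Ct shifts
golden_config <- function(out_dir, seed = 5L) {
  cfg <- pipeline_config(
    out_dir = out_dir, seed = seed,
    sim = sim_config(seed = seed, noise_free = TRUE,
                     interactions_per_mirna = 3),
    unidirectional_strength = 6, n_random_strong = 3, strong_floor = 2,
    qpcr_n_planted = 5)
  attr(cfg, "planted") <- list(strengths = c(7, 6), genes_each = c(4, 10))
  cfg
}
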