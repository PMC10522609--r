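#' Pipeline configuration
#'
#' One structured object drives an end-to-end run: simulation settings (or
#' paths to pre-existing inputs), thresholds for every stage, target
#' selection settings, and stage toggles.
#'
#' @param out_dir output directory; every stage writes beneath it.
#' @param seed master seed; stage-level seeds derive from it.
#' @param sim a [sim_config()] used when `simulate = TRUE` (its seed is
#'   overridden by `seed`).
#' @param inputs optional named list of paths (counts, samples, validated,
#'   mirdb, mirsvr, echo, qpcr) used when `simulate = FALSE`.
#' @param alpha significance threshold for DE and qPCR calls.
#' @param fc_threshold linear fold-change threshold for DE calls.
#' @param mirdb_min,mirsvr_max interaction-score thresholds.
#' @param ef_cutoff heart-failure EF threshold, percent, in (0, 100).
#' @param unidirectional_strength,n_random_strong,strong_floor target
#'   selection settings (see [select_targets()]).
#' @param qpcr_n_planted in synthetic mode, how many of the selected genes
#'   get a planted Ct shift of `qpcr_shift` cycles in the case arm.
#' @param qpcr_exclude sample ids blacklisted from the qPCR comparison.
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate","phenotype","de","network","select","qpcr","concordance")`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            inputs = NULL,
                            alpha = 0.05, fc_threshold = 1.5,
                            mirdb_min = 80, mirsvr_max = -1.2,
                            ef_cutoff = 30,
                            unidirectional_strength = NULL,
                            n_random_strong = 0, strong_floor = 1,
                            qpcr_n_planted = 0, qpcr_shift = 1,
                            qpcr_exclude = character(0),
                            stages = c("simulate", "phenotype", "de",
                                       "network", "select", "qpcr",
                                       "concordance")) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 1,
            ef_cutoff > 0, ef_cutoff < 100)
  known <- c("simulate", "phenotype", "de", "network", "select", "qpcr",
             "concordance")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 inputs = inputs, alpha = alpha,
                 fc_threshold = fc_threshold, mirdb_min = mirdb_min,
                 mirsvr_max = mirsvr_max, ef_cutoff = ef_cutoff,
                 unidirectional_strength = unidirectional_strength,
                 n_random_strong = n_random_strong,
                 strong_floor = strong_floor,
                 qpcr_n_planted = qpcr_n_planted, qpcr_shift = qpcr_shift,
                 qpcr_exclude = qpcr_exclude, stages = stages),
            class = "pipeline_config")
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order -- simulate, phenotype, DE call,
#' network build + node strengths, target selection, qPCR comparison,
#' concordance -- writing each stage's outputs (TSV) under `config$out_dir`
#' before the next stage starts. A failure aborts with a stage-tagged error.
#' Returns (and writes) a run manifest with the config snapshot, package
#' version, per-file MD5 checksums and stage log; deterministic stages
#' reproduce identical checksums under an identical config.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also written as manifest.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  paths <- list()
  sim <- NULL

  if ("simulate" %in% config$stages) {
    stage_error("simulate", {
      sim <- simulate_study(config$sim,
                            planted = attr(config, "planted"))
      p <- write_simulation(sim, file.path(config$out_dir, "inputs"),
                            config$sim)
      paths$inputs <- as.list(p)
      log$simulate <- list(n_mirnas = nrow(sim$counts),
                           n_samples = ncol(sim$counts),
                           n_planted_de = nrow(sim$truth$de_mirnas))
    })
    inputs <- paths$inputs
  } else {
    if (is.null(config$inputs)) stop("stage 'simulate' disabled but no ",
                                     "input paths configured")
    inputs <- config$inputs
    for (f in c("counts", "samples", "validated", "mirdb", "mirsvr"))
      if (!is.null(inputs[[f]]) && !file.exists(inputs[[f]]))
        stop("stage 'inputs': missing input file: ", inputs[[f]])
  }

  if ("phenotype" %in% config$stages) {
    stage_error("phenotype", {
      echo <- utils::read.delim(inputs$echo, stringsAsFactors = FALSE)
      ph <- phenotype_table(echo, ef_cutoff = config$ef_cutoff)
      paths$phenotype <- file.path(config$out_dir, "phenotype.tsv")
      utils::write.table(ph, paths$phenotype, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      grp <- unique(ph[ph$week == 12, c("animal_id", "assigned_group")])
      paths$groups <- file.path(config$out_dir, "groups.tsv")
      utils::write.table(grp, paths$groups, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      log$phenotype <- list(n_animals = nrow(grp),
                            groups = as.list(table(grp$assigned_group)))
    })
  }

  de <- NULL
  if ("de" %in% config$stages) {
    stage_error("de", {
      cnt <- utils::read.delim(inputs$counts, check.names = FALSE,
                               stringsAsFactors = FALSE)
      m <- as.matrix(cnt[, -1, drop = FALSE])
      rownames(m) <- cnt[[1]]
      smp <- utils::read.delim(inputs$samples, stringsAsFactors = FALSE)
      grp <- smp$group[match(colnames(m), smp$sample_id)]
      de <- call_de(m, grp,
                     group_a = config$sim$de_pair[2],
                     group_b = config$sim$de_pair[1],
                     alpha = config$alpha,
                     fc_threshold = config$fc_threshold)
      p <- write_de(de, config$out_dir)
      paths$de <- as.list(p)
      log$de <- list(n_tested = nrow(de$table),
                     n_up = length(de$signed$up),
                     n_down = length(de$signed$down))
    })
  }

  net <- NULL; strengths <- NULL
  if ("network" %in% config$stages) {
    stage_error("network", {
      if (is.null(de)) {
        sg <- utils::read.delim(file.path(config$out_dir, "signed_set.tsv"),
                                stringsAsFactors = FALSE)
        signed <- signed_mirna_set(up = sg$mirna_id[sg$direction == "up"],
                                   down = sg$mirna_id[sg$direction == "down"])
      } else signed <- de$signed
      ia <- list(
        read_interactions(inputs$validated, "validated"),
        read_interactions(inputs$mirdb, "mirdb",
                          mirdb_min = config$mirdb_min),
        read_interactions(inputs$mirsvr, "mirsvr",
                          mirsvr_max = config$mirsvr_max))
      net <- build_network(signed, ia)
      strengths <- node_strengths(net)
      paths$network <- file.path(config$out_dir, "network_edges.tsv")
      export_network(net, paths$network, format = "tsv")
      paths$strengths <- file.path(config$out_dir, "node_strengths.tsv")
      utils::write.table(strengths, paths$strengths, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log$network <- list(n_rows_in = sum(vapply(ia, nrow, 1L)),
                          n_edges = nrow(net$edges),
                          n_genes = length(net$genes))
    })
  }

  selection <- NULL
  if ("select" %in% config$stages) {
    stage_error("select", {
      if (is.null(strengths))
        strengths <- utils::read.delim(
          file.path(config$out_dir, "node_strengths.tsv"),
          stringsAsFactors = FALSE)
      selection <- select_targets(
        strengths,
        unidirectional_strength = config$unidirectional_strength,
        n_random_strong = config$n_random_strong,
        strong_floor = config$strong_floor,
        seed = config$seed)
      paths$selection <- file.path(config$out_dir, "selection.tsv")
      utils::write.table(selection, paths$selection, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log$select <- list(tier_sizes = as.list(table(selection$tier)))
    })
  }

  comparison <- NULL
  if ("qpcr" %in% config$stages) {
    stage_error("qpcr", {
      if (!is.null(sim) && !is.null(selection)) {
        shifts <- if (config$qpcr_n_planted > 0) {
          stats::setNames(
            rep(config$qpcr_shift,
                min(config$qpcr_n_planted, nrow(selection))),
            utils::head(selection$gene_id, config$qpcr_n_planted))
        } else numeric(0)
        q <- generate_qpcr(config$sim, selection$gene_id, shifts = shifts)
        ct <- q$ct
        paths$qpcr_input <- file.path(config$out_dir, "inputs", "qpcr.tsv")
        utils::write.table(ct, paths$qpcr_input, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        log$qpcr_planted <- as.list(q$truth$de_genes)
      } else {
        ct <- utils::read.delim(inputs$qpcr, stringsAsFactors = FALSE)
      }
      res <- compare_qpcr(ct, case_group = config$sim$de_pair[1],
                          reference_group = config$sim$de_pair[2],
                          alpha = config$alpha,
                          exclude_samples = config$qpcr_exclude)
      comparison <- res$comparison
      paths$expression <- file.path(config$out_dir, "relative_expression.tsv")
      utils::write.table(res$expression, paths$expression, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths$comparison <- file.path(config$out_dir, "qpcr_comparison.tsv")
      utils::write.table(comparison, paths$comparison, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log$qpcr <- list(n_genes = nrow(comparison),
                       n_significant =
                         sum(comparison$observed_direction != "none"))
    })
  }

  if ("concordance" %in% config$stages) {
    stage_error("concordance", {
      if (is.null(strengths) || is.null(comparison))
        stop("needs the network and qpcr stages")
      conc <- concordance(strengths, comparison, alpha = config$alpha)
      paths$concordance <- file.path(config$out_dir, "concordance.tsv")
      utils::write.table(conc$report, paths$concordance, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log$concordance <- as.list(conc$summary)
    })
  }

  flat <- unlist(paths, use.names = TRUE)
  manifest <- list(
    config = unclass(config)[setdiff(names(unclass(config)), "sim")],
    sim_config = unclass(config$sim),
    version = as.character(utils::packageVersion("mitanet")),
    stages_run = intersect(config$stages, config$stages),
    log = log,
    checksums = as.list(unname_safe(tools::md5sum(flat))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}

unname_safe <- function(x) {
  stats::setNames(as.vector(x), basename(names(x)))
}

#' Summarize a completed (or partial) pipeline run
#'
#' Reads the stage outputs under `out_dir` and reports per-stage counts:
#' DE up/down, genes and edges in the network, selection tier sizes, and the
#' concordance summary. Missing artifacts are reported as gaps instead of
#' failing, so partial runs can be inspected.
#'
#' @param out_dir a pipeline output directory.
#' @return list of per-stage summaries (also written as summary.json).
#' @export
summarize_run <- function(out_dir) {
  if (!dir.exists(out_dir)) stop("no such output directory: ", out_dir)
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  out <- list(missing = character(0))
  sg <- rd("signed_set.tsv")
  if (is.null(sg)) out$missing <- c(out$missing, "signed_set.tsv")
  else out$de <- list(n_up = sum(sg$direction == "up"),
                      n_down = sum(sg$direction == "down"))
  ns <- rd("node_strengths.tsv")
  if (is.null(ns)) out$missing <- c(out$missing, "node_strengths.tsv")
  else out$network <- list(
    n_genes = nrow(ns),
    max_abs_strength = if (nrow(ns)) max(abs(ns$node_strength)) else 0)
  sel <- rd("selection.tsv")
  if (is.null(sel)) out$missing <- c(out$missing, "selection.tsv")
  else out$selection <- as.list(table(sel$tier))
  cc <- rd("concordance.tsv")
  if (is.null(cc)) out$missing <- c(out$missing, "concordance.tsv")
  else out$concordance <- list(n_tested = sum(cc$status != "untestable"),
                               n_validated = sum(cc$validated))
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}
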