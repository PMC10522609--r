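#' Simulation configuration for the synthetic pressure-overload study
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' study design of the rat abdominal aortic-banding experiment the pipeline
#' was built around: three arms (Sham n = 8, AB_LVH n = 8, AB_HF n = 5),
#' overdispersed small-RNA UMI counts, a 50-miRNA differential signature
#' between the two banded arms, and miRNA-target interaction tables emitted
#' in three source dialects (validated catalog, 0-100 prediction score,
#' negative mirSVR-style score).
#'
#' @param n_per_group named integer vector of animals per arm.
#' @param n_mirnas number of miRNAs in the count matrix.
#' @param n_genes number of candidate target genes.
#' @param frac_de fraction of miRNAs planted as differentially expressed
#'   between `de_pair[1]` and `de_pair[2]`.
#' @param frac_down of the planted miRNAs, the fraction planted downregulated
#'   (the remainder are up). Default mirrors a 44 up / 6 down split.
#' @param log2fc_range interval the planted |log2 fold changes| are drawn
#'   from (uniformly).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param lib_size_range interval of per-sample library-size factors,
#'   relative to 1.
#' @param interactions_per_mirna mean out-degree of a miRNA in the emitted
#'   interaction tables (Poisson-distributed per miRNA).
#' @param source_mix named proportions over the dialects
#'   `c(validated, mirdb, mirsvr)`; must sum to 1.
#' @param de_pair the two arms the differential signature is planted between,
#'   `c(case, reference)`.
#' @param qpcr_noise_sd Gaussian SD of Ct replicate noise, cycles.
#' @param echo_noise multiplier on the between-animal SDs of the echo
#'   generator (0 = every animal sits at its group mean).
#' @param noise_free logical; TRUE zeroes all stochastic noise (counts become
#'   rounded expected values, Ct and echo noise SDs become 0) for golden-run
#'   ground-truth recovery tests.
#' @param seed RNG seed; identical seeds give bit-identical outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(Sham = 8L, AB_LVH = 8L, AB_HF = 5L),
                       n_mirnas = 200L, n_genes = 500L,
                       frac_de = 0.25, frac_down = 6 / 50,
                       log2fc_range = c(1, 2),
                       nb_dispersion = 0.15,
                       lib_size_range = c(0.7, 1.3),
                       interactions_per_mirna = 10,
                       source_mix = c(validated = 0.4, mirdb = 0.3,
                                      mirsvr = 0.3),
                       de_pair = c("AB_HF", "AB_LVH"),
                       qpcr_noise_sd = 0.3,
                       echo_noise = 1,
                       noise_free = FALSE,
                       seed = 1L) {
  stopifnot(all(n_per_group >= 0), n_mirnas > 0, n_genes > 0,
            frac_de >= 0, frac_de <= 1, frac_down >= 0, frac_down <= 1,
            length(log2fc_range) == 2, log2fc_range[1] <= log2fc_range[2],
            nb_dispersion >= 0, lib_size_range[1] > 0,
            lib_size_range[1] <= lib_size_range[2],
            interactions_per_mirna >= 0,
            length(source_mix) == 3, qpcr_noise_sd >= 0, echo_noise >= 0)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be named by study arm")
  if (abs(sum(source_mix) - 1) > 1e-8) stop("source_mix must sum to 1")
  if (!all(de_pair %in% names(n_per_group)))
    stop("de_pair arms must be present in n_per_group")
  if (noise_free) {
    nb_dispersion <- 0
    qpcr_noise_sd <- 0
    echo_noise <- 0
  }
  structure(list(
    n_per_group = as.integer(n_per_group) |> stats::setNames(names(n_per_group)),
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    frac_de = frac_de, frac_down = frac_down,
    log2fc_range = log2fc_range, nb_dispersion = nb_dispersion,
    lib_size_range = lib_size_range,
    interactions_per_mirna = interactions_per_mirna,
    source_mix = source_mix, de_pair = de_pair,
    qpcr_noise_sd = qpcr_noise_sd, echo_noise = echo_noise,
    noise_free = noise_free, seed = as.integer(seed)),
    class = "sim_config")
}

sim_mirna_ids <- function(n) sprintf("rno-miR-s%04d", seq_len(n))
sim_gene_ids <- function(n) sprintf("Gene%04d", seq_len(n))

sim_sample_frame <- function(config) {
  grp <- rep(names(config$n_per_group), config$n_per_group)
  data.frame(sample_id = sprintf("%s_%d", grp,
                                 unlist(lapply(config$n_per_group, seq_len),
                                        use.names = FALSE)),
             group = grp, stringsAsFactors = FALSE)
}

#' Generate a miRNA x sample UMI count matrix with planted fold changes
#'
#' Baseline expression is log-normal across miRNAs; counts are negative
#' binomial around `mu * library factor` (Poisson when dispersion is 0, and
#' deterministic rounded means when `noise_free`). A seeded subset of
#' `frac_de * n_mirnas` miRNAs gets its mean multiplied by the planted fold
#' change in arm `de_pair[1]` only; all other arms share the baseline mean.
#' Planted miRNAs have their baseline mean floored at 32 counts so the
#' planted ratio survives integer rounding.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, miRNA x sample), `samples`
#'   (data.frame sample_id, group) and `truth` (list with `de_mirnas`:
#'   data.frame mirna_id, direction, log2fc).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mirnas <- sim_mirna_ids(config$n_mirnas)
  samples <- sim_sample_frame(config)
  mu <- stats::rlnorm(config$n_mirnas, log(100), 1.2)
  n_de <- round(config$frac_de * config$n_mirnas)
  de_idx <- if (n_de > 0) sort(sample.int(config$n_mirnas, n_de)) else integer(0)
  # planted miRNAs sit at moderate abundance so the extra library mass they
  # add in the case arm keeps the CPM compositional shift of the unplanted
  # majority inside (1/1.5, 1.5) -- otherwise per-sample renormalization
  # would turn planting 44 up-miRNAs into spurious "down" calls everywhere
  mu[de_idx] <- pmax(stats::rlnorm(n_de, log(50), 0.5), 20)
  n_down <- round(config$frac_down * n_de)
  dir_vec <- rep("up", n_de)
  if (n_down > 0) dir_vec[sample.int(n_de, n_down)] <- "down"
  l2fc <- stats::runif(n_de, config$log2fc_range[1], config$log2fc_range[2])
  l2fc <- ifelse(dir_vec == "down", -l2fc, l2fc)
  lib <- if (config$noise_free) rep(1, nrow(samples)) else
    stats::runif(nrow(samples), config$lib_size_range[1],
                 config$lib_size_range[2])
  case <- samples$group == config$de_pair[1]
  mu_mat <- outer(mu, lib)
  if (n_de > 0) mu_mat[de_idx, case] <- mu_mat[de_idx, case] * 2^l2fc
  counts <- if (config$noise_free) {
    round(mu_mat)
  } else if (config$nb_dispersion == 0) {
    matrix(stats::rpois(length(mu_mat), mu_mat), nrow = config$n_mirnas)
  } else {
    matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                          size = 1 / config$nb_dispersion),
           nrow = config$n_mirnas)
  }
  dimnames(counts) <- list(mirnas, samples$sample_id)
  storage.mode(counts) <- "integer"
  de_mirnas <- data.frame(mirna_id = mirnas[de_idx],
                          direction = dir_vec, log2fc = l2fc,
                          stringsAsFactors = FALSE)[seq_len(n_de), , drop = FALSE]
  list(counts = counts, samples = samples,
       truth = list(de_mirnas = de_mirnas))
}

# Brute-force node strengths from raw dialect tables: apply the per-dialect
# score thresholds, deduplicate (miRNA, gene) pairs, then sum planted signs.
# Kept deliberately naive -- it is the oracle the network module is checked
# against.
brute_force_strengths <- function(tables, de_mirnas,
                                  mirdb_min = 80, mirsvr_max = -1.2) {
  keep <- rbind(
    tables$validated[, c("mirna", "gene")],
    tables$mirdb[tables$mirdb$score > mirdb_min, c("mirna", "gene")],
    tables$mirsvr[tables$mirsvr$mirsvr_score < mirsvr_max, c("mirna", "gene")])
  keep <- unique(keep)
  sgn <- stats::setNames(ifelse(de_mirnas$direction == "up", 1L, -1L),
                         de_mirnas$mirna_id)
  keep <- keep[keep$mirna %in% names(sgn), , drop = FALSE]
  if (nrow(keep) == 0) return(stats::setNames(integer(0), character(0)))
  out <- tapply(sgn[keep$mirna], keep$gene, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Generate miRNA-target interaction tables in three source dialects
#'
#' Every miRNA receives a Poisson-distributed number of target genes; each
#' interaction is assigned to one dialect by `source_mix`. The validated
#' dialect carries an evidence label and no score; the prediction dialects
#' carry scores spanning both sides of their inclusion thresholds (80.0 and
#' -1.2) so thresholding is exercised. Optionally plants a block of genes
#' wired only to same-direction planted miRNAs, to build selection-tier
#' fixtures with known maximal node strengths.
#'
#' @param config a [sim_config()].
#' @param mirna_ids,gene_ids identifier vectors (non-empty).
#' @param de_mirnas data.frame (mirna_id, direction) of the planted signed
#'   set; ground-truth strengths are recorded for this set.
#' @param planted optional list like `list(strengths = c(7, 6), genes_each =
#'   c(4, 10))`: for each element, that many reserved genes are wired to
#'   exactly that many distinct planted-up miRNAs through the validated
#'   dialect (unidirectional by construction); reserved genes are excluded
#'   from the random background.
#' @return list with `tables` (named list validated/mirdb/mirsvr of
#'   data.frames) and `truth` (list with `true_node_strengths`, a named
#'   integer vector, and `planted_genes` when planting was requested).
#' @export
generate_interactions <- function(config, mirna_ids, gene_ids, de_mirnas,
                                  planted = NULL) {
  stopifnot(inherits(config, "sim_config"),
            length(mirna_ids) > 0, length(gene_ids) > 0)
  set.seed(config$seed + 1L)
  planted_genes <- list()
  plant_rows <- NULL
  background_genes <- gene_ids
  if (!is.null(planted)) {
    up_mirnas <- de_mirnas$mirna_id[de_mirnas$direction == "up"]
    need <- sum(planted$genes_each)
    if (need > length(gene_ids)) stop("not enough genes to plant")
    if (max(planted$strengths) > length(up_mirnas))
      stop("not enough planted-up miRNAs for requested strength")
    reserved <- gene_ids[seq_len(need)]
    background_genes <- setdiff(gene_ids, reserved)
    at <- 0L
    plant_rows <- do.call(rbind, lapply(seq_along(planted$strengths), function(i) {
      g <- reserved[at + seq_len(planted$genes_each[i])]
      at <<- at + planted$genes_each[i]
      planted_genes[[as.character(planted$strengths[i])]] <<- g
      do.call(rbind, lapply(g, function(gene) {
        data.frame(mirna = sample(up_mirnas, planted$strengths[i]),
                   gene = gene, stringsAsFactors = FALSE)
      }))
    }))
  }
  deg <- stats::rpois(length(mirna_ids), config$interactions_per_mirna)
  deg <- pmin(deg, length(background_genes))
  bg <- do.call(rbind, lapply(seq_along(mirna_ids), function(i) {
    if (deg[i] == 0) return(NULL)
    data.frame(mirna = mirna_ids[i],
               gene = sample(background_genes, deg[i]),
               stringsAsFactors = FALSE)
  }))
  all_rows <- rbind(plant_rows, bg)
  if (is.null(all_rows) || nrow(all_rows) == 0) {
    tables <- list(
      validated = data.frame(mirna = character(0), gene = character(0),
                             evidence = character(0), species = character(0)),
      mirdb = data.frame(mirna = character(0), gene = character(0),
                         score = numeric(0), species = character(0)),
      mirsvr = data.frame(mirna = character(0), gene = character(0),
                          mirsvr_score = numeric(0), species = character(0)))
    return(list(tables = tables,
                truth = list(true_node_strengths =
                               stats::setNames(integer(0), character(0)),
                             planted_genes = planted_genes)))
  }
  src <- sample(names(config$source_mix), nrow(all_rows), replace = TRUE,
                prob = config$source_mix)
  if (!is.null(plant_rows))   # planted wiring must survive thresholding
    src[seq_len(nrow(plant_rows))] <- "validated"
  evid <- c("Luciferase reporter assay", "Western blot", "qRT-PCR", "CLIP-seq")
  tables <- list(
    validated = {
      d <- all_rows[src == "validated", , drop = FALSE]
      d$evidence <- sample(evid, nrow(d), replace = TRUE)
      d$species <- rep("rno", nrow(d)); rownames(d) <- NULL; d
    },
    mirdb = {
      d <- all_rows[src == "mirdb", , drop = FALSE]
      d$score <- stats::runif(nrow(d), 60, 100)
      d$species <- rep("rno", nrow(d)); rownames(d) <- NULL; d
    },
    mirsvr = {
      d <- all_rows[src == "mirsvr", , drop = FALSE]
      d$mirsvr_score <- stats::runif(nrow(d), -2.5, -0.5)
      d$species <- rep("rno", nrow(d)); rownames(d) <- NULL; d
    })
  truth <- list(true_node_strengths = brute_force_strengths(tables, de_mirnas),
                planted_genes = planted_genes)
  list(tables = tables, truth = truth)
}

#' Generate a qPCR Ct table with planted expression shifts
#'
#' One row per sample x gene with a target Ct and a housekeeping Ct. Genes in
#' `shifts` have the named delta-Ct added in the case arm (`de_pair[1]`): a
#' positive shift means a later crossing cycle, i.e. lower expression. The
#' housekeeping channel never shifts.
#'
#' @param config a [sim_config()].
#' @param gene_ids genes assayed.
#' @param shifts named numeric vector, gene -> planted delta-Ct in the case
#'   arm (may be empty).
#' @param groups arms assayed; defaults to the DE pair.
#' @return list with `ct` (data.frame sample_id, group, gene, ct_target,
#'   ct_housekeeping) and `truth` (list with `de_genes` = `shifts`).
#' @export
generate_qpcr <- function(config, gene_ids, shifts = numeric(0),
                          groups = config$de_pair) {
  stopifnot(inherits(config, "sim_config"), length(gene_ids) > 0)
  if (length(shifts) && !all(names(shifts) %in% gene_ids))
    stop("shifted genes must be among gene_ids")
  set.seed(config$seed + 2L)
  samples <- sim_sample_frame(config)
  samples <- samples[samples$group %in% groups, , drop = FALSE]
  base_ct <- stats::setNames(stats::runif(length(gene_ids), 22, 28), gene_ids)
  grid <- expand.grid(sample_id = samples$sample_id, gene = gene_ids,
                      stringsAsFactors = FALSE)
  grid$group <- samples$group[match(grid$sample_id, samples$sample_id)]
  shift <- ifelse(grid$group == config$de_pair[1] & grid$gene %in% names(shifts),
                  shifts[grid$gene], 0)
  grid$ct_target <- base_ct[grid$gene] + shift +
    stats::rnorm(nrow(grid), 0, config$qpcr_noise_sd)
  grid$ct_housekeeping <- 18 +
    stats::rnorm(nrow(grid), 0, config$qpcr_noise_sd / 2)
  ct <- grid[, c("sample_id", "group", "gene", "ct_target", "ct_housekeeping")]
  list(ct = ct, truth = list(de_genes = shifts))
}

#' Reference group means for the echo generator
#'
#' Published week-6 and week-12 group means (and SEMs) for the abdominal
#' aortic-banding rat model: body weight, heart rate, wall thicknesses,
#' chamber diameters and chamber volumes per arm. Long-axis lengths are not
#' tabulated in the source and are back-solved from the volume and diameter
#' means under the ellipsoid model. Necropsy means (heart/lung weight, tibial
#' length) are plausible values for 12-week-old Sprague-Dawley rats, chosen
#' so the heart-failure arm shows pulmonary congestion; they are synthetic.
#'
#' @return data.frame with columns group, week, variable, mean, sem.
#' @export
echo_reference_means <- function() {
  # variable, Sham / AB_LVH / AB_HF means (sem) at week 6 then week 12
  w <- function(week, group, ...) {
    v <- c(...)
    data.frame(group = group, week = week,
               variable = names(v)[c(TRUE, FALSE)],
               mean = unname(v[c(TRUE, FALSE)]),
               sem = unname(v[c(FALSE, TRUE)]),
               stringsAsFactors = FALSE)
  }
  rbind(
    w(6, "Sham",  body_weight = 460, 13, heart_rate = 360, 9,
      AWTd = 1.92, 0.07, AWTs = 3.44, 0.08, LVEDD = 8.05, 0.16,
      LVESD = 4.68, 0.19, PWTd = 2.00, 0.08, PWTs = 3.24, 0.08,
      LVEDV = 460, 14, LVESV = 202, 14),
    w(6, "AB_LVH", body_weight = 480, 9, heart_rate = 349, 19,
      AWTd = 2.55, 0.10, AWTs = 4.50, 0.21, LVEDD = 8.56, 0.14,
      LVESD = 4.97, 0.20, PWTd = 2.73, 0.09, PWTs = 4.24, 0.10,
      LVEDV = 518, 27, LVESV = 243, 21),
    w(6, "AB_HF", body_weight = 450, 15, heart_rate = 365, 16,
      AWTd = 2.69, 0.11, AWTs = 3.84, 0.12, LVEDD = 8.71, 0.27,
      LVESD = 6.14, 0.45, PWTd = 2.60, 0.12, PWTs = 3.53, 0.21,
      LVEDV = 551, 48, LVESV = 369, 52),
    w(12, "Sham", body_weight = 549, 14, heart_rate = 356, 14,
      AWTd = 1.99, 0.06, AWTs = 3.57, 0.11, LVEDD = 8.32, 0.13,
      LVESD = 4.83, 0.12, PWTd = 2.00, 0.07, PWTs = 3.19, 0.10,
      LVEDV = 511, 25, LVESV = 211, 10),
    w(12, "AB_LVH", body_weight = 576, 12, heart_rate = 353, 8,
      AWTd = 2.65, 0.05, AWTs = 4.25, 0.12, LVEDD = 8.87, 0.15,
      LVESD = 5.53, 0.26, PWTd = 2.50, 0.05, PWTs = 4.13, 0.06,
      LVEDV = 572, 25, LVESV = 307, 21),
    w(12, "AB_HF", body_weight = 543, 23, heart_rate = 340, 13,
      AWTd = 2.78, 0.06, AWTs = 3.92, 0.09, LVEDD = 9.93, 0.46,
      LVESD = 7.59, 0.60, PWTd = 2.46, 0.11, PWTs = 3.26, 0.17,
      LVEDV = 734, 80, LVESV = 605, 69))
}

# synthetic necropsy means: g (weights) and mm (tibia)
necropsy_reference_means <- function() {
  data.frame(group = c("Sham", "AB_LVH", "AB_HF"),
             heart_weight = c(1.45, 2.25, 2.40),
             lung_weight = c(1.60, 1.75, 2.90),
             tibial_length = c(43, 43, 43),
             sem_scale = c(0.05, 0.06, 0.08),
             stringsAsFactors = FALSE)
}

#' Generate per-animal echocardiographic and necropsy measurements
#'
#' Draws every measured quantity (weights, heart rate, wall thicknesses,
#' diameters, long-axis lengths) independently from a Gaussian around its
#' group/week reference mean, with SD = SEM * sqrt(n) * `echo_noise`. Derived
#' quantities (volumes, SV, CO, EF, LV mass) are never drawn -- they are left
#' to the phenotyping stage. Long-axis lengths are back-solved from the
#' reference volume and diameter means so the ellipsoid model reproduces the
#' reference volumes at zero noise. Heart-failure animals are redrawn until
#' their week-12 measurements imply an ejection fraction below 30%.
#'
#' @param config a [sim_config()].
#' @return data.frame, one row per animal per week, with measured echo
#'   columns plus necropsy columns (week-12 rows only) and the surgery flag.
#' @export
generate_echo <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ref <- echo_reference_means()
  nec <- necropsy_reference_means()
  samples <- sim_sample_frame(config)
  if (nrow(samples) == 0) {
    return(data.frame(animal_id = character(0), group = character(0),
                      week = integer(0)))
  }
  draw_row <- function(group, week, n_arm) {
    r <- ref[ref$group == group & ref$week == week, ]
    m <- stats::setNames(r$mean, r$variable)
    s <- stats::setNames(r$sem, r$variable) * sqrt(n_arm) * config$echo_noise
    la_d <- 6 * m[["LVEDV"]] / (pi * m[["LVEDD"]]^2)
    la_s <- 6 * m[["LVESV"]] / (pi * m[["LVESD"]]^2)
    repeat {
      v <- stats::rnorm(length(m), m, s)
      names(v) <- names(m)
      v["long_axis_d"] <- stats::rnorm(1, la_d, 0.3 * config$echo_noise)
      v["long_axis_s"] <- stats::rnorm(1, la_s, 0.3 * config$echo_noise)
      v <- v[setdiff(names(v), c("LVEDV", "LVESV"))]
      if (any(v <= 0)) next
      edv <- pi / 6 * v["long_axis_d"] * v["LVEDD"]^2
      esv <- pi / 6 * v["long_axis_s"] * v["LVESD"]^2
      ef <- 100 * (edv - esv) / edv
      ok <- if (week == 12 && group == "AB_HF") ef < 30
            else if (week == 12 && group == "AB_LVH") ef >= 30
            else TRUE
      if (ok) return(v)
    }
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    g <- samples$group[i]
    n_arm <- config$n_per_group[[g]]
    do.call(rbind, lapply(c(6, 12), function(wk) {
      v <- draw_row(g, wk, n_arm)
      out <- data.frame(animal_id = samples$sample_id[i], group = g,
                        week = wk, surgery = if (g == "Sham") "sham" else "AB",
                        t(v), stringsAsFactors = FALSE)
      if (wk == 12) {
        nr <- nec[nec$group == g, ]
        sdm <- nr$sem_scale * sqrt(n_arm) * config$echo_noise
        out$heart_weight <- max(stats::rnorm(1, nr$heart_weight, sdm), 0.1)
        out$lung_weight <- max(stats::rnorm(1, nr$lung_weight, sdm), 0.1)
        out$tibial_length <- max(stats::rnorm(1, nr$tibial_length, 5 * sdm), 1)
      } else {
        out$heart_weight <- NA_real_
        out$lung_weight <- NA_real_
        out$tibial_length <- NA_real_
      }
      out
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Run every generator and collect inputs plus ground truth
#'
#' Convenience wrapper producing all pipeline inputs from one config: counts,
#' interaction tables, echo table, and a qPCR panel over the genes selected
#' by `qpcr_genes` with shifts `qpcr_shifts`.
#'
#' @param config a [sim_config()].
#' @param planted passed to [generate_interactions()].
#' @param qpcr_genes genes to assay by qPCR (default none -> no Ct table).
#' @param qpcr_shifts named delta-Ct shifts planted in the case arm.
#' @return list with `counts`, `samples`, `interactions`, `echo`, `qpcr`
#'   (NULL if no genes), and `truth` (de_mirnas, true_node_strengths,
#'   planted_genes, de_genes).
#' @export
simulate_study <- function(config, planted = NULL, qpcr_genes = character(0),
                           qpcr_shifts = numeric(0)) {
  cnt <- generate_counts(config)
  gene_ids <- sim_gene_ids(config$n_genes)
  inter <- generate_interactions(config, rownames(cnt$counts), gene_ids,
                                 cnt$truth$de_mirnas, planted = planted)
  echo <- generate_echo(config)
  qpcr <- if (length(qpcr_genes)) {
    generate_qpcr(config, qpcr_genes, shifts = qpcr_shifts)
  } else NULL
  list(counts = cnt$counts, samples = cnt$samples,
       interactions = inter$tables, echo = echo,
       qpcr = if (is.null(qpcr)) NULL else qpcr$ct,
       truth = c(cnt$truth, inter$truth,
                 list(de_genes = if (is.null(qpcr)) numeric(0)
                      else qpcr$truth$de_genes)))
}

#' Write a simulated study to disk as TSVs plus a manifest
#'
#' Emits counts.tsv (miRNA x sample), samples.tsv, the three interaction
#' tables, echo.tsv, qpcr.tsv (if present) and manifest.json recording the
#' config and seed so a run can be reproduced exactly.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @param config the config used, stored in the manifest.
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             validated = file.path(dir, "interactions_validated.tsv"),
             mirdb = file.path(dir, "interactions_mirdb.tsv"),
             mirsvr = file.path(dir, "interactions_mirsvr.tsv"),
             echo = file.path(dir, "echo.tsv"),
             manifest = file.path(dir, "manifest.json"))
  cnt <- data.frame(mirna_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (d in c("validated", "mirdb", "mirsvr"))
    utils::write.table(sim$interactions[[d]], paths[d], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(sim$echo, paths["echo"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sim$qpcr)) {
    paths["qpcr"] <- file.path(dir, "qpcr.tsv")
    utils::write.table(sim$qpcr, paths["qpcr"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cfg <- unclass(config)
  jsonlite::write_json(list(config = cfg, seed = config$seed,
                            files = as.list(basename(paths))),
                       paths["manifest"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
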