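test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_mirnas = 0), "n_mirnas")
  expect_error(sim_config(frac_de = 1.5))
  expect_error(sim_config(source_mix = c(a = 0.5, b = 0.4, c = 0.3)),
               "sum to 1")
  expect_error(sim_config(de_pair = c("AB_HF", "nope")), "de_pair")
  cfg <- sim_config(noise_free = TRUE)
  expect_equal(cfg$nb_dispersion, 0)
  expect_equal(cfg$qpcr_noise_sd, 0)
})

test_that("count generator plants exactly the configured signature", {
  cfg <- sim_config(n_mirnas = 200, frac_de = 0.25, seed = 3)
  g <- generate_counts(cfg)
  expect_equal(nrow(g$truth$de_mirnas), 50L)  # 50-miRNA signature
  expect_equal(ncol(g$counts), 21L)           # 8 + 8 + 5 animals
  expect_true(all(g$counts >= 0))
  expect_true(all(g$truth$de_mirnas$mirna_id %in% rownames(g$counts)))
  # direction encoded in the sign of the planted log2FC
  expect_true(all((g$truth$de_mirnas$direction == "up") ==
                  (g$truth$de_mirnas$log2fc > 0)))
  # no planting when frac_de = 0
  g0 <- generate_counts(sim_config(frac_de = 0, seed = 9))
  expect_equal(nrow(g0$truth$de_mirnas), 0L)
})

test_that("planted fold changes hold in expectation", {
  cfg <- sim_config(seed = 21, noise_free = TRUE)
  g <- generate_counts(cfg)
  case <- g$samples$group == "AB_HF"
  ref <- g$samples$group == "AB_LVH"
  for (i in sample(nrow(g$truth$de_mirnas), 10)) {
    tr <- g$truth$de_mirnas[i, ]
    obs <- mean(g$counts[tr$mirna_id, case]) /
           mean(g$counts[tr$mirna_id, ref])
    expect_equal(log2(obs), tr$log2fc, tolerance = 0.1)
  }
  # unplanted miRNAs share raw means across arms
  un <- setdiff(rownames(g$counts), g$truth$de_mirnas$mirna_id)[1:10]
  for (m in un)
    expect_equal(mean(g$counts[m, case]), mean(g$counts[m, ref]),
                 tolerance = 1)
})

test_that("all generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 1)
  s1 <- simulate_study(cfg, qpcr_genes = c("Gene0001", "Gene0002"))
  s2 <- simulate_study(cfg, qpcr_genes = c("Gene0001", "Gene0002"))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$echo, s2$echo)
  expect_identical(s1$qpcr, s2$qpcr)
  expect_identical(s1$truth, s2$truth)
})

test_that("interaction generator: empty, planted and threshold structure", {
  cfg0 <- sim_config(interactions_per_mirna = 0, seed = 2)
  de <- data.frame(mirna_id = c("m1", "m2"), direction = c("up", "down"))
  r0 <- generate_interactions(cfg0, c("m1", "m2"), c("g1", "g2"), de)
  expect_true(all(vapply(r0$tables, nrow, 1L) == 0L))
  expect_length(r0$truth$true_node_strengths, 0)
  expect_error(generate_interactions(cfg0, character(0), "g1", de),
               "length")

  # a gene wired to 7 planted-up miRNAs and nothing else: strength +7
  de7 <- data.frame(mirna_id = sprintf("m%d", 1:8),
                    direction = c(rep("up", 7), "down"))
  r7 <- generate_interactions(cfg0, de7$mirna_id, sprintf("g%d", 1:3), de7,
                              planted = list(strengths = 7, genes_each = 1))
  expect_equal(unname(r7$truth$true_node_strengths["g1"]), 7L)

  # prediction dialect scores straddle their thresholds
  cfg <- sim_config(seed = 4)
  s <- simulate_study(cfg)
  expect_true(any(s$interactions$mirdb$score > 80) &&
              any(s$interactions$mirdb$score <= 80))
  expect_true(any(s$interactions$mirsvr$mirsvr_score < -1.2) &&
              any(s$interactions$mirsvr$mirsvr_score >= -1.2))
  expect_false("score" %in% names(s$interactions$validated))
})

test_that("stored ground-truth strengths equal an independent recount", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_mirnas = 40, n_genes = 120,
                      interactions_per_mirna = 5)
    s <- simulate_study(cfg)
    up <- s$truth$de_mirnas$mirna_id[s$truth$de_mirnas$direction == "up"]
    dn <- s$truth$de_mirnas$mirna_id[s$truth$de_mirnas$direction == "down"]
    ora <- oracle_strengths(s$interactions, up, dn)
    tru <- s$truth$true_node_strengths
    expect_equal(sort(names(ora)), sort(names(tru)))
    expect_identical(ora[sort(names(ora))], tru[sort(names(tru))])
  }
})

test_that("qPCR generator plants Ct shifts only in the case arm", {
  cfg <- sim_config(seed = 6, noise_free = TRUE)
  genes <- c("gA", "gB", "gC")
  q <- generate_qpcr(cfg, genes, shifts = c(gB = 1))
  ct <- q$ct
  mean_by <- function(g, grp, col)
    mean(ct[[col]][ct$gene == g & ct$group == grp])
  # unshifted gene: identical group means at zero noise
  expect_equal(mean_by("gA", "AB_HF", "ct_target"),
               mean_by("gA", "AB_LVH", "ct_target"))
  # +1 cycle in the case arm halves relative expression exactly
  rel_hf <- 2^-(mean_by("gB", "AB_HF", "ct_target") -
                mean_by("gB", "AB_HF", "ct_housekeeping"))
  rel_ref <- 2^-(mean_by("gB", "AB_LVH", "ct_target") -
                 mean_by("gB", "AB_LVH", "ct_housekeeping"))
  expect_equal(rel_hf / rel_ref, 0.5, tolerance = 1e-12)
  # housekeeping channel never shifts
  expect_equal(mean_by("gB", "AB_HF", "ct_housekeeping"),
               mean_by("gB", "AB_LVH", "ct_housekeeping"))
  expect_error(generate_qpcr(cfg, genes, shifts = c(nope = 1)), "among")
})

test_that("echo generator honours group EF constraints and sizes", {
  cfg <- sim_config(seed = 8)
  e <- generate_echo(cfg)
  expect_equal(nrow(e), 2 * 21)
  ph <- phenotype_table(e)
  wk12 <- ph[ph$week == 12, ]
  hf <- wk12$animal_id %in% e$animal_id[e$group == "AB_HF"]
  lvh <- wk12$animal_id %in% e$animal_id[e$group == "AB_LVH"]
  expect_true(all(wk12$EF_pct[hf] < 30))
  expect_true(all(wk12$EF_pct[lvh] >= 30))
  # empty design gives an empty table
  e0 <- generate_echo(sim_config(n_per_group = c(Sham = 0L, AB_LVH = 0L,
                                                 AB_HF = 0L)))
  expect_equal(nrow(e0), 0L)
})

test_that("simulation TSV round-trip preserves the count matrix", {
  td <- withr::local_tempdir()
  cfg <- sim_config(seed = 12, n_mirnas = 30, n_genes = 40)
  s <- simulate_study(cfg)
  p <- write_simulation(s, td, cfg)
  expect_true(all(file.exists(p)))
  cnt <- read.delim(p[["counts"]], check.names = FALSE)
  m <- as.matrix(cnt[, -1]); rownames(m) <- cnt[[1]]
  storage.mode(m) <- "integer"
  expect_identical(m, s$counts)
  man <- jsonlite::read_json(p[["manifest"]])
  expect_equal(man$seed, 12L)
})
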