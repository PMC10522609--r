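test_that("2^-dCt arithmetic and housekeeping aggregation", {
  expect_equal(delta_ct(20, 20), 1)
  expect_equal(delta_ct(21, 20), 0.5)
  expect_equal(delta_ct(18, 20), 4)
  # several housekeeping wells: arithmetic mean of Ct
  expect_equal(delta_ct(20, cbind(19, 21)), 1)
  expect_error(delta_ct(Inf, 20), "finite")
  expect_error(delta_ct(20, NA), "finite")
})

test_that("reference-group normalization pins the reference mean at 1", {
  rel <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("ref", "case"), each = 3),
    gene = "g1",
    rel_expr = c(2, 2, 2, 1, 1, 1))
  out <- normalize_to_group(rel, "ref")
  expect_equal(out$rel_to_reference[out$group == "ref"], rep(1, 3))
  expect_equal(out$rel_to_reference[out$group == "case"], rep(0.5, 3))
  # invariance to a global Ct offset: shifting every well's Ct by a
  # constant multiplies rel_expr uniformly, which the ratio cancels
  rel2 <- rel; rel2$rel_expr <- rel$rel_expr * 2^-3
  out2 <- normalize_to_group(rel2, "ref")
  expect_equal(out2$rel_to_reference, out$rel_to_reference)
  expect_error(normalize_to_group(rel, "nope"), "not present")
})

test_that("qPCR comparison flags planted shifts and honours blacklists", {
  cfg <- sim_config(seed = 22, noise_free = TRUE)
  genes <- sprintf("t%02d", 1:17)
  shifts <- stats::setNames(rep(1, 5), genes[1:5])
  q <- generate_qpcr(cfg, genes, shifts = shifts)
  res <- compare_qpcr(q$ct, case_group = "AB_HF",
                      reference_group = "AB_LVH")
  cmp <- res$comparison
  expect_setequal(cmp$gene_id[cmp$observed_direction == "down"], names(shifts))
  expect_true(all(cmp$observed_direction[!cmp$gene_id %in% names(shifts)]
                  == "none"))
  # planted +1 cycle: case mean exactly half the reference at zero noise
  expect_equal(cmp$mean_case[cmp$gene_id == "t01"], 0.5, tolerance = 1e-10)
  # reference-group mean of rel_to_reference is 1 per gene
  ref_means <- tapply(
    res$expression$rel_to_reference[res$expression$group == "AB_LVH"],
    res$expression$gene[res$expression$group == "AB_LVH"], mean)
  expect_equal(as.numeric(ref_means), rep(1, 17), tolerance = 1e-12)
  # blacklisting all but one case sample makes genes untestable
  hf_ids <- unique(q$ct$sample_id[q$ct$group == "AB_HF"])
  res2 <- compare_qpcr(q$ct, "AB_HF", "AB_LVH",
                       exclude_samples = hf_ids[-1])
  expect_true(all(res2$comparison$test == "untestable"))
  expect_error(compare_qpcr(q$ct[, -4], "AB_HF", "AB_LVH"),
               "missing columns")
  expect_error(compare_qpcr(q$ct[0, ], "AB_HF", "AB_LVH"), "no samples")
})

test_that("concordance validates only significant agreement and partitions", {
  pred <- data.frame(
    gene_id = c("gDown", "gWrong", "gTrend", "gFlat", "gMissing"),
    node_strength = c(7L, 7L, 6L, 6L, 6L),
    predicted_direction = "down",
    unidirectional = TRUE,
    n_up_regulators = c(7L, 7L, 6L, 6L, 6L), n_down_regulators = 0L)
  cmp <- data.frame(
    gene_id = c("gDown", "gWrong", "gTrend", "gFlat", "gMissing"),
    mean_case = c(0.5, 2.0, 0.9, 1.05, NA),
    mean_reference = 1,
    p_value = c(0.001, 0.001, 0.40, 0.90, NA),
    test = c("t", "t", "t", "t", "untestable"),
    observed_direction = c("down", "up", "none", "none", "none"))
  cc <- concordance(pred, cmp)
  st <- stats::setNames(cc$report$status, cc$report$gene_id)
  expect_equal(unname(st["gDown"]), "validated")
  expect_equal(unname(st["gWrong"]), "discordant")  # significant, opposite
  expect_equal(unname(st["gTrend"]), "trend_only")
  expect_equal(unname(st["gFlat"]), "unchanged")
  expect_equal(unname(st["gMissing"]), "untestable")
  # summary counts partition the gene set
  expect_equal(sum(cc$summary[c("n_validated", "n_trend_only",
                                "n_unchanged", "n_discordant")]),
               unname(cc$summary["n_tested"]))
  expect_equal(unname(cc$summary["n_tested"] + cc$summary["n_untestable"]),
               nrow(cc$report))
  expect_error(concordance(pred[0, ], cmp), "no overlap")
})

test_that("planted-null qPCR yields validated fraction within alpha", {
  # no planted shifts anywhere: any validation is a false positive
  n_false <- 0L; n_total <- 0L
  for (seed in 1:12) {
    cfg <- sim_config(seed = 100 + seed)
    genes <- sprintf("n%02d", 1:17)
    q <- generate_qpcr(cfg, genes)
    res <- compare_qpcr(q$ct, "AB_HF", "AB_LVH")
    pred <- data.frame(gene_id = genes, node_strength = 6L,
                       predicted_direction = "down")
    cc <- concordance(pred, res$comparison)
    n_false <- n_false + cc$summary[["n_validated"]]
    n_total <- n_total + cc$summary[["n_tested"]]
  }
  # one-sided binomial bound at alpha = 0.05
  expect_lte(n_false, qbinom(0.995, n_total, 0.05))
})
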