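test_that("dialect readers apply strict score thresholds", {
  td <- withr::local_tempdir()
  mdb <- write_tsv_fixture(
    data.frame(mirna = paste0("m", 1:4), gene = paste0("g", 1:4),
               score = c(80.0, 80.01, 95, 12)),
    file.path(td, "mirdb.tsv"))
  got <- read_interactions(mdb, "mirdb")
  expect_setequal(got$mirna, c("m2", "m3"))  # 80.0 out, 80.01 in
  msv <- write_tsv_fixture(
    data.frame(mirna = paste0("m", 1:4), gene = paste0("g", 1:4),
               mirsvr_score = c(-1.2, -1.21, -0.3, -2.0)),
    file.path(td, "mirsvr.tsv"))
  got2 <- read_interactions(msv, "mirsvr")
  expect_setequal(got2$mirna, c("m2", "m4"))  # -1.2 out, -1.21 in
  val <- write_tsv_fixture(
    data.frame(mirna = "m1", gene = "g1", evidence = "Western blot"),
    file.path(td, "validated.tsv"))
  got3 <- read_interactions(val, "validated")
  expect_equal(nrow(got3), 1)
  expect_true(is.na(got3$score))
})

test_that("malformed rows are skipped with a warning, files must exist", {
  td <- withr::local_tempdir()
  bad <- write_tsv_fixture(
    data.frame(mirna = c("m1", "", "m3"), gene = c("g1", "g2", "g3"),
               score = c(90, 95, NA)),
    file.path(td, "bad.tsv"))
  expect_warning(got <- read_interactions(bad, "mirdb"), "malformed")
  expect_equal(got$mirna, "m1")
  expect_error(read_interactions(file.path(td, "nope.tsv"), "mirdb"),
               "no such file")
  nos <- write_tsv_fixture(data.frame(mirna = "m", gene = "g"),
                           file.path(td, "noscore.tsv"))
  expect_error(read_interactions(nos, "mirdb"), "score")
})

test_that("network construction: weights, dedup, exclusions, matching", {
  signed <- signed_mirna_set(up = c("rno-miR-10a", "rno-miR-20b"),
                             down = "rno-miR-30c")
  ia <- data.frame(
    mirna = c("rno-miR-10a", "RNO-MIR-10A", "rno-miR-20b", "rno-miR-30c",
              "rno-miR-99x"),
    gene = c("G1", "G1", "G1", "G2", "G3"),
    source = c("validated", "mirdb", "mirsvr", "validated", "validated"),
    score = NA_real_, stringsAsFactors = FALSE)
  net <- build_network(signed, ia)
  # duplicate pair (case-insensitive match) collapsed, provenance merged
  e_g1 <- net$edges[net$edges$gene == "G1", ]
  expect_equal(nrow(e_g1), 2)
  up_edge <- e_g1[e_g1$mirna == "rno-miR-10a", ]
  expect_equal(up_edge$weight, 1L)
  expect_equal(up_edge$sources, "mirdb,validated")
  # down miRNA contributes -1
  expect_equal(net$edges$weight[net$edges$gene == "G2"], -1L)
  # gene targeted only by a non-signed miRNA is absent
  expect_false("G3" %in% net$genes)
  # empty interactions: miRNA nodes only
  net0 <- build_network(signed, ia[0, ])
  expect_equal(nrow(net0$edges), 0)
  expect_length(net0$genes, 0)
  expect_length(net0$mirna_direction, 3)
  expect_error(build_network(signed_mirna_set(), ia), "empty")
})

test_that("intersection mode keeps only pairs in every source", {
  signed <- signed_mirna_set(up = "m1")
  ia <- data.frame(mirna = "m1", gene = c("gA", "gA", "gB"),
                   source = c("validated", "mirdb", "mirdb"),
                   score = NA_real_)
  net_u <- build_network(signed, ia, mode = "union", species = "")
  net_i <- build_network(signed, ia, mode = "intersection", species = "")
  expect_setequal(net_u$genes, c("gA", "gB"))
  expect_setequal(net_i$genes, "gA")
})

test_that("node strengths: signs, cancellation, ordering", {
  up7 <- sprintf("u%d", 1:7)
  signed <- signed_mirna_set(up = c(up7, "u8"), down = sprintf("d%d", 1:3))
  ia <- rbind(
    data.frame(mirna = up7, gene = "hit7", source = "validated",
               score = NA_real_),
    data.frame(mirna = c("u8", sprintf("d%d", 1:3)),
               gene = c("mix", "mix", "mix", "bal"),
               source = "validated", score = NA_real_),
    data.frame(mirna = "u8", gene = "bal", source = "validated",
               score = NA_real_))
  ns <- node_strengths(build_network(signed, ia, species = ""))
  rownames(ns) <- ns$gene_id
  # seven same-direction regulators: +7, predicted downregulation
  expect_equal(ns["hit7", "node_strength"], 7L)
  expect_equal(ns["hit7", "predicted_direction"], "down")
  expect_true(ns["hit7", "unidirectional"])
  # 1 up + 2 down = -1, mixed
  expect_equal(ns["mix", "node_strength"], -1L)
  expect_false(ns["mix", "unidirectional"])
  expect_equal(ns["mix", "predicted_direction"], "up")
  # 1 up + 1 down cancels: ambiguous
  expect_equal(ns["bal", "node_strength"], 0L)
  expect_equal(ns["bal", "predicted_direction"], "ambiguous")
  # sorted by |strength| descending, lexicographic within ties
  expect_equal(ns$gene_id[1], "hit7")
  expect_equal(order(-abs(ns$node_strength), ns$gene_id),
               seq_len(nrow(ns)))
})

test_that("strengths equal the brute-force oracle on random fixtures", {
  for (seed in 1:30) {
    fx <- random_network_fixture(seed)
    net <- build_network(fx$signed, fixture_to_interactions(fx$tables))
    ns <- node_strengths(net)
    ora <- oracle_strengths(fx$tables, fx$signed$up, fx$signed$down)
    ora <- ora[ora != 0 | names(ora) %in% ns$gene_id]
    got <- stats::setNames(ns$node_strength, ns$gene_id)
    expect_identical(got[sort(names(got))], ora[sort(names(ora))])
    # |strength| <= degree with equality iff unidirectional
    deg <- table(net$edges$gene)
    expect_true(all(abs(ns$node_strength) <=
                    as.integer(deg[ns$gene_id])))
    expect_equal(abs(ns$node_strength) == as.integer(deg[ns$gene_id]),
                 ns$unidirectional)
  }
})

test_that("flipping every miRNA direction negates every strength", {
  fx <- random_network_fixture(99)
  ia <- fixture_to_interactions(fx$tables)
  ns <- node_strengths(build_network(fx$signed, ia))
  flipped <- signed_mirna_set(up = fx$signed$down, down = fx$signed$up)
  ns_f <- node_strengths(build_network(flipped, ia))
  m <- match(ns$gene_id, ns_f$gene_id)
  expect_identical(ns_f$node_strength[m], -ns$node_strength)
})

test_that("restricting the signed set never increases regulator counts", {
  fx <- random_network_fixture(123)
  ia <- fixture_to_interactions(fx$tables)
  full <- node_strengths(build_network(fx$signed, ia))
  sub <- signed_mirna_set(up = fx$signed$up[1:3],
                          down = fx$signed$down[seq_len(min(2,
                            length(fx$signed$down)))])
  part <- node_strengths(build_network(sub, ia))
  m <- match(part$gene_id, full$gene_id)
  expect_true(all(part$n_up_regulators <= full$n_up_regulators[m]))
  expect_true(all(part$n_down_regulators <= full$n_down_regulators[m]))
})

test_that("target selection builds disjoint tiers with seeded sampling", {
  ns <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    node_strength = c(rep(7L, 4), rep(6L, 10), rep(3L, 4), 2L, 1L),
    n_up_regulators = c(rep(7L, 4), rep(6L, 10), rep(3L, 4), 3L, 2L),
    n_down_regulators = c(rep(0L, 18), 1L, 1L),
    predicted_direction = "down",
    unidirectional = c(rep(TRUE, 18), FALSE, FALSE))
  sel <- select_targets(ns, unidirectional_strength = 6,
                        n_random_strong = 4, strong_floor = 2, seed = 3)
  expect_equal(sum(sel$tier == 1), 4)   # all genes at maximal |strength|
  expect_equal(sum(sel$tier == 2), 10)  # unidirectional at strength 6
  expect_equal(sum(sel$tier == 3), 4)
  expect_equal(anyDuplicated(sel$gene_id), 0)
  sel2 <- select_targets(ns, unidirectional_strength = 6,
                         n_random_strong = 4, strong_floor = 2, seed = 3)
  expect_identical(sel, sel2)
  # no random tier when n = 0
  sel0 <- select_targets(ns, unidirectional_strength = 6)
  expect_equal(sum(sel0$tier == 3), 0)
  expect_warning(selw <- select_targets(ns, unidirectional_strength = 99),
                 "exceeds")
  expect_equal(sum(selw$tier == 2), 0)
  expect_error(select_targets(ns[0, ]), "empty")
})

test_that("exports: SIF lines, GraphML attributes, TSV round-trip", {
  td <- withr::local_tempdir()
  signed <- signed_mirna_set(up = "rno-miR-1", down = "rno-miR-2")
  ia <- data.frame(mirna = c("rno-miR-1", "rno-miR-2"),
                   gene = c("gA", "gB"),
                   source = c("validated", "mirdb"), score = NA_real_)
  net <- build_network(signed, ia)
  sif <- file.path(td, "net.sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 2)
  gml <- file.path(td, "net.graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_setequal(igraph::E(g)$weight, c(1, -1))
  expect_true("direction" %in% igraph::vertex_attr_names(g))
  tsv <- file.path(td, "net.tsv")
  export_network(net, tsv, "tsv")
  back <- import_network_edges(tsv, signed)
  expect_identical(node_strengths(back), node_strengths(net))
  expect_identical(back$edges$sources, net$edges$sources)
  expect_error(export_network(net, tsv, "gexf"))
  # empty network exports a header-only edge list
  net0 <- build_network(signed, ia[0, ])
  export_network(net0, tsv, "tsv")
  expect_length(readLines(tsv), 1)
  expect_identical(nrow(import_network_edges(tsv, signed)$edges), 0L)
})
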