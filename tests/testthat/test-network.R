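make_grouping <- function() {
  c(a = "Coding", b = "Coding", c = "Coding",
    x = "Noncoding", y = "Noncoding")
}

test_that("enumerate_pairs counts group-pair combinations", {
  grp <- make_grouping()
  expect_equal(nrow(enumerate_pairs(grp, "Coding|Noncoding")), 6L)
  expect_equal(nrow(enumerate_pairs(grp, "Coding|Coding")), 3L)
  all3 <- enumerate_pairs(grp, c("Coding|Coding", "Coding|Noncoding",
                                 "Noncoding|Noncoding"))
  expect_equal(nrow(all3), choose(5, 2))
  expect_equal(nrow(enumerate_pairs(grp, "all")), choose(5, 2))
  # canonical ordering and deterministic output
  expect_true(all(all3$gene1 < all3$gene2))
  expect_identical(all3, enumerate_pairs(grp, "all"))
  expect_error(enumerate_pairs(grp, character()), "empty")
  # list-of-pairs form
  expect_equal(nrow(enumerate_pairs(grp, list(c("Noncoding", "Coding")))),
               6L)
})

test_that("compute_measures is deterministic across worker counts", {
  fx <- generate_fixture(fixture_spec(n_samples = 20L, n_mirnas = 10L,
                                      n_coding = 12L, n_noncoding = 4L,
                                      n_planted_triads = 4L, seed = 5L))
  grp <- assign_groups(fx$annotation, "biotype",
                       c(protein_coding = "Coding"), "Noncoding")
  pairs <- enumerate_pairs(grp, "all")[1:50, ]
  t1 <- suppressMessages(compute_measures(
    pairs, fx$cerna_expr, fx$mirna_expr, fx$interactions,
    measures = c("MS", "PCC", "MI", "CMI", "LA"), workers = 1L))
  t4 <- suppressMessages(compute_measures(
    pairs, fx$cerna_expr, fx$mirna_expr, fx$interactions,
    measures = c("MS", "PCC", "MI", "CMI", "LA"), workers = 4L))
  expect_identical(t1, t4)
})

test_that("compute_measures populates only the selected measures", {
  inp <- tiny_inputs()
  grp <- assign_groups(inp$annotation, "biotype",
                       c(protein_coding = "Coding"), "Noncoding")
  pairs <- enumerate_pairs(grp, "all")
  tab <- suppressMessages(compute_measures(
    pairs, inp$cerna_expr, inp$mirna_expr, inp$interactions,
    measures = "PCC"))
  expect_true("PCC" %in% colnames(tab))
  expect_false(any(c("MS", "MI", "CMI", "LA") %in% colnames(tab)))
  expect_error(compute_measures(pairs, inp$cerna_expr, inp$mirna_expr,
                                inp$interactions, measures = "XXX"),
               "unknown measure")
})

test_that("pairs sharing no miRNA get NA CMI/LA", {
  inp <- tiny_inputs()
  grp <- setNames(rep("All", 4), rownames(inp$cerna_expr))
  pairs <- enumerate_pairs(grp, "all")
  tab <- suppressMessages(compute_measures(
    pairs, inp$cerna_expr, inp$mirna_expr, inp$interactions,
    measures = c("MS", "CMI", "LA")))
  # A-B share m1, m2; every pair involving C or L shares nothing
  ab <- tab$gene1 == "A" & tab$gene2 == "B"
  expect_false(is.na(tab$CMI[ab]))
  expect_true(all(is.na(tab$CMI[!ab])))
  expect_true(all(is.na(tab$LA[!ab])))
  expect_true(all(tab$MS[tab$t == 0] == 1))
})

test_that("user measure hooks add columns", {
  inp <- tiny_inputs()
  grp <- setNames(rep("All", 4), rownames(inp$cerna_expr))
  pairs <- enumerate_pairs(grp, "all")
  tab <- suppressMessages(compute_measures(
    pairs, inp$cerna_expr, inp$mirna_expr, inp$interactions,
    measures = "MS",
    hooks = list(TSUM = function(x, y, ctx) ctx$t + 0)))
  expect_equal(tab$TSUM, as.numeric(tab$t))
})

test_that("measure_density bins per group pair and sums to the row count", {
  tab <- data.frame(gene1 = letters[1:6], gene2 = LETTERS[1:6],
                    group_pair = rep(c("G|G", "G|H"), each = 3),
                    PCC = c(0.1, 0.1, 0.1, 0, 0.5, 1))
  d <- measure_density(tab, "PCC", breaks = 5)
  expect_setequal(unique(d$group_pair), c("G|G", "G|H"))
  expect_equal(sum(d$count), 6)
  # single spike: all mass in one bin
  spike <- measure_density(tab[1:3, ], "PCC", breaks = 5)
  expect_equal(sum(spike$count > 0), 1L)
  expect_error(measure_density(tab, "MI"), "not present")
})

test_that("apply_thresholds keeps exactly the strictly-passing rows", {
  tab <- data.frame(
    gene1 = paste0("g", 1:5), gene2 = paste0("h", 1:5),
    group_pair = c("C|C", "C|C", "C|N", "C|N", "N|N"),
    MS = c(0.01, 0.20, 0.04, 0.05, 0.001),
    PCC = c(0.60, 0.70, 0.50, 0.90, 0.48))
  specs <- list(threshold_spec("MS", "lt", 0.05, "all"),
                threshold_spec("PCC", "gt", 0.48, "all"))
  kept <- apply_thresholds(tab, specs)
  # row 1: pass/pass; row 2: MS fails; row 3: pass; row 4: MS == 0.05
  # fails (strict); row 5: PCC == 0.48 fails (strict)
  expect_identical(kept$gene1, c("g1", "g3"))

  # group-pair-specific spec only constrains matching rows
  gp_specs <- list(threshold_spec("PCC", "gt", 0.65, "C|C"))
  expect_identical(apply_thresholds(tab, gp_specs)$gene1,
                   c("g2", "g3", "g4", "g5"))

  expect_identical(apply_thresholds(tab, list()), tab)
  expect_error(apply_thresholds(tab, list(threshold_spec("LA", "gt", 0))),
               "uncomputed")
  expect_error(
    apply_thresholds(tab, list(threshold_spec("MS", "lt", 0.05),
                               threshold_spec("MS", "lt", 0.01))),
    "duplicate")
  # NA value for a thresholded measure fails
  tab_na <- tab
  tab_na$PCC[1] <- NA
  expect_identical(apply_thresholds(tab_na, specs)$gene1, "g3")
})

test_that("tightening any threshold never adds an edge", {
  set.seed(9)
  tab <- data.frame(
    gene1 = sprintf("a%03d", 1:200), gene2 = sprintf("b%03d", 1:200),
    group_pair = sample(c("C|C", "C|N"), 200, replace = TRUE),
    MS = runif(200), PCC = runif(200, -1, 1))
  base <- list(threshold_spec("MS", "lt", 0.5),
               threshold_spec("PCC", "gt", 0))
  kept0 <- apply_thresholds(tab, base)
  for (dm in seq(0.05, 0.45, by = 0.1)) {
    tighter <- list(threshold_spec("MS", "lt", 0.5 - dm),
                    threshold_spec("PCC", "gt", 0))
    expect_true(all(apply_thresholds(tab, tighter)$gene1 %in% kept0$gene1))
    tighter2 <- list(threshold_spec("MS", "lt", 0.5),
                     threshold_spec("PCC", "gt", dm))
    expect_true(all(apply_thresholds(tab, tighter2)$gene1 %in%
                      kept0$gene1))
  }
})

test_that("adjust_measure adds a per-group-pair BH column", {
  tab <- data.frame(gene1 = paste0("g", 1:6), gene2 = paste0("h", 1:6),
                    group_pair = rep(c("C|C", "C|N"), each = 3),
                    MS = c(0.01, 0.02, 0.03, 0.2, 0.4, 0.6))
  adj <- adjust_measure(tab, "MS")
  expect_true("MS_adj" %in% colnames(adj))
  for (gp in unique(tab$group_pair)) {
    i <- tab$group_pair == gp
    expect_equal(adj$MS_adj[i], p.adjust(tab$MS[i], "BH"))
  }
  # adjusted column is thresholdable like any measure
  kept <- apply_thresholds(adj, list(threshold_spec("MS_adj", "lt",
                                                    0.05)))
  expect_true(all(kept$MS_adj < 0.05))
  expect_error(adjust_measure(tab, "PCCX"), "not present")
})

test_that("build_network keeps isolated nodes and collapses duplicates", {
  edges <- data.frame(gene1 = c("a", "b", "a"), gene2 = c("b", "a", "b"),
                      group_pair = "G|G", t = 1L, shared_mirnas = "m1",
                      PCC = 0.9)
  net <- suppressMessages(build_network(edges, all_nodes = c("a", "b",
                                                             "c")))
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 1L)  # duplicates collapsed
  s <- summarize_network(net)
  expect_equal(s, list(n_connected_nodes = 2L, n_isolated_nodes = 1L,
                       n_edges = 1L, n_components = 1L))

  empty <- build_network(edges[0, ], all_nodes = letters[1:4])
  expect_equal(summarize_network(empty),
               list(n_connected_nodes = 0L, n_isolated_nodes = 4L,
                    n_edges = 0L, n_components = 0L))
})

test_that("summarize_network counts components among connected nodes", {
  # two disjoint triangles + 1 isolate -> (6, 1, 6, 2)
  edges <- data.frame(
    gene1 = c("a", "a", "b", "x", "x", "y"),
    gene2 = c("b", "c", "c", "y", "z", "z"))
  net <- build_network(edges, all_nodes = c(letters[1:3], "x", "y", "z",
                                            "iso"))
  expect_equal(summarize_network(net),
               list(n_connected_nodes = 6L, n_isolated_nodes = 1L,
                    n_edges = 6L, n_components = 2L))
  # path of 4 -> (4, 0, 3, 1)
  path4 <- build_network(data.frame(gene1 = c("a", "b", "c"),
                                    gene2 = c("b", "c", "d")))
  expect_equal(summarize_network(path4),
               list(n_connected_nodes = 4L, n_isolated_nodes = 0L,
                    n_edges = 3L, n_components = 1L))
})

test_that("network exports round-trip through GraphML", {
  edges <- data.frame(gene1 = "a", gene2 = "b", group_pair = "G|G",
                      t = 2L, shared_mirnas = "m1;m2", PCC = 0.7)
  net <- build_network(edges, all_nodes = c("a", "b", "c"),
                       grouping = c(a = "G", b = "G", c = "H"))
  td <- withr::local_tempdir()
  paths <- export_network(net, file.path(td, "net"))
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(paths[1], format = "graphml")
  expect_equal(igraph::vcount(back), 3L)
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  expect_equal(igraph::E(back)$PCC, 0.7)
})
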