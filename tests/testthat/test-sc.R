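test_that("enrichment score follows the pct.1/pct.2 conventions", {
  expect_equal(enrichment_score(0.8, 0.2), 4)
  expect_equal(enrichment_score(0.5, 0.5), 1)
  expect_equal(enrichment_score(0.3, 0), Inf)
  expect_equal(enrichment_score(0, 0), 0)
  expect_equal(enrichment_score(0, 0.4), 0)
  expect_error(enrichment_score(1.2, 0.5), "\\[0, 1\\]")
  expect_error(enrichment_score(0.5, -0.1), "\\[0, 1\\]")
  # scale invariance within [0,1]
  set.seed(13)
  p1 <- runif(50, 0.01, 0.5); p2 <- runif(50, 0.01, 0.5)
  k <- runif(50, 0.1, 2)
  ok <- p1 * k <= 1 & p2 * k <= 1
  expect_equal(enrichment_score(p1[ok] * k[ok], p2[ok] * k[ok]),
               enrichment_score(p1[ok], p2[ok]))
})

test_that("compute_pcts equals brute-force per-cell counting", {
  dm0 <- detection_matrix(
    matrix(c(TRUE, TRUE, FALSE, FALSE), ncol = 1,
           dimnames = list(NULL, "G")),
    c("c1", "c1", "c2", "c2"))
  expect_equal(compute_pcts(dm0, "G", "c1"), c(pct1 = 1, pct2 = 0))
  # 3 clusters with per-cluster fractions (0.5, 0.2, 0.8):
  # pct2 for cluster a = mean(0.2, 0.8) = 0.5
  det <- matrix(c(rep(c(TRUE, FALSE), 5),               # a: 5/10
                  rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2),  # b: 2/10
                  rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2)),    # c: 8/10
                ncol = 1, dimnames = list(NULL, "G"))
  dm1 <- detection_matrix(det, rep(c("a", "b", "c"), each = 10))
  expect_equal(compute_pcts(dm1, "G", "a"), c(pct1 = 0.5, pct2 = 0.5))
  expect_equal(compute_pcts(dm1, "G", "a", other = "pooled"),
               c(pct1 = 0.5, pct2 = 0.5))
  # randomized matrices, every (gene, cluster), both pct2 modes, exact
  set.seed(41)
  for (rep_i in 1:5) {
    n_cells <- sample(30:80, 1)
    genes <- paste0("g", 1:4)
    det <- matrix(runif(n_cells * 4) < runif(1, 0.1, 0.9), ncol = 4,
                  dimnames = list(NULL, genes))
    cl <- sample(c("x", "y", "z"), n_cells, replace = TRUE)
    while (length(unique(cl)) < 3) cl <- sample(c("x", "y", "z"), n_cells,
                                                replace = TRUE)
    dm <- detection_matrix(det, cl)
    for (g in genes) for (c0 in c("x", "y", "z")) {
      expect_identical(compute_pcts(dm, g, c0),
                       brute_pcts(det, cl, g, c0))
      expect_identical(compute_pcts(dm, g, c0, other = "pooled"),
                       brute_pcts(det, cl, g, c0, pooled = TRUE))
    }
  }
  expect_error(compute_pcts(dm0, "NOPE", "c1"), "unknown gene")
  expect_error(compute_pcts(dm0, "G", "c9"), "unknown or empty cluster")
})

test_that("marker tables derived from a matrix carry exact pcts", {
  set.seed(8)
  det <- matrix(runif(200) < 0.4, ncol = 4,
                dimnames = list(NULL, paste0("g", 1:4)))
  dm <- detection_matrix(det, rep(c("0", "1"), 25))
  mk <- marker_table_from_matrix(dm)
  for (i in seq_len(nrow(mk))) {
    expect_equal(unname(unlist(mk[i, c("pct1", "pct2")])),
                 unname(brute_pcts(det, dm$clusters, mk$gene_id[i],
                                   mk$cluster_id[i])))
  }
  expect_true(all(mk$p_adj >= 0 & mk$p_adj <= 1))
})

test_that("marker-set annotation takes the argmax with overrides and ties", {
  mk <- make_markers(
    list("C1QA", "2", 0.9, 0.1), list("C1QB", "2", 0.8, 0.1),
    list("GAP43", "2", 0.1, 0.5),
    list("C1QA", "0", 0.05, 0.6), list("GAP43", "0", 0.9, 0.1),
    list("C1QA", "17", 0.2, 0.2), list("GAP43", "17", 0.2, 0.2)
  )
  sets <- list(TAM = c("C1QA", "C1QB"), malignant = "GAP43")
  ann <- annotate_clusters_by_markers(mk, sets)
  expect_equal(ann$cell_type[ann$cluster_id == "2"], "TAM")
  expect_equal(ann$cell_type[ann$cluster_id == "0"], "malignant")
  # explicit override wins regardless of scores
  ann2 <- annotate_clusters_by_markers(mk, sets,
                                       overrides = c("17" = "T_cell"))
  expect_equal(ann2$cell_type[ann2$cluster_id == "17"], "T_cell")
  # tied mean scores break lexicographically (malignant < TAM); cluster 17
  # has identical stats for both sets' present genes
  expect_equal(ann$cell_type[ann$cluster_id == "17"], "malignant")
  # cluster with no marker present -> other, with a warning
  mk3 <- dplyr::bind_rows(mk, make_markers(list("BG1", "5", 0.5, 0.5)))
  expect_warning(ann3 <- annotate_clusters_by_markers(
    mk3[mk3$cluster_id == "5", ], sets), "assigned 'other'")
  expect_equal(ann3$cell_type, "other")
  expect_error(annotate_clusters_by_markers(mk, list(TAM = character())),
               "non-empty")
  expect_error(annotate_clusters_by_markers(
    mk, list(TAM = "C1QA", malignant = "C1QA")), "disjoint")
})

test_that("TAM predominance is the argmax cluster's annotation", {
  mk <- make_markers(
    list("BIGH3", "2", 0.9, 0.15),  # enrichment 6 in TAM cluster
    list("BIGH3", "0", 0.3, 0.25),  # enrichment 1.2 in malignant
    list("GAP43", "0", 0.8, 0.1)
  )
  ann <- make_annotation(c("0", "2"), c("malignant", "TAM"))
  got <- tam_predominant("BIGH3", mk, ann)
  expect_true(got$tam_predominant)
  expect_equal(got$best_cluster, "2")
  expect_equal(got$enrichment, 6)
  got2 <- tam_predominant("GAP43", mk, ann)
  expect_false(got2$tam_predominant)
  expect_equal(got2$best_cluster, "0")
  expect_message(got3 <- tam_predominant("ABSENT", mk, ann), "absent")
  expect_false(got3$tam_predominant)
  expect_true(is.na(got3$best_cluster))
  # invariant to row order of the marker table
  set.seed(2)
  for (i in 1:5) {
    shuf <- mk[sample(nrow(mk)), ]
    expect_identical(tam_predominant("BIGH3", shuf, ann), got)
  }
  # argmax ties: higher pct1 wins, then lower cluster id
  tie <- make_markers(list("L", "3", 0.8, 0.2), list("L", "1", 0.4, 0.1))
  ann_t <- make_annotation(c("1", "3"), c("TAM", "TAM"))
  expect_equal(tam_predominant("L", tie, ann_t)$best_cluster, "3")
  tie2 <- make_markers(list("L", "3", 0.4, 0.1), list("L", "1", 0.4, 0.1))
  expect_equal(tam_predominant("L", tie2, ann_t)$best_cluster, "1")
})

test_that("ontogeny calls compare max enrichment across BMD and microglia", {
  ann <- make_annotation(c("2", "6", "0"), c("TAM", "TAM", "malignant"),
                         c("BMD", "microglia", NA))
  mk <- make_markers(
    list("BIGH3", "2", 0.9, 0.15),  # BMD enrichment 6
    list("BIGH3", "6", 0.2, 0.2),   # microglia enrichment 1
    list("MIXED", "2", 0.4, 0.2), list("MIXED", "6", 0.4, 0.2)
  )
  expect_equal(ontogeny_call("BIGH3", mk, ann), "BMD")
  expect_equal(ontogeny_call("MIXED", mk, ann), "mixed")
  mic <- make_markers(list("X", "2", 0.1, 0.2), list("X", "6", 0.9, 0.1))
  expect_equal(ontogeny_call("X", mic, ann), "microglia")
  no_onto <- make_annotation("2", "TAM")
  expect_error(ontogeny_call("BIGH3", mk, no_onto), "ontogeny")
})

test_that("DEG filtering keeps |lfc| >= 1 (inclusive) at padj < 0.05 (strict)", {
  degs <- tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E"),
    log2_fc = c(1.0, 0.99, -1.5, 3, 2),
    p_adj = c(0.049, 0.001, 0.01, 0.05, 0.2)
  )
  kept <- filter_degs(degs)
  expect_equal(kept$gene_id, c("A", "C"))  # D fails strict padj, E fails padj
  expect_equal(nrow(filter_degs(degs[0, ])), 0)
})

test_that("BMD DEG ranking orders by effect size with deterministic ties", {
  degs <- tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E"),
    log2_fc = c(3, 2, 0.5, 2, -4),
    p_adj = c(1e-5, 1e-5, 1e-9, 1e-7, 1e-9)
  )
  expect_equal(rank_bmd_degs(degs, k = 2), c("A", "D"))  # tie at 2: lower p
  expect_equal(rank_bmd_degs(degs, k = 4), c("A", "D", "B", "C"))
  down <- tibble::tibble(gene_id = "Z", log2_fc = -2, p_adj = 1e-9)
  expect_message(none <- rank_bmd_degs(down), "0 gene")
  expect_equal(none, character())
  loose <- tibble::tibble(gene_id = "Y", log2_fc = 2, p_adj = 1e-4)
  expect_message(expect_equal(rank_bmd_degs(loose), "Y"), "1 gene")
})

test_that("synthetic single-cell data recovers planted TAM/BMD structure", {
  p <- scenario_params(seed = 7, n_cells = 600, n_clusters = 6,
                       tam_clusters = c("2", "3", "4"),
                       bmd_clusters = c("2", "3"),
                       planted_pct1 = 0.8, background_pct = 0.05)
  sc <- generate_sc_markers(p)
  pri <- suppressMessages(prioritize_ligands(p$planted_tam_genes,
                                             sc$markers, sc$annotation))
  expect_true(all(pri$tam_predominant))
  bmd <- pri$ontogeny[match(p$planted_bmd_genes, pri$ligand)]
  expect_true(all(bmd == "BMD"))
  # BMD-vs-microglia DEG table ranks the BMD-planted genes on top
  top <- suppressMessages(rank_bmd_degs(sc$bmd_degs, padj_max = 1e-3,
                                        k = 3))
  expect_setequal(top, p$planted_bmd_genes)
})

test_that("detection matrix constructor validates its invariants", {
  m <- matrix(TRUE, 2, 1, dimnames = list(NULL, "G"))
  expect_error(detection_matrix(m, "one-label"), "every cell")
  expect_error(detection_matrix(m, c("a", "a")), "2 clusters")
  expect_error(detection_matrix(matrix(1, 2, 1), c("a", "b")), "logical")
  no_names <- matrix(TRUE, 2, 1)
  expect_error(detection_matrix(no_names, c("a", "b")), "column names")
})
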