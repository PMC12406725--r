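test_that("harmonize_id canonicalizes case, whitespace and aliases", {
  expect_equal(harmonize_id("TGFBI", c(TGFBI = "BIGH3", BIGH3 = "BIGH3")),
               "BIGH3")
  expect_equal(harmonize_id("BIGH3", c(TGFBI = "BIGH3", BIGH3 = "BIGH3")),
               "BIGH3")
  expect_equal(harmonize_id("s100a9", character()), "S100A9")
  expect_equal(harmonize_id(" lyz\t", character()), "LYZ")
  expect_error(harmonize_id(""), "empty identifier")
  expect_error(harmonize_id(c("A", "", "B")), "2")
})

test_that("harmonize_id is idempotent, incl. over random mixed-case input", {
  al <- default_aliases()
  set.seed(7)
  pool <- c(names(al), "GAS6", "apoE", " Mmp9 ", "x1", "ecm1")
  raw <- sample(pool, 50, replace = TRUE)
  once <- harmonize_id(raw, al)
  expect_identical(harmonize_id(once, al), once)
})

test_that("non-canonical alias maps are rejected", {
  expect_error(harmonize_id("A", c(A = "B", B = "C")), "canonical-stable")
  expect_error(harmonize_id("A", c("B")), "named")
})

test_that("intensity table round-trips through disk, TSV and CSV", {
  tab <- make_intensity(c("BIGH3", "S100A9", "G1"),
                        m1 = rbind(c(2, 4, NA), c(1, 1, 1), c(NA, NA, NA)),
                        m2 = rbind(c(8, 8, 8), c(NA, 2, 2), c(5, 5, NA)))
  for (ext in c("tsv", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_intensity_table(tab, f)
    expect_equal(read_intensity_table(f), tab)
  }
})

test_that("intensity reader applies missing-value and validity rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tM1_1\tM1_2\tM1_3\tM2_1\tM2_2\tM2_3",
               "tgfbi\t0\t2\tNA\t3\t\t4"), f)
  tab <- read_intensity_table(f)
  expect_equal(tab$protein_id, "BIGH3")
  expect_true(is.na(tab$M1_1))  # literal 0 is non-detection by default
  expect_equal(read_intensity_table(f, zero_is_missing = FALSE)$M1_1, 0)

  # alias collision after harmonization is an error naming the collision
  writeLines(c("protein_id\tM1_1\tM1_2\tM1_3\tM2_1\tM2_2\tM2_3",
               "TGFBI\t1\t1\t1\t1\t1\t1",
               "BIGH3\t2\t2\t2\t2\t2\t2"), f)
  expect_error(read_intensity_table(f), "duplicate.*BIGH3")

  writeLines(c("protein_id\tM1_1\tM2_1", "A\t-1\t1"), f)
  expect_error(read_intensity_table(f), "negative")

  writeLines("protein_id\tfoo\tbar", f)
  expect_error(read_intensity_table(f), "no intensity columns")

  writeLines(c("protein_id\tM1_1\tM1_2\tM2_1", "A\t1\t1\t1"), f)
  expect_error(read_intensity_table(f), "unequal replicate")

  writeLines("protein_id\tM1_1\tM1_2\tM2_1\tM2_2", f)
  empty <- read_intensity_table(f)
  expect_equal(nrow(empty), 0)
})

test_that("pair database reader dedups and reports duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\treceptor", "L1\tR1", "l1\tR1", "L2\tR1", "L2\tL2"), f)
  expect_message(db <- read_rl_database(f), "1 duplicate")
  expect_equal(nrow(db), 3)
  expect_true(any(db$ligand == db$receptor))  # self-pairs permitted
  writeLines("ligand_only\tx", f)
  expect_error(read_rl_database(f), "ligand")
})

test_that("expression reader enforces base-mean invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "r1\t1.5\t0", "R2\t0\t3"), f)
  expr <- read_expression_table(f)
  expect_equal(expr$gene_id, c("R1", "R2"))
  writeLines(c("gene_id\ts1", "R1\t-0.5"), f)
  expect_error(read_expression_table(f), "negative")
  writeLines(c("gene_id", "R1"), f)
  expect_error(read_expression_table(f), "no sample columns")
})

test_that("marker and annotation readers validate their contracts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcluster_id\tpct.1\tpct.2\tavg_log2FC\tp_adj",
               "bigh3\t2\t0.8\t0.2\t2.0\t0.001"), f)
  mk <- read_marker_table(f)
  expect_equal(mk$gene_id, "BIGH3")
  expect_equal(mk$pct1, 0.8)
  writeLines(c("gene_id\tcluster_id\tpct.1\tavg_log2FC\tp_adj",
               "A\t1\t0.5\t1\t0.1"), f)
  expect_error(read_marker_table(f), "pct.2 missing")
  writeLines(c("gene_id\tcluster_id\tpct.1\tpct.2\tavg_log2FC\tp_adj",
               "A\t1\t1.5\t0.2\t1\t0.1"), f)
  expect_error(read_marker_table(f), "\\[0, 1\\]")

  writeLines(c("cluster_id\tcell_type\tontogeny",
               "2\tTAM\tBMD", "0\tmalignant\t"), f)
  ann <- read_cluster_annotation(f)
  expect_equal(ann$ontogeny, c("BMD", NA))
  writeLines(c("cluster_id\tcell_type\tontogeny", "0\tmalignant\tBMD"), f)
  expect_error(read_cluster_annotation(f), "non-TAM")
  writeLines(c("cluster_id\tcell_type", "0\tblob"), f)
  expect_error(read_cluster_annotation(f), "unknown cell_type")
})

test_that("mixed-case aliased input yields identical pipeline output", {
  # inject aliases/case noise into every table and assert the joined
  # interaction records are unchanged
  al <- c(TGFBI = "BIGH3", BIGH3 = "BIGH3")
  tab <- make_intensity(c("TGFBI", "g2"),
                        m1 = rbind(c(1, 1, 1), c(2, 2, 2)),
                        m2 = rbind(c(4, 4, 4), c(2, 2, 2)))
  tab_clean <- make_intensity(c("BIGH3", "G2"),
                              m1 = rbind(c(1, 1, 1), c(2, 2, 2)),
                              m2 = rbind(c(4, 4, 4), c(2, 2, 2)))
  d <- withr::local_tempdir()
  for (v in list(list("noisy", tab, c("tgfbi", "g2"), c("TGFBI", "G2")),
                 list("clean", tab_clean, c("BIGH3", "G2"),
                      c("BIGH3", "G2")))) {
    write_intensity_table(v[[2]], file.path(d, paste0(v[[1]], "_int.tsv")))
    readr::write_tsv(tibble::tibble(gene_id = v[[3]]),
                     file.path(d, paste0(v[[1]], "_sec.tsv")))
    readr::write_tsv(tibble::tibble(ligand = v[[4]], receptor = "REC1"),
                     file.path(d, paste0(v[[1]], "_db.tsv")))
  }
  expr <- tibble::tibble(gene_id = "rec1", s = 2)
  readr::write_tsv(expr, file.path(d, "expr.tsv"))
  run_one <- function(tag) {
    ti <- read_intensity_table(file.path(d, paste0(tag, "_int.tsv")),
                               aliases = al)
    se <- read_secretome(file.path(d, paste0(tag, "_sec.tsv")), al)
    db <- read_rl_database(file.path(d, paste0(tag, "_db.tsv")), al)
    ex <- read_expression_table(file.path(d, "expr.tsv"), al)
    filt <- filter_by_replicates(ti)
    su <- condition_summary(filt)
    lg <- filter_secreted(unlist(detection_sets(filt)), se)
    build_interactions(lg, su, ex, db, crosstalk_config(gate_sample = "s"))
  }
  expect_identical(run_one("noisy"), run_one("clean"))
})
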