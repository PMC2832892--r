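mk_hit <- function(query, db, evalue, strand = "plus/plus",
                   bitscore = 100, subject = "subj") {
  tibble::tibble(query_id = query, subject_id = subject,
                 pct_identity = 0.99, align_len = 100L, mismatches = 1L,
                 gap_openings = 0L, qstart = 1L, qend = 100L,
                 sstart = 1L, send = 100L, evalue = evalue,
                 bitscore = bitscore, strand = strand, db = db)
}

test_that("priority annotation filters strand and e-value, then ranks dbs", {
  hits <- dplyr::bind_rows(
    mk_hit("q1", "rfam", 1e-30, subject = "snoRNA_X"),
    mk_hit("q1", "nt", 1e-50, subject = "ncRNA_Y"),
    mk_hit("q2", "nt", 1e-40, strand = "plus/minus"),
    mk_hit("q3", "rfam", 1e-10))
  ann <- annotate_by_priority(hits)
  expect_equal(ann$assigned_class[ann$query_id == "q1"], "snoRNA_X")
  expect_equal(ann$source_db[ann$query_id == "q1"], "rfam")
  # minus-strand-only and weak-e-value queries stay unclassified
  expect_equal(ann$assigned_class[ann$query_id == "q2"], "unclassified")
  expect_equal(ann$assigned_class[ann$query_id == "q3"], "unclassified")
  expect_error(annotate_by_priority(mk_hit("q", "mystery_db", 1e-30)),
               "unknown database")
})

test_that("name-based classification follows rule order", {
  cls <- assign_class_by_name(c("SNORA36a", "snoU6-53", "U4atac", "U8",
                                "SNORD116", "SCARNA11", "Y5", "7SLa",
                                "7SK", "RNaseP_nuc", "RNase_MRP",
                                "Vault RNA", "unclassified 3",
                                "snosnR60_Z15", "U3k", "U12"))
  expect_equal(cls$klass,
               c("snoRNA_HACA", "snoRNA_CD", "snRNA", "snoRNA_CD",
                 "snoRNA_CD", "scaRNA", "YRNA", "SRP", "7SK", "RPPH1",
                 "RMRP", "vault", "unclassified", "snoRNA_CD",
                 "snoRNA_CD", "snRNA"))
  expect_equal(cls$is_snorna,
               cls$klass %in% c("snoRNA_CD", "snoRNA_HACA", "scaRNA"))
  expect_error(assign_class_by_name("mystery-RNA"), "mystery-RNA")
})

test_that("family collapsing strips one paralog letter next to a digit", {
  expect_equal(collapse_family(c("U3a", "U3n", "SNORD17b", "SNORA36a")),
               c("U3", "U3", "SNORD17", "SNORA36"))
  expect_equal(collapse_family(c("snoU6-53", "RNaseP_nuc", "Y5", "U8")),
               c("snoU6-53", "RNaseP_nuc", "Y5", "U8"))
})

test_that("expression grouping maps the six observed patterns", {
  expect_equal(group_expression(TRUE, TRUE, TRUE), 1L)
  expect_equal(group_expression(FALSE, TRUE, TRUE), 2L)
  expect_equal(group_expression(FALSE, FALSE, TRUE), 3L)
  expect_equal(group_expression(FALSE, FALSE, FALSE), 4L)
  expect_equal(group_expression(FALSE, TRUE, FALSE), 5L)
  expect_equal(group_expression(TRUE, FALSE, TRUE), 6L)
  expect_warning(g <- group_expression(TRUE, TRUE, FALSE), "outside")
  expect_equal(g, 0L)
  # the six patterns cover every observed call triple in the catalog
  rows <- load_catalog_fixture()
  g <- group_expression(rows$det_chicken, rows$det_mouse, rows$det_human)
  expect_true(all(g %in% 1:6))
  # computed groups agree with the printed labels except for the three
  # printed anomalies, which the fixture keeps as published
  mism <- rows$name[g != rows$group_label]
  expect_setequal(mism, c("U2-1", "U2-2", "SNORD116"))
})

test_that("consistency flags conserved-but-silent rows one-sidedly", {
  rows <- load_catalog_fixture()
  fl <- consistency_flag(rows)
  expect_equal(fl$flag[fl$name == "SNORA19"], "inconsistent")
  # all-detected rows are consistent whatever their scores
  all_yes <- fl[fl$det_chicken & fl$det_mouse & fl$det_human, ]
  expect_true(all(all_yes$flag == "consistent"))
  # detection without conservation is not flagged (one-sided rule):
  # the vault RNA row (human 0.53, detected) stays consistent
  expect_equal(fl$flag[fl$name == "Vault RNA"], "consistent")
  toy <- tibble::tibble(det_chicken = FALSE, det_mouse = FALSE,
                        det_human = TRUE, cons_chicken = 0.2,
                        cons_mouse = 0.3, cons_human = 1.0)
  expect_equal(consistency_flag(toy)$flag, "consistent")
  # missing scores restrict the species used
  toy$cons_chicken <- NA
  expect_equal(consistency_flag(toy)$n_species_used, 2)
})

test_that("catalog summary reproduces the published totals", {
  rows <- load_catalog_fixture()
  s <- catalog_summary(rows)
  expect_equal(s$n_rows, 117L)
  expect_equal(s$clone_sum, 835L)
  expect_equal(s$n_snorna, 80L)
  expect_equal(s$n_cd, 32L)
  expect_equal(s$n_haca_incl_scarna, 48L)
  expect_equal(s$n_snrna, 17L)
  expect_equal(s$n_yrna, 6L)
  expect_equal(s$n_srp, 2L)
  expect_equal(s$n_7sk + s$n_vault + s$n_rpph1 + s$n_rmrp, 4L)
  expect_equal(s$n_unclassified, 8L)
  expect_equal(s$n_families, 64L)
  expect_equal(s$n_mouse_lowcons, 13L)
  expect_equal(s$n_human_perfect, 68L)
  # permutation invariance and the empty catalog
  s2 <- catalog_summary(rows[sample.int(117), ])
  expect_identical(s, s2)
  empty <- catalog_summary(rows[0, ])
  expect_true(all(unlist(empty) == 0))
})
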