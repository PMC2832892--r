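fake_cd_ann <- function(seq, c_start, c_end, d_start, d_end) {
  ann <- structure(
    list(sno_id = "x", length = nchar(seq), seq = seq,
         boxes = tibble::tibble(kind = c("C", "D"),
                                start = c(c_start, d_start),
                                end = c(c_end, d_end),
                                matched = "", mismatches = 0L,
                                role = c("C", "D")),
         box_pairs = tibble::tibble(pair = 1L, c_role = "C",
                                    c_start = c_start, c_end = c_end,
                                    d_role = "D", d_start = d_start,
                                    d_end = d_end)),
    class = "cd_annotation")
  ann$guides <- extract_cd_guides(ann)
  ann
}

test_that("guides are the interval between the C and D boxes", {
  s <- strrep("A", 60)
  g <- fake_cd_ann(s, 5L, 12L, 40L, 44L)$guides
  expect_equal(g$start, 12L)
  expect_equal(g$end, 40L)
  expect_equal(g$end - g$start, 28L)
  # a 5-nt gap yields no guide
  expect_equal(nrow(fake_cd_ann(s, 5L, 12L, 17L, 21L)$guides), 0L)
})

test_that("C/D target prediction finds an exact antisense window", {
  set.seed(61)
  target <- random_seq(200)
  window <- substr(target, 101, 118)
  guide <- revcomp(window)
  p <- predict_cd_target(guide, tibble::tibble(id = "t", seq = target,
                                               class = "rRNA"))
  expect_equal(p$t_start, 100L)
  expect_equal(p$t_end, 118L)
  expect_equal(p$duplex_len, 18L)
  expect_equal(p$score, 18)
})

test_that("C/D target prediction applies the length floor and priority", {
  set.seed(62)
  # guide with no complementarity to a pyrimidine-free target
  guide <- strrep("A", 12)
  expect_null(predict_cd_target(guide,
                                tibble::tibble(id = "t",
                                               seq = strrep("C", 100),
                                               class = "rRNA")))
  expect_error(predict_cd_target("ACGTACGT",
                                 tibble::tibble(id = character(),
                                                seq = character())),
               "empty target set")
  # equal-scoring windows in an rRNA and an snRNA: rRNA wins
  core <- random_seq(60)
  window <- substr(core, 21, 35)
  guide <- revcomp(window)
  pad1 <- strrep("C", 40)
  targets <- tibble::tibble(
    id = c("sn", "rr"),
    seq = c(paste0(pad1, core, pad1), paste0(pad1, core, pad1)),
    class = c("snRNA", "rRNA"))
  p <- predict_cd_target(guide, targets)
  expect_equal(p$target_id, "rr")
})

test_that("the D+5 methylated residue maps onto the duplex", {
  set.seed(63)
  target <- random_seq(120)
  window <- substr(target, 51, 66)  # 16-mer
  sno <- paste0("AAAAA", "GTGATGA", revcomp(window), "CTGA", "AAAA")
  ann <- pair_cd_boxes(sno)
  expect_false(is.null(ann))
  pred <- predict_cd_targets(ann, tibble::tibble(id = "t", seq = target,
                                                 class = "rRNA"))
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$modification, "2primeOme")
  # guide base 5 nt upstream of D pairs target position t_end - 1 - (glen - 5)
  glen <- pred$guide_end - pred$guide_start
  expect_equal(pred$modified_pos, pred$t_end - 1L - (glen - 5L))
})

test_that("pocket target prediction recovers a planted uridine site", {
  st <- synth_study(seed = 41, n_cd = 0, n_haca = 2, n_retro = 0)
  tr <- st$genome$truth
  els <- tr[tr$type == "haca_sno", ]
  for (i in seq_len(nrow(els))) {
    e <- els[i, ]
    ann <- detect_haca_architecture(truth_seq(st$genome, e))
    pred <- predict_haca_target(ann, st$targets)
    psi <- as.integer(sub(".*psi=[^:]+:", "", e$note))
    expect_true(psi %in% pred$psi_pos)
    # every reported site centres a uridine and respects the length floors
    base <- substr(st$targets$seq[match(pred$target_id, st$targets$id)],
                   pred$psi_pos + 1, pred$psi_pos + 1)
    expect_true(all(base == "T"))
    expect_true(all(pred$left_len >= 3 & pred$right_len >= 3))
    expect_true(all(pred$score >= 7))
  }
})

test_that("pocket predictions re-validate base by base", {
  st <- synth_study(seed = 43, n_cd = 0, n_haca = 1, n_retro = 0)
  e <- st$genome$truth[st$genome$truth$type == "haca_sno", ][1, ]
  s <- truth_seq(st$genome, e)
  ann <- detect_haca_architecture(s)
  pred <- predict_haca_target(ann, st$targets)
  expect_gt(nrow(pred), 0)
  comp_ok <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  for (i in seq_len(nrow(pred))) {
    r <- pred[i, ]
    tb <- strsplit(st$targets$seq[match(r$target_id, st$targets$id)],
                   "")[[1]]
    po <- ann$pockets[r$pocket, ]
    la <- strsplit(substr(s, po$l_start + 1, po$l_end), "")[[1]]
    ra <- strsplit(substr(s, po$r_start + 1, po$r_end), "")[[1]]
    for (m in seq_len(r$right_len)) {
      expect_true(comp_ok(ra[m], tb[r$psi_pos - m + 1]))
    }
    for (m in seq_len(r$left_len)) {
      expect_true(comp_ok(la[length(la) - m + 1], tb[r$psi_pos + 2 + m]))
    }
  }
})

test_that("non-uridine sites and short duplexes are rejected", {
  # construct a pocket complementary to a site whose centre is a C
  target <- paste0(strrep("G", 30), "ATCGA", "CG", "TTGCA", strrep("G", 30))
  # psi candidate at the C (position 35): base not T, so no acceptance
  ann <- structure(
    list(sno_id = "x", length = 60, seq = strrep("A", 60),
         pockets = tibble::tibble(hairpin = "5prime",
                                  l_start = 10L, l_end = 15L,
                                  r_start = 25L, r_end = 30L)),
    class = "haca_annotation")
  # left arm must pair target[37..41] = TTGCA -> arm = revcomp = TGCAA
  s <- paste0(strrep("A", 10), "TGCAA", strrep("A", 10), "TCGAT",
              strrep("A", 30))
  ann$seq <- s
  pred <- predict_haca_target(ann, tibble::tibble(id = "t", seq = target,
                                                  class = "rRNA"))
  expect_false(35L %in% pred$psi_pos)
  # a true uridine version of the same site is accepted
  target_u <- paste0(strrep("G", 30), "ATCGA", "TG", "TTGCA", strrep("G", 30))
  pred_u <- predict_haca_target(ann, tibble::tibble(id = "t", seq = target_u,
                                                    class = "rRNA"))
  expect_true(35L %in% pred_u$psi_pos)
  # 3 + 3 paired nt misses the 7-nt floor
  pred6 <- predict_haca_target(ann, tibble::tibble(id = "t", seq = target_u,
                                                   class = "rRNA"),
                               min_side = 3L, min_total = 7L)
  expect_true(all(pred6$left_len + pred6$right_len >= 7))
})

test_that("target predictions are deterministic across runs", {
  st <- synth_study(seed = 47, n_cd = 1, n_haca = 1, n_retro = 0)
  tr <- st$genome$truth
  cd <- tr[tr$type == "cd_sno", ][1, ]
  ann <- pair_cd_boxes(truth_seq(st$genome, cd))
  p1 <- predict_cd_targets(ann, st$targets)
  p2 <- predict_cd_targets(ann, st$targets)
  expect_identical(p1, p2)
})
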