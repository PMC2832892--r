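test_that("poly(A) runs respect purity, endpoints, and the window", {
  one <- find_polya(paste0("CC", strrep("A", 12), "GG"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 2L)
  expect_equal(one$length, 12L)
  two <- find_polya(paste0(strrep("A", 10), "CCC", strrep("A", 9)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$length, c(10L, 9L))
  expect_equal(nrow(find_polya(strrep("C", 120))), 0L)
  # runs never overlap and never exceed the window
  set.seed(71)
  for (k in 1:20) {
    f <- random_seq(300, c("A", "A", "C", "G", "T"))
    runs <- find_polya(f, window = 100L)
    if (nrow(runs) < 2) next
    expect_true(all(diff(runs$start) >= head(runs$length, -1)))
    expect_lte(sum(runs$length), 100L)
    expect_true(all(runs$start + runs$length <= 100L))
  }
})

test_that("TSD search finds planted duplications and resists noise", {
  set.seed(72)
  tsd <- random_seq(12)
  f5 <- paste0(random_seq(200), tsd)
  f3 <- paste0(tsd, random_seq(200))
  hit <- find_tsd(f5, f3)
  expect_equal(hit$length, 12L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$up_start, 200L)
  expect_equal(hit$down_start, 0L)
  # a 6-mer duplication is below the default minimum
  six <- random_seq(6)
  expect_null(find_tsd(paste0(strrep("C", 100), six),
                       paste0(six, strrep("G", 100))))
  # unrelated flanks almost never produce a TSD call
  fp <- 0L
  for (k in 1:100) {
    if (!is.null(find_tsd(random_seq(250), random_seq(250)))) fp <- fp + 1L
  }
  expect_lte(fp, 5L)
})

test_that("L1 site search matches TTAAAA near the TSD boundary", {
  f5 <- paste0(strrep("C", 94), "TTAAAA", strrep("G", 20))
  hit <- find_l1_site(f5, tsd_start = 100L)
  expect_equal(hit$position, 94L)
  expect_equal(hit$mismatches, 0L)
  one_mm <- find_l1_site(paste0(strrep("C", 94), "TTGAAA", strrep("G", 20)),
                         tsd_start = 100L)
  expect_equal(one_mm$mismatches, 1L)
  expect_null(find_l1_site(strrep("C", 120), tsd_start = 100L))
  expect_error(find_l1_site("ACGT", tsd_start = 50L), "outside")
})

test_that("retro calls recover planted features with exact boundaries", {
  st <- synth_study(seed = 73, n_cd = 1, n_haca = 1, n_retro = 4)
  tr <- st$genome$truth
  retros <- tr[tr$type == "retrocopy", ]
  loci <- tibble::tibble(locus_id = retros$element_id,
                         seq_id = retros$seq_id,
                         start = retros$start, end = retros$end)
  calls <- call_retro_set(st$genome$seqs, loci)
  expect_true(all(calls$verdict == "L1_retrogene"))
  for (i in seq_len(nrow(calls))) {
    truth_up <- tr[tr$type == "tsd" & tr$parent_id == calls$locus_id[i] &
                     tr$note == "upstream", ]
    flank_start <- loci$start[i] - 1000L
    expect_equal(calls$tsd_up_start[i] + flank_start, truth_up$start)
    expect_equal(calls$tsd_len[i], truth_up$end - truth_up$start)
  }
  # parental intronic elements are not retro calls
  parents <- tr[tr$type %in% c("cd_sno", "haca_sno"), ]
  ploci <- tibble::tibble(locus_id = parents$element_id,
                          seq_id = parents$seq_id,
                          start = parents$start, end = parents$end)
  pcalls <- call_retro_set(st$genome$seqs, ploci)
  expect_true(all(!pcalls$verdict %in% c("retrogene", "L1_retrogene")))
})

test_that("feature combinations map to the verdict ladder", {
  set.seed(74)
  tsd <- "GCGTACGTTGCA"
  f5 <- paste0(random_seq(150), "TTAAAA", tsd)
  f3_all <- paste0(strrep("A", 15), tsd, random_seq(150))
  expect_equal(call_retro(f5, f3_all)$verdict, "L1_retrogene")
  f5_no_l1 <- paste0(random_seq(150), "CCCCCC", tsd)
  expect_equal(call_retro(f5_no_l1, f3_all)$verdict, "retrogene")
  f3_no_tsd <- paste0(strrep("A", 15), random_seq(150))
  expect_equal(call_retro(f5_no_l1, f3_no_tsd)$verdict, "candidate")
  expect_equal(call_retro(random_seq(150),
                          paste0(random_seq(60), random_seq(90)))$verdict,
               "none")
})

test_that("flank consensus recovers shared blocks and ignores noise", {
  set.seed(75)
  block <- random_seq(500)
  flanks <- vapply(1:5, function(i) {
    paste0(random_seq(sample(80:150, 1)), block,
           random_seq(sample(80:150, 1)))
  }, character(1))
  blocks <- flank_consensus(flanks)
  expect_gte(nrow(blocks), 1L)
  expect_gte(max(blocks$length), 490L)
  # identical flanks agree everywhere
  same <- rep(paste0(block, block), 3)
  full <- flank_consensus(same)
  expect_equal(nrow(full), 1L)
  expect_equal(full$length, 1000L)
  expect_equal(full$mean_agreement, 1)
  # unrelated flanks yield nothing
  noise <- vapply(1:4, function(i) random_seq(600), character(1))
  expect_equal(nrow(flank_consensus(noise)), 0L)
  expect_error(flank_consensus(noise[1:2]), "at least 3")
})
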