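test_that("box scanning matches the consensus definitions", {
  cb <- find_box("GGGTGATGACC", "C")
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$start, 2L)
  expect_equal(cb$end, 9L)
  expect_equal(cb$matched, "GTGATGA")
  expect_equal(cb$mismatches, 0L)
  db <- find_box("AAACTGAAA", "D")
  expect_equal(db$start, 3L)
  expect_equal(db$end, 7L)
  for (kind in c("C", "D", "ACA")) {
    expect_equal(nrow(find_box("AAAAAAA", kind,
                               max_mismatch = 0L)), 0L)
  }
  # the H consensus ANANNA is A-rich by definition, so an all-A string
  # does match it; the specific boxes cannot
  expect_equal(nrow(find_box("AAAAAAA", "H")), 1L)
  expect_error(find_box("ACGT", "Ebox"), "unknown box kind")
})

test_that("raising the mismatch ceiling never loses boxes", {
  set.seed(21)
  for (k in 1:25) {
    s <- random_seq(sample(40:150, 1))
    for (kind in c("C", "D", "H")) {
      counts <- vapply(0:3, function(mm) {
        nrow(find_box(s, kind, max_mismatch = mm))
      }, integer(1))
      expect_true(all(diff(counts) >= 0), info = paste(kind, s))
    }
  }
})

test_that("maximum pairing matches exhaustive structure enumeration", {
  expect_equal(fold_max_pairing("GGGAAACCC")$n_pairs, 3L)
  h <- fold_max_pairing("GGGAAACCC")
  # the loop bases are unpaired
  expect_false(any(h$pairs$i %in% 3:5 | h$pairs$j %in% 3:5))
  expect_equal(fold_max_pairing(strrep("A", 30))$n_pairs, 0L)
  expect_error(fold_max_pairing("ACGTA"), "too short")
  # true enumeration for short strings
  set.seed(33)
  for (k in 1:25) {
    s <- random_seq(sample(6:12, 1))
    expect_equal(fold_max_pairing(s)$n_pairs, enum_max_pairs(s), info = s)
  }
  # independent memoised recursion up to 20 nt
  for (k in 1:30) {
    s <- random_seq(sample(13:20, 1))
    expect_equal(fold_max_pairing(s)$n_pairs, memo_max_pairs(s), info = s)
  }
})

test_that("folded structures are valid: non-crossing, min loop, pairable", {
  set.seed(44)
  for (k in 1:20) {
    s <- random_seq(sample(15:60, 1))
    h <- fold_max_pairing(s)
    if (nrow(h$pairs) == 0) next
    expect_true(all(h$pairs$j - h$pairs$i > 3))
    ch <- strsplit(s, "")[[1]]
    expect_true(all(pairable_ref(ch[h$pairs$i + 1], ch[h$pairs$j + 1])))
    # non-crossing
    for (x in seq_len(nrow(h$pairs))) {
      crossing <- h$pairs$i < h$pairs$i[x] & h$pairs$j > h$pairs$i[x] &
        h$pairs$j < h$pairs$j[x]
      expect_false(any(crossing))
    }
  }
})

test_that("a minimum helix length of 2 eliminates isolated pairs", {
  set.seed(45)
  for (k in 1:20) {
    s <- random_seq(sample(20:60, 1))
    h <- fold_max_pairing(s, min_helix = 2L)
    partner <- rep(-1L, nchar(s))
    partner[h$pairs$i + 1] <- h$pairs$j
    partner[h$pairs$j + 1] <- h$pairs$i
    hel <- snoscout:::helices_from_partner(partner)
    if (nrow(hel) > 0) expect_true(all(hel$helix_len >= 2))
    expect_true(h$n_pairs <= fold_max_pairing(s)$n_pairs)
  }
})

test_that("dot-bracket input bypasses folding", {
  h <- fold_max_pairing("GGGAAACCC", structure = "(((...)))")
  expect_equal(h$n_pairs, 3L)
  expect_error(fold_max_pairing("GGGAAACCC", structure = "((....)))"),
               "unbalanced")
})

test_that("planted C/D elements are re-detected at planted coordinates", {
  st <- synth_study(seed = 17, n_cd = 3, n_haca = 0, n_retro = 0)
  tr <- st$genome$truth
  els <- tr[tr$type == "cd_sno", ]
  expect_equal(nrow(els), 3L)
  for (i in seq_len(nrow(els))) {
    e <- els[i, ]
    ann <- pair_cd_boxes(truth_seq(st$genome, e), e$element_id)
    expect_false(is.null(ann))
    cspan <- note_span(e$note, "C")
    dspan <- note_span(e$note, "D")
    bx <- ann$boxes
    expect_equal(bx$start[bx$role == "C"], cspan[1])
    expect_equal(bx$start[bx$role == "D"], dspan[1])
    # every reported box and guide lies inside the sequence / its pair
    expect_true(all(bx$start >= 0 & bx$end <= ann$length))
    g <- ann$guides
    for (j in seq_len(nrow(g))) {
      p <- ann$box_pairs[ann$box_pairs$pair == g$pair[j], ]
      expect_true(g$start[j] >= p$c_end && g$end[j] <= p$d_start)
    }
  }
})

test_that("C/D detection requires a terminal pair and rarely fires at random", {
  # C box present but no D box
  s <- paste0("AAAAA", "GTGATGA", strrep("C", 60))
  expect_null(pair_cd_boxes(s))
  set.seed(202)
  hits <- 0L
  for (k in 1:100) {
    if (!is.null(pair_cd_boxes(random_seq(120)))) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("planted H/ACA elements are re-detected with planted pockets", {
  st <- synth_study(seed = 23, n_cd = 0, n_haca = 3, n_retro = 0)
  tr <- st$genome$truth
  els <- tr[tr$type == "haca_sno", ]
  expect_equal(nrow(els), 3L)
  for (i in seq_len(nrow(els))) {
    e <- els[i, ]
    ann <- detect_haca_architecture(truth_seq(st$genome, e), e$element_id)
    expect_false(is.null(ann))
    expect_equal(ann$h_box$start, note_span(e$note, "h")[1])
    lp <- note_span(e$note, "l_pair")
    rp <- note_span(e$note, "r_pair")
    hit <- ann$pockets$l_end == lp[2] & ann$pockets$r_start == rp[1] &
      ann$pockets$l_start <= lp[1] & ann$pockets$r_end >= rp[2]
    expect_true(any(hit))
    # ACA box sits exactly 6 nt before the 3' end
    expect_equal(ann$aca_box$start, ann$length - 6L)
  }
})

test_that("H/ACA detection needs the terminal ACA and resists shuffles", {
  st <- synth_study(seed = 29, n_cd = 0, n_haca = 1, n_retro = 0)
  e <- st$genome$truth[st$genome$truth$type == "haca_sno", ][1, ]
  s <- truth_seq(st$genome, e)
  # strip the terminal ACA
  broken <- paste0(substr(s, 1, nchar(s) - 6), "GGG",
                   substr(s, nchar(s) - 2, nchar(s)))
  expect_null(detect_haca_architecture(broken))
  hits <- 0L
  for (k in 1:100) {
    if (!is.null(detect_haca_architecture(shuffle_dinucleotide(s, k)))) {
      hits <- hits + 1L
    }
  }
  expect_lte(hits, 10L)
})

test_that("classification prefers C/D, falls back to H/ACA, else none", {
  st <- synth_study(seed = 31, n_cd = 1, n_haca = 1, n_retro = 0)
  tr <- st$genome$truth
  cd <- tr[tr$type == "cd_sno", ][1, ]
  ha <- tr[tr$type == "haca_sno", ][1, ]
  expect_equal(classify_sequence(truth_seq(st$genome, cd))$class, "CD")
  expect_equal(classify_sequence(truth_seq(st$genome, ha))$class, "HACA")
  set.seed(303)
  classes <- classify_sequences(
    tibble::tibble(id = paste0("r", 1:20),
                   seq = vapply(1:20, function(i) random_seq(110),
                                character(1))))
  expect_gte(sum(classes$class == "none"), 18L)
})

test_that("box-pair counting sums 2 for internal pairs and 1 without", {
  st <- synth_study(seed = 37, n_cd = 2, n_haca = 0, n_retro = 0)
  tr <- st$genome$truth
  els <- tr[tr$type == "cd_sno", ]
  seqs <- tibble::tibble(
    id = els$element_id,
    seq = vapply(seq_len(nrow(els)), function(i) {
      truth_seq(st$genome, els[i, ])
    }, character(1)))
  # synth_study alternates with/without the internal pair
  with_internal <- grepl("Cp=", els$note)
  expect_equal(count_cd_box_pairs(seqs), sum(ifelse(with_internal, 2L, 1L)))
  expect_equal(count_cd_box_pairs(seqs[1, ]),
               if (with_internal[1]) 2L else 1L)
})
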