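#' @section Synthetic study data:
#' The synthetic-genome generator is the statistical stand-in for the raw
#' study data: it emulates intron/intergenic genomic context, C/D box
#' snoRNAs with antisense guides against a target RNA, H/ACA snoRNAs with
#' pseudouridylation pockets complementary to a uridine-centred target
#' site, and SINE-like retrocopies with poly(A) tail, target site
#' duplication and optional L1 endonuclease site. Every planted feature is
#' recorded in a machine-readable truth ledger so detector recall and
#' precision can be computed without the detectors and the truth ever
#' sharing a code path.
#' @name synth
NULL

rand_bases <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

empty_truth <- function() {
  tibble(element_id = character(), type = character(), seq_id = character(),
         start = integer(), end = integer(), strand = character(),
         parent_id = character(), note = character())
}

#' Generate a synthetic genome with gene models
#'
#' Sequences are i.i.d. bases at the requested GC content. Genes with 2-5
#' exons (exons 100-300 nt, introns 800-2000 nt) are placed left to right
#' without overlap, separated by at least 500 nt of intergenic sequence.
#' Output is reproducible under `seed`.
#'
#' @param n_seq Number of sequences.
#' @param length Length of each sequence (>= 10 kb).
#' @param gc GC content in `(0, 1)`.
#' @param n_genes Genes per sequence (default scales with length).
#' @param seed Integer seed; recorded in the object and in output headers.
#' @return A `synth_genome` list: `seqs` (tibble `id`, `seq`, `desc`),
#'   `exons` (0-based half-open exon tibble), `truth` (empty ledger),
#'   `seed`, `params`.
#' @export
gen_genome <- function(n_seq = 1L, length = 20000L, gc = 0.5,
                       n_genes = max(1L, length %/% 6000L), seed = 1L) {
  if (length < 10000L) abort("sequence length must be at least 10 kb")
  withr::with_seed(seed, {
    ids <- paste0("chr", seq_len(n_seq))
    seqs <- vapply(ids, function(i) rand_bases(length, gc), character(1))
    exons <- list()
    for (sid in ids) {
      cursor <- sample(500:1500, 1)
      placed <- 0L
      for (gi in seq_len(n_genes)) {
        n_ex <- sample(2:5, 1)
        ex_len <- sample(100:300, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) sample(800:2000, n_ex - 1, replace = TRUE)
        else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (cursor + span > length - 500L) break
        gene_id <- paste0(sid, "_g", gi)
        st <- cursor
        for (e in seq_len(n_ex)) {
          exons[[length(exons) + 1]] <-
            tibble(seqid = sid, start = st, end = st + ex_len[e],
                   strand = "+", gene_id = gene_id,
                   transcript_id = paste0(gene_id, ".t1"))
          st <- st + ex_len[e] + if (e < n_ex) in_len[e] else 0L
        }
        cursor <- cursor + span + sample(500:1500, 1)
        placed <- placed + 1L
      }
      if (placed == 0L) abort("gene placement infeasible for sequence length")
    }
    structure(list(
      seqs = tibble(id = ids, seq = unname(seqs),
                    desc = paste0(ids, " synthetic seed=", seed)),
      exons = bind_rows(exons),
      truth = empty_truth(),
      seed = seed,
      params = list(n_seq = n_seq, length = length, gc = gc,
                    n_genes = n_genes)),
      class = "synth_genome")
  })
}

#' Introns of a synthetic genome
#'
#' @param g A `synth_genome`.
#' @return Tibble of 0-based half-open introns (`seqid`, `start`, `end`,
#'   `strand`, `gene_id`).
#' @export
synth_introns <- function(g) {
  g$exons %>%
    group_by(.data$seqid, .data$strand, .data$gene_id,
             .data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(int_start = list(.data$end[-n()]),
              int_end = list(.data$start[-1]), .groups = "drop") %>%
    tidyr::unnest(c("int_start", "int_end")) %>%
    rename(start = "int_start", end = "int_end")
}

# Insert `ins` into sequence `seq_id` at 0-based position `pos`, shifting
# gene models and previously planted truth entries downstream of the
# insertion point. Exons or elements spanning the insertion point are an
# error (insertions only go into introns or intergenic space).
insert_at <- function(g, seq_id, pos, ins) {
  k <- match(seq_id, g$seqs$id)
  if (is.na(k)) abort(paste0("unknown sequence id: ", seq_id))
  s <- g$seqs$seq[k]
  stopifnot(pos >= 0, pos <= nchar(s))
  w <- nchar(ins)
  tr <- g$truth$seq_id == seq_id
  if (any(tr & g$truth$start < pos & g$truth$end > pos)) {
    abort("insertion site inside an existing planted element")
  }
  ex <- g$exons$seqid == seq_id
  if (any(ex & g$exons$start < pos & g$exons$end > pos)) {
    abort("insertion site inside an exon")
  }
  g$seqs$seq[k] <- paste0(substr(s, 1, pos), ins,
                          substr(s, pos + 1, nchar(s)))
  g$exons <- g$exons %>%
    mutate(shift = .data$seqid == seq_id & .data$start >= pos,
           start = .data$start + ifelse(.data$shift, w, 0L),
           end = .data$end + ifelse(.data$shift, w, 0L)) %>%
    select(-"shift")
  if (nrow(g$truth) > 0) {
    g$truth <- g$truth %>%
      mutate(shift = .data$seq_id == !!seq_id & .data$start >= pos,
             start = .data$start + ifelse(.data$shift, w, 0L),
             end = .data$end + ifelse(.data$shift, w, 0L)) %>%
      select(-"shift")
  }
  g
}

pick_intron <- function(g, min_len) {
  intr <- synth_introns(g)
  if (nrow(intr) == 0) abort("no eligible intron")
  ok <- vapply(seq_len(nrow(intr)), function(i) {
    r <- intr[i, ]
    if (r$end - r$start < min_len) return(FALSE)
    !any(g$truth$seq_id == r$seqid & g$truth$start < r$end &
           g$truth$end > r$start)
  }, logical(1))
  if (!any(ok)) abort("no eligible intron")
  intr[which(ok)[sample.int(sum(ok), 1)], ]
}

#' Plant a C/D box snoRNA into an intron
#'
#' Builds a 70-120 nt element -- 5' pad, C box (`RTGATGA`), an antisense
#' guide (the reverse complement of a window of the supplied target RNA),
#' optionally an internal C'/D' pair with a second guide, and the terminal
#' D box (`CTGA`) -- and inserts it into an eligible intron. Random
#' spacers are resampled until the element's detected boxes sit exactly at
#' the planted coordinates and no spurious internal pair is created, so
#' that the construction is unambiguous by design. The ledger records the
#' element, its guides, and the guide target windows.
#'
#' @param g A `synth_genome`.
#' @param target One-row target tibble (`id`, `seq`) the guides are
#'   antisense to.
#' @param with_internal Plant an internal C'/D' pair (default `TRUE`).
#' @param intron Optional one-row intron tibble (default: random eligible
#'   intron).
#' @param id Element id (default auto-numbered).
#' @param seed Integer seed.
#' @return The updated `synth_genome`.
#' @export
plant_cd_sno <- function(g, target, with_internal = TRUE, intron = NULL,
                         id = NULL, seed = 1L) {
  stopifnot(nrow(target) == 1)
  withr::with_seed(seed, {
    if (is.null(id)) id <- paste0("cd_", sum(g$truth$type == "cd_sno") + 1L)
    tlen <- nchar(target$seq)
    build <- function() {
      g1len <- sample(12:18, 1)
      t1s <- sample.int(tlen - g1len, 1) - 1L
      w1 <- substr(target$seq, t1s + 1, t1s + g1len)
      guide1 <- revcomp(w1)
      cbox <- paste0(sample(c("A", "G"), 1), "TGATGA")
      pad5 <- rand_bases(5)
      spacer1 <- rand_bases(sample(8:14, 1))
      pad3 <- rand_bases(4)
      if (with_internal) {
        g2len <- sample(10:14, 1)
        t2s <- sample.int(tlen - g2len, 1) - 1L
        w2 <- substr(target$seq, t2s + 1, t2s + g2len)
        guide2 <- revcomp(w2)
        cpbox <- paste0(sample(c("A", "G"), 1), "TGATGA")
        mid <- paste0(cpbox, guide2, "CTGA", rand_bases(sample(8:14, 1)))
      } else {
        t2s <- NA_integer_; g2len <- NA_integer_
        mid <- rand_bases(sample(18:28, 1))
      }
      el <- paste0(pad5, cbox, guide1, spacer1, mid, "CTGA", pad3)
      c_start <- 5L
      g1_start <- c_start + 7L
      mid_start <- g1_start + g1len + nchar(spacer1)
      d_start <- nchar(el) - 8L
      list(el = el, c_start = c_start, d_start = d_start,
           g1_start = g1_start, g1len = g1len, t1s = t1s,
           cp_start = if (with_internal) mid_start else NA_integer_,
           g2_start = if (with_internal) mid_start + 7L else NA_integer_,
           g2len = g2len, t2s = t2s,
           dp_start = if (with_internal) mid_start + 7L + g2len
           else NA_integer_)
    }
    ok <- NULL
    for (try in 1:60) {
      b <- build()
      ann <- pair_cd_boxes(b$el)
      if (is.null(ann)) next
      if (!is.null(detect_haca_architecture(b$el))) next
      bx <- ann$boxes
      cb <- bx[bx$role == "C", ]
      db <- bx[bx$role == "D", ]
      if (cb$start != b$c_start || db$start != b$d_start) next
      want_pairs <- if (with_internal) 2L else 1L
      if (nrow(ann$box_pairs) != want_pairs) next
      if (with_internal) {
        cp <- bx[bx$role == "Cprime", ]
        dp <- bx[bx$role == "Dprime", ]
        if (nrow(cp) != 1 || cp$start != b$cp_start ||
            dp$start != b$dp_start) next
      }
      ok <- b
      break
    }
    if (is.null(ok)) abort("could not construct an unambiguous C/D element")
    if (is.null(intron)) {
      intron <- pick_intron(g, nchar(ok$el) + 40L)
    }
    if (intron$end - intron$start < nchar(ok$el) + 40L) {
      abort("no eligible intron")
    }
    pos <- intron$start + 20L +
      sample.int(intron$end - intron$start - nchar(ok$el) - 40L + 1L, 1) - 1L
    g <- insert_at(g, intron$seqid, pos, ok$el)
    note <- paste0("C=", ok$c_start, "-", ok$c_start + 7L,
                   ";D=", ok$d_start, "-", ok$d_start + 4L,
                   if (!is.na(ok$cp_start)) {
                     paste0(";Cp=", ok$cp_start, "-", ok$cp_start + 7L,
                            ";Dp=", ok$dp_start, "-", ok$dp_start + 4L)
                   } else "")
    rows <- bind_rows(
      tibble(element_id = id, type = "cd_sno", seq_id = intron$seqid,
             start = pos, end = pos + nchar(ok$el), strand = "+",
             parent_id = NA_character_, note = note),
      tibble(element_id = paste0(id, "_guide1"), type = "guide",
             seq_id = intron$seqid, start = pos + ok$g1_start,
             end = pos + ok$g1_start + ok$g1len, strand = "+",
             parent_id = id, note = "terminal"),
      tibble(element_id = paste0(id, "_site1"), type = "target_site",
             seq_id = target$id, start = ok$t1s, end = ok$t1s + ok$g1len,
             strand = "+", parent_id = id, note = "terminal"))
    if (!is.na(ok$g2_start)) {
      rows <- bind_rows(rows,
        tibble(element_id = paste0(id, "_guide2"), type = "guide",
               seq_id = intron$seqid, start = pos + ok$g2_start,
               end = pos + ok$g2_start + ok$g2len, strand = "+",
               parent_id = id, note = "internal"),
        tibble(element_id = paste0(id, "_site2"), type = "target_site",
               seq_id = target$id, start = ok$t2s, end = ok$t2s + ok$g2len,
               strand = "+", parent_id = id, note = "internal"))
    }
    g$truth <- bind_rows(g$truth, rows)
    g
  })
}

#' Plant an H/ACA box snoRNA into an intron
#'
#' Builds a ~120-140 nt two-hairpin element whose 5' hairpin carries an
#' internal-loop pocket complementary to the supplied target around a
#' uridine at `psi_pos` (the pseudouridine dinucleotide left unpaired), an
#' H box between the hairpins, and the terminal `ACA` box 6 nt before the
#' 3' end. Stems, loops and linkers are resampled until the detected
#' architecture recovers the planted pocket exactly and the planted
#' pseudouridine site is re-predicted, making the construction unambiguous
#' by design.
#'
#' @param g A `synth_genome`.
#' @param target One-row target tibble (`id`, `seq`).
#' @param psi_pos 0-based target position of the pseudouridine; its base
#'   must be `T`/`U`.
#' @param intron Optional intron row; default random eligible intron.
#' @param id Element id.
#' @param seed Integer seed.
#' @return The updated `synth_genome`.
#' @export
plant_haca_sno <- function(g, target, psi_pos, intron = NULL, id = NULL,
                           seed = 1L) {
  stopifnot(nrow(target) == 1)
  tb <- target$seq
  if (substr(tb, psi_pos + 1, psi_pos + 1) != "T") {
    abort("target base at psi_pos is not a uridine")
  }
  withr::with_seed(seed, {
    if (is.null(id)) id <- paste0("haca_",
                                  sum(g$truth$type == "haca_sno") + 1L)
    build <- function() {
      # pairing regions complementary to the target around the psi site;
      # the outer end of each pocket arm gets a short random pad so that
      # chance helix extension from the lower stem never eats into them
      pair_l <- sample(4:5, 1)
      pair_r <- sample(4:5, 1)
      if (psi_pos - pair_r < 0 || psi_pos + 2 + pair_l > nchar(tb)) {
        abort("psi_pos too close to the target ends for the pocket arms")
      }
      up <- substr(tb, psi_pos - pair_r + 1, psi_pos)
      dn <- substr(tb, psi_pos + 3, psi_pos + 2 + pair_l)
      pad_l <- sample(2:3, 1)
      pad_r <- sample(2:3, 1)
      la <- paste0(rand_bases(pad_l), revcomp(dn))
      ra <- paste0(revcomp(up), rand_bases(pad_r))
      s1 <- rand_bases(12)
      u1 <- rand_bases(8)
      al <- rand_bases(5)
      hp5 <- paste0(s1, la, u1, al, revcomp(u1), ra, revcomp(s1))
      hbox <- paste0("A", rand_bases(1), "A", rand_bases(2), "A")
      s2 <- rand_bases(13)
      lp2 <- rand_bases(6)
      linker <- rand_bases(sample(18:30, 1))
      el <- paste0(hp5, hbox, s2, lp2, revcomp(s2), linker, "ACA",
                   rand_bases(3))
      list(el = el, pair_l = pair_l, pair_r = pair_r,
           # junction-adjacent pairing regions, element coordinates
           lp_start = 12L + pad_l, lp_end = 12L + pad_l + pair_l,
           rp_start = nchar(hp5) - 12L - pad_r - pair_r,
           rp_end = nchar(hp5) - 12L - pad_r,
           h_start = nchar(hp5))
    }
    ok <- NULL
    for (try in 1:100) {
      b <- build()
      if (!is.null(pair_cd_boxes(b$el))) next
      ann <- detect_haca_architecture(b$el)
      if (is.null(ann)) next
      if (ann$h_box$start != b$h_start) next
      po <- ann$pockets
      # a detected pocket must end exactly at the planted stem junctions
      # and fully cover both planted pairing regions
      hit <- po$l_end == b$lp_end & po$r_start == b$rp_start &
        po$l_start <= b$lp_start & po$r_end >= b$rp_end
      if (!any(hit)) next
      pred <- predict_haca_target(ann, target)
      if (!any(pred$psi_pos == psi_pos & pred$target_id == target$id &
                 pred$score >= b$pair_l + b$pair_r)) next
      ok <- b
      break
    }
    if (is.null(ok)) abort("could not construct an unambiguous H/ACA element")
    l_arm_len <- ok$pair_l
    r_arm_len <- ok$pair_r
    if (is.null(intron)) intron <- pick_intron(g, nchar(ok$el) + 40L)
    if (intron$end - intron$start < nchar(ok$el) + 40L) {
      abort("no eligible intron")
    }
    pos <- intron$start + 20L +
      sample.int(intron$end - intron$start - nchar(ok$el) - 40L + 1L, 1) - 1L
    g <- insert_at(g, intron$seqid, pos, ok$el)
    note <- paste0("h=", ok$h_start, "-", ok$h_start + 6L,
                   ";l_pair=", ok$lp_start, "-", ok$lp_end,
                   ";r_pair=", ok$rp_start, "-", ok$rp_end,
                   ";psi=", target$id, ":", psi_pos)
    g$truth <- bind_rows(g$truth,
      tibble(element_id = id, type = "haca_sno", seq_id = intron$seqid,
             start = pos, end = pos + nchar(ok$el), strand = "+",
             parent_id = NA_character_, note = note),
      tibble(element_id = paste0(id, "_site"), type = "target_site",
             seq_id = target$id, start = psi_pos - r_arm_len,
             end = psi_pos + 2L + l_arm_len, strand = "+",
             parent_id = id, note = paste0("psi=", psi_pos)))
    g
  })
}

#' Plant a SINE-like retrocopy of a planted snoRNA
#'
#' Copies the source element, appends a poly(A) tail, duplicates
#' `tsd_len` bases of the insertion site on both ends of the insertion
#' (the target site duplication), optionally writes the L1 endonuclease
#' motif `TTAAAA` at the 5' junction, and applies i.i.d. point
#' substitutions to the inserted copy at `mut_rate`. The ledger records
#' the retrocopy, its poly(A), both TSD copies and the L1 site.
#'
#' @param g A `synth_genome`.
#' @param source_id Element id of a planted snoRNA to copy.
#' @param site 0-based intergenic insertion position (`NULL`: random
#'   intergenic site on the source's sequence). Planting inside an
#'   existing planted element is an error.
#' @param tsd_len TSD length, 5-50.
#' @param polya_len Poly(A) length, 8-30.
#' @param with_l1 Write the `TTAAAA` motif at the 5' junction.
#' @param mut_rate Per-base substitution rate on the inserted copy.
#' @param id Element id.
#' @param seed Integer seed.
#' @return The updated `synth_genome`.
#' @export
plant_retrocopy <- function(g, source_id, site = NULL, tsd_len = 12L,
                            polya_len = 15L, with_l1 = TRUE, mut_rate = 0,
                            id = NULL, seed = 1L) {
  if (tsd_len < 5 || tsd_len > 50) abort("tsd_len must be in [5, 50]")
  if (polya_len < 8 || polya_len > 30) abort("polya_len must be in [8, 30]")
  src <- g$truth[g$truth$element_id == source_id &
                   g$truth$type %in% c("cd_sno", "haca_sno"), ]
  if (nrow(src) != 1) abort(paste0("unknown source element: ", source_id))
  withr::with_seed(seed, {
    if (is.null(id)) id <- paste0("retro_",
                                  sum(g$truth$type == "retrocopy") + 1L)
    k <- match(src$seq_id, g$seqs$id)
    gseq <- g$seqs$seq[k]
    glen <- nchar(gseq)
    if (is.null(site)) {
      # random intergenic site away from genes, elements and sequence ends
      spans <- g$exons %>%
        filter(.data$seqid == src$seq_id) %>%
        group_by(.data$gene_id) %>%
        summarise(start = min(.data$start), end = max(.data$end),
                  .groups = "drop")
      for (try in 1:300) {
        cand <- sample(seq(1000L, glen - 1000L), 1)
        in_gene <- nrow(spans) > 0 &&
          any(spans$start - 60 <= cand & spans$end + 60 >= cand)
        in_el <- any(g$truth$seq_id == src$seq_id &
                       g$truth$start - 200 < cand &
                       g$truth$end + 200 > cand)
        # the duplicated site must not begin with adenosines, or the TSD
        # would be indistinguishable from the end of the poly(A) tail
        a_lead <- grepl("A", substr(gseq, cand + 1, cand + 2), fixed = TRUE)
        if (!in_gene && !in_el && !a_lead) { site <- cand; break }
      }
      if (is.null(site)) abort("could not find an intergenic insertion site")
    }
    if (any(g$truth$seq_id == src$seq_id & g$truth$start < site &
              g$truth$end > site)) {
      abort("insertion site inside an existing planted element")
    }
    if (with_l1) {
      substr(g$seqs$seq[k], site - 5L, site) <- "TTAAAA"
      gseq <- g$seqs$seq[k]
    }
    element <- substr(gseq, src$start + 1, src$end)
    tsd <- substr(gseq, site + 1, site + tsd_len)
    ins <- mutate_seq(paste0(element, strrep("A", polya_len), tsd), mut_rate)
    pos <- site + tsd_len
    g <- insert_at(g, src$seq_id, pos, ins)
    el_len <- nchar(element)
    g$truth <- bind_rows(g$truth,
      tibble(element_id = id, type = "retrocopy", seq_id = src$seq_id,
             start = pos, end = pos + el_len, strand = "+",
             parent_id = source_id,
             note = paste0("mut_rate=", mut_rate)),
      tibble(element_id = paste0(id, "_polya"), type = "polya",
             seq_id = src$seq_id, start = pos + el_len,
             end = pos + el_len + polya_len, strand = "+",
             parent_id = id, note = NA_character_),
      tibble(element_id = paste0(id, "_tsd_up"), type = "tsd",
             seq_id = src$seq_id, start = site, end = site + tsd_len,
             strand = "+", parent_id = id, note = "upstream"),
      tibble(element_id = paste0(id, "_tsd_down"), type = "tsd",
             seq_id = src$seq_id, start = pos + el_len + polya_len,
             end = pos + el_len + polya_len + tsd_len,
             strand = "+", parent_id = id, note = "downstream"))
    if (with_l1) {
      g$truth <- bind_rows(g$truth,
        tibble(element_id = paste0(id, "_l1"), type = "l1_site",
               seq_id = src$seq_id, start = site - 6L, end = site,
               strand = "+", parent_id = id, note = NA_character_))
    }
    g
  })
}

#' Generate a synthetic target RNA database
#'
#' Emulates the reference RNA collections used for snoRNA target
#' prediction: a handful of rRNA-, snRNA- and tRNA-like records with class
#' tags in their description lines. Every 20-nt window of every record is
#' guaranteed to contain a uridine, so pseudouridylation candidates exist
#' throughout.
#'
#' @param seed Integer seed.
#' @return Sequence tibble `id`, `desc`, `seq`, `class`.
#' @export
gen_target_db <- function(seed = 1L) {
  withr::with_seed(seed, {
    spec <- tibble(id = c("rRNA_LSU_like", "snRNA_U_like", "tRNA_like",
                          "misc_RNA_1"),
                   class = c("rRNA", "snRNA", "tRNA", "other"),
                   len = c(1500L, 300L, 150L, 400L))
    seqs <- vapply(spec$len, function(n) {
      s <- strsplit(rand_bases(n, gc = 0.5), "")[[1]]
      # constructive uridine guarantee: one T in every 20-nt window
      for (w0 in seq(1, n, by = 20)) {
        w1 <- min(n, w0 + 19)
        if (!any(s[w0:w1] == "T")) s[w0 + 10] <- "T"
      }
      paste(s, collapse = "")
    }, character(1))
    tibble(id = spec$id,
           desc = paste0(spec$id, " class=", spec$class, " seed=", seed),
           seq = seqs, class = spec$class)
  })
}

#' Generate a full synthetic study data set
#'
#' Convenience orchestrator: one genome, a target database, `n_cd` C/D
#' and `n_haca` H/ACA snoRNAs planted into introns, and `n_retro`
#' retrocopies of the planted elements inserted intergenically.
#'
#' @param seed Master integer seed (per-element seeds are derived from
#'   it).
#' @param n_cd,n_haca,n_retro Element counts.
#' @param length,n_seq,gc,n_genes Genome parameters.
#' @param retro_mut_rate Substitution rate on retrocopies.
#' @param retro_with_l1 Plant the L1 motif on retrocopies.
#' @return List `genome` (a `synth_genome`), `targets`.
#' @export
synth_study <- function(seed = 1L, n_cd = 2L, n_haca = 2L, n_retro = 0L,
                        length = 60000L, n_seq = 1L, gc = 0.5,
                        n_genes = max(3L, (n_cd + n_haca + 1L)),
                        retro_mut_rate = 0, retro_with_l1 = TRUE) {
  targets <- gen_target_db(seed)
  g <- gen_genome(n_seq = n_seq, length = length, gc = gc,
                  n_genes = n_genes, seed = seed)
  rr <- targets[targets$class == "rRNA", ][1, ]
  for (i in seq_len(n_cd)) {
    g <- plant_cd_sno(g, rr, with_internal = i %% 2L == 1L,
                      seed = seed * 1000L + i)
  }
  # candidate pseudouridine sites; sites whose flanking complementarity
  # folds back on itself are skipped for the next candidate
  t_positions <- withr::with_seed(seed + 7L, {
    tpos <- which(strsplit(rr$seq, "")[[1]] == "T") - 1L
    tpos <- tpos[tpos >= 10 & tpos <= nchar(rr$seq) - 10]
    sample(tpos, min(length(tpos), max(3L * n_haca, 1L)))
  })
  planted <- 0L
  for (i in seq_along(t_positions)) {
    if (planted >= n_haca) break
    ok <- tryCatch({
      g <- plant_haca_sno(g, rr, psi_pos = t_positions[i],
                          seed = seed * 2000L + i)
      TRUE
    }, error = function(e) {
      if (grepl("unambiguous", conditionMessage(e))) FALSE else stop(e)
    })
    if (ok) planted <- planted + 1L
  }
  if (planted < n_haca) {
    abort("exhausted pseudouridine site candidates during planting")
  }
  sources <- g$truth$element_id[g$truth$type %in% c("cd_sno", "haca_sno")]
  for (i in seq_len(n_retro)) {
    src <- sources[(i - 1L) %% length(sources) + 1L]
    g <- plant_retrocopy(g, src, mut_rate = retro_mut_rate,
                         with_l1 = retro_with_l1,
                         seed = seed * 3000L + i)
  }
  list(genome = g, targets = targets)
}

#' Write a synthetic genome to FASTA + GFF3 + truth TSV
#'
#' @param g A `synth_genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synth <- function(g, dir, prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_fasta(g$seqs, fa)
  con <- file(gff, "wt")
  writeLines(c("##gff-version 3",
               paste0("# synthetic genome seed=", g$seed)), con)
  genes <- g$exons %>%
    group_by(.data$seqid, .data$strand, .data$gene_id) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  for (i in seq_len(nrow(genes))) {
    r <- genes[i, ]
    writeLines(paste(r$seqid, "snoscout", "gene", r$start + 1L, r$end, ".",
                     r$strand, ".", paste0("ID=", r$gene_id), sep = "\t"),
               con)
  }
  for (i in seq_len(nrow(g$exons))) {
    r <- g$exons[i, ]
    writeLines(paste(r$seqid, "snoscout", "exon", r$start + 1L, r$end, ".",
                     r$strand, ".", paste0("Parent=", r$gene_id), sep = "\t"),
               con)
  }
  close(con)
  write_tsv_commented(g$truth, truth,
                      comment = paste0("planted-element truth ledger seed=",
                                       g$seed))
  invisible(c(fasta = fa, gff = gff, truth = truth))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-walk shuffle preserving the dinucleotide composition;
#' used for negative structural controls.
#'
#' @param s Sequence (character scalar).
#' @param seed Integer seed.
#' @return Shuffled sequence with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(s, seed = 1L) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3) return(s)
  withr::with_seed(seed, {
    for (attempt in 1:200) {
      edges <- split(ch[-1], ch[-n])  # outgoing edges per source base
      edges <- lapply(edges, sample)
      walk <- character(n)
      walk[1] <- ch[1]
      ok <- TRUE
      for (i in 2:n) {
        src <- walk[i - 1]
        out <- edges[[src]]
        if (is.null(out) || length(out) == 0) { ok <- FALSE; break }
        walk[i] <- out[1]
        edges[[src]] <- out[-1]
      }
      if (ok) return(paste(walk, collapse = ""))
    }
    abort("dinucleotide shuffle failed to find an Eulerian walk")
  })
}
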