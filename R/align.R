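#' Reverse complement
#'
#' @param x Character vector of DNA sequences (`A,C,G,T,N`).
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @examples
#' revcomp("AAAC")
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Alignment scoring scheme
#'
#' Default scheme mirrors common nucleotide-search practice: match +1,
#' mismatch -3, affine gaps with open -5 and extension -2 (a gap of length
#' k costs `gap_open + k * gap_ext`).
#'
#' @param match Positive match score.
#' @param mismatch Negative mismatch score.
#' @param gap_open Negative gap opening penalty.
#' @param gap_ext Negative per-base gap extension penalty.
#' @return A named list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -3, gap_open = -5,
                          gap_ext = -2) {
  if (match <= 0 || mismatch >= 0 || gap_open >= 0 || gap_ext >= 0) {
    abort("scoring must have match > 0 and mismatch/gap penalties < 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "align_scoring")
}

#' Optimal local alignment of two sequences
#'
#' Explicit affine-gap Smith-Waterman dynamic programming with a
#' deterministic traceback: among equal-scoring cells the one with the
#' smallest query coordinate wins, and diagonal moves are preferred during
#' traceback.
#'
#' @param query,subject Single DNA sequences (character scalars).
#' @param scoring An [align_scoring()] scheme.
#' @return One-row tibble: `score`, 0-based half-open `qstart`, `qend`,
#'   `sstart`, `send`, `matches`, `aligned_len` (alignment columns),
#'   `gaps`, `identity` (= matches / aligned_len) and the aligned strings
#'   `qaln`, `saln`.
#' @examples
#' local_align("ACGT", "ACGT")
#' @export
local_align <- function(query, subject, scoring = align_scoring()) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1, length(subject) == 1)
  if (nchar(query) == 0 || nchar(subject) == 0) {
    abort("local_align requires non-empty sequences")
  }
  r <- sw_align_cpp(query, subject, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_ext)
  tibble(score = r$score,
         qstart = r$qstart, qend = r$qend,
         sstart = r$sstart, send = r$send,
         matches = r$matches, aligned_len = r$aligned_len, gaps = r$gaps,
         identity = ifelse(r$aligned_len > 0, r$matches / r$aligned_len, 0),
         qaln = r$qaln, saln = r$saln)
}

#' Conservation score of ncRNAs against another genome
#'
#' The score of one ncRNA in one genome is the best-hit product of
#' alignment coverage and identity: `max over hits of
#' (align_len / query_length) * identity`, clipped to `[0, 1]`; `0` when
#' no hit qualifies. A score of 1 therefore requires a full-length perfect
#' hit. Hits may come from an imported hit table (genome-scale searches
#' delegated to an external engine) or be computed in-process against a
#' genome sequence with [local_align()].
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @param hits Optional hit tibble as from [read_hits()]; matched to
#'   queries by `query_id`.
#' @param genome Optional genome sequence tibble to align against
#'   in-process (used when `hits` is `NULL`).
#' @param genome_label Label recorded in the output.
#' @param scoring Scoring scheme for in-process alignment.
#' @return Tibble with `ncrna_id`, `genome_label`, `score`.
#' @export
conservation_score <- function(seqs, hits = NULL, genome = NULL,
                               genome_label = "genome",
                               scoring = align_scoring()) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  score_one <- function(id, s) {
    qlen <- nchar(s)
    if (!is.null(hits)) {
      h <- hits[hits$query_id == id, , drop = FALSE]
      if (nrow(h) == 0) return(0)
      max(pmin(1, (h$align_len / qlen) * h$pct_identity))
    } else if (!is.null(genome)) {
      best <- 0
      for (g in genome$seq) {
        for (subj in c(g, revcomp(g))) {
          a <- local_align(s, subj, scoring)
          best <- max(best, min(1, (a$aligned_len / qlen) * a$identity))
        }
      }
      best
    } else {
      0
    }
  }
  tibble(ncrna_id = seqs$id, genome_label = genome_label,
         score = purrr::map2_dbl(seqs$id, seqs$seq, score_one))
}

#' Collapse redundant sequences into clusters
#'
#' Greedy clustering by decreasing length: a sequence joins the cluster of
#' a longer representative when it aligns to it at >= `min_identity` over
#' >= `min_coverage` of its own length; otherwise it founds a new cluster.
#' The representative is the longest member (ties broken by the
#' lexicographically smallest id).
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param min_identity Identity threshold (default 0.99).
#' @param min_coverage Fraction of the joining sequence's own length that
#'   must be aligned (default 0.95).
#' @param scoring Scoring scheme.
#' @return Tibble `id`, `length`, `cluster` (representative id),
#'   `is_representative`.
#' @export
cluster_redundant <- function(seqs, min_identity = 0.99,
                              min_coverage = 0.95,
                              scoring = align_scoring()) {
  stopifnot(nrow(seqs) >= 1)
  ord <- order(-nchar(seqs$seq), seqs$id)
  ids <- seqs$id[ord]
  ss <- seqs$seq[ord]
  reps <- character(0)
  rep_seq <- character(0)
  assign <- character(length(ids))
  for (k in seq_along(ids)) {
    placed <- NA_character_
    for (r in seq_along(reps)) {
      a <- local_align(ss[k], rep_seq[r], scoring)
      cov <- (a$qend - a$qstart) / nchar(ss[k])
      if (a$identity >= min_identity && cov >= min_coverage) {
        placed <- reps[r]
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, ids[k])
      rep_seq <- c(rep_seq, ss[k])
      placed <- ids[k]
    }
    assign[k] <- placed
  }
  tibble(id = ids, length = nchar(ss), cluster = assign,
         is_representative = ids == assign) %>%
    arrange(match(.data$id, seqs$id))
}
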