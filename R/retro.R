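#' Find poly(A) runs in a 3' flank
#'
#' Reports maximal non-overlapping runs in the first `window` nt of the
#' flank that start and end on an `A`, contain at least `min_purity`
#' adenosine, and are at least `min_len` nt long, in 5' to 3' order. Runs
#' are grown greedily from left to right: a run absorbs downstream `A`s as
#' long as overall purity stays at or above the threshold.
#'
#' @param flank3 3'-flanking sequence (character scalar, 5' to 3' away
#'   from the element).
#' @param window Search window from the element boundary (default 100 nt).
#' @param min_len Minimum run length (default 8).
#' @param min_purity Minimum A fraction within a run (default 0.9).
#' @return Tibble `start` (0-based), `length`, `n_a`.
#' @examples
#' find_polya(paste0("CC", strrep("A", 12), "GG"))
#' @export
find_polya <- function(flank3, window = 100L, min_len = 8L,
                       min_purity = 0.9) {
  w <- substr(flank3, 1, min(window, nchar(flank3)))
  ch <- strsplit(w, "")[[1]]
  is_a <- ch == "A"
  n <- length(ch)
  out <- list()
  k <- 1L
  while (k <= n) {
    if (!is_a[k]) { k <- k + 1L; next }
    # grow from k: extend end to further A positions while purity holds
    end <- k
    j <- k + 1L
    while (j <= n) {
      if (is_a[j]) {
        purity <- sum(is_a[k:j]) / (j - k + 1L)
        if (purity >= min_purity) end <- j
        # an A that breaks purity could still be reachable later; but a
        # drop below threshold that never recovers ends the run
        if (purity < min_purity && (sum(is_a[k:j]) + 1) / (j - k + 2L) <
            min_purity) break
      } else if (sum(is_a[k:j]) / (j - k + 1L) < min_purity &&
                 (sum(is_a[k:j]) + 1) / (j - k + 2L) < min_purity) {
        break
      }
      j <- j + 1L
    }
    len <- end - k + 1L
    if (len >= min_len) {
      out[[length(out) + 1]] <- tibble(start = k - 1L, length = len,
                                       n_a = sum(is_a[k:end]))
    }
    k <- end + 1L
    if (len < min_len) k <- k + 1L
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), length = integer(), n_a = integer()))
  }
  bind_rows(out)
}

#' Find a target site duplication between two flanks
#'
#' Searches the last `window` nt of the 5' flank and the first `window` nt
#' of the (post-poly(A)) 3' flank for the longest duplicated substring with
#' Hamming mismatch fraction at most `max_mm_frac`; ties are broken by
#' fewer mismatches, then by the copy closest to the insertion boundary.
#' Although integration biology produces duplications of 5-50 bp, the
#' default minimum is 8 nt because shorter matches are overwhelmingly
#' spurious in windows of this size; the full range remains configurable.
#'
#' @param flank5 5'-flanking sequence (the insertion boundary is its 3'
#'   end).
#' @param flank3_after_polya 3' flank downstream of the last poly(A) run.
#' @param min_len,max_len Length bounds of the duplication (defaults 8
#'   and 50).
#' @param max_mm_frac Maximum mismatch fraction (default 0.1).
#' @param window Search window on each side (default 50 nt).
#' @return One-row tibble `up_start` (0-based on `flank5`), `down_start`
#'   (0-based on `flank3_after_polya`), `length`, `mismatches`, or `NULL`.
#' @export
find_tsd <- function(flank5, flank3_after_polya, min_len = 8L,
                     max_len = 50L, max_mm_frac = 0.1, window = 50L) {
  n5 <- nchar(flank5)
  a <- substr(flank5, max(1L, n5 - window + 1L), n5)
  off_a <- max(0L, n5 - window)
  b <- substr(flank3_after_polya, 1, min(window, nchar(flank3_after_polya)))
  if (nchar(a) < min_len || nchar(b) < min_len) return(NULL)
  r <- tsd_search_cpp(a, b, as.integer(min_len), as.integer(max_len),
                      max_mm_frac)
  if (r[3] == 0) return(NULL)
  tibble(up_start = off_a + r[1], down_start = r[2],
         length = r[3], mismatches = r[4])
}

#' Find an L1 endonuclease recognition site near the 5' TSD
#'
#' The LINE-1 nicking endonuclease preferentially cuts at `TTAAAA`-like
#' sites, leaving the motif immediately 5' of the target site duplication.
#' The best match to `TTAAAA` with at most 1 mismatch whose 6-mer overlaps
#' a `window`-nt region centred on the 5' TSD start is reported; ties are
#' broken by proximity of the motif end to the TSD start.
#'
#' @param flank5 5'-flanking sequence.
#' @param tsd_start 0-based start of the upstream TSD copy on `flank5`.
#' @param window Width of the centred search region (default 10 nt).
#' @return One-row tibble `position` (0-based motif start on `flank5`),
#'   `matched`, `mismatches`, or `NULL`.
#' @export
find_l1_site <- function(flank5, tsd_start, window = 10L) {
  n <- nchar(flank5)
  if (tsd_start < 0 || tsd_start > n) abort("tsd_start outside flank")
  motif <- "TTAAAA"
  half <- window %/% 2L
  lo <- max(0L, tsd_start - half - nchar(motif) + 1L)
  hi <- min(n - nchar(motif), tsd_start + half - 1L)
  if (hi < lo) return(NULL)
  best <- NULL
  for (p in seq(lo, hi)) {
    sub <- substr(flank5, p + 1, p + nchar(motif))
    mm <- sum(strsplit(sub, "")[[1]] != strsplit(motif, "")[[1]])
    if (mm > 1) next
    dist <- abs((p + nchar(motif)) - tsd_start)
    if (is.null(best) || mm < best$mm ||
        (mm == best$mm && dist < best$dist)) {
      best <- list(p = p, sub = sub, mm = mm, dist = dist)
    }
  }
  if (is.null(best)) return(NULL)
  tibble(position = best$p, matched = best$sub, mismatches = best$mm)
}

#' Call SINE-like retrogene features at one locus
#'
#' Combines the three diagnostic features of SINE-like retroposition on
#' the flanks of a locus: a poly(A) end, a target site duplication (TSD),
#' and an L1 endonuclease recognition site. The verdict is `"candidate"`
#' with poly(A) only, `"retrogene"` with poly(A) plus TSD,
#' `"L1_retrogene"` when an L1 site backs the TSD, and `"none"` otherwise.
#' The downstream TSD copy is searched strictly after the last reported
#' poly(A) run.
#'
#' @param flank5,flank3 Flanking sequences (default extraction windows of
#'   1 kb each side are the caller's responsibility).
#' @param locus_id Identifier carried into the output.
#' @param polya_window,polya_min_len,tsd_min_len,tsd_max_len,tsd_max_mm_frac,tsd_window,l1_window
#'   Passed to the feature detectors.
#' @return One-row tibble: `locus_id`, `n_polya`, `polya_start`,
#'   `polya_len`, `tsd_len`, `tsd_mm`, `tsd_up_start`, `tsd_down_start`
#'   (on `flank3` coordinates), `l1_pos`, `l1_mm`, `verdict`.
#' @export
call_retro <- function(flank5, flank3, locus_id = "locus",
                       polya_window = 100L, polya_min_len = 8L,
                       tsd_min_len = 8L, tsd_max_len = 50L,
                       tsd_max_mm_frac = 0.1, tsd_window = 50L,
                       l1_window = 10L) {
  pa <- find_polya(flank3, polya_window, polya_min_len)
  tsd <- NULL
  l1 <- NULL
  after <- 0L
  if (nrow(pa) > 0) {
    last <- pa[nrow(pa), ]
    after <- last$start + last$length
    tsd <- find_tsd(flank5, substr(flank3, after + 1, nchar(flank3)),
                    tsd_min_len, tsd_max_len, tsd_max_mm_frac, tsd_window)
    if (!is.null(tsd)) {
      l1 <- find_l1_site(flank5, tsd$up_start, l1_window)
    }
  }
  verdict <- if (nrow(pa) == 0) "none"
  else if (is.null(tsd)) "candidate"
  else if (is.null(l1)) "retrogene"
  else "L1_retrogene"
  tibble(locus_id = locus_id,
         n_polya = nrow(pa),
         polya_start = if (nrow(pa) > 0) pa$start[1] else NA_integer_,
         polya_len = if (nrow(pa) > 0) pa$length[1] else NA_integer_,
         tsd_len = if (!is.null(tsd)) tsd$length else NA_integer_,
         tsd_mm = if (!is.null(tsd)) tsd$mismatches else NA_integer_,
         tsd_up_start = if (!is.null(tsd)) tsd$up_start else NA_integer_,
         tsd_down_start = if (!is.null(tsd)) after + tsd$down_start
         else NA_integer_,
         l1_pos = if (!is.null(l1)) l1$position else NA_integer_,
         l1_mm = if (!is.null(l1)) l1$mismatches else NA_integer_,
         verdict = verdict)
}

#' Call retrogene features for loci on a genome
#'
#' Extracts `flank_len` nt of flanking sequence on each side of every
#' locus and runs [call_retro()].
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param loci Tibble `locus_id`, `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @param flank_len Flank length (default 1000 nt).
#' @param ... Passed to [call_retro()].
#' @return Tibble with one row per locus.
#' @export
call_retro_set <- function(genome, loci, flank_len = 1000L, ...) {
  purrr::map_dfr(seq_len(nrow(loci)), function(k) {
    l <- loci[k, ]
    g <- genome$seq[match(l$seq_id, genome$id)]
    if (is.na(g)) abort(paste0("unknown sequence id: ", l$seq_id))
    f5 <- substr(g, max(1L, l$start - flank_len + 1L), l$start)
    f3 <- substr(g, l$end + 1L, min(nchar(g), l$end + flank_len))
    call_retro(f5, f3, l$locus_id, ...)
  })
}

#' Shared consensus blocks among flanking sequences
#'
#' Star alignment against the longest flank: every other flank is locally
#' aligned to it and the alignment columns are projected onto the
#' reference coordinates. Maximal column ranges of at least `min_block`
#' columns in which at least `agreement` of the members (reference
#' included) carry the majority base are reported as consensus blocks --
#' the signature of a shared trans-duplicated segment.
#'
#' @param flanks Character vector of 3 or more flanking sequences.
#' @param min_block Minimum block length in reference columns
#'   (default 100).
#' @param agreement Minimum per-column fraction of members matching the
#'   majority base (default 0.7).
#' @param scoring Alignment scoring scheme.
#' @return Tibble `start`, `end` (0-based half-open on the longest
#'   flank), `length`, `mean_agreement`.
#' @export
flank_consensus <- function(flanks, min_block = 100L, agreement = 0.7,
                            scoring = align_scoring()) {
  if (length(flanks) < 3) abort("flank_consensus requires at least 3 flanks")
  ref_idx <- which.max(nchar(flanks))
  ref <- flanks[ref_idx]
  n <- nchar(ref)
  members <- flanks[-ref_idx]
  # per-member base observed at each reference column (NA where unaligned)
  mat <- matrix(NA_character_, nrow = length(members) + 1L, ncol = n)
  mat[1, ] <- strsplit(ref, "")[[1]]
  for (m in seq_along(members)) {
    a <- local_align(members[m], ref, scoring)
    if (a$aligned_len == 0) next
    qa <- strsplit(a$qaln, "")[[1]]
    sa <- strsplit(a$saln, "")[[1]]
    col <- a$sstart  # 0-based reference position of next reference base
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        if (qa[k] != "-") mat[m + 1L, col + 1L] <- qa[k]
        col <- col + 1L
      }
    }
  }
  n_members <- nrow(mat)
  colstat <- vapply(seq_len(n), function(j) {
    b <- mat[, j]
    b <- b[!is.na(b)]
    if (length(b) == 0) return(0)
    max(table(b)) / n_members
  }, numeric(1))
  ok <- colstat >= agreement
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- tibble(start = starts[r$values] - 1L,
                   end = ends[r$values],
                   length = r$lengths[r$values])
  blocks <- blocks[blocks$length >= min_block, , drop = FALSE]
  blocks$mean_agreement <- vapply(seq_len(nrow(blocks)), function(i) {
    mean(colstat[(blocks$start[i] + 1L):blocks$end[i]])
  }, numeric(1))
  blocks
}
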