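#' Box motif consensus definitions
#'
#' Consensus strings (IUPAC: `R` = A/G, `N` = any) and default mismatch
#' ceilings for the snoRNA hallmark boxes. The C/C' consensus is `RTGATGA`,
#' the D/D' consensus `CTGA`, the H box `ANANNA` and the 3' `ACA` box is
#' exact. `N` positions never count as mismatches.
#'
#' @return Named list of `list(pattern, max_mm)` per box kind.
#' @export
box_consensus <- function() {
  list(C      = list(pattern = "RTGATGA", max_mm = 2L),
       Cprime = list(pattern = "RTGATGA", max_mm = 3L),
       D      = list(pattern = "CTGA",    max_mm = 1L),
       Dprime = list(pattern = "CTGA",    max_mm = 1L),
       H      = list(pattern = "ANANNA",  max_mm = 1L),
       ACA    = list(pattern = "ACA",     max_mm = 0L))
}

iupac_mismatches <- function(seq, start0, pattern) {
  # mismatch count of pattern placed at 0-based start0 in seq
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(substr(seq, start0 + 1, start0 + length(p)), "")[[1]]
  ok <- mapply(function(pc, sc) {
    switch(pc,
           "N" = TRUE,
           "R" = sc %in% c("A", "G"),
           "Y" = sc %in% c("C", "T"),
           sc == pc)
  }, p, s)
  sum(!ok)
}

#' Scan a sequence for a box motif
#'
#' Reports all non-overlapping matches of the consensus for `kind` with at
#' most `max_mismatch` mismatches, ranked by (mismatches, 5' position);
#' overlap resolution is greedy in that ranking. Raising `max_mismatch`
#' never decreases the number of reported boxes.
#'
#' @param seq DNA sequence (character scalar).
#' @param kind One of `"C"`, `"Cprime"`, `"D"`, `"Dprime"`, `"H"`, `"ACA"`.
#' @param search_start,search_end 0-based half-open search region
#'   (default: whole sequence); the box must lie entirely inside it.
#' @param max_mismatch Mismatch ceiling; default from [box_consensus()].
#' @return Tibble `kind`, `start`, `end` (0-based half-open), `matched`,
#'   `mismatches`, ranked by (mismatches, position).
#' @examples
#' find_box("GGGTGATGACC", "C")
#' @export
find_box <- function(seq, kind, search_start = 0L, search_end = NULL,
                     max_mismatch = NULL) {
  cons <- box_consensus()
  if (!kind %in% names(cons)) abort(paste0("unknown box kind: ", kind))
  pat <- cons[[kind]]$pattern
  if (is.null(max_mismatch)) max_mismatch <- cons[[kind]]$max_mm
  len <- nchar(seq)
  w <- nchar(pat)
  if (is.null(search_end)) search_end <- len
  search_start <- max(0L, as.integer(search_start))
  search_end <- min(len, as.integer(search_end))
  starts <- seq_len(max(0L, search_end - w - search_start + 1L)) - 1L +
    search_start
  if (length(starts) == 0) {
    return(tibble(kind = character(), start = integer(), end = integer(),
                  matched = character(), mismatches = integer()))
  }
  mm <- vapply(starts, function(s0) iupac_mismatches(seq, s0, pat), 0)
  keep <- mm <= max_mismatch
  if (!any(keep)) {
    return(tibble(kind = character(), start = integer(), end = integer(),
                  matched = character(), mismatches = integer()))
  }
  cand <- tibble(kind = kind, start = starts[keep],
                 end = starts[keep] + w,
                 matched = substring(seq, starts[keep] + 1, starts[keep] + w),
                 mismatches = as.integer(mm[keep])) %>%
    arrange(.data$mismatches, .data$start)
  # greedy non-overlap in rank order
  taken <- rep(FALSE, nrow(cand))
  occupied <- integer(0)
  for (i in seq_len(nrow(cand))) {
    span <- seq(cand$start[i], cand$end[i] - 1L)
    if (!any(span %in% occupied)) {
      taken[i] <- TRUE
      occupied <- c(occupied, span)
    }
  }
  cand[taken, , drop = FALSE]
}

#' Detect and pair C/D snoRNA boxes
#'
#' The terminal pair is the best C box whose start lies within the first
#' `terminal_window` nt plus the best D box lying within the last
#' `terminal_window` nt; the combined mismatch count of the terminal pair
#' must not exceed `max_terminal_mm_total` (stricter than the per-box
#' ceilings, to keep chance matches in unrelated sequence rare). An
#' optional internal pair is the best C' box followed by the best D' box,
#' both strictly between the terminal boxes. Each pair's guide region is
#' the interval between the 3' end of its C-type box and the 5' start of
#' its D-type box.
#'
#' @param seq DNA sequence.
#' @param id Sequence id carried into the annotation.
#' @param terminal_window Width of the terminal search windows (nt).
#' @param max_terminal_mm_total Combined mismatch ceiling for the terminal
#'   C + D pair.
#' @return A `cd_annotation` (list with `sno_id`, `length`, `boxes`,
#'   `box_pairs`, `guides`), or `NULL` when no terminal pair exists.
#' @export
pair_cd_boxes <- function(seq, id = "", terminal_window = 25L,
                          max_terminal_mm_total = 1L) {
  len <- nchar(seq)
  cw <- nchar(box_consensus()$C$pattern)
  cboxes <- find_box(seq, "C", 0L, min(len, terminal_window + cw - 1L))
  cboxes <- cboxes[cboxes$start < terminal_window, , drop = FALSE]
  dboxes <- find_box(seq, "D", max(0L, len - terminal_window), len)
  if (nrow(cboxes) == 0 || nrow(dboxes) == 0) return(NULL)
  cb <- cboxes[1, ]
  db <- dboxes[1, ]
  if (cb$end > db$start) return(NULL)
  if (cb$mismatches + db$mismatches > max_terminal_mm_total) return(NULL)
  boxes <- bind_rows(mutate(cb, role = "C"), mutate(db, role = "D"))
  pairs <- tibble(pair = 1L, c_role = "C", c_start = cb$start, c_end = cb$end,
                  d_role = "D", d_start = db$start, d_end = db$end)
  # internal pair between the terminal boxes
  cp <- find_box(seq, "Cprime", cb$end, db$start)
  if (nrow(cp) > 0) {
    cp <- cp[1, ]
    dp <- find_box(seq, "Dprime", cp$end, db$start)
    if (nrow(dp) > 0) {
      dp <- dp[1, ]
      boxes <- bind_rows(boxes, mutate(cp, role = "Cprime"),
                         mutate(dp, role = "Dprime"))
      pairs <- bind_rows(pairs, tibble(pair = 2L, c_role = "Cprime",
                                       c_start = cp$start, c_end = cp$end,
                                       d_role = "Dprime", d_start = dp$start,
                                       d_end = dp$end))
    }
  }
  ann <- structure(list(sno_id = id, length = len, seq = seq,
                        boxes = boxes, box_pairs = pairs),
                   class = "cd_annotation")
  ann$guides <- extract_cd_guides(ann)
  ann
}

#' Fold a region by maximum base pairing
#'
#' Nussinov-style dynamic programming maximising the number of allowed
#' pairs (`AT`, `GC` and `GT` wobble) with a minimum hairpin loop of 3 nt;
#' the traceback closes the current helix before opening a new one, so the
#' reported structure is deterministic. Internal loops are reported as
#' pseudouridylation-style pockets: the stretches between two successive
#' nested major helices (>= `min_stem` stacked pairs), both arms at least
#' `min_arm` nt. Chance short stacks inside a loop are treated as part of
#' the pocket, so the pocket junctions stay anchored to the stable stems.
#'
#' @param seq DNA sequence.
#' @param start,end 0-based half-open region to fold (default: whole
#'   sequence); must be at least 6 nt (the shortest region that can hold
#'   one pair around a 3-nt loop).
#' @param min_arm Minimum single-stranded arm length for a pocket.
#' @param min_helix Minimum helix length: every helix must have at least
#'   this many contiguous stacked pairs (1 = classic maximum pairing;
#'   2 disallows isolated pairs).
#' @param structure Optional dot-bracket string for the region, bypassing
#'   the folding step entirely.
#' @return A `hairpin` list: `start`, `end`, `n_pairs`, `pairs` (tibble of
#'   0-based absolute `i`, `j`) and `pockets` (tibble `l_start`, `l_end`,
#'   `r_start`, `r_end`).
#' @export
fold_max_pairing <- function(seq, start = 0L, end = nchar(seq),
                             min_arm = 3L, min_stem = 4L, min_helix = 1L,
                             structure = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (end - start < 6) abort("fold region too short to pair")
  region <- substr(seq, start + 1, end)
  if (is.null(structure)) {
    partner <- nussinov_cpp(region, 3L, as.integer(min_helix))
  } else {
    partner <- parse_dot_bracket(structure)
    if (length(partner) != nchar(region)) {
      abort("dot-bracket length does not match region length")
    }
  }
  idx <- which(partner >= 0) - 1L
  pr <- tibble(i = idx, j = partner[idx + 1L])
  pr <- pr[pr$i < pr$j, , drop = FALSE]
  pockets <- internal_loops(partner, min_arm, min_stem)
  structure(list(start = start, end = end,
                 n_pairs = nrow(pr),
                 pairs = mutate(pr, i = .data$i + start, j = .data$j + start),
                 pockets = mutate(pockets,
                                  l_start = .data$l_start + start,
                                  l_end = .data$l_end + start,
                                  r_start = .data$r_start + start,
                                  r_end = .data$r_end + start)),
            class = "hairpin")
}

#' Parse a dot-bracket structure string
#'
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @return Integer partner vector (0-based, -1 for unpaired).
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  partner <- rep(-1L, length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      o <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[o] <- k - 1L
      partner[k] <- o - 1L
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  partner
}

# Maximal helices (runs of contiguous stacked pairs) of a 0-based partner
# vector: tibble of outer/inner coordinates and length, ordered 5' to 3'.
helices_from_partner <- function(partner) {
  n <- length(partner)
  out <- list()
  seen <- rep(FALSE, n)
  for (i0 in seq_len(n) - 1L) {
    j0 <- partner[i0 + 1L]
    if (j0 <= i0 || seen[i0 + 1L]) next
    # i0 starts a helix unless (i0-1, j0+1) is also a pair
    if (i0 > 0 && j0 + 1L < n && partner[i0] == j0 + 1L) next
    len <- 1L
    while (i0 + len < n && j0 - len > i0 + len &&
           partner[i0 + len + 1L] == j0 - len) {
      len <- len + 1L
    }
    seen[seq(i0, i0 + len - 1L) + 1L] <- TRUE
    out[[length(out) + 1]] <- tibble(outer_i = i0, outer_j = j0,
                                     inner_i = i0 + len - 1L,
                                     inner_j = j0 - len + 1L,
                                     helix_len = len)
  }
  if (length(out) == 0) {
    return(tibble(outer_i = integer(), outer_j = integer(),
                  inner_i = integer(), inner_j = integer(),
                  helix_len = integer()))
  }
  bind_rows(out)
}

# Internal loops read between successive nested major helices (at least
# `min_stem` stacked pairs): the two arms are everything between the outer
# helix's inner pair and the nested helix's outer pair. Minor helices
# (chance short stacks) inside a loop are treated as part of the
# single-stranded pocket -- short transient stacks do not abolish guide
# accessibility, and the junctions stay anchored to the stable stems.
internal_loops <- function(partner, min_arm = 3L, min_stem = 4L) {
  empty <- tibble(l_start = integer(), l_end = integer(),
                  r_start = integer(), r_end = integer())
  hel <- helices_from_partner(partner)
  major <- hel[hel$helix_len >= min_stem, , drop = FALSE]
  if (nrow(major) < 2) return(empty)
  out <- empty
  for (a in seq_len(nrow(major))) {
    A <- major[a, ]
    inside <- major$outer_i > A$inner_i & major$outer_j < A$inner_j
    if (sum(inside) == 0) next
    kids <- major[inside, , drop = FALSE]
    # direct children: not nested inside another candidate child
    direct <- vapply(seq_len(nrow(kids)), function(k) {
      !any(kids$outer_i < kids$outer_i[k] & kids$outer_j > kids$outer_j[k])
    }, logical(1))
    kids <- kids[direct, , drop = FALSE]
    if (nrow(kids) != 1) next  # hairpin loop or multiloop, not internal
    B <- kids[1, ]
    left <- B$outer_i - A$inner_i - 1L
    right <- A$inner_j - B$outer_j - 1L
    if (left >= min_arm && right >= min_arm) {
      out <- bind_rows(out, tibble(l_start = A$inner_i + 1L,
                                   l_end = B$outer_i,
                                   r_start = B$outer_j + 1L,
                                   r_end = A$inner_j))
    }
  }
  out
}

#' Detect the two-hairpin H/ACA snoRNA architecture
#'
#' Requires an exact `ACA` box starting exactly 6 nt before the 3' end
#' (followed by exactly 3 nt) and an H box (`ANANNA`, at most 1 mismatch)
#' in the middle third of the sequence. The segment 5' of the H box and
#' the segment between the H box and the ACA box are folded separately by
#' [fold_max_pairing()]; each half must form at least `min_pairs` pairs and
#' at least one half must present an internal-loop pocket.
#'
#' @param seq DNA sequence (at least 60 nt; shorter input yields `NULL`).
#' @param id Sequence id.
#' @param min_pairs Minimum pairs per hairpin half.
#' @param min_arm Minimum pocket arm length.
#' @param min_stem Minimum stacked-pair count for a helix to delimit a
#'   pocket.
#' @param min_helix Minimum helix length constraint of the fold.
#' @param structure5,structure3 Optional dot-bracket strings for the two
#'   halves, bypassing folding.
#' @return An `haca_annotation` (list with `sno_id`, `length`, `h_box`,
#'   `aca_box`, `hairpin5`, `hairpin3`, `pockets`), or `NULL`.
#' @export
detect_haca_architecture <- function(seq, id = "", min_pairs = 4L,
                                     min_arm = 3L, min_stem = 4L,
                                     min_helix = 1L, structure5 = NULL,
                                     structure3 = NULL) {
  len <- nchar(seq)
  if (len < 60) return(NULL)
  aca_start <- len - 6L
  if (substr(seq, aca_start + 1, aca_start + 3) != "ACA") return(NULL)
  third <- floor(len / 3)
  hb <- find_box(seq, "H", third, len - third)
  if (nrow(hb) == 0) return(NULL)
  hb <- hb[1, ]
  if (hb$start < 10 || (aca_start - hb$end) < 10) return(NULL)
  hp5 <- fold_max_pairing(seq, 0L, hb$start, min_arm = min_arm,
                          min_stem = min_stem, min_helix = min_helix,
                          structure = structure5)
  hp3 <- fold_max_pairing(seq, hb$end, aca_start, min_arm = min_arm,
                          min_stem = min_stem, min_helix = min_helix,
                          structure = structure3)
  if (hp5$n_pairs < min_pairs || hp3$n_pairs < min_pairs) return(NULL)
  pockets <- bind_rows(mutate(hp5$pockets, hairpin = "5prime"),
                       mutate(hp3$pockets, hairpin = "3prime"))
  if (nrow(pockets) == 0) return(NULL)
  structure(list(sno_id = id, length = len, seq = seq,
                 h_box = hb,
                 aca_box = tibble(kind = "ACA", start = aca_start,
                                  end = aca_start + 3L, matched = "ACA",
                                  mismatches = 0L),
                 hairpin5 = hp5, hairpin3 = hp3,
                 pockets = pockets),
            class = "haca_annotation")
}

#' Classify a sequence as C/D snoRNA, H/ACA snoRNA, or neither
#'
#' C/D detection ([pair_cd_boxes()]) takes precedence; a sequence
#' satisfying both architectures is reported as `"CD"` with a warning.
#'
#' @param seq DNA sequence.
#' @param id Sequence id.
#' @return List with `id`, `class` (`"CD"`, `"HACA"`, `"none"`) and
#'   `annotation` (the class annotation object or `NULL`).
#' @export
classify_sequence <- function(seq, id = "") {
  cd <- pair_cd_boxes(seq, id)
  haca <- detect_haca_architecture(seq, id)
  if (!is.null(cd)) {
    if (!is.null(haca)) {
      warn(paste0(id, ": sequence satisfies both C/D and H/ACA ",
                  "architectures; reporting C/D"))
    }
    return(list(id = id, class = "CD", annotation = cd))
  }
  if (!is.null(haca)) return(list(id = id, class = "HACA", annotation = haca))
  list(id = id, class = "none", annotation = NULL)
}

#' Classify every sequence in a tibble
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @return Tibble `id`, `class`.
#' @export
classify_sequences <- function(seqs) {
  tibble(id = seqs$id,
         class = purrr::map2_chr(seqs$seq, seqs$id,
                                 ~ classify_sequence(.x, .y)$class))
}

#' Count C/D box pairs across a sequence set
#'
#' Sums the number of (C/C', D/D') box pairs over all sequences classified
#' as C/D snoRNAs (1 or 2 per molecule).
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @return Integer pair total.
#' @export
count_cd_box_pairs <- function(seqs) {
  total <- 0L
  for (k in seq_len(nrow(seqs))) {
    ann <- pair_cd_boxes(seqs$seq[k], seqs$id[k])
    if (!is.null(ann)) total <- total + nrow(ann$box_pairs)
  }
  total
}
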