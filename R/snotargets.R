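#' Extract guide regions from a C/D annotation
#'
#' One guide per box pair: the interval between the 3' end of the C (or
#' C') box and the 5' start of the D (or D') box. Guides shorter than
#' `min_len` are dropped.
#'
#' @param ann A `cd_annotation` from [pair_cd_boxes()].
#' @param min_len Minimum guide length in nt (default 7).
#' @return Tibble `pair`, `start`, `end` (0-based half-open on the snoRNA).
#' @export
extract_cd_guides <- function(ann, min_len = 7L) {
  stopifnot(inherits(ann, "cd_annotation"))
  g <- ann$box_pairs %>%
    mutate(start = .data$c_end, end = .data$d_start) %>%
    filter(.data$end - .data$start >= min_len) %>%
    select("pair", "start", "end")
  g
}

target_priority <- c(rRNA = 1L, snRNA = 2L, tRNA = 3L, other = 4L)

# Ensure targets carry a class column; parse "class=..." tags from the
# FASTA description line, defaulting to "other".
target_classes <- function(targets) {
  if (!"class" %in% names(targets)) {
    cls <- if ("desc" %in% names(targets)) {
      m <- stringr::str_match(targets$desc, "class=(\\S+)")[, 2]
      ifelse(is.na(m), "other", m)
    } else {
      rep("other", nrow(targets))
    }
    targets$class <- cls
  }
  targets$class[!targets$class %in% names(target_priority)] <- "other"
  targets
}

complement_ok <- function(x, y, wobble = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (wobble) wc | (x == "G" & y == "T") | (x == "T" & y == "G") else wc
}

# Best ungapped antisense duplex of a guide against one target sequence.
# Watson-Crick pairs score `1`, G.T wobble pairs `wobble`; a non-pairing
# position terminates the duplex (no internal mismatches, no gaps).
# Returns NULL or a list(score, duplex_len, g_start, g_end, t_start, t_end)
# with the antiparallel mapping guide[g_start + k] <-> target[t_end - 1 - k].
best_duplex <- function(guide, target, wobble = 0.5, min_len = 7L) {
  g <- strsplit(guide, "")[[1]]
  t <- strsplit(target, "")[[1]]
  ng <- length(g); nt <- length(t)
  best <- NULL
  for (cc in seq(0L, ng + nt - 2L)) {
    p_lo <- max(0L, cc - nt + 1L)
    p_hi <- min(ng - 1L, cc)
    if (p_hi - p_lo + 1L < min_len) next
    p <- seq(p_lo, p_hi)
    gb <- g[p + 1L]
    tb <- t[cc - p + 1L]
    w <- ifelse((gb == "A" & tb == "T") | (gb == "T" & tb == "A") |
                  (gb == "G" & tb == "C") | (gb == "C" & tb == "G"), 1,
                ifelse((gb == "G" & tb == "T") | (gb == "T" & tb == "G"),
                       wobble, NA_real_))
    # contiguous complementary runs (NA breaks)
    r <- rle(!is.na(w))
    pos <- 1L
    for (seg in seq_along(r$lengths)) {
      L <- r$lengths[seg]
      if (r$values[seg] && L >= min_len) {
        sc <- sum(w[pos:(pos + L - 1L)])
        gs <- p_lo + pos - 1L
        ge <- gs + L
        te <- cc - gs + 1L
        ts <- te - L
        cand <- list(score = sc, duplex_len = L, g_start = gs, g_end = ge,
                     t_start = ts, t_end = te)
        if (is.null(best) || sc > best$score ||
            (sc == best$score && ts < best$t_start)) {
          best <- cand
        }
      }
      pos <- pos + L
    }
  }
  best
}

#' Predict the 2'-O-methylation target of one C/D guide
#'
#' Antisense-aligns the guide against every target without gaps,
#' scoring Watson-Crick pairs 1.0 and G.T wobble pairs `wobble`; the
#' best-scoring duplex wins, with ties broken by target class priority
#' (rRNA > snRNA > tRNA > other) and then by the lowest target
#' coordinate. Duplexes shorter than `min_len` nt are discarded.
#'
#' @param guide Guide sequence (character scalar, >= 7 nt).
#' @param targets Target tibble (`id`, `seq`, optional `class`/`desc`).
#' @param wobble Wobble pair weight (default 0.5).
#' @param min_len Minimum duplex length (default 7).
#' @return One-row tibble (`target_id`, `target_class`, `t_start`, `t_end`,
#'   `g_start`, `g_end`, `duplex_len`, `score`) or `NULL`.
#' @export
predict_cd_target <- function(guide, targets, wobble = 0.5, min_len = 7L) {
  if (nrow(targets) == 0) abort("empty target set")
  stopifnot(nchar(guide) >= min_len)
  targets <- target_classes(targets)
  best <- NULL
  for (k in seq_len(nrow(targets))) {
    d <- best_duplex(guide, targets$seq[k], wobble, min_len)
    if (is.null(d)) next
    pri <- target_priority[[targets$class[k]]]
    cand <- c(d, list(target_id = targets$id[k],
                      target_class = targets$class[k], pri = pri))
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$pri < best$pri) ||
        (cand$score == best$score && cand$pri == best$pri &&
         cand$t_start < best$t_start)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  tibble(target_id = best$target_id, target_class = best$target_class,
         t_start = best$t_start, t_end = best$t_end,
         g_start = best$g_start, g_end = best$g_end,
         duplex_len = best$duplex_len, score = best$score)
}

#' Predict 2'-O-methylation targets for a C/D annotation
#'
#' Runs [predict_cd_target()] for every guide of the annotation and
#' annotates the modified residue by the D+5 convention: the target base
#' paired to the guide base 5 nt upstream of the D/D' box (`NA` when that
#' base is outside the reported duplex). The convention is an annotation
#' only; it does not affect target selection.
#'
#' @param ann A `cd_annotation`.
#' @param targets Target tibble.
#' @param wobble,min_len Passed to [predict_cd_target()].
#' @return Tibble with one row per guide with a prediction: `sno_id`,
#'   `pair`, `guide_start`, `guide_end`, `target_id`, `target_class`,
#'   `t_start`, `t_end`, `duplex_len`, `score`, `modification`,
#'   `modified_pos`.
#' @export
predict_cd_targets <- function(ann, targets, wobble = 0.5, min_len = 7L) {
  stopifnot(inherits(ann, "cd_annotation"))
  out <- list()
  for (k in seq_len(nrow(ann$guides))) {
    g <- ann$guides[k, ]
    gseq <- substr(ann$seq, g$start + 1, g$end)
    p <- predict_cd_target(gseq, targets, wobble, min_len)
    if (is.null(p)) next
    glen <- g$end - g$start
    dpos <- glen - 5L  # guide-local index of the D+5 base
    modified_pos <- if (dpos >= p$g_start && dpos < p$g_end) {
      p$t_end - 1L - (dpos - p$g_start)
    } else {
      NA_integer_
    }
    out[[length(out) + 1]] <-
      tibble(sno_id = ann$sno_id, pair = g$pair,
             guide_start = g$start, guide_end = g$end,
             target_id = p$target_id, target_class = p$target_class,
             t_start = p$t_start, t_end = p$t_end,
             duplex_len = p$duplex_len, score = p$score,
             modification = "2primeOme", modified_pos = modified_pos)
  }
  if (length(out) == 0) {
    return(tibble(sno_id = character(), pair = integer(),
                  guide_start = integer(), guide_end = integer(),
                  target_id = character(), target_class = character(),
                  t_start = integer(), t_end = integer(),
                  duplex_len = integer(), score = double(),
                  modification = character(), modified_pos = integer()))
  }
  bind_rows(out)
}

#' Predict pseudouridylation targets for an H/ACA annotation
#'
#' For each internal-loop pocket, slides over every target seeking a
#' bipartite duplex: the target segment 3' of the candidate site pairs the
#' pocket's 5' (left) arm and the segment 5' of the site pairs the 3'
#' (right) arm, antiparallel, extending outward from the stem junctions;
#' between the two halves the target leaves an unpaired dinucleotide whose
#' first base is the candidate pseudouridine and must be a U. Accepted
#' when each half pairs at least `min_side` nt and both together at least
#' `min_total` nt.
#'
#' @param ann An `haca_annotation` from [detect_haca_architecture()].
#' @param targets Target tibble (`id`, `seq`, optional `class`).
#' @param min_side Minimum paired nt per duplex half (default 3).
#' @param min_total Minimum total paired nt (default 7).
#' @param wobble Allow G.T wobble pairs (default `TRUE`).
#' @return Tibble of accepted sites ranked by total paired nt, then target
#'   class priority, then coordinate: `sno_id`, `hairpin`, `pocket`,
#'   `target_id`, `target_class`, `site_start`, `site_end`, `psi_pos`
#'   (0-based, always a U), `left_len`, `right_len`, `score`,
#'   `modification`.
#' @export
predict_haca_target <- function(ann, targets, min_side = 3L, min_total = 7L,
                                wobble = TRUE) {
  stopifnot(inherits(ann, "haca_annotation"))
  if (nrow(ann$pockets) == 0) abort("annotation has no pockets")
  targets <- target_classes(targets)
  rows <- list()
  for (pk in seq_len(nrow(ann$pockets))) {
    po <- ann$pockets[pk, ]
    la <- strsplit(substr(ann$seq, po$l_start + 1, po$l_end), "")[[1]]
    ra <- strsplit(substr(ann$seq, po$r_start + 1, po$r_end), "")[[1]]
    for (k in seq_len(nrow(targets))) {
      tb <- strsplit(targets$seq[k], "")[[1]]
      nt <- length(tb)
      for (u in which(tb == "T") - 1L) {
        # upstream half: Ra[1 + m] pairs target[u - 1 - m], m = 0, 1, ...
        r <- 0L
        while (r < length(ra) && (u - 1L - r) >= 0 &&
               complement_ok(ra[r + 1L], tb[u - r], wobble)) {
          r <- r + 1L
        }
        if (r < min_side) next
        # downstream half: La[end - m] pairs target[u + 2 + m]
        l <- 0L
        while (l < length(la) && (u + 2L + l) < nt &&
               complement_ok(la[length(la) - l], tb[u + 3L + l], wobble)) {
          l <- l + 1L
        }
        if (l < min_side || l + r < min_total) next
        rows[[length(rows) + 1]] <-
          tibble(sno_id = ann$sno_id, hairpin = po$hairpin, pocket = pk,
                 target_id = targets$id[k], target_class = targets$class[k],
                 site_start = u - r, site_end = u + 2L + l,
                 psi_pos = u, left_len = l, right_len = r,
                 score = l + r, modification = "pseudouridine")
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(sno_id = character(), hairpin = character(),
                  pocket = integer(), target_id = character(),
                  target_class = character(), site_start = integer(),
                  site_end = integer(), psi_pos = integer(),
                  left_len = integer(), right_len = integer(),
                  score = integer(), modification = character()))
  }
  bind_rows(rows) %>%
    mutate(pri = target_priority[.data$target_class]) %>%
    arrange(desc(.data$score), .data$pri, .data$target_id, .data$psi_pos) %>%
    select(-"pri")
}
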