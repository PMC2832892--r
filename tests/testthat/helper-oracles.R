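# Independent reference implementations used as oracles.

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Plain-R affine-gap local alignment score (Gotoh three-matrix DP), written
# independently of the package kernel; a gap of length k costs
# gap_open + k * gap_ext.
ref_local_score <- function(a, b, match = 1, mismatch = -3,
                            gap_open = -5, gap_ext = -2) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_ext,
                             E[i + 1, j] + gap_ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_ext,
                             F[i, j + 1] + gap_ext)
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s,
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

pairable_ref <- function(x, y) {
  paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# True exhaustive enumeration of all non-crossing structures (no
# memoisation): maximum number of pairs with j - i > min_loop. Only
# feasible for short strings.
enum_max_pairs <- function(s, min_loop = 3) {
  ch <- strsplit(s, "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)            # i unpaired
    for (k in seq(i + min_loop + 1L, j)) {
      if (pairable_ref(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(ch))
}

# Memoised independent recursion (classic Nussinov form, distinct from the
# helix-decomposition kernel); handles n up to a few dozen.
memo_max_pairs <- function(s, min_loop = 3) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste0(i, ":", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- rec(i + 1L, j)
    for (k in seq(i + min_loop + 1L, j)) {
      if (pairable_ref(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# Planted-element sequence straight from the genome string.
truth_seq <- function(genome, row) {
  substr(genome$seqs$seq[match(row$seq_id, genome$seqs$id)],
         row$start + 1, row$end)
}

parse_note <- function(note) {
  parts <- strsplit(note, ";")[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=")[[1]]
    out[[kv[1]]] <- kv[2]
  }
  out
}

note_span <- function(note, key) {
  v <- parse_note(note)[[key]]
  as.integer(strsplit(v, "-")[[1]])
}
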