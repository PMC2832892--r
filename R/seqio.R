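#' Read a FASTA file into a sequence tibble
#'
#' Sequences are normalised to the uppercase DNA alphabet `A,C,G,T,N`.
#' RNA input (containing `U`) is recorded as `alphabet = "RNA"` and mapped
#' `U -> T`; [write_fasta()] restores the source alphabet, so a read/write
#' round trip is byte-identical for normalised input.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `desc` (full header line), `seq` and `alphabet`
#'   (`"DNA"` or `"RNA"`). Record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  desc <- names(set)
  id <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  raw <- unname(toupper(as.character(set)))
  bad <- grepl("[^ACGTUN]", raw)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in records: ",
                 paste(id[bad], collapse = ", ")))
  }
  alphabet <- ifelse(grepl("U", raw, fixed = TRUE), "RNA", "DNA")
  tibble(id = id, desc = desc,
         seq = chartr("U", "T", raw), alphabet = alphabet)
}

#' Write a sequence tibble to FASTA
#'
#' Rows with `alphabet == "RNA"` are written back with `T -> U` restored.
#'
#' @param seqs Tibble with columns `id` and `seq` (optionally `desc`,
#'   `alphabet`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  out <- seqs$seq
  if ("alphabet" %in% names(seqs)) {
    rna <- !is.na(seqs$alphabet) & seqs$alphabet == "RNA"
    out[rna] <- chartr("T", "U", out[rna])
  }
  hdr <- if ("desc" %in% names(seqs)) seqs$desc else seqs$id
  set <- Biostrings::BStringSet(out)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Load the packaged 117-entry ncRNA catalog
#'
#' The fixture transcribes the published table of 117 rhesus monkey
#' intermediate-size ncRNAs: clone counts, lengths, probe ids, northern-blot
#' expression calls in chicken/mouse/human, per-species conservation scores,
#' the printed expression-group label (1-6) and the printed consistency flag.
#' Cells printed as `**` (unavailable) load as `NA` and are excluded from
#' all score-based filters. The table is kept exactly as printed, including
#' its internal anomalies (e.g. two rows with a `no` call inside a group
#' block whose defining pattern is `yes`); the printed group label, not the
#' call pattern, defines block membership.
#'
#' @param path Path to a catalog TSV; defaults to the packaged fixture.
#' @return A tibble with 117 rows and columns `name`, `clone_count`,
#'   `length_nt`, `probe_id`, `det_chicken`, `det_mouse`, `det_human`
#'   (logical), `cons_chicken`, `cons_mouse`, `cons_human` (in `[0, 1]` or
#'   `NA`), `consistent` (`"Y"`, `"N"` or `NA`) and `group_label` (1-6).
#' @examples
#' cat117 <- load_catalog_fixture()
#' nrow(cat117)
#' @export
load_catalog_fixture <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    path <- system.file("extdata", "table1_catalog.tsv", package = "snoscout")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = "**",
                         col_types = readr::cols(
                           name = "c", clone_count = "i", length_nt = "i",
                           probe_id = "c", det_chicken = "c", det_mouse = "c",
                           det_human = "c", cons_chicken = "d",
                           cons_mouse = "d", cons_human = "d",
                           consistent = "c", group_label = "i"))
  rows <- raw %>%
    mutate(across(c("det_chicken", "det_mouse", "det_human"), ~ .x == "yes"))
  if (default && nrow(rows) != 117) {
    abort(paste0("catalog fixture integrity error: expected 117 rows, got ",
                 nrow(rows)))
  }
  rows
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` and `exon` features are used. Introns are computed per
#' transcript as the gaps between consecutive exons on the same strand, in
#' 0-based half-open coordinates; overlapping transcripts contribute the
#' union of their per-transcript introns.
#'
#' @param path Path to a GFF3 file.
#' @return A list of class `gene_models` with tibbles `genes`, `exons` and
#'   `introns` (all 0-based half-open: `seqid`, `start`, `end`, `strand`,
#'   plus `gene_id`/`transcript_id`).
#' @export
read_gene_models <- function(path) {
  gff <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  gff <- as_tibble(gff)
  attr_field <- function(x, key) {
    m <- stringr::str_match(x, paste0("(?:^|;)", key, "=([^;]+)"))
    m[, 2]
  }
  genes <- gff %>%
    filter(.data$type == "gene") %>%
    mutate(gene_id = attr_field(.data$attributes, "ID"),
           start = .data$start - 1L) %>%   # to 0-based half-open
    select("seqid", "start", "end", "strand", "gene_id")
  exons <- gff %>%
    filter(.data$type == "exon") %>%
    mutate(transcript_id = attr_field(.data$attributes, "Parent"),
           start = .data$start - 1L) %>%
    select("seqid", "start", "end", "strand", "transcript_id")
  # map exons to genes through transcript Parent or direct gene Parent
  mrna <- gff %>%
    filter(.data$type %in% c("mRNA", "transcript")) %>%
    mutate(transcript_id = attr_field(.data$attributes, "ID"),
           gene_id = attr_field(.data$attributes, "Parent")) %>%
    select("transcript_id", "gene_id")
  exons <- exons %>% left_join(mrna, by = "transcript_id") %>%
    mutate(gene_id = dplyr::coalesce(.data$gene_id, .data$transcript_id))
  # integrity: every exon inside its gene's span
  chk <- exons %>% dplyr::inner_join(genes, by = c("seqid", "gene_id"),
                                     suffix = c("", ".g"))
  if (nrow(chk) > 0 &&
      any(chk$start < chk$start.g | chk$end > chk$end.g)) {
    abort("exon outside its gene span")
  }
  introns <- exons %>%
    group_by(.data$seqid, .data$strand, .data$transcript_id, .data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(int_start = list(.data$end[-dplyr::n()]),
              int_end = list(.data$start[-1]), .groups = "drop") %>%
    tidyr::unnest(c("int_start", "int_end")) %>%
    filter(.data$int_end > .data$int_start) %>%
    rename(start = "int_start", end = "int_end") %>%
    distinct(.data$seqid, .data$start, .data$end, .data$strand,
             .data$gene_id, .data$transcript_id)
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_models")
}

#' Read a 12-column tabular alignment hit file
#'
#' The dialect is the standard tab-separated hit table (query, subject,
#' percent identity, alignment length, mismatches, gap openings, 1-based
#' query start/end, 1-based subject start/end, e-value, bit score).
#' Percent identity is converted to a fraction in `[0, 1]` and the match
#' strand is derived from the subject coordinate order (`plus/minus` when
#' `sstart > send`). Lines starting with `#` are ignored.
#'
#' @param path Path to the hit table.
#' @return A tibble with columns `query_id`, `subject_id`, `pct_identity`,
#'   `align_len`, `mismatches`, `gap_openings`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `strand`.
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "align_len",
            "mismatches", "gap_openings", "qstart", "qend",
            "sstart", "send", "evalue", "bitscore")
  h <- readr::read_tsv(path, comment = "#", col_names = cols,
                       show_col_types = FALSE,
                       col_types = "ccdiiiiiiidd")
  h %>% mutate(pct_identity = .data$pct_identity / 100,
               strand = ifelse(.data$sstart <= .data$send,
                               "plus/plus", "plus/minus"))
}

# Shared writer for tab-separated outputs with a commented header line.
write_tsv_commented <- function(tbl, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(tbl), collapse = "\t"), con)
  if (nrow(tbl) > 0) {
    body <- apply(tbl, 1, function(r) paste(ifelse(is.na(r), "NA", trimws(r)),
                                            collapse = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
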