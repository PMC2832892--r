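#' Priority-ordered library annotation from hit tables
#'
#' Library clones are annotated against several reference databases; hits
#' on the minus strand or weaker than the e-value stringency floor are
#' discarded, and each query is assigned from the first database in
#' priority order that retains a surviving hit (best hit = lowest e-value,
#' ties by highest bit score). Queries with no surviving hit anywhere are
#' `"unclassified"`.
#'
#' @param hits Hit tibble as from [read_hits()] with an additional `db`
#'   column naming the source database of each hit.
#' @param priority Character vector of database labels, highest priority
#'   first. Every `db` value in `hits` must appear in it.
#' @param max_evalue E-value stringency floor (default `1e-20`): hits with
#'   larger (less significant) e-values are discarded.
#' @return Tibble with one row per query: `query_id`, `assigned_class`
#'   (the subject id of the best hit, or `"unclassified"`), `source_db`,
#'   `evalue`, `bitscore`.
#' @export
annotate_by_priority <- function(hits,
                                 priority = c("rfam", "nt", "ensembl_ncrna",
                                              "refseq_mrna", "ensembl_cdna"),
                                 max_evalue = 1e-20) {
  stopifnot("db" %in% names(hits))
  unknown <- setdiff(unique(hits$db), priority)
  if (length(unknown) > 0) {
    abort(paste0("unknown database label(s): ", paste(unknown, collapse = ", ")))
  }
  surviving <- hits %>%
    filter(.data$strand == "plus/plus", .data$evalue <= max_evalue) %>%
    mutate(db_rank = match(.data$db, priority)) %>%
    arrange(.data$query_id, .data$db_rank, .data$evalue, desc(.data$bitscore))
  best <- surviving %>% group_by(.data$query_id) %>% dplyr::slice(1) %>% ungroup()
  all_q <- unique(hits$query_id)
  tibble(query_id = all_q) %>%
    left_join(best %>% select("query_id", "subject_id", "db",
                              "evalue", "bitscore"),
              by = "query_id") %>%
    mutate(assigned_class = ifelse(is.na(.data$subject_id), "unclassified",
                                   .data$subject_id),
           source_db = .data$db) %>%
    select("query_id", "assigned_class", "source_db", "evalue", "bitscore")
}

#' Assign an ncRNA class from its catalog name
#'
#' First matching rule wins, in this order: `SNORD*`, `U3*`, `U8`,
#' `snoU6*`, `snosnR60*` are C/D snoRNAs; `SNORA*` H/ACA snoRNAs;
#' `SCARNA*` scaRNAs (counted with the H/ACA box class in tallies);
#' `U1*`/`U2*`/`U4*`/`U5*`/`U6*`/`U11`/`U12` (including `atac` variants)
#' snRNAs; `Y<digit>` Y RNAs; `7SL*` SRP RNA; `7SK`; `RNaseP_nuc` (RPPH1);
#' `RNase_MRP` (RMRP); `Vault*`; `unclassified*`. Note the `snoU6` rule is
#' tested before the `U6` snRNA rule.
#'
#' @param name Character vector of catalog names.
#' @return Tibble `name`, `klass`, `is_snorna` (`TRUE` exactly for
#'   `snoRNA_CD`, `snoRNA_HACA` and `scaRNA`).
#' @examples
#' assign_class_by_name(c("SNORA36a", "snoU6-53", "U4atac"))
#' @export
assign_class_by_name <- function(name) {
  rules <- list(
    c("^(SNORD|U3[a-z]?$|U8$|snoU6|snosnR60)", "snoRNA_CD"),
    c("^SNORA", "snoRNA_HACA"),
    c("^SCARNA", "scaRNA"),
    c("^(U1|U2|U4|U5|U6|U11$|U12$)", "snRNA"),
    c("^Y[0-9]", "YRNA"),
    c("^7SL", "SRP"),
    c("^7SK$", "7SK"),
    c("^RNaseP_nuc$", "RPPH1"),
    c("^RNase_MRP$", "RMRP"),
    c("^Vault", "vault"),
    c("^unclassified", "unclassified"))
  klass <- rep(NA_character_, length(name))
  for (r in rules) {
    hit <- is.na(klass) & grepl(r[1], name)
    klass[hit] <- r[2]
  }
  if (anyNA(klass)) {
    abort(paste0("no classification rule matches: ",
                 paste(name[is.na(klass)], collapse = ", ")))
  }
  tibble(name = name, klass = klass,
         is_snorna = klass %in% c("snoRNA_CD", "snoRNA_HACA", "scaRNA"))
}

#' Collapse a paralog name to its family name
#'
#' Strips exactly one trailing lowercase letter when the remainder is
#' non-empty and contains a digit (`SNORA36a -> SNORA36`, `U3k -> U3`);
#' hyphen-number suffixes are left untouched.
#'
#' @param name Character vector of names.
#' @return Character vector of family names.
#' @examples
#' collapse_family(c("U3a", "SNORD17b", "snoU6-53"))
#' @export
collapse_family <- function(name) {
  strip <- grepl("[a-z]$", name) & nchar(name) > 1 &
    grepl("[0-9]", substr(name, 1, nchar(name) - 1))
  ifelse(strip, substr(name, 1, nchar(name) - 1), name)
}

#' Cross-species expression group from northern-blot calls
#'
#' Groups reflect progressive phylogenetic restriction of expression:
#' group 1 detected in chicken, mouse and human (besides the monkey);
#' group 2 in mouse and human but not chicken; group 3 in human only;
#' group 4 in none of the three; group 5 mouse only; group 6 chicken and
#' human but not mouse. Any other pattern returns 0 with a warning.
#'
#' @param chicken,mouse,human Logical vectors of detection calls.
#' @return Integer vector of group labels (1-6, or 0).
#' @examples
#' group_expression(TRUE, TRUE, TRUE)
#' group_expression(FALSE, TRUE, FALSE)
#' @export
group_expression <- function(chicken, mouse, human) {
  pattern <- paste0(as.integer(chicken), as.integer(mouse), as.integer(human))
  map <- c("111" = 1L, "011" = 2L, "001" = 3L, "000" = 4L,
           "010" = 5L, "101" = 6L)
  g <- unname(map[pattern])
  if (anyNA(g)) {
    warn(paste0("expression pattern(s) outside the six defined groups: ",
                paste(unique(pattern[is.na(g)]), collapse = ", ")))
    g[is.na(g)] <- 0L
  }
  g
}

#' Flag conserved-but-silent inconsistencies
#'
#' A row is inconsistent when some species shows a conservation score at
#' or above `tau` but no detectable expression (conserved but silent). The
#' rule is deliberately one-sided: expression without strong conservation
#' is not flagged. Missing conservation scores are skipped, and rows whose
#' flag was computed over fewer than three species are marked in
#' `n_species_used`.
#'
#' @param rows Catalog tibble as from [load_catalog_fixture()].
#' @param tau Conservation threshold (default 0.6).
#' @return `rows` with added `flag` (`"consistent"`/`"inconsistent"`) and
#'   `n_species_used`.
#' @export
consistency_flag <- function(rows, tau = 0.6) {
  species <- c("chicken", "mouse", "human")
  det <- as.matrix(rows[paste0("det_", species)])
  cons <- as.matrix(rows[paste0("cons_", species)])
  silent_conserved <- !is.na(cons) & cons >= tau & !det
  rows %>%
    mutate(flag = ifelse(rowSums(silent_conserved) > 0,
                         "inconsistent", "consistent"),
           n_species_used = rowSums(!is.na(cons)))
}

#' Summarise an ncRNA catalog
#'
#' One-row summary of a catalog tibble: row and clone totals, per-class
#' counts from [assign_class_by_name()], the snoRNA family count after
#' [collapse_family()], the number of SNORA/SNORD rows with mouse
#' conservation below 0.6, and the number of snoRNA rows perfectly
#' conserved in human.
#'
#' @param rows Catalog tibble (may be empty).
#' @return One-row tibble: `n_rows`, `clone_sum`, `n_snorna`, `n_cd`,
#'   `n_haca_incl_scarna`, `n_snrna`, `n_yrna`, `n_srp`, `n_7sk`,
#'   `n_vault`, `n_rpph1`, `n_rmrp`, `n_unclassified`, `n_families`,
#'   `n_mouse_lowcons`, `n_human_perfect`.
#' @examples
#' catalog_summary(load_catalog_fixture())
#' @export
catalog_summary <- function(rows) {
  if (nrow(rows) == 0) {
    zero <- tibble(n_rows = 0L, clone_sum = 0L, n_snorna = 0L, n_cd = 0L,
                   n_haca_incl_scarna = 0L, n_snrna = 0L, n_yrna = 0L,
                   n_srp = 0L, n_7sk = 0L, n_vault = 0L, n_rpph1 = 0L,
                   n_rmrp = 0L, n_unclassified = 0L, n_families = 0L,
                   n_mouse_lowcons = 0L, n_human_perfect = 0L)
    return(zero)
  }
  cls <- assign_class_by_name(rows$name)
  nk <- function(k) sum(cls$klass == k)
  sno_names <- cls$name[cls$is_snorna]
  sno_rows <- rows[cls$is_snorna, ]
  snoad <- grepl("^(SNORA|SNORD)", rows$name)
  tibble(
    n_rows = nrow(rows),
    clone_sum = sum(rows$clone_count),
    n_snorna = sum(cls$is_snorna),
    n_cd = nk("snoRNA_CD"),
    n_haca_incl_scarna = nk("snoRNA_HACA") + nk("scaRNA"),
    n_snrna = nk("snRNA"),
    n_yrna = nk("YRNA"),
    n_srp = nk("SRP"),
    n_7sk = nk("7SK"),
    n_vault = nk("vault"),
    n_rpph1 = nk("RPPH1"),
    n_rmrp = nk("RMRP"),
    n_unclassified = nk("unclassified"),
    n_families = length(unique(collapse_family(sno_names))),
    n_mouse_lowcons = sum(snoad & !is.na(rows$cons_mouse) &
                            rows$cons_mouse < 0.6),
    n_human_perfect = sum(!is.na(sno_rows$cons_human) &
                            sno_rows$cons_human == 1))
}
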