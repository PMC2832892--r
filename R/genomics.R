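#' Classify snoRNA loci as intronic or intergenic
#'
#' A locus is intronic when it is fully contained in an intron on the same
#' strand; anything else is intergenic (vertebrate intron-encoded snoRNAs
#' are transcribed with their host gene, hence the strand requirement).
#' Loci overlapping an exon are reported as intergenic with a warning.
#'
#' @param loci Tibble of 0-based half-open loci: `seq_id`, `start`, `end`,
#'   `strand` (plus any carried columns such as `family`).
#' @param gene_models A `gene_models` list from [read_gene_models()], or a
#'   list with `introns`/`exons` tibbles in the same layout.
#' @return `loci` with an added `context` column.
#' @export
classify_context <- function(loci, gene_models) {
  introns <- gene_models$introns
  exons <- gene_models$exons
  known <- unique(c(introns$seqid, exons$seqid, gene_models$genes$seqid))
  bad <- setdiff(unique(loci$seq_id), known)
  if (length(bad) > 0 && length(known) > 0) {
    abort(paste0("loci reference unknown sequence(s): ",
                 paste(bad, collapse = ", ")))
  }
  ctx <- vapply(seq_len(nrow(loci)), function(k) {
    l <- loci[k, ]
    hit <- introns$seqid == l$seq_id & introns$strand == l$strand &
      introns$start <= l$start & introns$end >= l$end
    if (any(hit)) return("intronic")
    ex <- exons$seqid == l$seq_id & exons$start < l$end & exons$end > l$start
    if (any(ex)) {
      warn(paste0("locus ", l$seq_id, ":", l$start, "-", l$end,
                  " overlaps an exon; reported intergenic"))
    }
    "intergenic"
  }, character(1))
  mutate(loci, context = ctx)
}

#' Family and paralog census of snoRNA loci
#'
#' Per species: the number of distinct families, the total locus (copy)
#' count, how many families are singletons versus multi-copy, and the
#' intronic/intergenic split. The census invariants
#' `n_copies == n_intronic + n_intergenic` and
#' `n_families == n_singleton_families + n_multi_families` are asserted
#' on every output.
#'
#' @param loci Tibble with `species`, `family` and `context`
#'   (`"intronic"`/`"intergenic"`, e.g. from [classify_context()]).
#' @return Tibble with one row per species: `species`, `n_families`,
#'   `n_copies`, `n_singleton_families`, `n_multi_families`, `n_intronic`,
#'   `n_intergenic`.
#' @export
sno_census <- function(loci) {
  if (nrow(loci) == 0) {
    return(tibble(species = character(), n_families = integer(),
                  n_copies = integer(), n_singleton_families = integer(),
                  n_multi_families = integer(), n_intronic = integer(),
                  n_intergenic = integer()))
  }
  stopifnot(all(c("species", "family", "context") %in% names(loci)))
  out <- loci %>%
    group_by(.data$species) %>%
    summarise(
      n_families = dplyr::n_distinct(.data$family),
      n_copies = n(),
      n_singleton_families = sum(table(.data$family) == 1),
      n_multi_families = sum(table(.data$family) > 1),
      n_intronic = sum(.data$context == "intronic"),
      n_intergenic = sum(.data$context == "intergenic"),
      .groups = "drop")
  stopifnot(all(out$n_copies == out$n_intronic + out$n_intergenic),
            all(out$n_families ==
                  out$n_singleton_families + out$n_multi_families))
  out
}

#' Functional tally of intronic snoRNA host genes
#'
#' Fraction of host genes per functional category (classically
#' ribosome/translation-related versus other); fractions sum to 1.
#'
#' @param host_map Tibble `sno`, `gene` mapping each intronic snoRNA to
#'   its host gene.
#' @param function_map Tibble `gene`, `category` labelling every host
#'   gene.
#' @return Tibble `category`, `n_genes`, `fraction`.
#' @export
host_function_tally <- function(host_map, function_map) {
  if (nrow(host_map) == 0) abort("no host genes to tally")
  genes <- unique(host_map$gene)
  lab <- function_map$category[match(genes, function_map$gene)]
  if (anyNA(lab)) {
    abort(paste0("missing function label for gene(s): ",
                 paste(genes[is.na(lab)], collapse = ", ")))
  }
  tibble(gene = genes, category = lab) %>%
    count(.data$category, name = "n_genes") %>%
    mutate(fraction = .data$n_genes / sum(.data$n_genes))
}

#' Fraction of host genes whose orthologs also host a snoRNA
#'
#' Of the snoRNA host genes in species A, the fraction whose one-to-one
#' ortholog in species B is itself a snoRNA host gene in B.
#'
#' @param hosts_a,hosts_b Character vectors of host gene ids in A and B.
#' @param ortholog_pairs Tibble `a`, `b` of one-to-one ortholog pairs.
#' @return A single fraction in `[0, 1]` (0 when A has no host genes).
#' @export
ortholog_host_sharing <- function(hosts_a, hosts_b, ortholog_pairs) {
  hosts_a <- unique(hosts_a)
  if (length(hosts_a) == 0) return(0)
  orth <- ortholog_pairs$b[match(hosts_a, ortholog_pairs$a)]
  mean(!is.na(orth) & orth %in% hosts_b)
}
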