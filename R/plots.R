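#' Bar chart of cross-species expression groups
#'
#' @param rows Catalog tibble with a `group_label` column.
#' @return A ggplot object.
#' @export
plot_expression_groups <- function(rows) {
  rows %>%
    count(.data$group_label) %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$group_label),
                                 y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "expression group",
                  y = "ncRNAs",
                  title = "Cross-species expression groups") +
    ggplot2::theme_minimal()
}

#' Conservation score profile across species
#'
#' @param rows Catalog tibble with `cons_chicken`, `cons_mouse`,
#'   `cons_human`.
#' @return A ggplot object.
#' @export
plot_conservation <- function(rows) {
  rows %>%
    select("name", dplyr::starts_with("cons_")) %>%
    tidyr::pivot_longer(-"name", names_to = "species", values_to = "score",
                        names_prefix = "cons_") %>%
    filter(!is.na(.data$score)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$species, y = .data$score)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.3, size = 0.7) +
    ggplot2::labs(x = NULL, y = "conservation score",
                  title = "Sequence conservation by species") +
    ggplot2::theme_minimal()
}

#' Family and copy census bar chart
#'
#' @param census Census tibble from [sno_census()].
#' @return A ggplot object.
#' @export
plot_family_census <- function(census) {
  census %>%
    select("species", "n_families", "n_copies") %>%
    tidyr::pivot_longer(-"species", names_to = "measure",
                        values_to = "count") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$species, y = .data$count,
                                 fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "snoRNA families and copies per species") +
    ggplot2::theme_minimal()
}
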