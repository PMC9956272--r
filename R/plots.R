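# Figure helpers for survey results.

#' Bar chart of genomes invaded per element group
#'
#' @param result a `tcme_result`.
#' @return a ggplot object.
#' @export
plot_invasion <- function(result) {
  d <- result$group_table
  d <- d[grepl("_total$", d$label), ]
  d$group <- sub("_total$", "", d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species,
                                  y = .data$n_genomes_containing,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genomes containing elements",
                  fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of mean copies per subgroup in positive genomes
#'
#' @param result a `tcme_result`.
#' @return a ggplot object.
#' @export
plot_copy_number <- function(result) {
  el <- dplyr::left_join(result$elements, result$census, by = "genome_id")
  el <- el[!el$decay_flag & el$subgroup %in% SUBGROUPS, ]
  d <- dplyr::summarise(
    dplyr::group_by(el, .data$species, .data$subgroup, .data$genome_id),
    n = dplyr::n(), .groups = "drop_last")
  d <- dplyr::summarise(d, mean_copies = mean(.data$n), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subgroup, y = .data$mean_copies,
                                  fill = .data$subgroup)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "mean copies per positive genome") +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname run_tcme_pipeline
#' @param object a `tcme_result`.
#' @param type `"invasion"` or `"copy_number"`.
#' @method autoplot tcme_result
#' @export
autoplot.tcme_result <- function(object, type = c("invasion", "copy_number"),
                                 ...) {
  type <- match.arg(type)
  switch(type,
         invasion = plot_invasion(object),
         copy_number = plot_copy_number(object))
}
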