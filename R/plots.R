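# ggplot2 methods for the result tibbles.

#' Plot a common-code curve
#'
#' @param object A `pgc_curve` from [common_pgc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pgc_curve
#' @export
autoplot.pgc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$n_common)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Runs incorporated",
                  y = "Common protein group codes") +
    ggplot2::theme_minimal()
}

#' Plot a mapping change log
#'
#' Shows, per processed file, the new protein identities, the new global
#' groups and the merge events of a stepwise dictionary build.
#'
#' @param object A `pgc_change_log` from [change_log()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pgc_change_log
#' @export
autoplot.pgc_change_log <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("new_accessions", "new_groups", "mergers"),
    names_to = "change", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$count,
                                     linetype = .data$change,
                                     linewidth = .data$change)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(new_accessions = "solid",
                                              new_groups = "solid",
                                              mergers = "dotted")) +
    ggplot2::scale_linewidth_manual(values = c(new_accessions = 1,
                                               new_groups = 0.4,
                                               mergers = 0.6),
                                    guide = "none") +
    ggplot2::labs(x = "Files processed", y = "Count", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a presence matrix
#'
#' @param object A `pgc_presence` from [presence_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map (codes by runs).
#' @method autoplot pgc_presence
#' @export
autoplot.pgc_presence <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), -"pgc",
    names_to = "run_id", values_to = "present"
  )
  long$run_id <- factor(long$run_id,
                        levels = setdiff(names(object), "pgc"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run_id,
                                     y = factor(.data$pgc),
                                     fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Run", y = "PGC", fill = "Present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a Dice comparison table
#'
#' @param object A `pgc_dice` from [dice_vs_dictionary()] or
#'   [dice_top_proteins()].
#' @param ... Unused.
#' @return A ggplot heat map of Dice values (0 = group absent from the run,
#'   1 = identical sets).
#' @method autoplot pgc_dice
#' @export
autoplot.pgc_dice <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$pgc),
                                       y = .data$run_id,
                                       fill = .data$dice)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkorange3", high = "lightyellow",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "PGC", y = "Run", fill = "Dice") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a group-size histogram
#'
#' @param object A `pgc_size_hist` from [group_size_histogram()].
#' @param ... Unused.
#' @return A ggplot bar chart over the size bins 1, 2, 3–5 and >5.
#' @method autoplot pgc_size_hist
#' @export
autoplot.pgc_size_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size_bin, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Group size", y = "Number of groups") +
    ggplot2::theme_minimal()
}
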