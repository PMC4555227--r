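# ggplot2 visualisations of the main result types.

#' Plot a SNP panel summary
#'
#' Median intensity (with MAD error bars) per panel sequence, SNPs
#' ordered by position and alternative base, consensus first — the
#' panel-overview layout of the array figures.
#'
#' @param object Panel summary from [summarize_snp_panel()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.etscre_snp_panel <- function(object, ...) {
  dat <- object %>%
    arrange(.data$role != "consensus", .data$position, .data$alt) %>%
    mutate(label = ifelse(.data$role == "consensus", "consensus",
                          sprintf("%d%s>%s", .data$position, .data$ref,
                                  .data$alt)),
           label = factor(.data$label, levels = unique(.data$label)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$median - .data$mad,
                                          ymax = .data$median + .data$mad),
                             size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "median intensity (a.u.)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot an energy model as per-position frequency bars
#'
#' A compact logo-like rendering: stacked per-position base frequencies
#' of the PFM.
#'
#' @param object An `energy_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_model <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$freq,
                                    fill = .data$base)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(dat$position))) +
    ggplot2::labs(title = object$name, x = "position", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a cooperative-call scatter
#'
#' Best score under the cooperative model set (x) against best score
#' under the single-protein set (y), with called regions highlighted —
#' cooperative-only sequences fall in the lower right, independently
#' bound sequences on the diagonal.
#'
#' @param object A `coop_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coop_calls <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$best_coop_score,
                                    y = .data$best_single_score,
                                    colour = .data$is_cooperative)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "magenta")) +
    ggplot2::labs(x = "best score, GABPa+CREB1 models",
                  y = "best score, single-protein models",
                  colour = "cooperative") +
    ggplot2::theme_minimal()
}

#' Plot a motif enrichment profile
#'
#' Enrichment score of the consensus motif and each 1-bp variant in the
#' GABPa+CREB1 and GABPa-CREB1 peak groups.
#'
#' @param object An `etscre_enrichment_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.etscre_enrichment_profile <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(label = ifelse(is.na(.data$position), "consensus",
                          sprintf("%d%s>%s", .data$position, .data$ref,
                                  .data$alt)),
           label = factor(.data$label, levels = unique(.data$label))) %>%
    tidyr::pivot_longer(c("E_plus", "E_minus"), names_to = "group",
                        values_to = "enrichment") %>%
    mutate(group = ifelse(.data$group == "E_plus", "GABPa+CREB1",
                          "GABPa-CREB1"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$enrichment,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "enrichment score E", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 7))
}
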