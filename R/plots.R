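#' Plot an anchor loop profile
#'
#' Bars are observed anchor contacts per restriction fragment along the
#' chromosome, the line is the fitted distance-decay expectation, and
#' looping fragments are highlighted.
#'
#' @param object A `loop_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loop_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1000)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed, fill = .data$looping),
                      width = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$expected), colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick"),
                               name = "looping") +
    ggplot2::labs(x = "position (kb)", y = "anchor contacts",
                  title = "Anchor contact profile",
                  subtitle = "bars: observed; step line: expected decay") +
    ggplot2::theme_minimal()
}

#' Plot per-gene allele specificity
#'
#' The pseudo-count log2 CAST/129 ratio per gene, faceted by clone; the
#' focal gene is highlighted. In monoallelic deletion clones only the focal
#' gene should leave the horizontal band.
#'
#' @param object An `allele_specificity` tibble.
#' @param focal_gene Gene to highlight (default `"focal"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.allele_specificity <- function(object, focal_gene = "focal", ...) {
  df <- as_tibble(object)
  df$is_focal <- df$gene == focal_gene
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$specificity,
                                   colour = .data$is_focal)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$clone_id)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "log2 (CAST + 10) / (129 + 10)",
                  title = "Allele-specific expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot signature calls as a clone-vs-clone scatter
#'
#' Log2 pseudo-counted FPKM of the mutant clone against the wild type, with
#' the three-fold call boundaries and signature genes coloured.
#'
#' @param object A `signature_calls` tibble.
#' @param pseudo Pseudo-count used for the axes (default 4, matching the
#'   calls).
#' @param fold Fold boundary drawn (default 3).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_calls <- function(object, pseudo = 4, fold = 3, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fpkm_wt + pseudo),
                                   y = log2(.data$fpkm_mut + pseudo),
                                   colour = .data$signature)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = c(-log2(fold), log2(fold)),
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            none = "grey55")) +
    ggplot2::labs(x = sprintf("log2(FPKM + %g), %s", pseudo, attr(object, "wt_clone")),
                  y = sprintf("log2(FPKM + %g), %s", pseudo, attr(object, "mut_clone")),
                  title = "Signature calls") +
    ggplot2::theme_minimal()
}

#' Plot clone copy numbers with genotype class bands
#'
#' @param object A `genotype_calls` tibble.
#' @param thresholds Class boundaries drawn (default `c(0.5, 1.5)`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genotype_calls <- function(object, thresholds = c(0.5, 1.5), ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clone_id, y = .data$copy_number,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "relative copy number (WT = 2)",
                  title = "qPCR copy-number genotyping") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
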