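# Tidiers and plots for screen results and logo matrices.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chimera screen: one row per protein
#'
#' @param x A `rep_screen` from [run_pipeline()].
#' @param ... Unused.
#' @return The calls tibble (`id`, `score`, `displacement`, `score_flag`,
#'   `tree_flag`, `tier`) with a `kept` column.
#' @exportS3Method generics::tidy
tidy.rep_screen <- function(x, ...) {
  dplyr::mutate(x$calls, kept = !.data$id %in% x$removed)
}

#' One-row summary of a chimera screen
#'
#' @param x A `rep_screen` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble: input size, tier counts, sequences kept,
#'   reduction percentage, split column, tanglegram crossings and number of
#'   supported groups.
#' @exportS3Method generics::glance
glance.rep_screen <- function(x, ...) {
  tiers <- table(factor(x$calls$tier, c("chimera", "review", "clean")))
  tibble::tibble(
    n_input = x$n_input,
    n_chimera = unname(tiers[["chimera"]]),
    n_review = unname(tiers[["review"]]),
    n_clean = unname(tiers[["clean"]]),
    n_kept = nrow(x$purged),
    reduction_pct = round(100 * (1 - nrow(x$purged) / x$n_input)),
    split_column = x$split_column,
    crossings = x$tanglegram$crossings,
    n_groups = nrow(x$groups)
  )
}

#' Scatter of the two detector statistics
#'
#' Plots each protein's connectedness score against its tree displacement,
#' coloured by call tier, with the two decision thresholds drawn as dashed
#' lines. Chimeras sit in the low-score / high-displacement corner.
#'
#' @param object A `rep_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rep_screen <- function(object, ...) {
  df <- tidy(object)
  cfg <- object$config
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$displacement,
                                   colour = .data$tier)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = cfg$score_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cfg$displacement_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(chimera = "#d73027", review = "#fc8d59", clean = "#4575b4")
    ) +
    ggplot2::labs(x = "domain connectedness score",
                  y = "tree displacement", colour = "call") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sequence-logo style plot of a motif window
#'
#' Stacked per-column bars of residue contributions `prob * information`
#' (bits), the quantity a sequence logo letter-height encodes.
#'
#' @param logo A `logo_matrix` from [logo_matrix()].
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  stopifnot(inherits(logo, "logo_matrix"))
  df <- dplyr::filter(tibble::as_tibble(logo), .data$prob > 0)
  df <- dplyr::mutate(df, bits = .data$prob * .data$information)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$column),
                                   y = .data$bits, fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue),
                       position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.5) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "alignment column",
                  y = "information (bits)",
                  title = attr(logo, "motif_name")) +
    ggplot2::theme_minimal()
}

#' Tanglegram plot of the two domain trees
#'
#' Draws the ordered leaf labels of the nuclease and helicase trees in two
#' columns with connector segments; crossing segments mark taxa whose two
#' domains disagree about their relatives.
#'
#' @param tangle Result of [tanglegram_order()].
#' @param highlight Optional character vector of leaf ids drawn in red
#'   (e.g. called chimeras).
#' @return A ggplot object.
#' @export
plot_tanglegram <- function(tangle, highlight = character(0)) {
  n <- length(tangle$order1)
  seg <- tibble::tibble(
    id = tangle$order1,
    y1 = n - seq_len(n) + 1L,
    y2 = n - match(tangle$order1, tangle$order2) + 1L,
    hot = tangle$order1 %in% highlight
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = 1, y = .data$y1,
                                       yend = .data$y2,
                                       colour = .data$hot)) +
    ggplot2::geom_text(ggplot2::aes(x = -0.02, y = .data$y1,
                                    label = .data$id),
                       hjust = 1, size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(x = 1.02, y = .data$y2,
                                    label = .data$id),
                       hjust = 0, size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#d73027")) +
    ggplot2::guides(colour = "none") +
    ggplot2::coord_cartesian(xlim = c(-0.35, 1.35)) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = sprintf("%d crossing(s)", tangle$crossings)) +
    ggplot2::theme_void()
}
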