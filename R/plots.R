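#' Plot a cleavage probability vector
#'
#' @param v Length-50 probability vector (offsets -25..+24 around the
#'   anchor).
#' @return A ggplot object.
#' @export
plot_cleavage_vector <- function(v) {
  df <- tibble::tibble(offset = -25:24, p = as.numeric(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$p)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "offset from anchor (nt)",
                  y = "cleavage probability") +
    ggplot2::theme_minimal()
}

#' Plot a scan track with consolidated site calls
#'
#' @param records Scan records from [scan_sequence()] / [scan_region()].
#' @param sites Optional consolidated sites from [consolidate()].
#' @return A ggplot object showing the classification probability along the
#'   scan with retained anchors highlighted and called sites marked.
#' @export
plot_scan <- function(records, sites = NULL) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$anchor_pos,
                                    y = .data$p_class)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(data = records[records$retained, ],
                        colour = "#2166ac", size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "position", y = "classification probability") +
    ggplot2::theme_minimal()
  if (!is.null(sites) && nrow(sites)) {
    p <- p + ggplot2::geom_vline(xintercept = sites$pos,
                                 colour = "#b2182b", linetype = 3)
  }
  p
}

#' Plot a positional importance profile
#'
#' @param profile Tibble from [positional_profile()].
#' @param hexamers Optional subset of hexamers to display (default: the ten
#'   with the largest summed importance).
#' @return A ggplot object.
#' @export
plot_importance_profile <- function(profile, hexamers = NULL) {
  if (is.null(hexamers)) {
    hexamers <- profile |>
      dplyr::group_by(.data$hexamer) |>
      dplyr::summarise(total = sum(.data$sum_importance), .groups = "drop") |>
      dplyr::slice_max(.data$total, n = 10) |>
      dplyr::pull(.data$hexamer)
  }
  df <- profile[profile$hexamer %in% hexamers, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$sum_importance,
                                   colour = .data$hexamer)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "hexamer start offset (nt)", y = "summed importance") +
    ggplot2::theme_minimal()
}

#' Training-history plot for a fitted model
#'
#' @param object A trained `polya_model`.
#' @param ... Unused.
#' @return A ggplot object of per-epoch training and validation losses.
#' @export
autoplot.polya_model <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0) stop("model has no training history")
  df <- tidyr::pivot_longer(h, -"epoch", names_to = "series",
                            values_to = "loss")
  df <- df[!grepl("unused", df$series), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
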