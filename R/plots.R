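#' Forest plot of disproportionality signals
#'
#' One row per event with the chosen method's point estimate and
#' interval on a log axis; the signal reference line (1 for ROR/PRR/
#' EBGM, 0 for IC) is drawn dashed and flagged rows are coloured.
#'
#' @param signals a [signal_table()] tibble.
#' @param method which column set to draw: `"ror"`, `"prr"`, `"ebgm"`
#'   or `"ic"`.
#' @return a ggplot object.
#' @export
plot_signal_forest <- function(signals,
                               method = c("ror", "ebgm", "ic")) {
  method <- match.arg(method)
  cols <- switch(method,
                 ror = c("ror", "ror_low", "ror_high", "signal_ror"),
                 ebgm = c("ebgm", "ebgm05", "ebgm05", "signal_ebgm"),
                 ic = c("ic", "ic025", "ic025", "signal_ic"))
  df <- tibble(
    event = factor(signals$event, levels = rev(signals$event)),
    point = signals[[cols[1]]],
    lo = signals[[cols[2]]],
    hi = signals[[cols[3]]],
    flagged = signals[[cols[4]]]
  )
  df <- df[!is.na(df$point), ]
  ref <- if (method == "ic") 0 else 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$event,
                                        colour = .data$flagged)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#b2182b", `FALSE` = "grey30"),
      name = "signal") +
    ggplot2::labs(x = toupper(method), y = NULL)
  if (method != "ic") p <- p + ggplot2::scale_x_log10()
  p
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
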