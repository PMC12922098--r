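#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a displacement trace
#'
#' Time course of horizontal displacement with invalid samples shown as
#' gaps; optionally overlays detected sawtooth events (slow phase green,
#' quick phase red, the usual nystagmography reading).
#'
#' @param object An [okn_trace()].
#' @param events Optional events tibble from [detect_sawteeth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot okn_trace
#' @export
autoplot.okn_trace <- function(object, events = NULL, ...) {
  units <- attr(object, "units") %||% "px"
  df <- tibble::tibble(
    t_s = object$t_s,
    dx = ifelse(object$valid, object$dx, NA_real_)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$dx)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "time (s)",
      y = sprintf("horizontal displacement (%s)", units),
      title = sprintf("%s trace", attr(object, "source") %||% "displacement")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    seg <- function(t0, t1) {
      i0 <- findInterval(t0, object$t_s)
      i1 <- findInterval(t1, object$t_s)
      tibble::tibble(x = object$t_s[i0], xend = object$t_s[i1],
                     y = object$dx[i0], yend = object$dx[i1])
    }
    sp <- seg(events$onset_s, events$peak_s)
    qp <- seg(events$peak_s, events$end_s)
    p <- p +
      ggplot2::geom_segment(
        data = sp, ggplot2::aes(x = .data$x, xend = .data$xend,
                                y = .data$y, yend = .data$yend),
        color = "forestgreen", linewidth = 1, alpha = 0.7
      ) +
      ggplot2::geom_segment(
        data = qp, ggplot2::aes(x = .data$x, xend = .data$xend,
                                y = .data$y, yend = .data$yend),
        color = "firebrick", linewidth = 1, alpha = 0.7
      )
  }
  p
}

#' Plot a confusion matrix
#'
#' @param object An [okn_confusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot okn_confusion
#' @export
autoplot.okn_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$predicted, c(TRUE, FALSE), c("present", "absent")),
    y = factor(.data$truth, c(FALSE, TRUE), c("absent", "present")),
    fill = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "ground truth") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot per-method performance of a pipeline run
#'
#' @param object An `okn_run` from [run_okn_pipeline()].
#' @param partition `"main"`, `"retest"` or `"all"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot okn_run
#' @export
autoplot.okn_run <- function(object, partition = "main", ...) {
  df <- object$metrics |>
    dplyr::filter(.data$partition == !!partition) |>
    tidyr::pivot_longer(
      c("mcc", "sensitivity", "specificity", "accuracy"),
      names_to = "measure", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("OKN detection performance (%s dataset)", partition)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
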