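#' Plot a ROM endpoint table
#'
#' Endpoint angle per motion, colored by how the sweep ended.
#'
#' @param object a `rom_table` from [simulate_standard_set()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.rom_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$motion <- factor(df$motion, levels = rev(df$motion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$motion,
                                   fill = .data$status)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(x = "endpoint angle (deg)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a native-versus-cam comparison
#'
#' Dumbbell plot of native and cam endpoints per motion; motions limited by
#' more than the threshold are marked.
#'
#' @param object a `rom_comparison` from [compare_conditions()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.rom_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$motion <- factor(df$motion, levels = rev(df$motion))
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$motion)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$cam, xend = .data$native,
                                       yend = .data$motion),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$native, color = "native"),
                        size = 2.5) +
    ggplot2::geom_point(ggplot2::aes(x = .data$cam, color = "cam"),
                        size = 2.5) +
    ggplot2::geom_text(
      data = df[df$limited, , drop = FALSE],
      ggplot2::aes(x = .data$cam, label = sprintf("-%.1f", .data$difference)),
      nudge_x = -3, size = 3) +
    ggplot2::labs(x = "endpoint angle (deg)", y = NULL, color = NULL,
                  subtitle = sprintf("limitation threshold: > %g deg", thr)) +
    ggplot2::theme_minimal()
}

#' Plot an impingement map summary
#'
#' Zone area and clock hour per motion at the blocked poses.
#'
#' @param object an [aggregate_map()] result.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.impingement_map <- function(object, ...) {
  df <- object$endpoints
  df <- df[!is.na(df$clock_hour), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clock_hour, y = .data$area,
                                   label = .data$motion)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(nudge_y = max(df$area) * 0.05, size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 12),
                                breaks = c(3, 6, 9, 12)) +
    ggplot2::labs(x = "clock hour (12 = superior)",
                  y = expression("zone area (mm"^2 * ")")) +
    ggplot2::theme_minimal()
}
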