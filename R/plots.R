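#' Plot a simulated trajectory
#'
#' Storage-product accumulation panels (starch, sucrose, glucose, total FA,
#' storage protein, acyl-ACP intermediates and TAG) plus seed mass over
#' development.
#'
#' @param object An `fa_trajectory`.
#' @param variables Variables to facet; defaults to the storage read-outs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fa_trajectory <- function(object,
                                   variables = c("STA", "SUC", "GLC",
                                                 "total_fa", "SPRT", "SCFA",
                                                 "TAG", "seed_mass"),
                                   ...) {
  dat <- dplyr::bind_rows(
    trajectory_states(object),
    total_fa(object) |>
      dplyr::transmute(time_daf = .data$time_daf, variable = "total_fa",
                       value = .data$total_fa),
    tibble::tibble(time_daf = object$time_daf, variable = "seed_mass",
                   value = object$mass)
  ) |>
    dplyr::filter(.data$variable %in% variables) |>
    dplyr::mutate(variable = factor(.data$variable, levels = variables))
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_daf, .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "days after fertilization",
                  y = "level (model units)") +
    ggplot2::theme_minimal()
}

#' Plot perturbation dose-response profiles
#'
#' One panel per reaction: percent change in total FA at 20 DAF against the
#' expression fold factor (log scale), the in-silico analogue of a
#' sensitivity scan figure.
#'
#' @param scan Result of [scan_all()].
#' @param targets Subset of reaction IDs to show (default all).
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, targets = NULL) {
  dat <- scan |> dplyr::filter(.data$ok)
  if (!is.null(targets)) dat <- dat |> dplyr::filter(.data$target %in% targets)
  ggplot2::ggplot(dat, ggplot2::aes(.data$factor, .data$delta_fa_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_point(color = "navy", size = 0.8) +
    ggplot2::geom_line(color = "navy", linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = "expression fold factor",
                  y = "% change in total FA at 20 DAF") +
    ggplot2::theme_minimal()
}

#' Plot physiological ratios
#'
#' @param ratios Result of [physiological_ratios()].
#' @return A ggplot object.
#' @export
plot_ratios <- function(ratios) {
  dat <- ratios |>
    tidyr::pivot_longer(-"time_daf", names_to = "ratio", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_daf, .data$value)) +
    ggplot2::geom_line(color = "darkred") +
    ggplot2::facet_wrap(~ratio, scales = "free_y") +
    ggplot2::labs(x = "days after fertilization", y = "ratio") +
    ggplot2::theme_minimal()
}

#' Plot fit residuals by observable
#'
#' @param object An `fa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fa_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(.data$time_daf, .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::facet_wrap(~observable) +
    ggplot2::labs(x = "days after fertilization",
                  y = "log10 residual (sim - obs)") +
    ggplot2::theme_minimal()
}
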