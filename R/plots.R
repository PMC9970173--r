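# ggplot2 visualisations for the main result types.

#' Plot template topographies
#'
#' One panel per microstate class: electrode positions (2D azimuthal
#' projection of the montage) coloured by template potential. A quick
#' visual check of class identity, not a publication-grade field
#' interpolation.
#'
#' @param object An `ms_templates`.
#' @param montage Montage tibble with the template's electrodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_templates <- function(object, montage = standard_montage(
  ncol(object$maps)), ...) {
  d <- tidy(object) |>
    dplyr::left_join(montage, by = c(channel = "name"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(title = sprintf("Microstate templates (%s level)",
                                  object$level),
                  colour = "a.u.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text = ggplot2::element_blank())
}

#' Plot a segmentation
#'
#' GFP trace coloured by assigned microstate class over a time window,
#' with GFP peaks marked.
#'
#' @param object An `ms_segmentation`.
#' @param time_range Window in seconds `c(from, to)` (default first 2 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_segmentation <- function(object, time_range = c(0, 2), ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$time_s >= time_range[1],
                  .data$time_s <= time_range[2])
  pk <- tibble(time_s = (object$peaks - 1) / object$srate,
               gfp = object$gfp[object$peaks]) |>
    dplyr::filter(.data$time_s >= time_range[1],
                  .data$time_s <= time_range[2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$gfp)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$class,
                                    group = .data$epoch)) +
    ggplot2::geom_point(data = pk, size = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(GFP ~ (mu * V)),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Compare microstate parameters between conditions
#'
#' Mean with standard-error bars per class and condition, one facet per
#' parameter, from a tidy per-subject parameter table.
#'
#' @param params Tibble with `subject`, `condition`, `class`,
#'   `duration_ms`, `occurrence_per_s`, `contribution`.
#' @return A ggplot object.
#' @export
plot_parameters <- function(params) {
  d <- params |>
    tidyr::pivot_longer(dplyr::any_of(c("duration_ms", "occurrence_per_s",
                                        "contribution")),
                        names_to = "parameter") |>
    dplyr::group_by(.data$condition, .data$class, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$mean,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "microstate class", y = NULL) +
    ggplot2::theme_minimal()
}

#' Mediation path diagram data plot
#'
#' A minimal triangle diagram of the model-4 paths with standardised
#' coefficients annotated.
#'
#' @param object An `ms_mediation`.
#' @param labels Names for x, m, y.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_mediation <- function(object,
                                  labels = c(x = "X", m = "M", y = "Y"),
                                  ...) {
  est <- function(term) {
    object$paths$estimate[object$paths$term == term]
  }
  pval <- function(term) object$paths$p.value[object$paths$term == term]
  star <- function(p) if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  nodes <- tibble(name = unname(labels[c("x", "m", "y")]),
                  nx = c(0, 1, 2), ny = c(0, 1, 0))
  edges <- tibble(
    x = c(0, 1, 0), y = c(0.05, 1, 0), xend = c(1, 2, 2), yend = c(1, 0.05, 0),
    lab = c(sprintf("a = %.2f%s", est("a"), star(pval("a"))),
            sprintf("b = %.2f%s", est("b"), star(pval("b"))),
            sprintf("c' = %.2f%s (c = %.2f)", est("c_prime"),
                    star(pval("c_prime")), est("c")))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(4, "mm"))) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$nx, y = .data$ny,
                                     label = .data$name)) +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                    y = (.data$y + .data$yend) / 2 + 0.12,
                                    label = .data$lab)) +
    ggplot2::labs(title = sprintf("Indirect effect %.3f, %g%% CI [%.3f, %.3f]: %s mediation",
                                  object$indirect, 100 * object$conf_level,
                                  object$ci[1], object$ci[2], object$verdict)) +
    ggplot2::theme_void()
}
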