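#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.evidence_matrix <- function(x, ...) {
  F <- x$F
  out <- as_tibble(F, .name_repair = ~ paste0("m", seq_len(ncol(F))))
  out$subject <- seq_len(nrow(F))
  if (!is.null(x$groups)) out$group <- x$groups
  out <- tidyr::pivot_longer(out, dplyr::starts_with("m"),
                             names_to = "model", values_to = "log_evidence")
  out$model <- as.integer(sub("^m", "", out$model))
  if (!is.null(x$tags)) {
    out <- dplyr::left_join(out, x$tags, by = "model")
  }
  out
}

#' Plot a block design timeline
#'
#' @param object a [build_block_design()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.block_design <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[d$condition != "FIXATION", ]
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$onset_s,
                                  xmax = .data$onset_s + .data$duration_s,
                                  ymin = as.integer(factor(.data$condition, .conditions)) - 0.4,
                                  ymax = as.integer(factor(.data$condition, .conditions)) + 0.4,
                                  fill = .data$condition)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(breaks = seq_along(.conditions), labels = .conditions) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot simulated or measured BOLD time series
#'
#' @param object a `bold_dataset`.
#' @param ... unused.
#' @return a ggplot object, one facet per region.
#' @export
autoplot.bold_dataset <- function(object, ...) {
  d <- as_tibble(object$series)
  d$scan <- seq_len(nrow(d))
  d <- tidyr::pivot_longer(d, -"scan", names_to = "region", values_to = "bold")
  ggplot2::ggplot(d, ggplot2::aes(.data$scan, .data$bold)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~region, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "scan", y = "BOLD (% signal change)") +
    ggplot2::theme_minimal()
}

#' Plot model or family probabilities
#'
#' Expected and exceedance probabilities side by side.
#'
#' @param object a `bms_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bms_result <- function(object, ...) {
  id_col <- if ("family_id" %in% names(object) && !"model" %in% names(object)) {
    "family_id"
  } else "model"
  d <- tidyr::pivot_longer(as_tibble(object),
                           c("expected_prob", "exceedance_prob"),
                           names_to = "measure", values_to = "probability")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data[[id_col]]), .data$probability)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = id_col, y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a pupil trace
#'
#' @param object a `pupil_trace`.
#' @param downsample keep every k-th sample for plotting (default 10).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pupil_trace <- function(object, downsample = 10, ...) {
  idx <- seq(1L, length(object$samples), by = downsample)
  d <- tibble(time_s = (idx - 1L) / object$fs, pupil = object$samples[idx])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$pupil)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "pupil size (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(object$blinks)) {
    b <- as_tibble(object$blinks, .name_repair = ~c("start", "end"))
    p <- p + ggplot2::geom_rect(data = b,
                                ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                             ymin = -Inf, ymax = Inf),
                                inherit.aes = FALSE, alpha = 0.2, fill = "red")
  }
  p
}
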