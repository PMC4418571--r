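#' Plot a tonotopic map
#'
#' Best-frequency raster of the sheet's first slice, masked voxels only,
#' on a log-frequency colour scale.
#'
#' @param object A `tonotopic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tonotopic_map <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$in_mask, .data$z == 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = log2(.data$best_freq))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = "best frequency (Hz)",
      breaks = log2(c(125, 500, 2000, 8000)),
      labels = c(125, 500, 2000, 8000)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medial-lateral (voxels)",
                  y = "posterior-anterior (voxels)") +
    ggplot2::theme_minimal()
}

#' Plot an ROI parcellation
#'
#' @param object A `roi_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roi_set <- function(object, ...) {
  idx <- which(object$label != 0, arr.ind = TRUE)
  df <- tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                       roi = factor(object$labels[object$label[idx]],
                                    levels = object$labels)) |>
    dplyr::filter(.data$z == 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$roi)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medial-lateral (voxels)",
                  y = "posterior-anterior (voxels)", fill = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot segmentation of block time courses
#'
#' Mean slope per frame-to-frame transition with the rise / plateau / decay
#' labels.
#'
#' @param object A `segment_labels`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.segment_labels <- function(object, ...) {
  tr <- object$transitions
  ggplot2::ggplot(tr, ggplot2::aes((.data$t_start + .data$t_end) / 2,
                                   .data$mean_slope, fill = .data$label)) +
    ggplot2::geom_col(width = diff(tr$t_start[1:2]) * 0.9) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "time from block onset (s)",
                  y = "mean slope (% signal change / frame)",
                  fill = "phase") +
    ggplot2::theme_minimal()
}

#' Plot condition-wise ROI time courses
#'
#' Group-mean REP and CTRL time courses with across-subject standard-error
#' ribbons, faceted by ROI when several are present.
#'
#' @param data A [extract_block_timecourses()] tibble (with a `subject`
#'   column for the ribbons).
#' @param segments Optional [segment_phases()] result; its rise and decay
#'   windows are shaded.
#' @return A ggplot.
#' @export
plot_timecourses <- function(data, segments = NULL) {
  grp <- intersect(c("roi", "hemisphere"), names(data))
  has_subj <- "subject" %in% names(data)
  summ <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "condition",
                                                  "time_s")))) |>
    dplyr::summarise(
      se = if (has_subj) sd(.data$psc) / sqrt(dplyr::n()) else 0,
      psc = mean(.data$psc), .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$time_s, .data$psc,
                                          colour = .data$condition,
                                          fill = .data$condition))
  if (!is.null(segments)) {
    ph <- segments$phases
    shade <- ph[ph$phase %in% c("rise", "decay"), ]
    if (nrow(shade) > 0) {
      p <- p + ggplot2::annotate("rect", xmin = shade$start_s,
                                 xmax = shade$end_s, ymin = -Inf, ymax = Inf,
                                 alpha = 0.12, fill = "grey40")
    }
  }
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$psc - .data$se,
                                      ymax = .data$psc + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from block onset (s)",
                  y = "BOLD signal change (%)", colour = "condition",
                  fill = "condition") +
    ggplot2::theme_minimal()
  if ("roi" %in% grp) p <- p + ggplot2::facet_wrap(~roi)
  p
}
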