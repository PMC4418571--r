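#' Extract condition-wise ROI block time courses
#'
#' Computes, for every ROI, the per-block 15-frame window from block onset,
#' baseline-corrects it (baseline = mean of the two frames preceding the
#' onset; the first block, which has no preceding frames, uses the first two
#' frames of the run), converts to percent signal change, averages across
#' same-condition blocks (and across runs when several are given), and
#' finally subtracts the first time point so every time course starts at 0.
#'
#' @param runs A [volume_series()] or a list of them (e.g. two repetition
#'   runs of one subject). All runs must share the grid and design geometry.
#' @param rois A [subdivide_surround()] `roi_set`, a
#'   [make_tonotopic_sheet()] ground truth (its labels are used), or a plain
#'   integer label array with a `labels` attribute.
#' @param design The [make_block_design()] of the runs; defaults to the
#'   design attached to the first run.
#' @param subject,hemisphere Optional identifiers added as columns.
#' @return A tibble of class `roi_timecourse` with columns `roi`,
#'   `condition`, `frame`, `time_s`, `psc` and `n_blocks` (plus `subject` /
#'   `hemisphere` when given).
#' @export
extract_block_timecourses <- function(runs, rois, design = NULL,
                                      subject = NULL, hemisphere = NULL) {
  if (inherits(runs, "volume_series")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  design <- design %||% runs[[1]]$design
  stopifnot(inherits(design, "block_design"))

  if (inherits(rois, "roi_set") || inherits(rois, "ground_truth_map")) {
    label <- rois$label; lab_names <- rois$labels
  } else {
    label <- rois; lab_names <- attr(rois, "labels")
    if (is.null(lab_names)) {
      lab_names <- as.character(sort(unique(label[label != 0])))
    }
  }

  tr <- design$tr
  n_bf <- as.integer(round(design$block_s / tr))   # frames per block window
  present <- sort(unique(label[label != 0L]))

  acc <- list()
  for (run in runs) {
    d <- dim(run$data)
    if (!identical(d[1:3], dim(label)[1:3])) {
      stop("run and ROI labels are on different grids", call. = FALSE)
    }
    flat <- matrix(run$data, prod(d[1:3]), d[4])
    roi_means <- vapply(present, function(k) {
      colMeans(flat[which(label == k), , drop = FALSE])
    }, numeric(d[4]))                              # frames x rois
    for (i in seq_len(nrow(design$blocks))) {
      b <- design$blocks[i, ]
      f0 <- as.integer(round(b$onset_s / tr)) + 1L
      if (f0 + n_bf - 1L > d[4]) {
        warning("block ", b$block, " extends past the run end; dropped",
                call. = FALSE)
        next
      }
      base_f <- if (f0 > 2) (f0 - 2):(f0 - 1) else 1:2
      base <- colMeans(roi_means[base_f, , drop = FALSE])
      win <- roi_means[f0:(f0 + n_bf - 1L), , drop = FALSE]
      psc <- 100 * sweep(sweep(win, 2, base), 2, base, "/")
      acc[[length(acc) + 1L]] <- tibble::tibble(
        roi = rep(lab_names[present], each = n_bf),
        condition = b$condition,
        frame = rep(seq_len(n_bf), times = length(present)),
        psc = as.vector(psc)
      )
    }
  }
  out <- dplyr::bind_rows(acc) |>
    dplyr::group_by(.data$roi, .data$condition, .data$frame) |>
    dplyr::summarise(psc = mean(.data$psc), n_blocks = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(.data$roi, .data$condition) |>
    dplyr::mutate(psc = .data$psc - .data$psc[.data$frame == 1]) |>
    dplyr::ungroup() |>
    dplyr::mutate(time_s = (.data$frame - 1) * tr, .after = "frame")
  if (!is.null(subject)) out <- dplyr::mutate(out, subject = subject,
                                              .before = 1)
  if (!is.null(hemisphere)) out <- dplyr::mutate(out, hemisphere = hemisphere,
                                                 .before = 1)
  class(out) <- c("roi_timecourse", class(out))
  out
}
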