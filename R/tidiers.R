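#' Tidiers for tonorep result objects
#'
#' `tidy()` returns the per-unit results (transitions, frames, bins) as a
#' tibble; `glance()` returns a one-row (or one-row-per-group) summary.
#'
#' @param x A tonorep result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tonorep-tidiers
NULL

#' @rdname tonorep-tidiers
#' @export
tidy.segment_labels <- function(x, ...) x$transitions

#' @rdname tonorep-tidiers
#' @export
glance.segment_labels <- function(x, ...) {
  ph <- x$phases
  out <- tibble::tibble(.rows = 1)
  for (p in c("rise", "plateau", "decay")) {
    out[[paste0(p, "_start_s")]] <-
      if (p %in% ph$phase) ph$start_s[ph$phase == p] else NA_real_
    out[[paste0(p, "_end_s")]] <-
      if (p %in% ph$phase) ph$end_s[ph$phase == p] else NA_real_
  }
  out$n_subjects <- x$n_subjects
  out$alpha <- x$alpha
  out
}

#' @rdname tonorep-tidiers
#' @export
tidy.contrast_result <- function(x, ...) x$by_frame

#' @rdname tonorep-tidiers
#' @export
glance.contrast_result <- function(x, ...) x$verdicts

#' @rdname tonorep-tidiers
#' @export
tidy.anova_result <- function(x, ...) x$by_frame

#' @rdname tonorep-tidiers
#' @export
tidy.extrema_stats <- function(x, ...) x$tests

#' @rdname tonorep-tidiers
#' @export
tidy.set_comparison <- function(x, ...) x$points

#' @rdname tonorep-tidiers
#' @export
glance.set_comparison <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, n_sig = x$n_sig,
                 fraction = x$fraction, alpha = x$alpha)
}

#' @rdname tonorep-tidiers
#' @export
glance.matched_sets <- function(x, ...) {
  tibble::tibble(status = x$status, iterations = x$iterations,
                 n_rep = length(x$rep_ids), n_ctrl = length(x$ctrl_ids),
                 fraction = x$comparison$fraction, threshold = x$threshold)
}

#' @rdname tonorep-tidiers
#' @export
tidy.spectrum_comparison <- function(x, ...) x$bins

#' @rdname tonorep-tidiers
#' @export
glance.spectrum_comparison <- function(x, ...) {
  tibble::tibble(n_sig = x$n_sig, n_sig_bonferroni = x$n_sig_bonferroni,
                 fraction = x$fraction, alpha = x$alpha)
}

#' @rdname tonorep-tidiers
#' @export
tidy.tonotopic_map <- function(x, ...) {
  obj <- x
  idx <- which(!is.na(obj$r), arr.ind = TRUE)
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    best_freq = obj$best_freq[idx],
    r = obj$r[idx],
    time_to_peak = obj$time_to_peak[idx],
    in_mask = obj$mask[idx]
  )
}

#' @rdname tonorep-tidiers
#' @export
tidy.roi_set <- function(x, ...) x$summary
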