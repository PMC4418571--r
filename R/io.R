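#' Write / read a 4-D volume series as NIfTI-1
#'
#' Volumes are stored as 4-D NIfTI with the voxel size and TR in `pixdim`;
#' the TR and free-form metadata are additionally written to a JSON sidecar
#' (`<path>.json`) which, when present at read time, takes precedence over
#' the header.
#'
#' @param vs A [volume_series()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_volume_series` returns `path` invisibly;
#'   `read_volume_series` returns a [volume_series()].
#' @export
write_volume_series <- function(vs, path) {
  stopifnot(inherits(vs, "volume_series"))
  img <- RNifti::asNifti(vs$data)
  img <- RNifti::`pixdim<-`(img, c(rep(vs$voxel_mm, 3), vs$tr))
  RNifti::writeNifti(img, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(tr = vs$tr, voxel_mm = vs$voxel_mm, meta = vs$meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 4) {
    stop("expected a 4-D volume series, got ", length(dim(arr)),
         " dimensions", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else NA_real_
  voxel_mm <- if (length(pd) >= 1) pd[1] else NA_real_
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$tr)) tr <- sc$tr
    if (!is.null(sc$voxel_mm)) voxel_mm <- sc$voxel_mm
    if (!is.null(sc$meta)) meta <- as.list(sc$meta)
  }
  if (!is.finite(tr)) {
    stop("repetition time not found in header pixdim[4] or sidecar JSON",
         call. = FALSE)
  }
  volume_series(arr, tr = tr, voxel_mm = voxel_mm, meta = meta)
}

#' Write / read ROI labels as NIfTI plus a JSON label table
#'
#' @param label Integer 3-D label array (e.g. from
#'   [roiset_to_label_volume()]), with label names in attribute `labels`.
#' @param path Output `.nii` / `.nii.gz` path. The label table goes to
#'   `<path>.json`.
#' @return `write_label_volume` returns `path` invisibly; `read_label_volume`
#'   returns the integer array with `labels` restored.
#' @export
write_label_volume <- function(label, path) {
  labels <- attr(label, "labels")
  img <- RNifti::asNifti(array(as.integer(label), dim(label)))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(labels = labels,
         counts = as.list(table(label[label != 0]))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  out <- array(as.integer(round(arr)), dim(arr))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "labels") <- sc$labels
  }
  out
}

#' Write / read a block design as JSON
#'
#' @param design A [make_block_design()].
#' @param path Output `.json` path.
#' @return `write_block_design` returns `path` invisibly; `read_block_design`
#'   returns a `block_design`.
#' @export
write_block_design <- function(design, path) {
  stopifnot(inherits(design, "block_design"))
  jsonlite::write_json(
    list(tr = design$tr, block_s = design$block_s, run_s = design$run_s,
         n_frames = design$n_frames,
         blocks = design$blocks |>
           dplyr::mutate(stim_onsets = purrr::map(.data$stim_onsets,
                                                  identity))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_block_design
#' @export
read_block_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- tibble::as_tibble(x$blocks)
  blocks$stim_onsets <- lapply(blocks$stim_onsets, as.numeric)
  structure(list(blocks = blocks, tr = x$tr, block_s = x$block_s,
                 run_s = x$run_s, n_frames = as.integer(x$n_frames)),
            class = "block_design")
}

#' Write a ground-truth map as NIfTI volumes plus a JSON sidecar
#'
#' Writes the best-frequency volume (`<stem>_bf.nii.gz`), the label volume
#' (`<stem>_label.nii.gz`) and a JSON sidecar with the label names, the
#' frequency ladder and the sheet specification.
#'
#' @param gt A [make_tonotopic_sheet()] result.
#' @param stem Output path stem.
#' @return The stem, invisibly.
#' @export
write_ground_truth <- function(gt, stem) {
  stopifnot(inherits(gt, "ground_truth_map"))
  bf <- gt$best_freq
  bf[is.na(bf)] <- 0
  RNifti::writeNifti(RNifti::asNifti(bf), paste0(stem, "_bf.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(gt$label),
                     paste0(stem, "_label.nii.gz"))
  jsonlite::write_json(
    list(labels = gt$labels, freqs = gt$freqs,
         spec = unclass(gt$spec)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
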