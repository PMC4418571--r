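#' Delineate the primary core (A1 and R) from a frequency-reversal pattern
#'
#' Finds the mirror-symmetric pair of primary gradients inside the masked
#' patch. For every medial--lateral column of the patch the log-frequency
#' profile along the posterior--anterior axis is examined: the low-frequency
#' ridge is the profile minimum, and the column belongs to the core when the
#' descending (posterior) and ascending (anterior) monotone spans around the
#' ridge each exceed half the ladder's total range. The core is the longest
#' contiguous run of such columns; its posterior and anterior borders sit at
#' the outer high-frequency representations (median positions of the flanking
#' maxima), and the A1/R border runs along the low-frequency ridge. A1 is the
#' posterior, high-to-low gradient; R the anterior, low-to-high one.
#'
#' @param map A masked `tonotopic_map` (see [threshold_map()]).
#' @param axis Posterior-to-anterior direction, `"y+"` or `"y-"`.
#' @return An object of class `core_delineation`: logical arrays `a1` and
#'   `r`, the border rows (`y_post`, `y_ridge`, `y_ant` in grid coordinates),
#'   the core column range `x_range`, and the axis.
#' @export
delineate_core <- function(map, axis = c("y+", "y-")) {
  stopifnot(inherits(map, "tonotopic_map"))
  axis <- match.arg(axis)
  d <- dim(map$r)
  # contiguous patch of interest: largest 6-connected suprathreshold
  # component (isolated noise voxels outside the patch are discarded)
  patch <- largest_component(map$mask)
  lf <- log2(map$best_freq)
  lf[!patch] <- NA
  half_range <- (max(log2(map$freqs)) - min(log2(map$freqs))) / 2

  # anatomical row order: posterior first
  rows <- if (axis == "y+") seq_len(d[2]) else rev(seq_len(d[2]))

  # NA-aware 3-point running mean along the posterior-anterior axis; damps
  # single-voxel mis-assignments so the reversal survives realistic noise
  smooth3 <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(j) {
      w <- v[max(1, j - 1):min(n, j + 1)]
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, numeric(1))
  }

  # a column qualifies when some interior ridge position shows descending
  # and ascending monotone spans both above half the ladder range; the
  # candidate maximizing the smaller span is the column's reversal
  best_ridge <- function(prof) {
    ok <- which(!is.na(prof))
    if (length(ok) < 4) return(NULL)
    v <- prof[ok]
    left <- cummax(v)
    right <- rev(cummax(rev(v)))
    score <- pmin(left - v, right - v)
    j <- which.max(score)
    list(ridge = ok[j], score = score[j], v = v, ok = ok, j = j)
  }
  col_stats <- lapply(seq_len(d[1]), function(x) {
    xs <- max(1, x - 1):min(d[1], x + 1)      # 3-column pooling window
    prof <- apply(lf[xs, rows, , drop = FALSE], 2, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    br <- best_ridge(prof)
    !is.null(br) && br$score > half_range
  })
  core_cols <- which(vapply(col_stats, isTRUE, logical(1)))
  if (length(core_cols) == 0) {
    stop("no core found: no column shows a mirror-symmetric frequency ",
         "reversal", call. = FALSE)
  }
  # longest contiguous run of qualifying columns
  runs <- rle(seq_len(d[1]) %in% core_cols)
  ends <- cumsum(runs$lengths)
  iw <- which(runs$values)
  best <- iw[which.max(runs$lengths[iw])]
  x1 <- ends[best]; x0 <- x1 - runs$lengths[best] + 1

  # borders from the profile pooled across core columns (noise averages
  # out; exact in the noiseless limit). Rows supported by fewer than half
  # the core columns (mask fringe) are excluded.
  width <- x1 - x0 + 1
  support <- vapply(seq_along(rows), function(j)
    sum(!is.na(lf[x0:x1, rows[j], ])), numeric(1))
  pooled_all <- vapply(seq_along(rows), function(j) {
    v <- lf[x0:x1, rows[j], ]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  pooled_all[support < pmax(2, ceiling(width / 2))] <- NA
  br <- best_ridge(pooled_all)
  if (is.null(br)) {
    stop("no core found: the pooled core profile is too sparse",
         call. = FALSE)
  }
  ridge_rel <- br$ridge
  okp <- which(!is.na(pooled_all))
  post_ok <- okp[okp <= ridge_rel]
  ant_ok <- okp[okp >= ridge_rel]
  post_rel <- post_ok[which.max(pooled_all[post_ok])]
  ant_rel <- ant_ok[which.max(pooled_all[ant_ok])]

  # warn when the pooled core profile between the outer maxima shows more
  # than the single expected high -> low -> high reversal
  pooled <- smooth3(pooled_all[post_rel:ant_rel])
  sg <- sign(diff(pooled[!is.na(pooled)]))
  flips <- sum(diff(sg[sg != 0]) != 0)
  if (!is.na(flips) && flips > 1) {
    warning("more than two gradient reversals detected; keeping the pair ",
            "with the strongest monotone span", call. = FALSE)
  }

  to_grid <- function(rel) rows[rel]
  a1 <- array(FALSE, d); rr <- array(FALSE, d)
  a1_rel <- post_rel:ridge_rel
  r_rel <- (ridge_rel + 1):ant_rel
  a1[x0:x1, rows[a1_rel], ] <- TRUE
  rr[x0:x1, rows[r_rel], ] <- TRUE
  a1 <- a1 & map$mask; rr <- rr & map$mask

  structure(
    list(a1 = a1, r = rr, patch = patch,
         y_post = to_grid(post_rel), y_ridge = to_grid(ridge_rel),
         y_ant = to_grid(ant_rel), x_range = c(x0, x1), axis = axis,
         hemisphere = map$hemisphere),
    class = "core_delineation"
  )
}

# largest 6-connected component of a logical 3-D array (flood fill)
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1))
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1]
      x <- rem %% d[1]
      for (k in seq_len(nrow(nb))) {
        xx <- x + nb[k, 1]; yy <- y + nb[k, 2]; zz <- z + nb[k, 3]
        if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] ||
            zz < 0 || zz >= d[3]) next
        w <- zz * d[1] * d[2] + yy * d[1] + xx + 1L
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  if (cur == 0L) return(mask)
  sizes <- tabulate(lab[lab != 0L], nbins = cur)
  lab == which.max(sizes)
}

#' Subdivide the suprathreshold surround into eight ROIs
#'
#' Extends the three core border lines (posterior border, A1/R border,
#' anterior border) across the whole patch, cutting it into four
#' posterior-to-anterior sectors; each sector is then split into a medial and
#' a lateral part at the core's medial/lateral edges (the strip directly
#' posterior/anterior of the core is split at the core midline, ties going to
#' the medial label). Together with A1 and R this partitions the patch into
#' the ten areas M1, L1, M2, A1, L2, M3, R, L3, M4, L4.
#'
#' @param map The masked `tonotopic_map` defining the patch.
#' @param core A [delineate_core()] result.
#' @param medial_side Which x direction is medial: `"x-"` (left hemisphere
#'   default) or `"x+"`. Defaults from the map's hemisphere tag.
#' @return An object of class `roi_set`: an integer `label` array (0 =
#'   background, codes per [roi_label_names()]), the label names, a summary
#'   tibble (roi, n_voxels, centroid) and provenance.
#' @export
subdivide_surround <- function(map, core, medial_side = NULL) {
  stopifnot(inherits(map, "tonotopic_map"), inherits(core, "core_delineation"))
  if (is.null(medial_side)) {
    medial_side <- if ((map$hemisphere %||% "LH") == "LH") "x-" else "x+"
  }
  d <- dim(map$r)
  lab_names <- roi_label_names()
  code <- setNames(seq_along(lab_names), lab_names)
  label <- array(0L, d)
  label[core$a1] <- code[["A1"]]
  label[core$r] <- code[["R"]]

  rows <- if (core$axis == "y+") seq_len(d[2]) else rev(seq_len(d[2]))
  rel_of <- match(seq_len(d[2]), rows)           # grid y -> anatomical rank
  post_rel <- rel_of[core$y_post]
  ridge_rel <- rel_of[core$y_ridge]
  ant_rel <- rel_of[core$y_ant]
  x0 <- core$x_range[1]; x1 <- core$x_range[2]
  x_mid <- (x0 + x1) / 2
  med_low_x <- medial_side == "x-"

  patch <- (core$patch %||% map$mask) & label == 0L
  idx <- which(patch, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    yr <- rel_of[idx[, 2]]
    sector <- ifelse(yr < post_rel, 1L,
              ifelse(yr <= ridge_rel, 2L,
              ifelse(yr <= ant_rel, 3L, 4L)))
    x <- idx[, 1]
    mid_is_medial <- if (med_low_x) x <= x_mid else x >= x_mid  # ties medial
    side <- ifelse(x < x0, ifelse(med_low_x, "M", "L"),
            ifelse(x > x1, ifelse(med_low_x, "L", "M"),
            ifelse(mid_is_medial, "M", "L")))
    label[patch] <- code[paste0(side, sector)]
  }

  empty <- setdiff(lab_names, lab_names[sort(unique(label[label != 0L]))])
  if (length(empty) > 0) {
    warning("empty ROI(s): ", paste(empty, collapse = ", "),
            " (core touches the patch boundary?)", call. = FALSE)
  }

  tab <- label_table(label, lab_names)
  summary <- tab |>
    dplyr::group_by(roi = factor(.data$roi, levels = lab_names)) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
                     .groups = "drop") |>
    dplyr::arrange(.data$roi)

  structure(
    list(label = label, labels = lab_names, summary = summary,
         provenance = list(axis = core$axis, medial_side = medial_side,
                           x_range = core$x_range,
                           borders = c(post = core$y_post,
                                       ridge = core$y_ridge,
                                       ant = core$y_ant)),
         voxel_mm = map$voxel_mm %||% 1.5,
         hemisphere = map$hemisphere %||% "LH"),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>", sum(x$label != 0), "voxels in",
      length(unique(x$label[x$label != 0])), "regions\n")
  print(x$summary)
  invisible(x)
}

#' Project ROI labels into a volumetric slab
#'
#' Writes the sheet's labels into a volume of given slab half-width around
#' the sheet plane, mirroring the projection of surface ROIs into a thin
#' volumetric band.
#'
#' @param rois A [subdivide_surround()] result.
#' @param slab_halfwidth_mm Half-width of the slab, mm (0 gives a
#'   single-voxel-thick label volume).
#' @param voxel_mm Voxel size of the target grid, mm; defaults to the ROI
#'   set's own.
#' @return Integer 3-D label array whose third dimension spans the slab; the
#'   label names are attached as attribute `labels`.
#' @export
roiset_to_label_volume <- function(rois, slab_halfwidth_mm = 1,
                                   voxel_mm = NULL) {
  stopifnot(inherits(rois, "roi_set"), slab_halfwidth_mm >= 0)
  voxel_mm <- voxel_mm %||% rois$voxel_mm
  n_half <- floor(slab_halfwidth_mm / voxel_mm + 1e-9)
  nz <- as.integer(2 * n_half + 1)
  d <- dim(rois$label)
  sheet <- rois$label[, , 1]
  out <- array(0L, c(d[1], d[2], nz))
  for (z in seq_len(nz)) out[, , z] <- sheet
  attr(out, "labels") <- rois$labels
  attr(out, "voxel_mm") <- voxel_mm
  out
}
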