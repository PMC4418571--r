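#' Specification of a synthetic tonotopic sheet
#'
#' Describes a flat cortical slab standing in for the supratemporal plane of
#' one hemisphere. The central core hosts two mirror-symmetric primary
#' gradients: a posterior area (A1) whose preferred frequency falls from high
#' to low along the posterior-to-anterior axis, abutting an anterior area (R)
#' that rises from low back to high, so a transect through the core reads
#' "high-low-low-high". A frequency-selective surround of eight regions
#' (M1--M4 medial, L1--L4 lateral, numbered posterior to anterior) encloses
#' the core; everything beyond the patch is unresponsive background.
#'
#' @param dim Grid dimensions `c(nx, ny, nz)` in voxels; x is the
#'   medial--lateral axis, y the posterior--anterior axis.
#' @param hemisphere `"LH"` or `"RH"`. For `"LH"` the medial side is low x;
#'   for `"RH"` it is high x (the sheet is mirrored).
#' @param freq_range Frequency range in Hz, within \[88, 8000\].
#' @param core_dim Core (A1 + R) extent `c(width_x, length_y)` in voxels;
#'   `length_y` is split equally between A1 (posterior) and R (anterior).
#' @param surround Surround extent in voxels on every side of the core.
#' @param margin Unresponsive background margin around the patch, voxels.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param axis Posterior-to-anterior direction: `"y+"` (anterior = increasing
#'   y) or `"y-"`.
#' @return An object of class `sheet_spec`.
#' @export
sheet_spec <- function(dim = c(32, 44, 1), hemisphere = c("LH", "RH"),
                       freq_range = c(88, 8000), core_dim = c(12, 16),
                       surround = 8, margin = 2, voxel_mm = 1.5,
                       axis = c("y+", "y-")) {
  hemisphere <- match.arg(hemisphere)
  axis <- match.arg(axis)
  stopifnot(length(dim) == 3, all(dim >= 1), length(core_dim) == 2,
            surround >= 1, margin >= 0, voxel_mm > 0)
  if (freq_range[1] < 88 || freq_range[2] > 8000 ||
      freq_range[1] >= freq_range[2]) {
    stop("`freq_range` must be increasing and within [88, 8000] Hz",
         call. = FALSE)
  }
  if (core_dim[1] < 2 || core_dim[2] < 4) {
    stop("core too small to host two mirror-symmetric gradients ",
         "(need core_dim >= c(2, 4))", call. = FALSE)
  }
  if (core_dim[1] + 2 * (surround + margin) > dim[1] ||
      core_dim[2] + 2 * (surround + margin) > dim[2]) {
    stop("grid too small to host the core plus surround and margin",
         call. = FALSE)
  }
  structure(
    list(dim = as.integer(dim), hemisphere = hemisphere,
         freq_range = freq_range, core_dim = as.integer(core_dim),
         surround = as.integer(surround), margin = as.integer(margin),
         voxel_mm = voxel_mm, axis = axis,
         gradient_layout = c("high", "low", "low", "high"),
         medial_side = if (hemisphere == "LH") "x-" else "x+"),
    class = "sheet_spec"
  )
}

#' ROI label names in canonical order
#' @return Character vector `A1, R, M1..M4, L1..L4`.
#' @export
roi_label_names <- function() {
  c("A1", "R", paste0("M", 1:4), paste0("L", 1:4))
}

#' Generate a ground-truth tonotopic sheet
#'
#' Builds the per-voxel best-frequency map and ROI labels for a [sheet_spec()].
#' Core voxels take frequencies from the half-octave ladder spanning
#' `freq_range`, arranged as the high-low-low-high double gradient; each
#' surround region is frequency-selective around a region-specific ladder step
#' (with one step of voxel-wise scatter) but carries no long-range gradient.
#' Background voxels are unresponsive (`NA` frequency).
#'
#' @param spec A [sheet_spec()].
#' @param seed Integer seed; the map is a pure function of `(spec, seed)`.
#' @return An object of class `ground_truth_map` with 3-D arrays `best_freq`
#'   (Hz, `NA` outside the patch) and `label` (integer codes, 0 = background,
#'   1..10 per [roi_label_names()]), the frequency ladder `freqs`, and the
#'   originating `spec`.
#' @export
make_tonotopic_sheet <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sheet_spec"))
  set.seed(seed)
  nx <- spec$dim[1]; ny <- spec$dim[2]; nz <- spec$dim[3]
  # half-octave ladder anchored at the high end, rounded to whole Hz (the
  # same convention as tone_frequencies(), so simulated runs and mapping
  # share one frequency set exactly)
  n_steps <- as.integer(round(2 * log2(spec$freq_range[2] /
                                         spec$freq_range[1]))) + 1L
  freqs <- round(spec$freq_range[2] * 2^seq(-(n_steps - 1) / 2, 0, by = 0.5))
  n_steps <- length(freqs)

  # core centred in the grid; the patch is the core plus the surround ring
  cx0 <- (nx - spec$core_dim[1]) %/% 2 + 1
  cx1 <- cx0 + spec$core_dim[1] - 1
  cy0 <- (ny - spec$core_dim[2]) %/% 2 + 1
  cy1 <- cy0 + spec$core_dim[2] - 1
  px <- (cx0 - spec$surround):(cx1 + spec$surround)
  py <- (cy0 - spec$surround):(cy1 + spec$surround)
  half <- spec$core_dim[2] %/% 2
  ridge_y <- cy0 + half - 1                      # last A1 row (low-frequency ridge)

  label <- array(0L, dim = c(nx, ny, nz))
  bf_idx <- array(NA_integer_, dim = c(nx, ny, nz))
  lab_names <- roi_label_names()
  code <- setNames(seq_along(lab_names), lab_names)

  # orientation helpers: "posterior" means low y for axis y+, high y for y-
  ant_of <- function(y_core_rel) if (spec$axis == "y+") y_core_rel else
    (spec$core_dim[2] + 1 - y_core_rel)
  medial_is_low_x <- spec$medial_side == "x-"

  # core frequencies: A1 posterior half high -> low, R anterior half low -> high
  a1_idx <- round(seq(n_steps, 1, length.out = half))
  r_idx <- round(seq(1, n_steps, length.out = spec$core_dim[2] - half))
  for (j in seq_len(spec$core_dim[2])) {
    y <- cy0 + ant_of(j) - 1
    in_a1 <- j <= half
    label[cx0:cx1, y, ] <- if (in_a1) code[["A1"]] else code[["R"]]
    bf_idx[cx0:cx1, y, ] <- if (in_a1) a1_idx[j] else r_idx[j - half]
  }

  # surround sectors along y: 1 posterior of core, 2 beside A1, 3 beside R,
  # 4 anterior of core; medial/lateral split at the core edges, with the
  # strip directly behind/ahead of the core split at its midline (ties medial)
  mid_steps <- seq(4L, min(10L, n_steps - 3L))
  base_idx <- setNames(sample(mid_steps, 8, replace = TRUE),
                       c(paste0("M", 1:4), paste0("L", 1:4)))
  x_mid <- (cx0 + cx1) / 2
  for (x in px) for (y in py) {
    if (label[x, y, 1] != 0L) next
    # sector number in anatomical (posterior -> anterior) order
    y_rel <- if (spec$axis == "y+") y else (ny + 1 - y)
    cy0_rel <- if (spec$axis == "y+") cy0 else (ny + 1 - cy1)
    cy1_rel <- if (spec$axis == "y+") cy1 else (ny + 1 - cy0)
    ridge_rel <- cy0_rel + half - 1
    sector <- if (y_rel < cy0_rel) 1L
      else if (y_rel <= ridge_rel) 2L
      else if (y_rel <= cy1_rel) 3L
      else 4L
    side <- if (x < cx0) { if (medial_is_low_x) "M" else "L" }
      else if (x > cx1) { if (medial_is_low_x) "L" else "M" }
      else { # strip directly posterior/anterior of the core
        med <- if (medial_is_low_x) x <= x_mid else x >= x_mid
        if (med) "M" else "L"
      }
    nm <- paste0(side, sector)
    label[x, y, ] <- code[[nm]]
    bf_idx[x, y, ] <- pmin(pmax(base_idx[[nm]] + sample(-1:1, 1), 1L), n_steps)
  }

  structure(
    list(best_freq = array(freqs[bf_idx], dim = dim(bf_idx)),
         label = label, labels = lab_names, freqs = freqs, spec = spec),
    class = "ground_truth_map"
  )
}

#' @export
print.ground_truth_map <- function(x, ...) {
  cat("<ground_truth_map>", paste(x$spec$dim, collapse = " x "),
      "voxels,", x$spec$hemisphere, "; patch",
      sum(x$label != 0), "voxels in", length(unique(x$label[x$label != 0])),
      "regions\n")
  invisible(x)
}

# tibble of labelled voxels (used by summaries and tests)
label_table <- function(label, labels) {
  idx <- which(label != 0, arr.ind = TRUE)
  tibble::tibble(
    roi = labels[label[label != 0]],
    x = idx[, 1], y = idx[, 2], z = idx[, 3]
  )
}
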