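#' 4-D BOLD volume series
#'
#' Light container for a simulated or ingested 4-D functional run: an
#' `(x, y, z, frame)` intensity array plus repetition time, voxel size and an
#' optional reference to the generating design.
#'
#' @param data 4-D numeric array `(x, y, z, frame)`.
#' @param tr Repetition time, seconds.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param design Optional design object ([make_block_design()] or
#'   [frequency_progression()]).
#' @param meta Optional named list of free-form metadata (hemisphere, subject,
#'   run, ...).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr, voxel_mm = 1.5, design = NULL,
                          meta = list()) {
  if (length(dim(data)) != 4) {
    stop("`data` must be a 4-D array (x, y, z, frame)", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume data must be finite", call. = FALSE)
  }
  stopifnot(tr > 0)
  structure(list(data = data, tr = tr, voxel_mm = voxel_mm,
                 design = design, meta = meta),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_series>", paste(d[1:3], collapse = " x "), "voxels x", d[4],
      "frames, TR", x$tr, "s\n")
  invisible(x)
}

#' Simulate a travelling-wave tonotopy run
#'
#' Generates the BOLD response of a ground-truth sheet to a periodic frequency
#' progression. Each responsive voxel follows the haemodynamic response to the
#' presentation step(s) near its best frequency: tuning is Gaussian on the
#' log-frequency axis (default half-octave SD, matching the half-octave step
#' size), so the voxel responds mostly during "its" step, with weak shoulders
#' on the neighbours. The noiseless per-voxel signal is normalised to peak
#' `amplitude` (percent-signal-change units) and riding on `baseline`. Noise
#' is the sum of voxel-wise white Gaussian noise and a global per-frame
#' Gaussian term shared by all voxels (the spatially coherent physiological
#' fluctuation that does not average away over ROIs).
#'
#' @param gt A [make_tonotopic_sheet()] ground truth.
#' @param prog A [frequency_progression()] whose ladder spans the sheet's
#'   frequency range.
#' @param hrf An [hrf_model()].
#' @param noise_sd SD of voxel-wise white noise (amplitude units).
#' @param global_sd SD of the global shared noise term (amplitude units).
#' @param seed Integer seed.
#' @param tr Repetition time, seconds; must divide the cycle duration.
#' @param amplitude Peak response amplitude (percent signal change).
#' @param baseline Baseline image intensity.
#' @param tuning_oct Tuning width (SD of the Gaussian on log2 frequency),
#'   octaves.
#' @return A [volume_series()] of `n_cycles * cycle_s / tr` frames.
#' @export
simulate_tonotopy_run <- function(gt, prog, hrf = hrf_model(),
                                  noise_sd = 1, global_sd = 0.3, seed = 1,
                                  tr = 2, amplitude = 1, baseline = 100,
                                  tuning_oct = 0.5) {
  stopifnot(inherits(gt, "ground_truth_map"),
            inherits(prog, "frequency_progression"))
  rng <- range(gt$best_freq, na.rm = TRUE)
  if (min(prog$freqs) > rng[1] || max(prog$freqs) < rng[2]) {
    stop("progression frequencies must span the map's frequency range",
         call. = FALSE)
  }
  ref <- build_reference_cycle(prog, hrf, tr)
  fpc <- length(ref)                              # frames per cycle
  n_frames <- prog$n_cycles * fpc
  step_frames <- prog$step_s / tr
  order_f <- presented_order(prog)
  n_steps <- length(order_f)

  # per-step regressors: reference delayed by the step's onset within a cycle
  X <- vapply(seq_len(n_steps) - 1L, function(k) {
    sh <- as.integer(round(k * step_frames)) %% fpc
    rep(ref[((seq_len(fpc) - 1 - sh) %% fpc) + 1], prog$n_cycles)
  }, numeric(n_frames))

  dims <- dim(gt$best_freq)
  resp <- which(!is.na(gt$best_freq))
  bf <- gt$best_freq[resp]
  W <- outer(log2(order_f), log2(bf), function(a, b)
    exp(-0.5 * ((a - b) / tuning_oct)^2))        # n_steps x n_resp
  S <- X %*% W                                   # n_frames x n_resp
  S <- sweep(S, 2, apply(S, 2, max), "/") * amplitude

  set.seed(seed)
  data <- array(baseline, dim = c(dims, n_frames))
  global <- rnorm(n_frames, 0, global_sd)
  nvox <- prod(dims)
  noise <- matrix(rnorm(nvox * n_frames, 0, noise_sd), nvox, n_frames)
  noise <- sweep(noise, 2, global, "+")
  flat <- matrix(data, nvox, n_frames)
  flat <- flat + noise
  flat[resp, ] <- flat[resp, ] + t(S)
  volume_series(array(flat, dim = c(dims, n_frames)), tr = tr,
                voxel_mm = gt$spec$voxel_mm, design = prog,
                meta = list(hemisphere = gt$spec$hemisphere, seed = seed,
                            kind = "tonotopy"))
}

# lagged circular shift of a per-cycle reference is built in
# simulate_tonotopy_run from the same build_reference_cycle used for mapping,
# so noiseless simulation + mapping recover ground truth exactly.

#' Simulate a repetition-suppression run
#'
#' Generates a block-design run in which CTRL blocks drive a full-amplitude
#' neural boxcar for the stimulation period, while REP blocks drive the same
#' boxcar scaled by the voxel's ROI-specific suppression factor after an
#' initial unsuppressed lead (see [suppression_profile()]). Both are convolved
#' with the haemodynamic model; noise is voxel-wise white plus a global shared
#' per-frame term, as in [simulate_tonotopy_run()].
#'
#' @param gt A [make_tonotopic_sheet()] ground truth (provides ROI labels).
#' @param design A [make_block_design()].
#' @param hrf An [hrf_model()].
#' @param profile A [suppression_profile()]; every named factor must refer to
#'   a label present in `gt`.
#' @param noise_sd SD of voxel-wise white noise (amplitude units).
#' @param global_sd SD of the global shared noise term (amplitude units).
#' @param seed Integer seed.
#' @param amplitude Sustained (plateau) response amplitude for CTRL blocks.
#' @param baseline Baseline image intensity.
#' @return A [volume_series()] with the design attached.
#' @export
simulate_repetition_run <- function(gt, design, hrf = hrf_model(),
                                    profile = suppression_profile(),
                                    noise_sd = 1, global_sd = 0.3, seed = 1,
                                    amplitude = 1, baseline = 100) {
  stopifnot(inherits(gt, "ground_truth_map"), inherits(design, "block_design"),
            inherits(profile, "suppression_profile"))
  present <- gt$labels[sort(unique(gt$label[gt$label != 0]))]
  unknown <- setdiff(names(profile$factors), present)
  if (length(unknown) > 0) {
    stop("suppression profile references ROI(s) absent from the map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tr <- design$tr
  n_frames <- design$n_frames
  frame_t <- (seq_len(n_frames) - 1) * tr

  # expected run time course for a given REP factor (CTRL = factor 1 drive)
  run_signal <- function(factor) {
    drive_fn <- function(tt) {
      d <- numeric(length(tt))
      for (i in seq_len(nrow(design$blocks))) {
        b <- design$blocks[i, ]
        rel <- tt - b$onset_s
        on <- rel >= 0 & rel < b$stim_s
        d[on] <- if (b$condition == "REP") {
          ifelse(rel[on] < profile$lead_s, 1, factor)
        } else 1
      }
      d
    }
    .hrf_convolve(hrf, drive_fn, frame_t) * amplitude
  }

  fac_for_label <- function(nm) {
    if (nm %in% names(profile$factors)) profile$factors[[nm]] else 1
  }
  dims <- dim(gt$label)
  vox_fac <- array(1, dim = dims)
  for (k in sort(unique(gt$label[gt$label != 0]))) {
    vox_fac[gt$label == k] <- fac_for_label(gt$labels[k])
  }
  uniq <- sort(unique(vox_fac[gt$label != 0]))
  signals <- vapply(uniq, run_signal, numeric(n_frames))

  set.seed(seed)
  nvox <- prod(dims)
  global <- rnorm(n_frames, 0, global_sd)
  flat <- matrix(rnorm(nvox * n_frames, 0, noise_sd), nvox, n_frames)
  flat <- sweep(flat, 2, global + baseline, "+")
  resp <- which(gt$label != 0)
  fac_idx <- match(vox_fac[resp], uniq)
  flat[resp, ] <- flat[resp, ] + t(signals)[fac_idx, , drop = FALSE]
  volume_series(array(flat, dim = c(dims, n_frames)), tr = tr,
                voxel_mm = gt$spec$voxel_mm, design = design,
                meta = list(hemisphere = gt$spec$hemisphere, seed = seed,
                            kind = "repetition"))
}
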