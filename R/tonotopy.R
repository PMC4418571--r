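#' Canonical single-step reference cycle
#'
#' Builds the expected periodic response to one tone step presented at the
#' start of a stimulation cycle: the haemodynamic model convolved with a
#' `step_s`-second boxcar, wrapped modulo the cycle (the travelling-wave run
#' is periodic at steady state) and sampled at the TR.
#'
#' @param prog A [frequency_progression()].
#' @param hrf An [hrf_model()].
#' @param tr Sampling interval, seconds; must divide the cycle duration.
#' @return Numeric vector of `cycle_s / tr` samples.
#' @export
build_reference_cycle <- function(prog, hrf = hrf_model(), tr = 2) {
  stopifnot(inherits(prog, "frequency_progression"))
  if (abs(prog$cycle_s / tr - round(prog$cycle_s / tr)) > 1e-9) {
    stop("`tr` must divide the cycle duration (", prog$cycle_s, " s)",
         call. = FALSE)
  }
  fpc <- as.integer(round(prog$cycle_s / tr))
  # response to a single step over two cycles, folded onto one
  tt <- (seq_len(2L * fpc) - 1) * tr
  y <- .hrf_convolve(hrf, function(t) as.numeric(t >= 0 & t < prog$step_s), tt)
  y[seq_len(fpc)] + y[fpc + seq_len(fpc)]
}

#' Best-frequency map from a travelling-wave run
#'
#' Assigns a best frequency, peak correlation and time-to-peak to every voxel
#' by lagged cross-correlation: the voxel time course is correlated with the
#' canonical reference cycle shifted by every whole-frame lag within one
#' cycle; the lag of maximum correlation (earliest lag on ties) is the
#' voxel's response delay, and the tone presented at that cycle position gives
#' its best frequency. Because the reference already includes the
#' haemodynamic model, the lag reads directly in stimulus time; any residual
#' mismatch between the assumed and true response delay biases ascending and
#' descending runs in opposite frequency directions and is cancelled by
#' [combine_directions()]. Lags falling inside the silent pause are wrapped
#' to the nearest presented step in circular time.
#'
#' Voxels with a constant time course have undefined correlation and are
#' excluded from the mask with reason `"constant"`.
#'
#' @param run A [volume_series()] whose frame count is a whole number of
#'   cycles.
#' @param prog The [frequency_progression()] used for the run.
#' @param hrf The [hrf_model()] assumed for the reference.
#' @return An object of class `tonotopic_map` with 3-D arrays `best_freq`
#'   (Hz), `r` (peak Pearson correlation), `time_to_peak` (s), a logical
#'   `mask`, a character `exclude_reason` array, the frequency ladder and
#'   `n_frames`.
#' @export
best_frequency_map <- function(run, prog, hrf = hrf_model()) {
  stopifnot(inherits(run, "volume_series"),
            inherits(prog, "frequency_progression"))
  tr <- run$tr
  ref <- build_reference_cycle(prog, hrf, tr)
  fpc <- length(ref)
  d <- dim(run$data)
  n_frames <- d[4]
  if (n_frames %% fpc != 0) {
    stop("run frame count (", n_frames, ") is not a whole number of cycles",
         call. = FALSE)
  }
  n_cycles <- n_frames %/% fpc
  nvox <- prod(d[1:3])
  V <- t(matrix(run$data, nvox, n_frames))        # frames x voxels

  # standardized voxel matrix; constant voxels flagged
  mu <- colMeans(V)
  Vc <- sweep(V, 2, mu)
  ss <- sqrt(colSums(Vc^2))
  const <- ss < 1e-12
  ss[const] <- 1
  Vs <- sweep(Vc, 2, ss, "/")

  # reference at each lag (circular within cycle), standardized
  R <- vapply(seq_len(fpc) - 1L, function(sh) {
    rep(ref[((seq_len(fpc) - 1 - sh) %% fpc) + 1], n_cycles)
  }, numeric(n_frames))
  Rc <- sweep(R, 2, colMeans(R))
  Rs <- sweep(Rc, 2, sqrt(colSums(Rc^2)), "/")

  C <- crossprod(Rs, Vs)                          # lags x voxels
  r <- apply(C, 2, max)
  lag <- apply(C, 2, which.max) - 1L              # earliest lag wins ties
  r[const] <- NA_real_

  # lag -> presented step; pause lags wrap to the nearest step circularly
  order_f <- presented_order(prog)
  n_steps <- length(order_f)
  lag_t <- lag * tr
  step <- floor(lag_t / prog$step_s)
  in_pause <- step >= n_steps
  if (any(in_pause)) {
    pt <- lag_t[in_pause]
    d_back <- pt - (n_steps * prog$step_s - prog$step_s)      # to last step onset
    d_fwd <- prog$cycle_s - pt                                # to next cycle's first step
    step[in_pause] <- ifelse(d_back <= d_fwd, n_steps - 1, 0)
  }
  bf <- order_f[step + 1L]
  bf[const] <- NA_real_

  reason <- rep(NA_character_, nvox)
  reason[const] <- "constant"
  structure(
    list(best_freq = array(bf, d[1:3]),
         r = array(r, d[1:3]),
         time_to_peak = array(lag_t, d[1:3]),
         mask = array(!const, d[1:3]),
         exclude_reason = array(reason, d[1:3]),
         freqs = prog$freqs, n_frames = n_frames, tr = tr,
         direction = prog$direction,
         hemisphere = run$meta$hemisphere %||% "LH",
         voxel_mm = run$voxel_mm),
    class = "tonotopic_map"
  )
}

#' @export
print.tonotopic_map <- function(x, ...) {
  cat("<tonotopic_map>", paste(dim(x$r), collapse = " x "), "voxels,",
      sum(x$mask), "in mask; r in [",
      round(min(x$r, na.rm = TRUE), 2), ",",
      round(max(x$r, na.rm = TRUE), 2), "]\n")
  invisible(x)
}

#' Average ascending and descending best-frequency maps
#'
#' Combines the two travelling-wave directions per voxel: best frequency is
#' the geometric mean of the two estimates (the ladder is multiplicative, so
#' averaging lives on the log-frequency scale), snapped to the nearest ladder
#' step (ties toward the lower step); the peak correlation and time-to-peak
#' are arithmetic means. A residual haemodynamic-delay error shifts the
#' ascending estimate up and the descending estimate down the ladder by the
#' same number of steps, so the combination cancels it. Voxels whose two
#' estimates disagree by more than `max_disagree_steps` ladder steps are
#' flagged `"unreliable"` and dropped from the mask.
#'
#' @param asc,desc `tonotopic_map`s from ascending and descending runs on the
#'   same grid.
#' @param max_disagree_steps Maximum tolerated disagreement, ladder steps.
#' @return A combined `tonotopic_map`.
#' @export
combine_directions <- function(asc, desc, max_disagree_steps = 2) {
  stopifnot(inherits(asc, "tonotopic_map"), inherits(desc, "tonotopic_map"))
  if (!identical(dim(asc$r), dim(desc$r))) {
    stop("maps come from different grids", call. = FALSE)
  }
  lf <- log2(asc$freqs)
  ia <- array(match_freq_step(asc$best_freq, asc$freqs), dim(asc$r))
  id <- array(match_freq_step(desc$best_freq, desc$freqs), dim(desc$r))
  mean_l <- (lf[ia] + lf[id]) / 2
  # snap to nearest ladder step, ties toward the lower step
  snapped <- vapply(mean_l, function(v) {
    if (is.na(v)) return(NA_real_)
    dd <- abs(lf - v)
    asc$freqs[which(dd <= min(dd) + 1e-12)[1]]
  }, numeric(1))
  disagree <- abs(ia - id)
  ok <- !is.na(disagree) & disagree <= max_disagree_steps
  reason <- asc$exclude_reason
  reason[!ok & is.na(reason)] <- "unreliable"
  bf <- array(snapped, dim(asc$r))
  bf[!ok] <- NA_real_
  structure(
    list(best_freq = bf,
         r = (asc$r + desc$r) / 2,
         time_to_peak = (asc$time_to_peak + desc$time_to_peak) / 2,
         mask = asc$mask & desc$mask & ok,
         exclude_reason = reason,
         freqs = asc$freqs, n_frames = asc$n_frames, tr = asc$tr,
         direction = "combined", hemisphere = asc$hemisphere,
         voxel_mm = asc$voxel_mm),
    class = "tonotopic_map"
  )
}

# index of each frequency on the ladder (NA-safe)
match_freq_step <- function(freq, freqs) {
  idx <- vapply(as.numeric(freq), function(f) {
    if (is.na(f)) return(NA_integer_)
    which.min(abs(log2(freqs) - log2(f)))
  }, integer(1))
  idx
}

#' Two-tailed p-value of a Pearson correlation
#'
#' Exact null-distribution p for a sample correlation with `n` observations,
#' via the t transform with `n - 2` degrees of freedom. The classic tonotopy
#' threshold r > 0.13 corresponds to p <= 0.05 at n = 240 frames.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @param n Number of samples (>= 3).
#' @return Two-tailed p-value(s).
#' @examples
#' r_to_p(0.13, 240)
#' @export
r_to_p <- function(r, n) {
  if (any(n < 3)) stop("`n` must be at least 3", call. = FALSE)
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  p <- rep(NA_real_, length(r))
  sat <- !is.na(r) & abs(r) >= 1
  p[sat] <- 0
  ok <- !is.na(r) & abs(r) < 1
  tv <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(tv), df = n - 2)
  p
}

#' Threshold a tonotopic map
#'
#' Restricts the mask to voxels with peak correlation strictly above `r_min`;
#' all other fields are untouched. Raising `r_min` can only shrink the mask.
#'
#' @param map A `tonotopic_map`.
#' @param r_min Correlation threshold (default 0.13, i.e. p <= 0.05
#'   uncorrected at 240 frames).
#' @return The thresholded `tonotopic_map`.
#' @export
threshold_map <- function(map, r_min = 0.13) {
  stopifnot(inherits(map, "tonotopic_map"))
  keep <- !is.na(map$r) & map$r > r_min
  map$mask <- map$mask & keep
  map$r_min <- r_min
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a
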