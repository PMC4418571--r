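#' Double-gamma haemodynamic response model
#'
#' Parameterises the BOLD impulse response as the difference of two gamma
#' densities, each given by its peak (mode) delay and dispersion (standard
#' deviation) in seconds. The response is scaled so that convolution with a
#' sustained boxcar saturates at 1, which makes simulated block responses
#' directly interpretable as fractions of the plateau amplitude.
#'
#' The defaults describe a compact early-auditory response: the positive lobe
#' peaks 4 s after a brief stimulus and has essentially returned to zero by
#' 7 s, so that a sustained block saturates within about 4 s of the effective
#' onset latency (~2 s). A mild undershoot (ratio 0.03) follows around 14 s.
#'
#' @param peak_delay Peak (mode) of the positive lobe, seconds. Must lie in
#'   \[4, 7\].
#' @param peak_disp Dispersion (SD) of the positive lobe, seconds.
#' @param undershoot_delay Peak of the undershoot lobe, seconds.
#' @param undershoot_disp Dispersion of the undershoot lobe, seconds.
#' @param undershoot_ratio Amplitude of the undershoot relative to the positive
#'   lobe, in \[0, 1).
#' @return An object of class `hrf_model`.
#' @examples
#' h <- hrf_model()
#' t <- seq(0, 30, 0.1)
#' plot(t, hrf_eval(h, t), type = "l")
#' @export
hrf_model <- function(peak_delay = 4, peak_disp = 0.75,
                      undershoot_delay = 14, undershoot_disp = 3,
                      undershoot_ratio = 0.03) {
  stopifnot(peak_disp > 0, undershoot_disp > 0)
  if (peak_delay < 4 || peak_delay > 7) {
    stop("`peak_delay` must lie in [4, 7] seconds", call. = FALSE)
  }
  if (undershoot_ratio < 0 || undershoot_ratio >= 1) {
    stop("`undershoot_ratio` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(peak_delay = peak_delay, peak_disp = peak_disp,
         undershoot_delay = undershoot_delay,
         undershoot_disp = undershoot_disp,
         undershoot_ratio = undershoot_ratio),
    class = "hrf_model"
  )
}

# gamma shape/scale from mode and sd
.gamma_pars <- function(mode, sd) {
  mu <- (mode + sqrt(mode^2 + 4 * sd^2)) / 2
  scale <- sd^2 / mu
  c(shape = mu / scale, scale = scale)
}

#' Evaluate a haemodynamic response model
#'
#' @param hrf An [hrf_model()].
#' @param t Time points in seconds (non-negative values contribute; the
#'   response is causal).
#' @return Response values, scaled so a sustained block saturates at 1.
#' @export
hrf_eval <- function(hrf, t) {
  stopifnot(inherits(hrf, "hrf_model"))
  p1 <- .gamma_pars(hrf$peak_delay, hrf$peak_disp)
  p2 <- .gamma_pars(hrf$undershoot_delay, hrf$undershoot_disp)
  r <- hrf$undershoot_ratio
  (dgamma(t, p1["shape"], scale = p1["scale"]) -
     r * dgamma(t, p2["shape"], scale = p2["scale"])) / (1 - r)
}

# expected response to an arbitrary neural drive, sampled at `times` (seconds).
# drive is a function of time; computed on a fine grid and read off by linear
# interpolation.
.hrf_convolve <- function(hrf, drive_fn, times, dt = 0.05, pad = 40) {
  t_max <- max(times) + dt
  tt <- seq(0, t_max, by = dt)
  drive <- drive_fn(tt)
  hh <- hrf_eval(hrf, seq(0, pad, by = dt))
  y <- convolve(drive, rev(hh), type = "open")[seq_along(tt)] * dt
  approx(tt, y, xout = times)$y
}

#' Sample per-subject response models
#'
#' Draws a cohort of subject-level haemodynamic models around a base model:
#' response amplitude, positive-lobe peak delay and undershoot ratio vary
#' across subjects, emulating the inter-individual variability of real BOLD
#' responses. Used by the simulation examples and the acceptance pipeline to
#' build multi-subject data sets.
#'
#' @param n Number of subjects.
#' @param base Base [hrf_model()].
#' @param seed Integer seed; the draw is a pure function of `(base, seed)`.
#' @param amp_mean,amp_sd Mean and SD of the subject response amplitude
#'   (percent signal change at plateau).
#' @param peak_sd SD of the subject peak delay jitter, seconds (truncated so
#'   the delay stays within the model's valid range).
#' @param ratio_sd SD of the subject undershoot-ratio jitter (folded at zero).
#' @return A tibble with columns `subject`, `amplitude` and a list-column
#'   `hrf`.
#' @export
sample_subject_hrfs <- function(n, base = hrf_model(), seed = 1,
                                amp_mean = 1, amp_sd = 0.1,
                                peak_sd = 0.2, ratio_sd = 0.015) {
  stopifnot(n >= 1)
  set.seed(seed)
  amps <- rnorm(n, amp_mean, amp_sd)
  peaks <- pmin(pmax(rnorm(n, base$peak_delay, peak_sd), 4), 7)
  ratios <- pmin(abs(rnorm(n, base$undershoot_ratio, ratio_sd)), 0.5)
  tibble::tibble(
    subject = paste0("S", seq_len(n)),
    amplitude = amps,
    hrf = purrr::map2(peaks, ratios, function(p, r) {
      hrf_model(peak_delay = p, peak_disp = base$peak_disp,
                undershoot_delay = base$undershoot_delay,
                undershoot_disp = base$undershoot_disp,
                undershoot_ratio = r)
    })
  )
}

#' @export
print.hrf_model <- function(x, ...) {
  cat("<hrf_model> double-gamma: peak", x$peak_delay, "s (disp",
      x$peak_disp, "s), undershoot", x$undershoot_delay, "s (disp",
      x$undershoot_disp, "s, ratio", x$undershoot_ratio, ")\n")
  invisible(x)
}
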