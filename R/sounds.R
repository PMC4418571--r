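#' Acoustic class distribution for synthetic sounds
#'
#' Parameters of the generative distribution a sound pool is drawn from:
#' each sound is band-filtered Gaussian noise with a random log-frequency
#' centre, multiplied by a random smooth envelope modulation, with linear
#' rise/fall ramps and peak normalisation.
#'
#' @param center_oct Mean of the spectral centre on the log2-frequency axis
#'   (default `log2(800)`, i.e. 800 Hz).
#' @param center_sd SD of the spectral centre, octaves.
#' @param bandwidth_oct Spectral bandwidth (full width of the Gaussian band),
#'   octaves.
#' @param mod_depth Depth of the random low-frequency envelope modulation,
#'   in \[0, 1\].
#' @param categories Optional character vector of semantic category tags to
#'   cycle over (e.g. animal, tool, ...); `NULL` for an untagged pool.
#' @return An object of class `sound_class`.
#' @export
sound_class <- function(center_oct = log2(800), center_sd = 0.4,
                        bandwidth_oct = 1, mod_depth = 0.3,
                        categories = NULL) {
  stopifnot(center_sd >= 0, bandwidth_oct > 0,
            mod_depth >= 0, mod_depth <= 1)
  structure(list(center_oct = center_oct, center_sd = center_sd,
                 bandwidth_oct = bandwidth_oct, mod_depth = mod_depth,
                 categories = categories),
            class = "sound_class")
}

SOUND_SR <- 44100L
SOUND_N <- 22050L     # 500 ms
RAMP_N <- 2205L       # 50 ms linear rise/fall

#' Generate a pool of candidate sound stimuli
#'
#' Draws `n_sounds` 500-ms waveforms at 44.1 kHz from a [sound_class()]
#' distribution: band-filtered noise with per-sound spectral centre, random
#' smooth envelope modulation, 50-ms linear rise/fall ramps, peak-normalised
#' to 0.9.
#'
#' @param n_sounds Number of sounds (>= 2).
#' @param class_params A [sound_class()].
#' @param seed Integer seed; the pool is a pure function of
#'   `(class_params, seed)`.
#' @return A tibble of class `sound_pool` with columns `id`, `category` and
#'   list-column `wave` (numeric vectors of 22050 samples); the sample rate
#'   is attached as attribute `sample_rate`.
#' @export
make_sound_pool <- function(n_sounds, class_params = sound_class(), seed = 1) {
  stopifnot(inherits(class_params, "sound_class"))
  if (n_sounds < 2) stop("a pool needs at least 2 sounds", call. = FALSE)
  set.seed(seed)
  # mirrored bin frequencies of the length-22050 DFT
  f <- c(0, seq_len(SOUND_N - 1)) * SOUND_SR / SOUND_N
  f[f > SOUND_SR / 2] <- SOUND_SR - f[f > SOUND_SR / 2]
  lf <- log2(pmax(f, 1))
  tt <- seq(0, 0.5, length.out = SOUND_N)
  ramp <- c(seq(0, 1, length.out = RAMP_N),
            rep(1, SOUND_N - 2L * RAMP_N),
            seq(1, 0, length.out = RAMP_N))
  waves <- lapply(seq_len(n_sounds), function(i) {
    c0 <- rnorm(1, class_params$center_oct, class_params$center_sd)
    w <- exp(-0.5 * ((lf - c0) / (class_params$bandwidth_oct / 2))^2)
    x <- Re(fft(fft(rnorm(SOUND_N)) * w, inverse = TRUE)) / SOUND_N
    ph <- runif(2, 0, 2 * pi)
    fr <- runif(2, 1, 6)
    env <- 1 + class_params$mod_depth *
      (sin(2 * pi * fr[1] * tt + ph[1]) +
         0.5 * sin(2 * pi * fr[2] * tt + ph[2])) / 1.5
    x <- x * pmax(env, 0) * ramp
    x / max(abs(x)) * 0.9
  })
  cats <- if (is.null(class_params$categories)) NA_character_ else
    rep_len(class_params$categories, n_sounds)
  out <- tibble::tibble(
    id = sprintf("snd%04d", seq_len(n_sounds)),
    category = cats,
    wave = waves
  )
  attr(out, "sample_rate") <- SOUND_SR
  class(out) <- c("sound_pool", class(out))
  out
}

#' Envelope and amplitude spectrum of a sound
#'
#' Decomposes a 500-ms, 44.1-kHz waveform into its temporal envelope (the
#' rectified amplitude averaged into `n_env` equal time bins, default 500,
#' i.e. 1-ms resolution) and its one-sided amplitude spectrum (magnitude of
#' the discrete Fourier transform, 11025 bins excluding the zero-frequency
#' term, 2-Hz spacing).
#'
#' @param wave Numeric waveform of 22050 samples with peak amplitude <= 1.
#' @param n_env Number of envelope time points.
#' @return An object of class `acoustic_profile` with `envelope` and
#'   `spectrum` vectors and the bin frequencies.
#' @export
acoustic_profile <- function(wave, n_env = 500) {
  wave <- as.numeric(wave)
  if (length(wave) != SOUND_N) {
    stop("waveform must have ", SOUND_N, " samples (500 ms at 44.1 kHz)",
         call. = FALSE)
  }
  if (max(abs(wave)) > 1 + 1e-9) {
    stop("waveform peak amplitude exceeds 1", call. = FALSE)
  }
  bin <- floor((seq_len(SOUND_N) - 1) * n_env / SOUND_N) + 1
  env <- as.numeric(tapply(abs(wave), bin, mean))
  sp <- Mod(fft(wave))[2:(SOUND_N / 2 + 1)]
  structure(
    list(envelope = env,
         spectrum = sp,
         freq_hz = seq_len(SOUND_N / 2) * SOUND_SR / SOUND_N,
         env_time_s = (seq_len(n_env) - 0.5) * 0.5 / n_env),
    class = "acoustic_profile"
  )
}

# envelope + spectrum matrices for a pool (rows = sounds)
pool_profiles <- function(pool, n_env = 500) {
  profs <- lapply(pool$wave, acoustic_profile, n_env = n_env)
  list(envelope = do.call(rbind, lapply(profs, `[[`, "envelope")),
       spectrum = do.call(rbind, lapply(profs, `[[`, "spectrum")))
}

#' Write / read a 16-bit PCM WAV file
#'
#' Minimal mono RIFF/PCM codec used to exchange synthetic stimuli with
#' external tools.
#'
#' @param wave Numeric waveform in \[-1, 1\].
#' @param path Output path.
#' @param sample_rate Samples per second.
#' @return `wav_write` returns `path` invisibly; `wav_read` returns a list
#'   with `wave` and `sample_rate`.
#' @export
wav_write <- function(wave, path, sample_rate = SOUND_SR) {
  pcm <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname wav_write
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) {
    stop("not a WAV file", call. = FALSE)
  }
  sample_rate <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little")
      wave <- pcm / 32767
      break
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
  if (is.null(wave)) stop("no data chunk found", call. = FALSE)
  list(wave = wave, sample_rate = sample_rate)
}
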