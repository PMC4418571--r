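#' Half-octave tone ladder
#'
#' The 14 pure-tone frequencies of the travelling-wave progression: half-octave
#' steps from 88 to 8000 Hz.
#'
#' @return Numeric vector of 14 frequencies in Hz.
#' @export
tone_frequencies <- function() {
  round(8000 * 2^(seq(-6.5, 0, by = 0.5)))
}

#' Travelling-wave frequency progression
#'
#' Describes one stimulation cycle of the phase-encoded tonotopy paradigm:
#' an ordered ladder of pure tones presented in consecutive steps, followed by
#' a silent pause, the whole cycle repeated a fixed number of times per run.
#' Defaults give the classic 14 x 2 s progression + 4 s pause = 32 s cycle,
#' repeated 15 times (8 min).
#'
#' @param freqs Tone frequencies in Hz, given in ascending order.
#' @param step_s Duration of each tone step, seconds.
#' @param pause_s Silent pause after the progression, seconds.
#' @param n_cycles Number of cycles per run.
#' @param direction `"ascending"` (low to high) or `"descending"`.
#' @return An object of class `frequency_progression`.
#' @export
frequency_progression <- function(freqs = tone_frequencies(), step_s = 2,
                                  pause_s = 4, n_cycles = 15,
                                  direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  freqs <- as.numeric(freqs)
  if (length(freqs) < 2 || any(diff(freqs) <= 0)) {
    stop("`freqs` must be at least two strictly increasing frequencies",
         call. = FALSE)
  }
  stopifnot(step_s > 0, pause_s >= 0, n_cycles >= 1)
  structure(
    list(freqs = freqs, step_s = step_s, pause_s = pause_s,
         n_cycles = n_cycles, direction = direction,
         cycle_s = length(freqs) * step_s + pause_s),
    class = "frequency_progression"
  )
}

# frequencies in the order presented within a cycle
presented_order <- function(prog) {
  if (prog$direction == "ascending") prog$freqs else rev(prog$freqs)
}

#' @export
print.frequency_progression <- function(x, ...) {
  cat("<frequency_progression>", length(x$freqs), x$direction, "steps of",
      x$step_s, "s +", x$pause_s, "s pause =", x$cycle_s, "s cycle x",
      x$n_cycles, "cycles\n")
  invisible(x)
}

#' Block design for the repetition-suppression experiment
#'
#' Builds a run of alternating (or pseudo-randomised) REP and CTRL blocks.
#' Each block comprises a stimulation period with eight sound onsets at 2-s
#' spacing followed by a silent pause; the default 16 s + 14 s gives 30-s
#' blocks, and with 8 blocks per condition an 8-min run of 240 frames at
#' TR 2 s.
#'
#' @param n_blocks_per_condition Number of blocks per condition (>= 1).
#' @param tr Repetition time in seconds; must divide the block duration.
#' @param seed Integer seed used when `order = "random"`.
#' @param stim_s Stimulation period per block, seconds.
#' @param silence_s Silent pause per block, seconds.
#' @param stim_dur_s Duration of each sound, seconds.
#' @param isi_s Inter-stimulus interval, seconds.
#' @param order `"alternating"` (REP first) or `"random"` (seeded shuffle with
#'   equal condition counts).
#' @return An object of class `block_design` with a `blocks` tibble
#'   (block, condition, onset_s, stimulation and silence durations and the
#'   stimulus onsets within the block), the TR, run duration and frame count.
#' @export
make_block_design <- function(n_blocks_per_condition = 8, tr = 2, seed = 1,
                              stim_s = 16, silence_s = 14,
                              stim_dur_s = 0.5, isi_s = 1.5,
                              order = c("alternating", "random")) {
  order <- match.arg(order)
  stopifnot(n_blocks_per_condition >= 1, tr > 0)
  block_s <- stim_s + silence_s
  if (abs(block_s / tr - round(block_s / tr)) > 1e-9) {
    stop("`tr` must divide the block duration (", block_s, " s)",
         call. = FALSE)
  }
  n_blocks <- 2L * n_blocks_per_condition
  conds <- rep(c("REP", "CTRL"), n_blocks_per_condition)
  if (order == "random") {
    set.seed(seed)
    conds <- sample(conds)
  }
  soa <- stim_dur_s + isi_s
  onsets_in_block <- seq(0, by = soa, length.out = floor(stim_s / soa))
  block_onsets <- (seq_len(n_blocks) - 1) * block_s
  blocks <- tibble::tibble(
    block = seq_len(n_blocks),
    condition = conds,
    onset_s = block_onsets,
    stim_s = stim_s,
    silence_s = silence_s,
    stim_onsets = purrr::map(block_onsets, function(o) o + onsets_in_block)
  )
  structure(
    list(blocks = blocks, tr = tr, block_s = block_s,
         run_s = n_blocks * block_s,
         n_frames = as.integer(round(n_blocks * block_s / tr))),
    class = "block_design"
  )
}

#' @export
print.block_design <- function(x, ...) {
  cat("<block_design>", nrow(x$blocks), "blocks of", x$block_s, "s (",
      sum(x$blocks$condition == "REP"), "REP /",
      sum(x$blocks$condition == "CTRL"), "CTRL ), run", x$run_s, "s,",
      x$n_frames, "frames at TR", x$tr, "s\n")
  invisible(x)
}

#' Per-region repetition suppression profile
#'
#' Describes how REP blocks differ from CTRL blocks in the generator: during a
#' REP block the neural drive starts at the full CTRL level and drops to a
#' region-specific multiplicative factor after an initial unsuppressed lead.
#' A factor of 1 means no suppression; smaller factors give a lower sustained
#' response, and a positive lead makes the REP response saturate earlier than
#' CTRL (the first, unadapted stimulus drives a full-amplitude onset).
#'
#' The default suppresses the primary areas and the medial surround
#' (factor 0.8 in A1, R, M1--M4) and leaves the lateral surround unaffected.
#'
#' @param factors Named numeric vector of multiplicative sustained-response
#'   factors in (0, 1], one per ROI label. Regions absent from the vector
#'   default to 1.
#' @param lead_s Unsuppressed lead at block onset, seconds (>= 0). This is the
#'   saturation-onset advance of the REP response.
#' @return An object of class `suppression_profile`.
#' @export
suppression_profile <- function(factors = c(A1 = 0.8, R = 0.8, M1 = 0.8,
                                            M2 = 0.8, M3 = 0.8, M4 = 0.8,
                                            L1 = 1, L2 = 1, L3 = 1, L4 = 1),
                                lead_s = 2) {
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("`factors` must be a named vector of ROI factors", call. = FALSE)
  }
  if (any(factors <= 0 | factors > 1)) {
    stop("suppression factors must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(lead_s >= 0)
  structure(list(factors = factors, lead_s = lead_s),
            class = "suppression_profile")
}
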