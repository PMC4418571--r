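# shared fixtures: everything is generated in code at test time

# small sheet that still hosts two gradients plus a surround ring
small_sheet <- function() {
  sheet_spec(dim = c(16, 22, 1), core_dim = c(8, 10), surround = 3,
             margin = 1)
}

# simulate one subject's ROI time courses through the full generator +
# extraction path on a small sheet; returns the tidy tibble
simulate_subject_tcs <- function(gt, design, hrf, seed, amplitude = 1,
                                 profile = suppression_profile(),
                                 n_runs = 1, ...) {
  runs <- lapply(seq_len(n_runs), function(r) {
    simulate_repetition_run(gt, design, hrf, profile,
                            seed = seed + r, amplitude = amplitude, ...)
  })
  extract_block_timecourses(runs, gt, design, subject = paste0("S", seed))
}

# subject-level null time courses (no signal), for type-I checks that do not
# need the volume generator
null_cohort_tcs <- function(n_sub = 9, n_frames = 15, sd = 0.1) {
  tidyr::expand_grid(subject = paste0("S", seq_len(n_sub)),
                     condition = c("REP", "CTRL"),
                     frame = seq_len(n_frames)) |>
    dplyr::mutate(time_s = (frame - 1) * 2,
                  psc = rnorm(dplyr::n(), 0, sd))
}

# brute-force repeated-measures 2x2 ANOVA oracle via stats::aov Error strata
aov_2x2_oracle <- function(df) {
  a <- stats::aov(psc ~ hemisphere * condition +
                    Error(subject / (hemisphere * condition)), data = df)
  s <- summary(a)
  get_f <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    c(f = tab$`F value`[row], p = tab$`Pr(>F)`[row])
  }
  list(hemisphere = get_f("Error: subject:hemisphere", 1),
       condition = get_f("Error: subject:condition", 1),
       interaction = get_f("Error: subject:hemisphere:condition", 1))
}

# ladder step index of a frequency
freq_step <- function(f, freqs) {
  vapply(as.numeric(f), function(v) {
    if (is.na(v)) return(NA_integer_)
    which.min(abs(log2(freqs) - log2(v)))
  }, integer(1))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
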