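#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic pipeline with explicit
#' seeds (no implicit entropy). All thresholds are validated.
#'
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param n_subjects Number of simulated subjects.
#' @param n_runs Repetition runs per subject.
#' @param tr Repetition time, seconds.
#' @param sheet A [sheet_spec()].
#' @param hrf Base [hrf_model()].
#' @param profile [suppression_profile()] for REP blocks.
#' @param noise_sd,global_sd Voxel-wise and global noise SDs of the
#'   repetition runs.
#' @param tono_noise_sd,tono_global_sd Noise SDs of the tonotopy runs.
#' @param r_min Correlation threshold of the tonotopic mask.
#' @param alpha Significance level of the per-frame statistics.
#' @param n_sounds Pool size for stimulus matching (0 skips that stage).
#' @param match_n_rep REP-set size drawn by the matching stage.
#' @param match_threshold,match_max_iter Acceptance rule of the matching.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 9, n_runs = 2, tr = 2,
                            sheet = sheet_spec(), hrf = hrf_model(),
                            profile = suppression_profile(),
                            noise_sd = 1, global_sd = 0.3,
                            tono_noise_sd = 1, tono_global_sd = 0.3,
                            r_min = 0.13, alpha = 0.05,
                            n_sounds = 300, match_n_rep = 64,
                            match_threshold = 0.01,
                            match_max_iter = 1000) {
  stopifnot(r_min >= -1, r_min <= 1, alpha > 0, alpha < 1,
            match_threshold > 0, match_threshold < 1,
            match_max_iter >= 1, n_subjects >= 3, n_runs >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a tonotopic sheet and its travelling-wave runs, maps best
#' frequency from both directions, thresholds and parcellates the patch into
#' ten regions, simulates the repetition-suppression experiment for the
#' cohort, extracts block time courses, segments them into rise / plateau /
#' decay, tests the per-frame REP vs CTRL contrast, and (optionally) runs
#' the stimulus-matching stage on a synthetic pool. Results and a manifest
#' (parameters, seeds, thresholds) can be written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for TSV/JSON/NIfTI artefacts.
#' @param verbose Print per-stage progress.
#' @return A list with the ground truth, tonotopic map, ROI set, time
#'   courses, segment labels, contrast result, matched sets (or `NULL`) and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[tonorep] ", ...)
  seeds <- config$seed + c(sheet = 11, tono = 23, rep = 47, match = 83)

  stage <- "synthesis"
  out <- tryCatch({
    say("stage 1/5: ground-truth sheet (seed ", seeds["sheet"], ")")
    gt <- make_tonotopic_sheet(config$sheet, seed = seeds["sheet"])

    stage <- "tonotopy"
    say("stage 2/5: tonotopy runs and best-frequency map")
    asc <- frequency_progression(direction = "ascending")
    desc <- frequency_progression(direction = "descending")
    run_a <- simulate_tonotopy_run(gt, asc, config$hrf,
                                   noise_sd = config$tono_noise_sd,
                                   global_sd = config$tono_global_sd,
                                   seed = seeds["tono"], tr = config$tr)
    run_d <- simulate_tonotopy_run(gt, desc, config$hrf,
                                   noise_sd = config$tono_noise_sd,
                                   global_sd = config$tono_global_sd,
                                   seed = seeds["tono"] + 1, tr = config$tr)
    map <- combine_directions(best_frequency_map(run_a, asc, config$hrf),
                              best_frequency_map(run_d, desc, config$hrf))
    map <- threshold_map(map, config$r_min)

    stage <- "parcellation"
    say("stage 3/5: gradient-reversal parcellation")
    core <- delineate_core(map, axis = config$sheet$axis)
    rois <- subdivide_surround(map, core)

    stage <- "repetition"
    say("stage 4/5: repetition experiment, ", config$n_subjects,
        " subjects x ", config$n_runs, " runs")
    design <- make_block_design(tr = config$tr)
    cohort <- sample_subject_hrfs(config$n_subjects, config$hrf,
                                  seed = seeds["rep"])
    tcs <- purrr::map_dfr(seq_len(config$n_subjects), function(s) {
      runs <- lapply(seq_len(config$n_runs), function(r) {
        simulate_repetition_run(gt, design, cohort$hrf[[s]], config$profile,
                                noise_sd = config$noise_sd,
                                global_sd = config$global_sd,
                                seed = seeds["rep"] + s * 100 + r,
                                amplitude = cohort$amplitude[s])
      })
      extract_block_timecourses(runs, rois, design,
                                subject = cohort$subject[s],
                                hemisphere = gt$spec$hemisphere)
    })
    segments <- segment_phases(tcs, alpha = config$alpha)
    contrast <- contrast_conditions(tcs, segments, alpha = config$alpha)

    stage <- "matching"
    matched <- NULL
    if (config$n_sounds > 0) {
      say("stage 5/5: stimulus-set matching on ", config$n_sounds, " sounds")
      pool <- make_sound_pool(config$n_sounds, seed = seeds["match"])
      matched <- select_matched_sets(pool, n_rep = config$match_n_rep,
                                     max_iter = config$match_max_iter,
                                     threshold = config$match_threshold,
                                     alpha = config$alpha,
                                     seed = seeds["match"])
    } else say("stage 5/5: stimulus matching skipped (n_sounds = 0)")

    manifest <- list(
      package_version = as.character(utils::packageVersion("tonorep")),
      seed = config$seed, stage_seeds = as.list(seeds),
      thresholds = list(r_min = config$r_min, alpha = config$alpha,
                        match_threshold = config$match_threshold,
                        match_max_iter = config$match_max_iter),
      n_subjects = config$n_subjects, n_runs = config$n_runs,
      tr = config$tr)

    list(ground_truth = gt, map = map, rois = rois, timecourses = tcs,
         segments = segments, contrast = contrast, matched = matched,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$rois$summary,
                       file.path(out_dir, "roi_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(format(out$timecourses, digits = 8),
                       file.path(out_dir, "timecourses.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(format(tidy(out$segments), digits = 8),
                       file.path(out_dir, "segments.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(format(tidy(out$contrast), digits = 8),
                       file.path(out_dir, "contrast.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_label_volume(roiset_to_label_volume(out$rois),
                       file.path(out_dir, "roi_labels.nii.gz"))
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
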