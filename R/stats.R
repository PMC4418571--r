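#' Slope-based segmentation of block time courses into rise, plateau, decay
#'
#' Subtracts consecutive time frames pairwise to obtain per-subject relative
#' slopes, tests each of the 14 frame-to-frame transitions against zero with
#' a paired (one-sample) t-test across subjects, and labels each transition:
#' a significantly positive mean slope marks a rise, a significantly negative
#' one a decay, and a non-significant one a plateau. A phase is only reported
#' when at least two consecutive transitions agree; isolated singleton labels
#' are absorbed into the surrounding phase (ties broken toward plateau). When
#' the input contains several conditions, ROIs or hemispheres, the slopes are
#' computed on each subject's mean time course across them.
#'
#' @param data A [extract_block_timecourses()] tibble across subjects (must
#'   contain `subject`, `frame`, `psc`; >= 3 subjects).
#' @param alpha Significance level of the slope test (two-sided, uncorrected).
#' @return An object of class `segment_labels`: a `transitions` tibble
#'   (transition index, interval, mean slope, t, p, label) and a `phases`
#'   tibble with the rise/plateau/decay windows in seconds.
#' @export
segment_phases <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data), all(c("subject", "frame", "psc") %in%
                                       names(data)))
  tr_s <- infer_tr(data)
  subj_tc <- data |>
    dplyr::group_by(.data$subject, .data$frame) |>
    dplyr::summarise(psc = mean(.data$psc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "frame", values_from = "psc")
  M <- as.matrix(subj_tc[, -1])
  n_sub <- nrow(M)
  if (n_sub < 3) {
    stop("segmentation needs at least 3 subjects", call. = FALSE)
  }
  slopes <- t(apply(M, 1, diff))                  # subjects x transitions
  n_tr <- ncol(slopes)
  tests <- apply(slopes, 2, function(s) {
    tt <- t.test(s)
    c(mean = mean(s), statistic = unname(tt$statistic), p = tt$p.value)
  })
  lab <- ifelse(tests["p", ] < alpha,
                ifelse(tests["mean", ] > 0, "rise", "decay"), "plateau")
  lab <- absorb_singletons(lab)
  transitions <- tibble::tibble(
    transition = seq_len(n_tr),
    t_start = (seq_len(n_tr) - 1) * tr_s,
    t_end = seq_len(n_tr) * tr_s,
    mean_slope = tests["mean", ],
    statistic = tests["statistic", ],
    p_value = tests["p", ],
    label = lab
  )
  structure(
    list(transitions = transitions,
         phases = phase_windows(lab, tr_s),
         alpha = alpha, n_subjects = n_sub),
    class = "segment_labels"
  )
}

# absorb length-1 label runs: an interior singleton flanked by two runs of
# the same label merges into them; any other singleton that is not already
# plateau falls back to plateau (it cannot form a reportable phase). Edge
# plateau singletons are left alone so no rise/decay is fabricated.
absorb_singletons <- function(lab) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) break
    changed <- FALSE
    for (i in which(r$lengths == 1)) {
      interior <- i > 1 && i < length(r$values)
      repl <- if (interior && identical(r$values[i - 1], r$values[i + 1])) {
        r$values[i - 1]
      } else "plateau"
      if (!identical(repl, r$values[i])) {
        r$values[i] <- repl
        changed <- TRUE
        break
      }
    }
    if (!changed) break
    lab <- inverse.rle(r)
  }
  lab
}

# first rise run, the plateau after it, the first decay after that
phase_windows <- function(lab, tr_s) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  win <- function(i) c((starts[i] - 1) * tr_s, ends[i] * tr_s)
  ri <- which(r$values == "rise" & r$lengths >= 2)[1]
  pl <- which(r$values == "plateau" & r$lengths >= 2 &
                (if (is.na(ri)) TRUE else starts > ends[ri]))[1]
  de <- which(r$values == "decay" & r$lengths >= 2 &
                (if (is.na(pl)) TRUE else starts > ends[pl]))[1]
  out <- list()
  if (!is.na(ri)) out$rise <- win(ri)
  if (!is.na(pl)) out$plateau <- win(pl)
  if (!is.na(de)) out$decay <- win(de)
  tibble::tibble(
    phase = names(out),
    start_s = unname(vapply(out, `[`, numeric(1), 1)),
    end_s = unname(vapply(out, `[`, numeric(1), 2))
  )
}

infer_tr <- function(data) {
  if ("time_s" %in% names(data)) {
    tt <- sort(unique(data$time_s))
    if (length(tt) > 1) return(tt[2] - tt[1])
  }
  2
}

#' Per-frame paired contrast between REP and CTRL time courses
#'
#' Runs a two-sided paired t-test (REP vs CTRL, paired by subject) at every
#' time frame, flags frames significant at `alpha`, collects qualifying
#' windows of at least two consecutive significant frames with CTRL > REP,
#' and judges the repetition effect: positive when such a window falls inside
#' the plateau phase. Grouped by `roi` and `hemisphere` when those columns
#' are present.
#'
#' @param data A [extract_block_timecourses()] tibble with both conditions
#'   and a `subject` column; subjects must contribute both conditions.
#' @param segments A [segment_phases()] result providing the plateau window;
#'   when `NULL`, any qualifying window yields a positive verdict.
#' @param alpha Significance level (two-sided, uncorrected).
#' @return An object of class `contrast_result`: `by_frame` tibble (per
#'   group and frame: mean difference CTRL - REP, t, p, significance),
#'   `windows` tibble, and `verdicts` tibble with the per-group repetition
#'   effect.
#' @export
contrast_conditions <- function(data, segments = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("subject", "condition", "frame", "psc") %in% names(data)))
  if (!all(sort(unique(data$condition)) == c("CTRL", "REP"))) {
    stop("`data` must contain exactly the conditions REP and CTRL",
         call. = FALSE)
  }
  tr_s <- infer_tr(data)
  grp <- intersect(c("hemisphere", "roi"), names(data))
  plateau <- if (!is.null(segments)) {
    ph <- segments$phases
    if ("plateau" %in% ph$phase) {
      unlist(ph[ph$phase == "plateau", c("start_s", "end_s")])
    } else NULL
  } else NULL

  wide <- data |>
    dplyr::select(dplyr::all_of(c(grp, "subject", "condition", "frame",
                                  "psc"))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "psc")
  if (anyNA(wide$REP) || anyNA(wide$CTRL)) {
    stop("subjects are not paired across conditions", call. = FALSE)
  }
  by_frame <- wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "frame")))) |>
    dplyr::summarise(
      estimate = mean(.data$CTRL - .data$REP),
      statistic = tryCatch(t.test(.data$CTRL, .data$REP,
                                  paired = TRUE)$statistic,
                           error = function(e) NA_real_),
      p_value = tryCatch(t.test(.data$CTRL, .data$REP, paired = TRUE)$p.value,
                         error = function(e) 1),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p_value = ifelse(is.na(.data$p_value), 1, .data$p_value),
                  time_s = (.data$frame - 1) * tr_s, .after = "frame",
                  significant = .data$p_value < alpha)

  windows <- by_frame |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      sig <- df$significant & df$estimate > 0
      r <- rle(sig)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      keep <- which(r$values & r$lengths >= 2)
      tibble::tibble(
        start_frame = df$frame[starts[keep]],
        end_frame = df$frame[ends[keep]],
        start_s = df$time_s[starts[keep]],
        end_s = df$time_s[ends[keep]]
      )
    }) |>
    dplyr::ungroup()

  # verdict: at least two consecutive significant CTRL > REP frames among
  # the frames lying inside the plateau window (a run extending beyond the
  # plateau still counts through its in-plateau portion)
  groups <- dplyr::distinct(by_frame, dplyr::across(dplyr::all_of(grp)))
  if (ncol(groups) == 0) groups <- tibble::tibble(.rows = 1)
  groups$repetition_effect <- vapply(seq_len(nrow(groups)), function(i) {
    df <- by_frame
    for (g in grp) df <- df[df[[g]] == groups[[g]][i], ]
    df <- df[order(df$frame), ]
    sig <- df$significant & df$estimate > 0
    if (!is.null(plateau)) {
      sig <- sig & df$time_s >= plateau[1] & df$time_s <= plateau[2]
    }
    r <- rle(sig)
    any(r$values & r$lengths >= 2)
  }, logical(1))
  verdicts <- groups

  structure(list(by_frame = by_frame, windows = windows, verdicts = verdicts,
                 alpha = alpha, plateau = plateau),
            class = "contrast_result")
}

#' Frame-by-frame 2 x 2 repeated-measures ANOVA (hemisphere x condition)
#'
#' At every time frame, fits a two-way repeated-measures ANOVA with
#' within-subject factors hemisphere (LH/RH) and condition (REP/CTRL) and
#' subject as the random factor, reporting F and p for the two main effects
#' and their interaction. Every subject must contribute all four cells.
#'
#' @param data A tibble with columns `subject`, `hemisphere`, `condition`,
#'   `frame`, `psc` (one value per cell, e.g. one ROI's time courses).
#' @param alpha Significance level used for the `significant` flag.
#' @return An object of class `anova_result` with a `by_frame` tibble
#'   (frame, effect, df1, df2, statistic, p_value).
#' @export
anova_2x2_timepoint <- function(data, alpha = 0.05) {
  need <- c("subject", "hemisphere", "condition", "frame", "psc")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  cells <- data |>
    dplyr::count(.data$subject, .data$hemisphere, .data$condition,
                 .data$frame)
  n_sub <- length(unique(data$subject))
  n_frames <- length(unique(data$frame))
  if (nrow(cells) != n_sub * 4 * n_frames || any(cells$n != 1)) {
    stop("every subject must contribute exactly one value per ",
         "hemisphere x condition cell and frame", call. = FALSE)
  }
  tr_s <- infer_tr(data)
  res <- lapply(sort(unique(data$frame)), function(fr) {
    df <- data[data$frame == fr, ]
    f <- rm_anova_2x2(df$psc, df$subject, df$hemisphere, df$condition)
    dplyr::mutate(f, frame = fr, .before = 1)
  })
  by_frame <- dplyr::bind_rows(res) |>
    dplyr::mutate(time_s = (.data$frame - 1) * tr_s, .after = "frame",
                  significant = .data$p_value < alpha)
  structure(list(by_frame = by_frame, alpha = alpha), class = "anova_result")
}

# closed-form sums-of-squares decomposition for the fully within-subject
# 2 x 2 design; F for each effect uses its own effect-by-subject error term.
# Zero-variance effects (all cells identical) are reported as F = 0.
rm_anova_2x2 <- function(y, subject, a, b) {
  subject <- as.factor(subject); a <- as.factor(a); b <- as.factor(b)
  n <- nlevels(subject)
  gm <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_sa <- tapply(y, list(subject, a), mean)
  m_sb <- tapply(y, list(subject, b), mean)
  m_s <- tapply(y, subject, mean)

  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_sa <- 2 * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + gm)^2)
  ss_sb <- 2 * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + gm)^2)
  # interaction-by-subject error SS by subtraction from the total
  ss_tot <- sum((y - gm)^2)
  ss_s <- 4 * sum((m_s - gm)^2)
  ss_sab <- max(ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb, 0)

  fstat <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_eff <= 1e-24) return(c(0, 1))
    if (ss_err <= 1e-24) return(c(Inf, 0))
    f <- (ss_eff / df_eff) / (ss_err / df_err)
    c(f, pf(f, df_eff, df_err, lower.tail = FALSE))
  }
  fa <- fstat(ss_a, 1, ss_sa, n - 1)
  fb <- fstat(ss_b, 1, ss_sb, n - 1)
  fab <- fstat(ss_ab, 1, ss_sab, n - 1)
  tibble::tibble(
    effect = c("hemisphere", "condition", "interaction"),
    df1 = 1, df2 = n - 1,
    statistic = c(fa[1], fb[1], fab[1]),
    p_value = c(fa[2], fb[2], fab[2])
  )
}

#' Extrema statistics of REP and CTRL time courses
#'
#' For every subject and condition, computes the maximum, minimum and
#' amplitude (max - min) of the block time course, then compares REP vs CTRL
#' with paired t-tests across subjects for each statistic. Grouped by `roi`
#' and `hemisphere` when present.
#'
#' @param data A [extract_block_timecourses()] tibble with both conditions
#'   and a `subject` column.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `extrema_stats` with `per_subject` and `tests`
#'   tibbles.
#' @export
extrema_stats <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("subject", "condition", "frame", "psc") %in% names(data)))
  grp <- intersect(c("hemisphere", "roi"), names(data))
  per_subject <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "subject",
                                                  "condition")))) |>
    dplyr::summarise(maximum = max(.data$psc), minimum = min(.data$psc),
                     .groups = "drop") |>
    dplyr::mutate(amplitude = .data$maximum - .data$minimum)
  long <- per_subject |>
    tidyr::pivot_longer(c("maximum", "minimum", "amplitude"),
                        names_to = "measure") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (anyNA(long$REP) || anyNA(long$CTRL)) {
    stop("subjects are not paired across conditions", call. = FALSE)
  }
  tests <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "measure")))) |>
    dplyr::summarise(
      estimate = mean(.data$REP - .data$CTRL),
      statistic = tryCatch(t.test(.data$REP, .data$CTRL,
                                  paired = TRUE)$statistic,
                           error = function(e) NA_real_),
      p_value = tryCatch(t.test(.data$REP, .data$CTRL, paired = TRUE)$p.value,
                         error = function(e) 1),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(significant = .data$p_value < alpha)
  structure(list(per_subject = per_subject, tests = tests, alpha = alpha),
            class = "extrema_stats")
}

#' REP/CTRL plateau amplitude ratio
#'
#' Ratio of the group-mean REP to the group-mean CTRL signal over the
#' sustained window (default 8--18 s: the plateau excluding its first frame,
#' which still carries the unsuppressed onset transient of REP blocks). The
#' ratio of group means is used rather than the mean of per-subject ratios,
#' whose noisy denominators bias it upward. In the generator's terms this
#' estimates the suppression factor of the ROI.
#'
#' @param data A [extract_block_timecourses()] tibble with both conditions.
#' @param window Time window in seconds (inclusive).
#' @param roi Optional ROI name to restrict to.
#' @return The scalar ratio.
#' @export
plateau_ratio <- function(data, window = c(8, 18), roi = NULL) {
  stopifnot(is.data.frame(data),
            all(c("condition", "time_s", "psc") %in% names(data)))
  if (!is.null(roi)) data <- data[data$roi == roi, ]
  d <- data[data$time_s >= window[1] & data$time_s <= window[2], ]
  mean(d$psc[d$condition == "REP"]) / mean(d$psc[d$condition == "CTRL"])
}

#' Sound-versus-rest GLM map
#'
#' Fits, per voxel, a single-regressor linear model: the haemodynamic model
#' convolved with the stimulation boxcar of all blocks (REP and CTRL pooled),
#' plus an intercept. Returns the t statistic of the regressor with optional
#' Bonferroni thresholding across in-mask voxels.
#'
#' @param run A [volume_series()] repetition run.
#' @param design Its [make_block_design()]; defaults to the attached design.
#' @param hrf The assumed [hrf_model()].
#' @param mask Optional logical array restricting the Bonferroni family.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return An object of class `glm_map`: arrays `t`, `p` and `beta`, the
#'   residual degrees of freedom, and the Bonferroni-thresholded
#'   `significant` array.
#' @export
glm_sound_vs_rest <- function(run, design = NULL, hrf = hrf_model(),
                              mask = NULL, alpha = 0.05) {
  stopifnot(inherits(run, "volume_series"))
  design <- design %||% run$design
  stopifnot(inherits(design, "block_design"))
  d <- dim(run$data)
  frame_t <- (seq_len(d[4]) - 1) * run$tr
  drive_fn <- function(tt) {
    on <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(design$blocks))) {
      b <- design$blocks[i, ]
      on <- on | (tt >= b$onset_s & tt < b$onset_s + b$stim_s)
    }
    as.numeric(on)
  }
  reg <- .hrf_convolve(hrf, drive_fn, frame_t)
  if (sd(reg) < 1e-12) {
    stop("degenerate design: the stimulation regressor is constant",
         call. = FALSE)
  }
  X <- cbind(1, reg)
  Y <- t(matrix(run$data, prod(d[1:3]), d[4]))     # frames x voxels
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)                    # 2 x voxels
  res <- Y - X %*% B
  df <- d[4] - 2L
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  tval <- B[2, ] / se
  pval <- 2 * pt(-abs(tval), df)
  n_fam <- if (is.null(mask)) prod(d[1:3]) else sum(mask)
  sig <- array(pval < alpha / n_fam, d[1:3])
  if (!is.null(mask)) sig <- sig & mask
  structure(
    list(t = array(tval, d[1:3]), p = array(pval, d[1:3]),
         beta = array(B[2, ], d[1:3]), df = df, regressor = reg,
         significant = sig, bonferroni_n = n_fam, alpha = alpha),
    class = "glm_map"
  )
}
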