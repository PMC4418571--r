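#' Point-wise acoustic comparison of two stimulus sets
#'
#' Compares two sets of sounds at every envelope time point and every
#' spectral bin with two-sided unpaired (pooled-variance Student) t-tests, and
#' reports the fraction of comparison points significant at `alpha`. No
#' multiple-comparison correction is applied: the test is used as a
#' *matching* criterion, where missing a real difference is the costly error.
#' Points with zero variance in both sets have an undefined t statistic and
#' are assigned p = 1.
#'
#' @param a,b Sets to compare: `sound_pool` tibbles, lists of
#'   [acoustic_profile()]s, or lists with `envelope` / `spectrum` matrices
#'   (rows = sounds). Each set needs >= 2 sounds.
#' @param alpha Significance level per point.
#' @param n_env Envelope resolution used when profiles must be computed.
#' @return An object of class `set_comparison`: a `points` tibble (domain,
#'   index, p_value), the significant `fraction`, counts, and `alpha`.
#' @export
compare_sets <- function(a, b, alpha = 0.05, n_env = 500) {
  A <- as_profile_matrices(a, n_env)
  B <- as_profile_matrices(b, n_env)
  if (nrow(A$envelope) < 2 || nrow(B$envelope) < 2) {
    stop("each set needs at least 2 sounds", call. = FALSE)
  }
  if (ncol(A$spectrum) != ncol(B$spectrum) ||
      ncol(A$envelope) != ncol(B$envelope)) {
    stop("sets have profiles of different lengths", call. = FALSE)
  }
  p_env <- pooled_t_pvals(A$envelope, B$envelope)
  p_spec <- pooled_t_pvals(A$spectrum, B$spectrum)
  points <- dplyr::bind_rows(
    tibble::tibble(domain = "envelope", index = seq_along(p_env),
                   p_value = p_env),
    tibble::tibble(domain = "spectrum", index = seq_along(p_spec),
                   p_value = p_spec)
  )
  n_sig <- sum(points$p_value < alpha)
  structure(
    list(points = points, n_sig = n_sig, n_points = nrow(points),
         fraction = n_sig / nrow(points), alpha = alpha,
         n_a = nrow(A$envelope), n_b = nrow(B$envelope)),
    class = "set_comparison"
  )
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("<set_comparison>", x$n_a, "vs", x$n_b, "sounds:", x$n_sig, "of",
      x$n_points, "points significant at", x$alpha,
      sprintf("(fraction %.4f)\n", x$fraction))
  invisible(x)
}

# column-wise two-sample pooled-variance t-test p-values
pooled_t_pvals <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- (colSums(A^2) - na * ma^2) / (na - 1)
  vb <- (colSums(B^2) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tv <- (ma - mb) / se
  p <- 2 * pt(-abs(tv), df = na + nb - 2)
  # zero variance in both sets: the t statistic is undefined; p := 1
  zero <- !is.finite(se) | se < 1e-300
  p[zero] <- 1
  p
}

as_profile_matrices <- function(x, n_env = 500) {
  if (inherits(x, "sound_pool") ||
      (is.data.frame(x) && "wave" %in% names(x))) {
    return(pool_profiles(x, n_env))
  }
  if (is.list(x) && !is.null(x$envelope) && !is.null(x$spectrum) &&
      is.matrix(x$envelope)) {
    return(x)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "acoustic_profile"))) {
    return(list(envelope = do.call(rbind, lapply(x, `[[`, "envelope")),
                spectrum = do.call(rbind, lapply(x, `[[`, "spectrum"))))
  }
  stop("cannot interpret input as a set of acoustic profiles", call. = FALSE)
}

#' Iterative acoustic matching of REP and CTRL stimulus sets
#'
#' Repeatedly draws random disjoint REP and CTRL candidate sets from the
#' pool, compares them point-by-point with [compare_sets()], and accepts the
#' first draw whose fraction of significantly different points falls below
#' `threshold` (default 1%). When the pool carries semantic category tags
#' the draw is stratified so categories are equally distributed across sets.
#' If no acceptable draw is found within `max_iter` iterations the result is
#' flagged as failed (with the best draw found) rather than silently
#' returning an unmatched set.
#'
#' @param pool A [make_sound_pool()] tibble.
#' @param n_rep,n_ctrl Sizes of the REP and CTRL sets; `n_ctrl = NULL` takes
#'   the whole remainder of the pool.
#' @param max_iter Iteration cap.
#' @param threshold Acceptance threshold on the significant fraction.
#' @param alpha Per-point significance level.
#' @param seed Integer seed.
#' @return An object of class `matched_sets`: `status` ("accepted" or
#'   "failed"), the REP and CTRL id vectors, the iteration count, the final
#'   [compare_sets()] comparison, and the acceptance parameters.
#' @export
select_matched_sets <- function(pool, n_rep = 64, n_ctrl = NULL,
                                max_iter = 1000, threshold = 0.01,
                                alpha = 0.05, seed = 1) {
  stopifnot(inherits(pool, "sound_pool") || is.data.frame(pool))
  n_pool <- nrow(pool)
  n_ctrl <- n_ctrl %||% (n_pool - n_rep)
  if (n_rep + n_ctrl > n_pool) {
    stop("pool too small: need n_rep + n_ctrl <= pool size", call. = FALSE)
  }
  if (n_rep < 2 || n_ctrl < 2) {
    stop("both sets need at least 2 sounds", call. = FALSE)
  }
  profs <- pool_profiles(pool)
  has_cats <- !all(is.na(pool$category))
  set.seed(seed)
  best <- NULL
  for (it in seq_len(max_iter)) {
    rep_idx <- draw_set(pool$category, n_rep, has_cats)
    remaining <- setdiff(seq_len(n_pool), rep_idx)
    ctrl_idx <- if (n_ctrl == length(remaining)) remaining else
      draw_set(pool$category, n_ctrl, has_cats, from = remaining)
    cmp <- compare_sets(
      list(envelope = profs$envelope[rep_idx, , drop = FALSE],
           spectrum = profs$spectrum[rep_idx, , drop = FALSE]),
      list(envelope = profs$envelope[ctrl_idx, , drop = FALSE],
           spectrum = profs$spectrum[ctrl_idx, , drop = FALSE]),
      alpha = alpha)
    if (is.null(best) || cmp$fraction < best$comparison$fraction) {
      best <- list(rep_ids = pool$id[rep_idx], ctrl_ids = pool$id[ctrl_idx],
                   comparison = cmp)
    }
    if (cmp$fraction < threshold) {
      return(structure(
        list(status = "accepted", rep_ids = pool$id[rep_idx],
             ctrl_ids = pool$id[ctrl_idx], iterations = it,
             comparison = cmp, threshold = threshold, alpha = alpha),
        class = "matched_sets"))
    }
  }
  structure(
    list(status = "failed", rep_ids = best$rep_ids,
         ctrl_ids = best$ctrl_ids, iterations = max_iter,
         comparison = best$comparison, threshold = threshold, alpha = alpha),
    class = "matched_sets"
  )
}

# stratified (by category, when present) random draw of `n` indices
draw_set <- function(categories, n, stratify, from = NULL) {
  idx <- from %||% seq_along(categories)
  if (!stratify) return(sample(idx, n))
  cats <- categories[idx]
  lv <- unique(cats)
  per <- n %/% length(lv)
  extra <- n - per * length(lv)
  take <- integer(0)
  for (k in seq_along(lv)) {
    pool_k <- idx[cats == lv[k]]
    n_k <- per + (k <= extra)
    take <- c(take, sample(pool_k, min(n_k, length(pool_k))))
  }
  short <- n - length(take)
  if (short > 0) take <- c(take, sample(setdiff(idx, take), short))
  take
}

#' @export
print.matched_sets <- function(x, ...) {
  cat("<matched_sets>", x$status, "after", x$iterations, "iteration(s):",
      length(x$rep_ids), "REP vs", length(x$ctrl_ids), "CTRL,",
      sprintf("significant fraction %.4f (threshold %g)\n",
              x$comparison$fraction, x$threshold))
  invisible(x)
}

#' Compare the mean amplitude spectra of two conditions
#'
#' Per-frequency-bin two-sample t-tests between the per-sound amplitude
#' spectra of the REP and CTRL sets, reporting the raw count of significant
#' bins, the count surviving Bonferroni correction across the 11025 bins,
#' and the raw count as a fraction of all bins.
#'
#' @param rep,ctrl Sets of sounds or profiles (as in [compare_sets()]).
#' @param alpha Significance level.
#' @return An object of class `spectrum_comparison` with a `bins` tibble
#'   (freq_hz, p_value), `n_sig`, `n_sig_bonferroni` and `fraction`.
#' @export
compare_mean_spectra <- function(rep, ctrl, alpha = 0.05) {
  A <- as_profile_matrices(rep)
  B <- as_profile_matrices(ctrl)
  if (ncol(A$spectrum) != ncol(B$spectrum)) {
    stop("spectra have different lengths", call. = FALSE)
  }
  p <- pooled_t_pvals(A$spectrum, B$spectrum)
  nb <- length(p)
  structure(
    list(bins = tibble::tibble(freq_hz = seq_len(nb) * SOUND_SR / SOUND_N,
                               p_value = p),
         n_sig = sum(p < alpha),
         n_sig_bonferroni = sum(p < alpha / nb),
         fraction = sum(p < alpha) / nb,
         alpha = alpha),
    class = "spectrum_comparison"
  )
}
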