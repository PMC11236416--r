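#' Peristimulus time histogram
#'
#' Histogram of spike times relative to stimulus onset over a window starting
#' 400 ms before onset and ending 400 ms after the end of the 1 s
#' presentation (1800 ms total), in 1 ms bins, averaged over presentations
#' and smoothed with a Gaussian filter.
#'
#' @param spike_times spike times, seconds.
#' @param onsets stimulus onset times, seconds.
#' @param pre_ms,post_ms window extent before/after onset, ms.
#' @param bin_ms bin width, ms.
#' @param smooth_sd_ms Gaussian smoothing width, ms (0 to disable).
#' @return numeric vector of length `(pre_ms + post_ms) / bin_ms` (1800 by
#'   default), spikes per bin per presentation.
#' @export
compute_psth <- function(spike_times, onsets, pre_ms = 400, post_ms = 1400,
                         bin_ms = 1, smooth_sd_ms = 10) {
  if (length(onsets) == 0L) stop("at least one stimulus onset is required")
  nbin <- (pre_ms + post_ms) / bin_ms
  counts <- numeric(nbin)
  if (length(spike_times) > 0) {
    rel <- as.vector(outer(spike_times, onsets, "-")) * 1000
    rel <- rel[rel >= -pre_ms & rel < post_ms]
    if (length(rel) > 0) {
      idx <- floor((rel + pre_ms) / bin_ms) + 1L
      tab <- tabulate(idx, nbins = nbin)
      counts <- tab
    }
  }
  psth <- counts / length(onsets)
  if (smooth_sd_ms > 0) {
    half <- ceiling(4 * smooth_sd_ms / bin_ms)
    kern <- stats::dnorm(seq(-half, half), sd = smooth_sd_ms / bin_ms)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), psth, numeric(half))
    sm <- stats::filter(padded, kern, sides = 2)
    psth <- as.numeric(sm[(half + 1):(half + nbin)])
  }
  psth
}

#' Visual fingerprint
#'
#' Mean spike count in response to each image, from stimulus onset to 1 s
#' afterwards, averaged over trials.
#'
#' @param spike_times spike times, seconds.
#' @param stim_table data.frame with `image_id`, `trial`, `onset_s`; every
#'   image must appear in every trial.
#' @param window_s response window after onset, seconds.
#' @return list with `vfp` (length = number of images, in image-id order) and
#'   `vfp_trials` (`[n_trials x n_images]` counts).
#' @export
compute_vfp <- function(spike_times, stim_table, window_s = 1) {
  images <- sort(unique(stim_table$image_id))
  trials <- sort(unique(stim_table$trial))
  tab <- table(stim_table$image_id)
  if (any(tab == 0) || length(images) * length(trials) != nrow(stim_table)) {
    stop("stimulus table must present every image once per trial")
  }
  st <- sort(spike_times)
  n_at <- function(t) findInterval(t, st)
  counts <- n_at(stim_table$onset_s + window_s) - n_at(stim_table$onset_s)
  m <- matrix(0, length(trials), length(images),
              dimnames = list(trials, images))
  m[cbind(match(stim_table$trial, trials),
          match(stim_table$image_id, images))] <- counts
  list(vfp = colMeans(m), vfp_trials = m)
}

#' Test whether a unit's image responses differ from flat
#'
#' Kruskal-Wallis rank test across images, applied to the per-trial visual
#' fingerprint counts.
#'
#' @param vfp_trials `[n_trials x n_images]` count matrix.
#' @param alpha significance level.
#' @return TRUE when the evoked response is significantly image dependent.
#' @export
response_significance <- function(vfp_trials, alpha = 0.05) {
  if (nrow(vfp_trials) < 2L || ncol(vfp_trials) < 2L) {
    stop("need at least 2 trials and 2 images")
  }
  x <- as.vector(vfp_trials)
  if (stats::sd(x) == 0) return(FALSE)
  g <- factor(rep(colnames(vfp_trials), each = nrow(vfp_trials)))
  kt <- stats::kruskal.test(x, g)
  is.finite(kt$p.value) && kt$p.value < alpha
}

#' Compute a unit's visual response
#'
#' Convenience wrapper bundling the PSTH, visual fingerprint and significance
#' test for one unit.
#'
#' @param spike_times spike times, seconds.
#' @param stim_table stimulus table (`image_id`, `trial`, `onset_s`).
#' @param ... passed to [compute_psth()].
#' @param alpha significance level for [response_significance()].
#' @return object of class `visual_response`: `psth`, `vfp`, `vfp_trials`,
#'   `significant`.
#' @export
visual_response <- function(spike_times, stim_table, alpha = 0.05, ...) {
  psth <- compute_psth(spike_times, stim_table$onset_s, ...)
  v <- compute_vfp(spike_times, stim_table)
  structure(list(psth = psth, vfp = v$vfp, vfp_trials = v$vfp_trials,
                 significant = response_significance(v$vfp_trials, alpha)),
            class = "visual_response")
}

#' Visual-response similarity between two units
#'
#' The sum of the Pearson correlation of the PSTHs and of the visual
#' fingerprints; each correlation lies in (-1, 1), so the similarity score
#' lies in (-2, 2).
#'
#' @param r1,r2 `visual_response` objects.
#' @return list `similarity`, `psth_corr`, `vfp_corr`, `valid` (FALSE when a
#'   zero-variance vector makes a correlation undefined).
#' @export
similarity_score <- function(r1, r2) {
  if (length(r1$psth) != length(r2$psth) || length(r1$vfp) != length(r2$vfp)) {
    stop("responses must have equal PSTH and fingerprint lengths")
  }
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }
  pc <- safe_cor(r1$psth, r2$psth)
  vc <- safe_cor(r1$vfp, r2$vfp)
  list(similarity = pc + vc, psth_corr = pc, vfp_corr = vc,
       valid = !is.na(pc) && !is.na(vc))
}

#' Build the visual-response reference set for a session pair
#'
#' Reference pairs validate the tracking without using it: a cross-session
#' pair qualifies when (1) both units are KSgood and have significant visual
#' responses, (2) the similarity score exceeds `min_similarity`, and (3) the
#' 3D distance both before and after drift correction is below `max_dist`.
#' When a unit has several qualifying partners only its highest-similarity
#' partner is kept, and pairs are retained only when mutual best, so the
#' reference set is a partial matching.
#'
#' @param responses1,responses2 named lists (by unit id) of
#'   `visual_response` objects.
#' @param units1,units2 `unit_table`s of the two sessions.
#' @param units2_corrected drift-corrected session-2 table (defaults to
#'   `units2`, i.e. zero drift).
#' @param min_similarity similarity threshold.
#' @param max_dist distance criterion, um.
#' @return data.frame with `unit1`, `unit2`, `similarity`, `psth_corr`,
#'   `vfp_corr`, `dist_pre`, `dist_post`.
#' @export
build_reference_set <- function(responses1, responses2, units1, units2,
                                units2_corrected = units2,
                                min_similarity = 1, max_dist = 30) {
  ok1 <- units1[units1$quality == "good" & units1$included, , drop = FALSE]
  ok2 <- units2[units2$quality == "good" & units2$included, , drop = FALSE]
  sig <- function(resps, ids) {
    ids[vapply(as.character(ids), function(i) {
      r <- resps[[i]]
      !is.null(r) && isTRUE(r$significant)
    }, TRUE)]
  }
  ids1 <- sig(responses1, ok1$unit_id)
  ids2 <- sig(responses2, ok2$unit_id)
  cand <- list()
  for (a in ids1) {
    ua <- ok1[ok1$unit_id == a, ]
    ra <- responses1[[as.character(a)]]
    for (b in ids2) {
      ub <- ok2[ok2$unit_id == b, ]
      ubc <- units2_corrected[units2_corrected$unit_id == b, ]
      d_pre <- sqrt((ua$x - ub$x)^2 + (ua$y - ub$y)^2 + (ua$z - ub$z)^2)
      d_post <- sqrt((ua$x - ubc$x)^2 + (ua$y - ubc$y)^2 + (ua$z - ubc$z)^2)
      if (d_pre >= max_dist || d_post >= max_dist) next
      s <- similarity_score(ra, responses2[[as.character(b)]])
      if (!s$valid || s$similarity <= min_similarity) next
      cand[[length(cand) + 1L]] <- data.frame(
        unit1 = a, unit2 = b, similarity = s$similarity,
        psth_corr = s$psth_corr, vfp_corr = s$vfp_corr,
        dist_pre = d_pre, dist_post = d_post)
    }
  }
  if (length(cand) == 0L) {
    warning("empty reference set: no qualifying pairs (possibly very large drift)")
    return(data.frame(unit1 = integer(0), unit2 = integer(0),
                      similarity = numeric(0), psth_corr = numeric(0),
                      vfp_corr = numeric(0), dist_pre = numeric(0),
                      dist_post = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  # mutual-best resolution: keep a pair only when it is the highest-similarity
  # partner for both of its units
  best1 <- tapply(cand$similarity, cand$unit1, max)
  best2 <- tapply(cand$similarity, cand$unit2, max)
  keep <- cand$similarity >= best1[as.character(cand$unit1)] - 1e-12 &
    cand$similarity >= best2[as.character(cand$unit2)] - 1e-12
  out <- cand[keep, , drop = FALSE]
  out <- out[!duplicated(out$unit1) & !duplicated(out$unit2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
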