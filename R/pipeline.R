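#' Match units between two sessions
#'
#' End-to-end two-stage matching of spike-sorted units across a session pair:
#' \enumerate{
#'   \item localize all units from their mean waveforms and keep included
#'     (peak amplitude > `min_ptp`) single units (\"good\"; optionally mua);
#'   \item compute the pairwise waveform distance over peak-relative
#'     22-channel patches;
#'   \item stage-1 EMD on `D = d_loc + omega * d_wf`, from whose matched
#'     z-displacements the rigid drift is estimated as a kernel-density mode;
#'   \item correct session 2 z-coordinates, rebuild the physical distances
#'     (waveform distances are peak-relative and unaffected by a rigid
#'     shift), and run the stage-2 EMD;
#'   \item flag pairs whose absolute corrected z-distance is within the
#'     threshold.
#' }
#' The threshold is either given directly (`z_threshold`, default 10 um) or
#' calibrated from the stage-2 z-distance distribution via
#' [fit_z_mixture()]/[select_threshold()] when `target_fpr` is supplied.
#'
#' @param s1,s2 [session_bundle()]s.
#' @param omega waveform-distance weight, um.
#' @param z_threshold z-distance threshold, um.
#' @param target_fpr optional target false-positive rate; when given, the
#'   threshold is selected from the fitted mixture (falling back to
#'   `z_threshold`, flagged, if the fit fails).
#' @param min_ptp amplitude inclusion filter, uV.
#' @param include_mua also match multi-unit clusters (default: good only).
#' @param estimate_drift estimate and correct rigid drift (default TRUE);
#'   when FALSE or when too few stage-1 pairs are available, the correction
#'   is 0 and flagged.
#' @param k_loc,k_wf neighborhood half-heights in rows for localization and
#'   the waveform patch.
#' @param background background handling for [localize_units()].
#' @return object of class `unit_match`: `pairs` (data.frame `unit1`,
#'   `unit2`, `d_loc`, `d_wf`, `d_combined`, `z_distance`,
#'   `passes_threshold`), `drift`, `threshold`, `threshold_fit`,
#'   `total_cost_pre`, `total_cost_post`, `session_ids`, `omega`, `n1`, `n2`,
#'   and the localized unit tables.
#' @export
match_sessions <- function(s1, s2, omega = 1500, z_threshold = 10,
                           target_fpr = NULL, min_ptp = 60,
                           include_mua = FALSE, estimate_drift = TRUE,
                           k_loc = 2, k_wf = 5, background = "estimate") {
  loc1 <- localize_units(s1, min_ptp = min_ptp, k_loc = k_loc, background = background)
  loc2 <- localize_units(s2, min_ptp = min_ptp, k_loc = k_loc, background = background)
  keep <- function(u) u[u$included & (include_mua | u$quality == "good"), , drop = FALSE]
  u1 <- keep(loc1)
  u2 <- keep(loc2)
  if (nrow(u1) == 0L || nrow(u2) == 0L) {
    stop("no included units to match in at least one session")
  }
  p1 <- extract_patches(s1, u1, k_wf = k_wf)
  p2 <- extract_patches(s2, u2, k_wf = k_wf)
  d_wf <- waveform_distance_matrix(p1, p2)

  cost1 <- build_cost_matrix(u1, u2, d_wf, omega)
  plan1 <- solve_transport(cost1)

  drift <- NULL
  if (estimate_drift) {
    drift <- tryCatch(
      estimate_rigid_drift(u1$z[plan1$pairs$i], u2$z[plan1$pairs$k]),
      error = function(e) {
        warning(sprintf("drift not estimated (%s); applying zero correction",
                        conditionMessage(e)))
        NULL
      })
  }
  z_mode <- if (is.null(drift)) 0 else drift$z_mode
  u2c <- apply_drift_correction(u2, z_mode)

  cost2 <- build_cost_matrix(u1, u2c, d_wf, omega)
  plan2 <- solve_transport(cost2)

  pr <- plan2$pairs
  z_distance <- u2c$z[pr$k] - u1$z[pr$i]
  pairs <- data.frame(unit1 = u1$unit_id[pr$i], unit2 = u2$unit_id[pr$k],
                      d_loc = cost2$d_loc[cbind(pr$i, pr$k)],
                      d_wf = cost2$d_wf[cbind(pr$i, pr$k)],
                      d_combined = cost2$D[cbind(pr$i, pr$k)],
                      z_distance = z_distance)

  threshold_fit <- NULL
  threshold <- z_threshold
  if (!is.null(target_fpr)) {
    # unbinned maximum likelihood: a session pair yields at most a few
    # hundred z-distances, too few for a stable histogram fit
    threshold_fit <- tryCatch(fit_z_mixture(abs(pairs$z_distance),
                                            method = "mle"),
                              error = function(e) NULL)
    threshold <- if (is.null(threshold_fit) || !threshold_fit$converged) {
      warning(sprintf("mixture fit unavailable; falling back to %g um", z_threshold))
      z_threshold
    } else {
      as.numeric(tryCatch(select_threshold(threshold_fit, target_fpr),
                          error = function(e) {
                            warning(conditionMessage(e))
                            z_threshold
                          }))
    }
  }
  pairs$passes_threshold <- abs(pairs$z_distance) <= threshold

  structure(list(session_ids = c(s1$session_id, s2$session_id),
                 pairs = pairs, drift = drift, threshold = threshold,
                 threshold_fit = threshold_fit,
                 total_cost_pre = plan1$total_cost,
                 total_cost_post = plan2$total_cost,
                 omega = omega, n1 = nrow(u1), n2 = nrow(u2),
                 units1 = u1, units2 = u2, units2_corrected = u2c),
            class = "unit_match")
}

#' @export
print.unit_match <- function(x, ...) {
  cat(sprintf(paste0("unit match %s -> %s: %d pairs (%d/%d units), ",
                     "%d pass |z| <= %g um\n"),
              x$session_ids[1], x$session_ids[2], nrow(x$pairs), x$n1, x$n2,
              sum(x$pairs$passes_threshold), x$threshold))
  if (!is.null(x$drift)) {
    cat(sprintf("  drift correction: %.2f um; EMD cost %.1f -> %.1f\n",
                x$drift$z_mode, x$total_cost_pre, x$total_cost_post))
  }
  invisible(x)
}

#' @export
summary.unit_match <- function(object, ...) {
  p <- object$pairs
  out <- list(session_ids = object$session_ids, n_pairs = nrow(p),
              n_pass = sum(p$passes_threshold), threshold = object$threshold,
              drift_um = if (is.null(object$drift)) 0 else object$drift$z_mode,
              total_cost_pre = object$total_cost_pre,
              total_cost_post = object$total_cost_post,
              median_abs_z = stats::median(abs(p$z_distance)),
              median_d_wf = stats::median(p$d_wf))
  class(out) <- "summary.unit_match"
  out
}

#' @export
print.summary.unit_match <- function(x, ...) {
  cat(sprintf("match %s -> %s\n", x$session_ids[1], x$session_ids[2]))
  cat(sprintf("  pairs: %d (%d pass %g um threshold)\n", x$n_pairs, x$n_pass,
              x$threshold))
  cat(sprintf("  drift: %.2f um; EMD cost pre %.1f / post %.1f\n",
              x$drift_um, x$total_cost_pre, x$total_cost_post))
  cat(sprintf("  median |z-distance|: %.2f um; median waveform distance: %.3f\n",
              x$median_abs_z, x$median_d_wf))
  invisible(x)
}

#' Re-apply a z-distance threshold to a match result
#'
#' @param match a `unit_match`.
#' @param z_thr new threshold (um); `Inf` passes everything.
#' @return the updated `unit_match`.
#' @export
filter_by_z_threshold <- function(match, z_thr) {
  match$pairs$passes_threshold <- abs(match$pairs$z_distance) <= z_thr
  match$threshold <- z_thr
  match
}

#' Recovery rate against a reference pairing
#'
#' The fraction of reference unit assignments that the EMD procedure
#' reproduces: `N(EMD intersect ref) / N(ref)`.
#'
#' @param match a `unit_match`.
#' @param reference data.frame with columns `unit1`, `unit2`.
#' @return fraction in `[0, 1]`.
#' @export
recovery_rate <- function(match, reference) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("recovery rate is undefined for an empty reference set")
  }
  key <- function(a, b) paste(a, b, sep = "->")
  mean(key(reference$unit1, reference$unit2) %in%
         key(match$pairs$unit1, match$pairs$unit2))
}

#' Accuracy of threshold-passing assignments of reference units
#'
#' Among the EMD assignments of reference units that pass the z-distance
#' threshold, the fraction that agree with the reference pairing.
#'
#' @param match a `unit_match`.
#' @param reference data.frame with columns `unit1`, `unit2`.
#' @param z_thr threshold (um); defaults to the match's own.
#' @return fraction in `[0, 1]`.
#' @export
match_accuracy <- function(match, reference, z_thr = match$threshold) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("accuracy is undefined for an empty reference set")
  }
  p <- match$pairs
  p <- p[abs(p$z_distance) <= z_thr & p$unit1 %in% reference$unit1, , drop = FALSE]
  if (nrow(p) == 0L) {
    stop("no reference-unit assignment passes the threshold; accuracy undefined")
  }
  key <- function(a, b) paste(a, b, sep = "->")
  mean(key(p$unit1, p$unit2) %in% key(reference$unit1, reference$unit2))
}

#' Trace matched units into chains across consecutive sessions
#'
#' Follows threshold-passing pairs through an ordered list of
#' consecutive-session match results and reports every unit that can be
#' traced across at least `min_length` consecutive sessions (a \"chain\").
#'
#' @param matches list of `unit_match` objects in session order; the second
#'   session of each must be the first session of the next.
#' @param min_length minimum number of consecutive sessions (default 3).
#' @return data.frame of class `unit_chains`: `chain_id`, `position`,
#'   `session_id`, `unit_id`; attribute `n_sessions` carries the total number
#'   of sessions, and `fully_trackable` per chain whether it spans all of
#'   them.
#' @export
trace_chains <- function(matches, min_length = 3) {
  stopifnot(length(matches) >= 1L)
  sessions <- c(matches[[1]]$session_ids[1],
                vapply(matches, function(m) m$session_ids[2], ""))
  for (t in seq_along(matches)) {
    if (matches[[t]]$session_ids[1] != sessions[t]) {
      stop("match results are not a consecutive-session sequence")
    }
  }
  n_sessions <- length(sessions)
  # per step: map from session-t unit to session-(t+1) unit (passing pairs)
  steps <- lapply(matches, function(m) {
    p <- m$pairs[m$pairs$passes_threshold, , drop = FALSE]
    stats::setNames(p$unit2, as.character(p$unit1))
  })

  chains <- list()
  chain_id <- 0L
  for (t in seq_len(n_sessions - 1L)) {
    prev <- if (t > 1L) steps[[t - 1L]] else stats::setNames(integer(0), character(0))
    for (u in names(steps[[t]])) {
      if (as.integer(u) %in% unname(prev)) next  # continued from earlier session
      units <- as.integer(u)
      tt <- t
      while (tt <= length(steps)) {
        nxt <- steps[[tt]][as.character(units[length(units)])]
        if (is.na(nxt)) break
        units <- c(units, unname(nxt))
        tt <- tt + 1L
      }
      if (length(units) >= min_length) {
        chain_id <- chain_id + 1L
        chains[[chain_id]] <- data.frame(
          chain_id = chain_id, position = seq_along(units),
          session_id = sessions[t:(t + length(units) - 1L)],
          unit_id = units)
      }
    }
  }
  out <- if (length(chains) > 0) do.call(rbind, chains) else
    data.frame(chain_id = integer(0), position = integer(0),
               session_id = character(0), unit_id = integer(0))
  attr(out, "n_sessions") <- n_sessions
  attr(out, "sessions") <- sessions
  class(out) <- c("unit_chains", "data.frame")
  out
}

#' Classify chains by receptive-field information
#'
#' A chain is a \"reference\" chain when receptive-field information is
#' available in every dataset it spans, \"putative\" when in none, and
#' \"mixed\" otherwise.
#'
#' @param chains a `unit_chains` table from [trace_chains()].
#' @param visual_info data.frame with `session_id`, `unit_id`,
#'   `has_reference` (logical) covering every chain member.
#' @return `chains` with a `classification` column added.
#' @export
classify_chains <- function(chains, visual_info) {
  key <- paste(visual_info$session_id, visual_info$unit_id)
  has <- visual_info$has_reference[match(paste(chains$session_id, chains$unit_id), key)]
  if (anyNA(has)) stop("visual_info does not cover every chain member")
  cls <- vapply(split(has, chains$chain_id), function(h) {
    if (all(h)) "reference" else if (!any(h)) "putative" else "mixed"
  }, "")
  chains$classification <- cls[as.character(chains$chain_id)]
  chains
}
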