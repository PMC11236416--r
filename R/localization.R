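#' Per-channel peak-to-peak amplitude
#'
#' @param waveform numeric matrix `[n_channels x n_samples]`, uV.
#' @return numeric vector of max-minus-min per channel.
#' @export
ptp_amplitude <- function(waveform) {
  apply(waveform, 1L, function(v) max(v) - min(v))
}

#' Estimate the background amplitude of a unit's waveform
#'
#' The background level is taken as the median raw peak-to-peak amplitude over
#' the channels of the unit's shank that lie outside its 22-channel waveform
#' neighborhood (rows within +/-5 of the peak row), where the mean waveform is
#' dominated by residual noise rather than spike signal.
#'
#' @param waveform numeric matrix `[n_channels x n_samples]` covering all
#'   sites of the channel map.
#' @param cm a [channel_map()].
#' @param peak_channel optional 0-based site index; defaults to the channel
#'   with the largest raw peak-to-peak amplitude.
#' @param k_exclude rows around the peak excluded from the background set.
#' @return non-negative scalar, uV.
#' @export
estimate_background <- function(waveform, cm, peak_channel = NULL, k_exclude = 5) {
  ptp <- ptp_amplitude(waveform)
  if (is.null(peak_channel)) peak_channel <- cm$site_index[which.max(ptp)]
  inside <- neighborhood_sites(cm, peak_channel, k_exclude)$site_index
  shank <- cm$shank_id[cm$site_index == peak_channel]
  outside <- setdiff(cm$site_index[cm$shank_id == shank], inside)
  if (length(outside) < 10L) {
    stop(sprintf("fewer than 10 channels available for background estimation (%d)",
                 length(outside)))
  }
  stats::median(ptp[match(outside, cm$site_index)])
}

#' Background-subtracted amplitudes on the localization channel set
#'
#' Selects the 10-channel set around the peak channel (rows `m_c - K_loc` to
#' `m_c + K_loc` across both columns: two rows above, two below, and the peak
#' row) and returns the background-subtracted peak-to-peak amplitudes, floored
#' at zero. Near the probe ends only existing rows are kept and the set is
#' flagged partial.
#'
#' @param waveform numeric matrix `[n_channels x n_samples]`.
#' @param cm a [channel_map()].
#' @param k_loc rows above/below the peak row (default 2, i.e. 10 channels).
#' @param background scalar background level to subtract, uV.
#' @return list with `peak_channel` (0-based), `amplitudes` (data.frame
#'   `site_index`, `x`, `z`, `amp`), `peak_ptp` (raw, uV), `partial_set`.
#' @export
compute_ptp_amplitudes <- function(waveform, cm, k_loc = 2, background = 0) {
  ptp <- ptp_amplitude(waveform)
  peak_row <- which.max(ptp)
  peak_channel <- cm$site_index[peak_row]
  sel <- neighborhood_sites(cm, peak_channel, k_loc)
  amp <- pmax(ptp[match(sel$site_index, cm$site_index)] - background, 0)
  list(peak_channel = peak_channel,
       amplitudes = data.frame(site_index = sel$site_index,
                               x = sel$x, z = sel$z, amp = amp),
       peak_ptp = ptp[peak_row],
       partial_set = sel$partial[1])
}

#' Triangulate a unit's 3D position from amplitudes
#'
#' Fits the monopole decay model `V_c = alpha / sqrt((x - x_c)^2 +
#' (z - z_c)^2 + y^2)` to the background-subtracted peak-to-peak amplitudes by
#' bounded least squares, where `y >= 0` is the distance from the probe plane
#' and `alpha` a free source strength. Initialization at the peak channel with
#' `y = 20` um and `alpha = peak amplitude x 20 um`; up to three restarts with
#' rescaled `y`. Degenerate inputs (flat amplitudes) and non-convergence fall
#' back to the peak-channel coordinates, flagged.
#'
#' @param amplitudes data.frame with `x`, `z`, `amp` as returned by
#'   [compute_ptp_amplitudes()].
#' @param y_init initial distance from the probe plane, um.
#' @return list `x`, `y`, `z`, `alpha`, `rss`, `flagged`.
#' @export
estimate_unit_location <- function(amplitudes, y_init = 20) {
  a <- amplitudes[amplitudes$amp > 0, , drop = FALSE]
  peak <- amplitudes[which.max(amplitudes$amp), ]
  fallback <- list(x = peak$x, y = y_init, z = peak$z,
                   alpha = max(peak$amp, 1) * y_init, rss = NA_real_, flagged = TRUE)
  if (nrow(a) < 3L) return(fallback)
  if (stats::sd(a$amp) < 1e-9 * mean(a$amp)) {
    # equal amplitudes carry no spatial gradient
    return(list(x = peak$x, y = 1000, z = peak$z,
                alpha = peak$amp * 1000, rss = NA_real_, flagged = TRUE))
  }

  obj <- function(p) {
    r <- sqrt((p[1] - a$x)^2 + (p[3] - a$z)^2 + p[2]^2)
    sum((a$amp - p[4] / r)^2)
  }
  lower <- c(-Inf, 1e-6, -Inf, 1e-9)
  best <- NULL
  for (scale in c(1, 2.5, 0.4)) {
    p0 <- c(peak$x, y_init * scale, peak$z, peak$amp * y_init * scale)
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (!is.null(best) && best$convergence == 0 &&
        best$value < 1e-8 * sum(a$amp^2) + 1e-12) break
  }
  if (is.null(best)) return(fallback)
  list(x = best$par[1], y = best$par[2], z = best$par[3],
       alpha = best$par[4], rss = best$value,
       flagged = best$convergence != 0)
}

#' Localize all units of a session
#'
#' Runs the full localization step for each cluster: background estimation,
#' amplitude extraction on the 10-channel set, and monopole triangulation.
#' Units whose raw peak amplitude does not exceed `min_ptp` (60 uV by
#' default) are excluded from downstream matching (`included = FALSE`).
#'
#' @param bundle a [session_bundle()].
#' @param min_ptp amplitude inclusion filter, uV.
#' @param k_loc localization neighborhood half-height in rows.
#' @param background `"estimate"` (default) to estimate per unit, or a
#'   numeric value applied to all units.
#' @return data.frame of class `unit_table`: `unit_id`, `session_id`,
#'   `quality`, `peak_channel`, `peak_ptp`, `x`, `y`, `z`, `alpha`,
#'   `firing_rate`, `included`, `partial_set`, `flagged`.
#' @export
localize_units <- function(bundle, min_ptp = 60, k_loc = 2, background = "estimate") {
  cm <- bundle$channel_map
  ids <- as.integer(dimnames(bundle$mean_waveforms)[[1]])
  duration <- max(c(unlist(bundle$spike_times, use.names = FALSE), 0))
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    wf <- bundle$mean_waveforms[j, , , drop = TRUE]
    bg <- if (identical(background, "estimate")) {
      tryCatch(estimate_background(wf, cm), error = function(e) 0)
    } else as.numeric(background)
    amps <- compute_ptp_amplitudes(wf, cm, k_loc = k_loc, background = bg)
    included <- amps$peak_ptp > min_ptp
    loc <- if (included) estimate_unit_location(amps$amplitudes) else
      list(x = NA_real_, y = NA_real_, z = NA_real_, alpha = NA_real_,
           flagged = FALSE)
    st <- bundle$spike_times[[as.character(ids[j])]]
    fr <- if (duration > 0 && !is.null(st)) length(st) / duration else 0
    quality <- bundle$cluster_labels$quality[
      match(ids[j], bundle$cluster_labels$cluster_id)]
    rows[[j]] <- data.frame(unit_id = ids[j], session_id = bundle$session_id,
                            quality = quality, peak_channel = amps$peak_channel,
                            peak_ptp = amps$peak_ptp, x = loc$x, y = loc$y,
                            z = loc$z, alpha = loc$alpha, firing_rate = fr,
                            included = included, partial_set = amps$partial_set,
                            flagged = loc$flagged)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(unit_id = integer(0), session_id = character(0),
               quality = character(0), peak_channel = integer(0),
               peak_ptp = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0), alpha = numeric(0), firing_rate = numeric(0),
               included = logical(0), partial_set = logical(0),
               flagged = logical(0))
  class(out) <- c("unit_table", "data.frame")
  out
}
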