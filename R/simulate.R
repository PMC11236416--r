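#' Simulation configuration
#'
#' Parameters of the ground-truth drifting-population generator. Defaults
#' emulate the chronic recording conditions the tracking method targets:
#' units spread over a 720 um probe section, ~60% of units surviving from one
#' session to the next (with new units appearing in their place), a rigid
#' vertical drift of 12 um per session plus 3 um per-unit jitter, 5%
#' multiplicative amplitude noise, and a residual noise floor of 8 uV
#' peak-to-peak on the mean waveforms.
#'
#' @param n_sessions number of sessions.
#' @param n_units units per session.
#' @param survival probability a unit survives to the next session, in (0,1].
#' @param drift_um rigid z-drift per session step, um (signed; positive =
#'   upward).
#' @param jitter_sd_um per-unit z jitter between sessions, um (sd).
#' @param amp_noise multiplicative per-channel amplitude noise fraction.
#' @param noise_ptp_uv expected peak-to-peak of the waveform noise floor on
#'   signal-free channels, uV.
#' @param duration_s recording duration for baseline-only sessions, s.
#' @param with_visual simulate image presentations and evoked responses.
#' @param visual_fraction fraction of units given image tuning.
#' @param n_images,n_trials stimulus protocol (112 images x 5 shuffled
#'   trials).
#' @param trial_period_s seconds per presentation slot (1 s stimulus + gap).
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 2, n_units = 60, survival = 0.6,
                       drift_um = 12, jitter_sd_um = 3, amp_noise = 0.05,
                       noise_ptp_uv = 8, duration_s = 100,
                       with_visual = FALSE, visual_fraction = 0.4,
                       n_images = 112, n_trials = 5, trial_period_s = 1.5,
                       seed) {
  if (missing(seed)) stop("a random seed is mandatory")
  if (survival <= 0 || survival > 1) stop("survival must be in (0, 1]")
  if (jitter_sd_um < 0 || amp_noise < 0 || noise_ptp_uv < 0) {
    stop("noise parameters must be non-negative")
  }
  structure(list(n_sessions = n_sessions, n_units = n_units,
                 survival = survival, drift_um = drift_um,
                 jitter_sd_um = jitter_sd_um, amp_noise = amp_noise,
                 noise_ptp_uv = noise_ptp_uv, duration_s = duration_s,
                 with_visual = with_visual, visual_fraction = visual_fraction,
                 n_images = n_images, n_trials = n_trials,
                 trial_period_s = trial_period_s, seed = as.integer(seed)),
            class = "sim_config")
}

# expected range (max - min) of n iid standard normals; used to convert a
# target noise-floor ptp into a per-sample noise sd
expected_normal_range <- function(n) {
  emax <- stats::integrate(function(x) x * n * stats::dnorm(x) * stats::pnorm(x)^(n - 1),
                           -10, 10)$value
  2 * emax
}

#' Canonical biphasic spike template
#'
#' A negative trough plus a delayed repolarization bump, normalized to unit
#' peak-to-peak amplitude; multiplying by a channel amplitude yields that
#' channel's mean waveform.
#'
#' @param n_samples,sample_rate waveform window (81 samples at 30 kHz =
#'   2.7 ms).
#' @param t0_ms trough time, ms.
#' @param trough_sd_ms trough width, ms.
#' @param rep_delay_ms,rep_sd_ms,rep_amp repolarization bump delay, width and
#'   relative amplitude.
#' @return numeric vector of length `n_samples` with unit peak-to-peak range.
#' @export
spike_template <- function(n_samples = 81, sample_rate = 30000, t0_ms = 0.9,
                           trough_sd_ms = 0.12, rep_delay_ms = 0.4,
                           rep_sd_ms = 0.35, rep_amp = 0.4) {
  t <- (seq_len(n_samples) - 1) / sample_rate * 1000
  w <- -exp(-(t - t0_ms)^2 / (2 * trough_sd_ms^2)) +
    rep_amp * exp(-(t - t0_ms - rep_delay_ms)^2 / (2 * rep_sd_ms^2))
  w / (max(w) - min(w))
}

#' Generate a ground-truth unit population
#'
#' Units are placed uniformly in z over the probe span, in x around the two
#' site columns, and at 10-40 um from the probe plane; each receives a source
#' strength alpha such that its rendered peak-to-peak amplitude exceeds the
#' 60 uV inclusion filter, a biphasic waveform template with per-unit shape
#' parameters, a baseline firing rate, and (for a configured fraction) a
#' Gaussian image-tuning curve with unit-specific response latency and width.
#'
#' @param config a [sim_config()]. The caller controls the RNG state.
#' @param probe a [channel_map()].
#' @param n number of units (defaults to `config$n_units`).
#' @param id_start first ground-truth id.
#' @return data.frame of ground-truth units.
#' @export
generate_population <- function(config, probe, n = config$n_units, id_start = 1L) {
  if (n == 0L) {
    return(data.frame(gt_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), alpha = numeric(0), ptp_design = numeric(0),
                      base_rate = numeric(0), tuned = logical(0)))
  }
  xr <- range(probe$x)
  zr <- range(probe$z)
  x <- stats::runif(n, xr[1] - 16, xr[2] + 16)
  y <- stats::runif(n, 10, 40)
  z <- stats::runif(n, zr[1], zr[2])
  ptp_design <- pmin(80 + stats::rexp(n, 1 / 80), 500)
  alpha <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x[i] - probe$x)^2 + (z[i] - probe$z)^2 + y[i]^2)
    alpha[i] <- ptp_design[i] * min(d)
  }
  units <- data.frame(
    gt_id = seq_len(n) + id_start - 1L, x = x, y = y, z = z,
    alpha = alpha, ptp_design = ptp_design,
    base_rate = stats::rlnorm(n, log(4), 0.5),
    trough_sd_ms = stats::runif(n, 0.08, 0.16),
    rep_delay_ms = stats::runif(n, 0.25, 0.55),
    rep_sd_ms = stats::runif(n, 0.25, 0.5),
    rep_amp = stats::runif(n, 0.25, 0.6),
    tuned = stats::runif(n) < config$visual_fraction,
    pref_image = sample.int(config$n_images, n, replace = TRUE),
    tuning_width = stats::runif(n, 2, 8),
    peak_rate = stats::runif(n, 12, 30),
    latency_s = stats::runif(n, 0.05, 0.25),
    resp_sd_s = stats::runif(n, 0.03, 0.12))
  units
}

#' Render the mean waveform of one ground-truth unit
#'
#' Channel amplitudes follow the monopole model (`alpha / R` peak-to-peak at
#' distance `R`), scale the unit's temporal template, receive multiplicative
#' per-channel amplitude noise, and sit on additive Gaussian sample noise.
#' Units farther than `cutoff` from every site render as pure noise, flagged.
#'
#' @param unit one row of a [generate_population()] table.
#' @param probe a [channel_map()].
#' @param noise_ptp_uv noise-floor peak-to-peak, uV.
#' @param amp_noise multiplicative amplitude noise fraction.
#' @param n_samples,sample_rate waveform window (81 samples at 30 kHz =
#'   2.7 ms).
#' @param cutoff maximum unit-to-site distance for signal rendering, um.
#' @return `[n_channels x n_samples]` matrix, uV; attribute `all_noise`.
#' @export
render_waveforms <- function(unit, probe, noise_ptp_uv = 8, amp_noise = 0.05,
                             n_samples = 81, sample_rate = 30000, cutoff = 200) {
  d <- sqrt((unit$x - probe$x)^2 + (unit$z - probe$z)^2 + unit$y^2)
  all_noise <- min(d) > cutoff
  tmpl <- spike_template(n_samples, sample_rate,
                         trough_sd_ms = unit$trough_sd_ms,
                         rep_delay_ms = unit$rep_delay_ms,
                         rep_sd_ms = unit$rep_sd_ms, rep_amp = unit$rep_amp)
  amps <- if (all_noise) numeric(nrow(probe)) else unit$alpha / d
  if (amp_noise > 0) {
    amps <- pmax(amps * (1 + amp_noise * stats::rnorm(length(amps))), 0)
  }
  w <- outer(amps, tmpl)
  if (noise_ptp_uv > 0) {
    sd_n <- noise_ptp_uv / expected_normal_range(n_samples)
    w <- w + matrix(stats::rnorm(length(w), sd = sd_n), nrow(w))
  }
  attr(w, "all_noise") <- all_noise
  w
}

#' Shuffled stimulus presentation table
#'
#' Builds a presentation schedule in which every image is shown exactly once
#' per trial, in a freshly shuffled order (the caller controls the RNG
#' state).
#'
#' @param n_images,n_trials protocol size.
#' @param trial_period_s seconds per presentation slot.
#' @param start_s onset of the first presentation, s.
#' @return data.frame with `image_id`, `trial`, `onset_s`.
#' @export
make_stim_table <- function(n_images, n_trials, trial_period_s, start_s = 5) {
  order <- unlist(lapply(seq_len(n_trials), function(t) sample.int(n_images)))
  k <- seq_along(order)
  data.frame(image_id = order,
             trial = rep(seq_len(n_trials), each = n_images),
             onset_s = start_s + (k - 1) * trial_period_s)
}

#' Simulate spike trains with image-evoked responses
#'
#' Inhomogeneous Poisson spiking: a homogeneous baseline at the unit's rate,
#' plus, for tuned units, image-evoked spikes during each presentation whose
#' expected count is the unit's tuning at the shown image and whose times
#' follow the unit's Gaussian response profile (latency, width) within the
#' 1 s response window. Tuning, latency and width are properties of the
#' ground-truth unit and therefore preserved across sessions.
#'
#' @param units ground-truth unit table (rows present in the session).
#' @param config a [sim_config()].
#' @param stim_table presentation table from the same session.
#' @param duration_s total recording duration, s.
#' @return list (per unit row) of sorted spike-time vectors, seconds.
#' @export
simulate_visual_responses <- function(units, config, stim_table, duration_s) {
  lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    n_base <- stats::rpois(1, u$base_rate * duration_s)
    spikes <- stats::runif(n_base, 0, duration_s)
    if (isTRUE(u$tuned)) {
      dimg <- abs(stim_table$image_id - u$pref_image)
      dimg <- pmin(dimg, config$n_images - dimg)   # circular image distance
      lambda <- u$peak_rate * exp(-dimg^2 / (2 * u$tuning_width^2))
      n_ev <- stats::rpois(length(lambda), lambda)
      for (j in which(n_ev > 0)) {
        t_rel <- stats::rnorm(n_ev[j], u$latency_s, u$resp_sd_s)
        t_rel <- pmin(pmax(t_rel, 0), 0.999)
        spikes <- c(spikes, stim_table$onset_s[j] + t_rel)
      }
    }
    sort(spikes)
  })
}

#' Simulate a multi-session recording sequence with ground truth
#'
#' Session 1 draws a fresh population. Each later session keeps every unit
#' with probability `survival`, shifts the survivors' z by the rigid drift
#' plus per-unit jitter, and draws new units to restore the session count.
#' Mean waveforms are re-rendered at the drifted locations (so drift induces
#' correlated location and waveform changes) with fresh noise; cluster ids
#' are shuffled per session. All randomness is governed by `config$seed`.
#'
#' @param config a [sim_config()].
#' @param probe a [channel_map()]; defaults to one shank of 96 sites (a
#'   720 um probe section), the per-shank unit of analysis.
#' @return list of class `sim_sequence`: `sessions` (list of
#'   [session_bundle()]s), `ground_truth` (data.frame `gt_id`, `session_id`,
#'   `unit_id`), `probe`, `config`, `units` (per-session ground-truth
#'   tables).
#' @export
simulate_session_sequence <- function(config, probe = NULL) {
  set.seed(config$seed)
  if (is.null(probe)) probe <- generate_probe(n_shanks = 1, sites_per_shank = 96)
  n_samples <- 81
  sample_rate <- 30000

  roster <- generate_population(config, probe)
  next_id <- if (nrow(roster) > 0) max(roster$gt_id) + 1L else 1L
  sessions <- vector("list", config$n_sessions)
  unit_tabs <- vector("list", config$n_sessions)
  gt <- list()

  for (t in seq_len(config$n_sessions)) {
    if (t > 1L) {
      alive <- stats::runif(nrow(roster)) < config$survival
      roster <- roster[alive, , drop = FALSE]
      if (nrow(roster) > 0) {
        roster$z <- roster$z + config$drift_um +
          stats::rnorm(nrow(roster), 0, config$jitter_sd_um)
      }
      n_new <- config$n_units - nrow(roster)
      if (n_new > 0) {
        fresh <- generate_population(config, probe, n = n_new, id_start = next_id)
        next_id <- next_id + n_new
        roster <- rbind(roster, fresh)
      }
    }
    session_id <- sprintf("day%02d", t)
    n <- nrow(roster)
    cluster_ids <- if (n > 0) sample(seq_len(n) - 1L) else integer(0)

    mw <- array(0, dim = c(n, nrow(probe), n_samples),
                dimnames = list(as.character(cluster_ids), NULL, NULL))
    for (i in seq_len(n)) {
      mw[i, , ] <- render_waveforms(roster[i, ], probe,
                                    noise_ptp_uv = config$noise_ptp_uv,
                                    amp_noise = config$amp_noise,
                                    n_samples = n_samples,
                                    sample_rate = sample_rate)
    }

    if (config$with_visual) {
      stim <- make_stim_table(config$n_images, config$n_trials,
                              config$trial_period_s)
      duration <- max(stim$onset_s) + 5
      spikes <- simulate_visual_responses(roster, config, stim, duration)
    } else {
      stim <- NULL
      duration <- config$duration_s
      spikes <- lapply(seq_len(n), function(i) {
        sort(stats::runif(stats::rpois(1, roster$base_rate[i] * duration),
                          0, duration))
      })
    }
    names(spikes) <- as.character(cluster_ids)

    labels <- data.frame(cluster_id = cluster_ids,
                         quality = rep("good", n))
    sessions[[t]] <- session_bundle(
      session_id = session_id, channel_map = probe,
      cluster_labels = labels[order(labels$cluster_id), , drop = FALSE],
      mean_waveforms = mw, spike_times = spikes,
      sample_rate = sample_rate, stim_table = stim)
    tab <- roster
    tab$unit_id <- cluster_ids
    tab$session_id <- session_id
    unit_tabs[[t]] <- tab
    gt[[t]] <- data.frame(gt_id = roster$gt_id, session_id = session_id,
                          unit_id = cluster_ids)
  }

  structure(list(sessions = sessions,
                 ground_truth = do.call(rbind, gt),
                 probe = probe, config = config, units = unit_tabs),
            class = "sim_sequence")
}

#' Ground-truth unit pairs between two simulated sessions
#'
#' @param sim a `sim_sequence`.
#' @param t1,t2 session indices.
#' @return data.frame `unit1`, `unit2`, `gt_id` of units present in both.
#' @export
gt_pairs <- function(sim, t1 = 1, t2 = 2) {
  g <- sim$ground_truth
  s <- vapply(sim$sessions, function(b) b$session_id, "")
  a <- g[g$session_id == s[t1], ]
  b <- g[g$session_id == s[t2], ]
  shared <- intersect(a$gt_id, b$gt_id)
  data.frame(unit1 = a$unit_id[match(shared, a$gt_id)],
             unit2 = b$unit_id[match(shared, b$gt_id)],
             gt_id = shared)
}

#' Write a simulated sequence as session directories
#'
#' Creates one session directory per simulated day (see [write_session()])
#' plus `ground_truth.csv` mapping ground-truth ids to per-session unit ids.
#'
#' @param sim a `sim_sequence`.
#' @param dir output directory.
#' @return vector of session directories, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(length(sim$sessions))
  for (t in seq_along(sim$sessions)) {
    dirs[t] <- file.path(dir, sim$sessions[[t]]$session_id)
    write_session(sim$sessions[[t]], dirs[t])
  }
  data.table::fwrite(sim$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dirs)
}

#' @export
print.sim_sequence <- function(x, ...) {
  cat(sprintf("simulated sequence: %d sessions x %d units (seed %d)\n",
              length(x$sessions), x$config$n_units, x$config$seed))
  invisible(x)
}
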