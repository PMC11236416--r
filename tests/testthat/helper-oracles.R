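# Shared oracles and small constructors used across test files.

# All injective maps from 1..n1 into 1..n2 (n1 <= n2), as a list of integer
# vectors. Exhaustive, so only usable for tiny problems.
all_injections <- function(n1, n2) {
  if (n1 == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == n1) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (j in remaining) rec(c(prefix, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(n2))
  out
}

# Exhaustive minimum-cost partial assignment: min over all injective maps of
# the smaller side into the larger side of the summed costs.
brute_force_assignment_cost <- function(cost) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  maps <- all_injections(nrow(cost), ncol(cost))
  min(vapply(maps, function(m) sum(cost[cbind(seq_along(m), m)]), 0))
}

# False-positive rate of the z-distance mixture by numerical quadrature,
# independent of the closed form used in the package.
quadrature_fpr <- function(f, sigma, cc, z) {
  gauss <- function(t) f * sqrt(2 / pi) / sigma * exp(-t^2 / (2 * sigma^2))
  expo <- function(t) (1 - f) / cc * exp(-t / cc)
  tp <- stats::integrate(gauss, 0, z, rel.tol = 1e-12)$value
  fp <- stats::integrate(expo, 0, z, rel.tol = 1e-12)$value
  fp / (fp + tp)
}

# Forward-render noiseless monopole peak-to-peak amplitudes on a probe for a
# point source at (x, y, z) with strength alpha.
monopole_amplitudes <- function(cm, x, y, z, alpha) {
  alpha / sqrt((x - cm$x)^2 + y^2 + (z - cm$z)^2)
}

# A minimal single-shank probe for geometry tests.
small_probe <- function(n_rows = 8, x_pitch = 32, z_pitch = 15) {
  generate_probe(n_shanks = 1, sites_per_shank = 2 * n_rows,
                 x_pitch = x_pitch, z_pitch = z_pitch)
}

# Build a session_bundle from a named list of [channels x samples] waveform
# matrices; spikes are evenly spaced placeholders unless supplied.
toy_bundle <- function(waveforms, cm, session_id = "s1",
                       quality = NULL, spike_times = NULL,
                       sample_rate = 30000, stim_table = NULL) {
  ids <- as.integer(names(waveforms))
  if (is.null(quality)) quality <- rep("good", length(ids))
  if (is.null(spike_times)) {
    spike_times <- lapply(seq_along(ids), function(i) seq(0.1, 10, by = 0.5))
    names(spike_times) <- names(waveforms)
  }
  n_samples <- ncol(waveforms[[1]])
  arr <- array(0, dim = c(length(ids), nrow(cm), n_samples),
               dimnames = list(names(waveforms), NULL, NULL))
  for (i in seq_along(waveforms)) arr[i, , ] <- waveforms[[i]]
  session_bundle(session_id = session_id, channel_map = cm,
                 cluster_labels = data.frame(cluster_id = ids,
                                             quality = quality),
                 mean_waveforms = arr,
                 spike_times = spike_times, sample_rate = sample_rate,
                 stim_table = stim_table)
}

# Noiseless forward-rendered bundle: point sources observed through the
# monopole model with a flat template, so localization sees exact amplitudes.
render_monopole_bundle <- function(cm, units, session_id = "s1",
                                   n_samples = 81) {
  tmpl <- spike_template(n_samples = n_samples)
  wfs <- lapply(seq_len(nrow(units)), function(i) {
    amps <- monopole_amplitudes(cm, units$x[i], units$y[i], units$z[i],
                                units$alpha[i])
    outer(amps, tmpl)
  })
  names(wfs) <- as.character(units$unit_id)
  toy_bundle(wfs, cm, session_id = session_id)
}
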