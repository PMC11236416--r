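test_that("peak-to-peak amplitude is max minus min per channel", {
  wf <- rbind(c(0, 3, -2, 1), c(1, 1, 1, 1))
  expect_equal(ptp_amplitude(wf), c(5, 0))
})

test_that("the monopole inversion recovers a noiseless source near-exactly", {
  cm <- generate_probe(1, 96)
  truth <- list(x = 16, y = 25, z = 350, alpha = 3000)
  amps_full <- monopole_amplitudes(cm, truth$x, truth$y, truth$z, truth$alpha)
  peak_site <- cm$site_index[which.max(amps_full)]
  sel <- emdtrack:::neighborhood_sites(cm, peak_site, 2)
  amps <- data.frame(site_index = sel$site_index, x = sel$x, z = sel$z,
                     amp = amps_full[match(sel$site_index, cm$site_index)])
  fit <- estimate_unit_location(amps)
  expect_lt(abs(fit$x - truth$x), 1e-4)
  expect_lt(abs(fit$z - truth$z), 1e-4)
  expect_lt(abs(fit$y - truth$y), 1e-3)
  expect_false(fit$flagged)
})

test_that("localization uses the 10-channel neighborhood around the peak", {
  cm <- generate_probe(1, 96)
  wf <- matrix(0, nrow(cm), 81)
  peak_row <- 45L
  amps <- monopole_amplitudes(cm, cm$x[peak_row], 20, cm$z[peak_row], 2000)
  wf[, 40] <- amps
  sel <- compute_ptp_amplitudes(wf, cm, k_loc = 2)
  expect_equal(nrow(sel$amplitudes), 10)
  expect_equal(sel$peak_channel, cm$site_index[peak_row])
  rows <- cm$row_index[match(sel$amplitudes$site_index, cm$site_index)]
  peak_r <- cm$row_index[peak_row]
  expect_true(all(abs(rows - peak_r) <= 2))
  expect_false(sel$partial_set)
})

test_that("an edge peak yields a smaller, flagged partial neighborhood", {
  cm <- generate_probe(1, 96)
  wf <- matrix(0, nrow(cm), 81)
  wf[1, 40] <- 100  # bottom-row site
  sel <- compute_ptp_amplitudes(wf, cm, k_loc = 2)
  expect_lt(nrow(sel$amplitudes), 10)
  expect_true(sel$partial_set)
})

test_that("background subtraction floors amplitudes at zero", {
  cm <- generate_probe(1, 96)
  wf <- matrix(0, nrow(cm), 81)
  wf[45, 40] <- 100
  wf[44, 40] <- 3   # below the background level
  sel <- compute_ptp_amplitudes(wf, cm, k_loc = 2, background = 5)
  a <- sel$amplitudes
  expect_true(all(a$amp >= 0))
  expect_equal(a$amp[a$site_index == cm$site_index[45]], 95)
  expect_equal(a$amp[a$site_index == cm$site_index[44]], 0)
})

test_that("background estimation needs enough far channels", {
  cm <- small_probe(n_rows = 4)  # 8 sites, everything inside the neighborhood
  wf <- matrix(rnorm(8 * 81), 8, 81)
  expect_error(estimate_background(wf, cm), "channels")
})

test_that("background estimation reports the median far-channel amplitude", {
  cm <- generate_probe(1, 96)
  wf <- matrix(0, nrow(cm), 81)
  wf[, 40] <- 6            # uniform 6 uV ptp floor everywhere
  wf[45, 40] <- 200        # plus one strong unit
  bg <- estimate_background(wf, cm)
  expect_equal(bg, 6)
})

test_that("units below the inclusion amplitude are excluded from matching", {
  cm <- generate_probe(1, 96)
  tmpl <- spike_template()
  strong <- outer(monopole_amplitudes(cm, 16, 20, 300, 200 * 20), tmpl)
  weak <- outer(monopole_amplitudes(cm, 16, 20, 500, 30 * 20), tmpl)
  b <- toy_bundle(list("1" = strong, "2" = weak), cm)
  units <- localize_units(b, background = 0)
  expect_true(units$included[units$unit_id == 1])
  expect_false(units$included[units$unit_id == 2])
})

test_that("a flat amplitude profile is flagged rather than fitted", {
  amps <- data.frame(site_index = 1:10, x = rep(c(0, 32), 5),
                     z = rep(seq(0, 60, 15), each = 2)[1:10],
                     amp = rep(5, 10))
  fit <- estimate_unit_location(amps)
  expect_true(fit$flagged)
})

test_that("unit tables carry firing rate and peak metadata", {
  sim <- simulate_session_sequence(sim_config(seed = 3, n_units = 15))
  units <- localize_units(sim$sessions[[1]])
  expect_s3_class(units, "unit_table")
  expect_true(all(c("unit_id", "peak_channel", "peak_ptp", "x", "y", "z",
                    "firing_rate", "included") %in% names(units)))
  expect_true(all(units$firing_rate >= 0))
  expect_true(all(units$y >= 0))
})
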