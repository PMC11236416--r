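test_that("a seed is mandatory and configs validate their arguments", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, survival = 1.5))
  expect_error(sim_config(seed = 1, amp_noise = -0.1))
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$drift_um, 12)
  expect_equal(cfg$survival, 0.6)
})

test_that("the spike template is biphasic with unit peak-to-peak range", {
  tmpl <- spike_template()
  expect_length(tmpl, 81)
  expect_equal(max(tmpl) - min(tmpl), 1)
  # trough at 0.9 ms (sample 28 at 30 kHz, 1-based)
  expect_equal(which.min(tmpl), 28)
  # repolarization bump after the trough
  expect_gt(max(tmpl[29:81]), 0)
})

test_that("the expected range of n standard normals matches known values", {
  enr <- emdtrack:::expected_normal_range
  expect_equal(enr(1), 0, tolerance = 1e-8)
  # E[max of 2 std normals] = 1/sqrt(pi), range is twice that
  expect_equal(enr(2), 2 / sqrt(pi), tolerance = 1e-6)
  expect_gt(enr(80), enr(10))
})

test_that("simulated sequences have the configured shape", {
  cfg <- sim_config(seed = 19, n_sessions = 3, n_units = 25)
  sim <- simulate_session_sequence(cfg)
  expect_s3_class(sim, "sim_sequence")
  expect_length(sim$sessions, 3)
  for (s in sim$sessions) {
    expect_s3_class(s, "session_bundle")
    expect_equal(nrow(s$cluster_labels), 25)
  }
  gt <- sim$ground_truth
  expect_true(all(c("gt_id", "session_id", "unit_id") %in% names(gt)))
  expect_equal(nrow(gt), 3 * 25)
})

test_that("survival controls cross-session persistence of ground-truth units", {
  cfg <- sim_config(seed = 20, n_units = 50, survival = 0.6)
  sim <- simulate_session_sequence(cfg)
  gt <- sim$ground_truth
  ids1 <- gt$gt_id[gt$session_id == sim$sessions[[1]]$session_id]
  ids2 <- gt$gt_id[gt$session_id == sim$sessions[[2]]$session_id]
  frac <- length(intersect(ids1, ids2)) / length(ids1)
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.85)
  # cluster ids are shuffled per session: survivors keep gt identity, not label
  expect_equal(length(ids2), 50)
})

test_that("imposed drift moves surviving units along z by the drift amount", {
  cfg <- sim_config(seed = 22, n_units = 40, drift_um = 12,
                    jitter_sd_um = 0)
  sim <- simulate_session_sequence(cfg)
  u1 <- sim$units[[1]]
  u2 <- sim$units[[2]]
  common <- intersect(u1$gt_id, u2$gt_id)
  dz <- u2$z[match(common, u2$gt_id)] - u1$z[match(common, u1$gt_id)]
  expect_equal(unname(dz), rep(12, length(common)), tolerance = 1e-9)
})

test_that("gt_pairs lists exactly the units present in both sessions", {
  sim <- simulate_session_sequence(sim_config(seed = 23, n_units = 30))
  gt <- gt_pairs(sim)
  g <- sim$ground_truth
  s1 <- sim$sessions[[1]]$session_id
  s2 <- sim$sessions[[2]]$session_id
  expected_n <- length(intersect(g$gt_id[g$session_id == s1],
                                 g$gt_id[g$session_id == s2]))
  expect_equal(nrow(gt), expected_n)
  expect_true(all(gt$unit1 %in% g$unit_id[g$session_id == s1]))
  expect_true(all(gt$unit2 %in% g$unit_id[g$session_id == s2]))
})

test_that("identical seeds reproduce the simulation exactly", {
  cfg <- sim_config(seed = 24, n_units = 20, with_visual = TRUE)
  a <- simulate_session_sequence(cfg)
  b <- simulate_session_sequence(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$sessions[[1]]$mean_waveforms,
                   b$sessions[[1]]$mean_waveforms)
  expect_identical(a$sessions[[2]]$spike_times, b$sessions[[2]]$spike_times)
  c_ <- simulate_session_sequence(sim_config(seed = 25, n_units = 20))
  expect_false(identical(a$sessions[[1]]$mean_waveforms,
                         c_$sessions[[1]]$mean_waveforms))
})

test_that("visual simulations carry a complete stimulus table and spikes", {
  cfg <- sim_config(seed = 26, n_units = 10, with_visual = TRUE,
                    n_images = 16, n_trials = 3)
  sim <- simulate_session_sequence(cfg)
  s <- sim$sessions[[1]]
  expect_false(is.null(s$stim_table))
  expect_equal(nrow(s$stim_table), 16 * 3)
  expect_equal(sort(unique(s$stim_table$image_id)), 1:16)
  for (st in s$spike_times) {
    expect_true(all(st >= 0))
    expect_true(all(diff(st) >= 0))
  }
})

test_that("simulations round-trip through disk with their ground truth", {
  sim <- simulate_session_sequence(sim_config(seed = 27, n_units = 8))
  dir <- tempfile("sim")
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  b <- load_session(file.path(dir, sim$sessions[[1]]$session_id))
  # loading reorders clusters canonically by id; compare unit by unit
  orig <- sim$sessions[[1]]$mean_waveforms
  expect_setequal(dimnames(b$mean_waveforms)[[1]], dimnames(orig)[[1]])
  for (id in dimnames(orig)[[1]]) {
    expect_equal(b$mean_waveforms[id, , ], orig[id, , ], tolerance = 1e-12)
  }
  unlink(dir, recursive = TRUE)
})

test_that("rendered waveforms embed the template scaled by monopole decay", {
  probe <- generate_probe(1, 96)
  unit <- data.frame(gt_id = 1L, x = 16, y = 20, z = 300, alpha = 150 * 20,
                     trough_sd_ms = 0.12, rep_delay_ms = 0.4,
                     rep_sd_ms = 0.35, rep_amp = 0.4)
  wf <- render_waveforms(unit, probe, noise_ptp_uv = 0, amp_noise = 0)
  expect_false(attr(wf, "all_noise"))
  ptp <- ptp_amplitude(wf)
  expected <- monopole_amplitudes(probe, 16, 20, 300, 150 * 20)
  expect_equal(ptp, expected, tolerance = 1e-9)
  # a source beyond the rendering cutoff is pure noise, flagged
  far <- unit; far$z <- 5000
  wf_far <- render_waveforms(far, probe, noise_ptp_uv = 0, amp_noise = 0)
  expect_true(attr(wf_far, "all_noise"))
  expect_true(all(wf_far == 0))
})
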