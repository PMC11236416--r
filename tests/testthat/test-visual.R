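test_that("the PSTH bins spikes relative to onset over the 1800 ms window", {
  onsets <- c(10, 20)
  # one spike 500 ms after each onset, one spike outside the window
  spikes <- c(10.5, 20.5, 30)
  psth <- compute_psth(spikes, onsets, smooth_sd_ms = 0)
  expect_length(psth, 1800)
  expect_equal(sum(psth), 1)  # 2 spikes / 2 presentations
  expect_equal(psth[901], 1)  # 400 pre-onset bins, then bin 501 covers +500 ms
  pre <- compute_psth(c(9.75, 19.75), onsets, smooth_sd_ms = 0)
  expect_equal(pre[151], 1)   # 250 ms before onset
})

test_that("Gaussian smoothing preserves the PSTH mass", {
  onsets <- c(5)
  spikes <- 5 + c(0.1, 0.3, 0.5)
  raw <- compute_psth(spikes, onsets, smooth_sd_ms = 0)
  sm <- compute_psth(spikes, onsets, smooth_sd_ms = 10)
  expect_equal(sum(sm), sum(raw), tolerance = 1e-9)
  expect_lt(max(sm), max(raw))
})

test_that("the visual fingerprint counts spikes per image and trial", {
  set.seed(50)
  stim <- make_stim_table(n_images = 3, n_trials = 2, trial_period_s = 1.5)
  # unit fires 4 spikes within image 2's window on every presentation
  on2 <- stim$onset_s[stim$image_id == 2]
  spikes <- sort(c(outer(on2, c(0.1, 0.3, 0.5, 0.9), "+")))
  v <- compute_vfp(spikes, stim)
  expect_equal(unname(v$vfp), c(0, 4, 0))
  expect_equal(dim(v$vfp_trials), c(2, 3))
  expect_true(all(v$vfp_trials[, "2"] == 4))
})

test_that("incomplete stimulus tables are rejected", {
  stim <- make_stim_table(n_images = 3, n_trials = 2, trial_period_s = 1.5)
  expect_error(compute_vfp(numeric(0), stim[-1, ]), "every image")
})

test_that("image-tuned responses are significant and flat ones are not", {
  set.seed(51)
  tuned <- matrix(rpois(5 * 16, lambda = rep(c(1, 1, 12, 1), each = 5 * 4)),
                  nrow = 5, dimnames = list(NULL, 1:16))
  expect_true(response_significance(tuned))
  flat <- matrix(rpois(5 * 16, 3), nrow = 5, dimnames = list(NULL, 1:16))
  expect_false(response_significance(flat))
  silent <- matrix(0, 5, 16, dimnames = list(NULL, 1:16))
  expect_false(response_significance(silent))
})

test_that("similarity adds PSTH and fingerprint correlations", {
  set.seed(52)
  stim <- make_stim_table(n_images = 8, n_trials = 3, trial_period_s = 1.5)
  on3 <- stim$onset_s[stim$image_id == 3]
  spikes <- sort(as.vector(outer(on3, seq(0.05, 0.8, by = 0.05), "+")))
  r1 <- visual_response(spikes, stim)
  r2 <- visual_response(spikes + 0.001, stim)
  s_same <- similarity_score(r1, r2)
  expect_true(s_same$valid)
  expect_gt(s_same$similarity, 1.5)
  expect_lt(s_same$similarity, 2)
  # a unit tuned to a different image is dissimilar
  on7 <- stim$onset_s[stim$image_id == 7]
  r3 <- visual_response(sort(as.vector(outer(on7, seq(0.05, 0.8, 0.05), "+"))),
                        stim)
  expect_lt(similarity_score(r1, r3)$similarity, 1)
})

test_that("zero-variance responses make the similarity invalid, not wrong", {
  stim <- make_stim_table(n_images = 4, n_trials = 2, trial_period_s = 1.5)
  r_silent <- visual_response(numeric(0), stim)
  r_active <- visual_response(stim$onset_s + 0.1, stim)
  s <- similarity_score(r_silent, r_active)
  expect_false(s$valid)
  expect_true(is.na(s$similarity))
})

test_that("reference pairs meet every gate and form a partial matching", {
  cfg <- sim_config(seed = 17, with_visual = TRUE, n_units = 30)
  sim <- simulate_session_sequence(cfg)
  s1 <- sim$sessions[[1]]; s2 <- sim$sessions[[2]]
  resp <- function(b) {
    out <- lapply(names(b$spike_times),
                  function(id) visual_response(b$spike_times[[id]], b$stim_table))
    names(out) <- names(b$spike_times)
    out
  }
  r1 <- resp(s1); r2 <- resp(s2)
  u1 <- localize_units(s1); u2 <- localize_units(s2)
  m <- match_sessions(s1, s2)
  u2c <- apply_drift_correction(u2, m$drift)
  ref <- build_reference_set(r1, r2, u1, u2, units2_corrected = u2c)
  expect_gt(nrow(ref), 0)
  expect_true(all(ref$similarity > 1))
  expect_true(all(ref$dist_pre < 30 & ref$dist_post < 30))
  expect_equal(anyDuplicated(ref$unit1), 0L)
  expect_equal(anyDuplicated(ref$unit2), 0L)
  # every reference unit is KSgood
  expect_true(all(ref$unit1 %in% u1$unit_id[u1$quality == "good"]))
  # most reference pairs agree with the simulation's ground truth
  gt <- gt_pairs(sim)
  agree <- paste(ref$unit1, ref$unit2) %in% paste(gt$unit1, gt$unit2)
  expect_gte(mean(agree), 0.8)
})

test_that("an impossible distance gate yields an empty set with a warning", {
  cfg <- sim_config(seed = 18, with_visual = TRUE, n_units = 15)
  sim <- simulate_session_sequence(cfg)
  s1 <- sim$sessions[[1]]; s2 <- sim$sessions[[2]]
  resp <- function(b) {
    out <- lapply(names(b$spike_times),
                  function(id) visual_response(b$spike_times[[id]], b$stim_table))
    names(out) <- names(b$spike_times)
    out
  }
  u1 <- localize_units(s1); u2 <- localize_units(s2)
  expect_warning(
    ref <- build_reference_set(resp(s1), resp(s2), u1, u2, max_dist = 1e-6),
    "empty reference set")
  expect_equal(nrow(ref), 0)
})
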