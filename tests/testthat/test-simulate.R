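test_that("LSA potential scales linearly and recovers the point-source limit", {
  v1 <- lsa_amplitude(1e-9, 0.3, 1e-6, r = 1e-3, h = 0)
  expect_equal(lsa_amplitude(2e-9, 0.3, 1e-6, r = 1e-3, h = 0), 2 * v1)
  expect_equal(lsa_amplitude(1e-9, 0.15, 1e-6, r = 1e-3, h = 0), 2 * v1)
  # r >> delta_s: within 5% of Coulomb I / (4 pi r sigma)
  coulomb <- 1e-9 / (4 * pi * 1e-3 * 0.3)
  expect_lte(abs(v1 - coulomb) / coulomb, 0.05)
  expect_error(lsa_amplitude(1e-9, 0.3, 1e-6, r = 0), "singular")
})

test_that("spike templates honour the window convention and amplitude", {
  tmpl <- spike_template(85, 12500)
  expect_identical(length(tmpl), 38L)
  expect_equal(max(tmpl) - min(tmpl), 85, tolerance = 1)
  expect_lt(min(tmpl), 0)  # negative trough
  expect_gt(max(tmpl), 0)  # positive rebound
})

test_that("simulated trains hit their target rates and couple as configured", {
  sim0 <- simulate_trains(rates = c(0, 2), duration = 300, seed = 1)
  expect_identical(length(sim0$trains[[1]]), 0L)
  n2 <- length(sim0$trains[[2]])
  expect_lte(abs(n2 - 600), 3 * sqrt(600))
  expect_false(is.unsorted(sim0$trains[[2]]))

  # coupling fraction 0: mean pairwise STTC near zero
  set.seed(2)
  many <- simulate_trains(rates = rep(1.5, 20), duration = 300, seed = 3)
  prs <- utils::combn(20, 2)
  vals <- vapply(seq_len(ncol(prs)), function(j)
    sttc(many$trains[[prs[1, j]]], many$trains[[prs[2, j]]], 300), 0)
  expect_lte(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.02)

  # full sharing, zero jitter: identical trains
  cp <- simulate_trains(rates = c(2, 2), duration = 300,
                        coupled_groups = cbind(1, 2), parent_share = 1,
                        jitter_sd_ms = 0, seed = 4)
  expect_identical(cp$trains[[1]], cp$trains[[2]])
  expect_error(simulate_trains(rates = -1, duration = 10), ">= 0")
})

test_that("the default plate geometry yields 768 distinct channels", {
  cfg <- sim_config(waveforms = FALSE, seed = 2,
                    recordings = tibble(recording_id = "R1",
                                        duration_s = 60, phase = "pre"))
  sim <- simulate_plate(cfg)
  chans <- sim$truth$neurons %>% dplyr::distinct(well, electrode)
  expect_identical(nrow(chans), 768L)
})

test_that("zero rate spread gives every array the common rate", {
  cfg <- sim_config(layout = tiny_layout(6, 2), waveforms = FALSE,
                    array_log_rate = c(mean = 0.3, sd = 0),
                    recordings = tibble(recording_id = "R1",
                                        duration_s = 1800, phase = "pre"),
                    seed = 5)
  act <- array_activity(simulate_plate(cfg)$table)
  lambda <- 10^0.3 * 1800
  expect_true(all(abs(act$n_spikes - lambda) <= 3 * sqrt(lambda)))
})

test_that("simulated MFRs are right-skewed in Hz and symmetric in log10 Hz", {
  cfg <- sim_config(waveforms = FALSE, seed = 6,
                    recordings = tibble(recording_id = "R1",
                                        duration_s = 900, phase = "pre"))
  act <- array_activity(simulate_plate(cfg)$table)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew(act$mfr), 0.5)
  expect_lt(abs(skew(act$log_mfr)), 0.5)
})

test_that("treatment multipliers act on rates and amplitudes with exact algebra", {
  recs <- tibble(recording_id = c("R1", "R2"), duration_s = 600,
                 phase = c("pre", "post"))
  groups <- tibble(well = tiny_layout(6, 2)$well_labels,
                   group = rep(c("media", "ttx"), 3))
  # rate multiplier 0: silence in the treated group post
  eff0 <- tibble(group = "ttx", phase = "post", rate_mult = 0, amp_mult = 1)
  cfg <- sim_config(layout = tiny_layout(6, 2), recordings = recs,
                    groups = groups, effects = eff0, waveforms = FALSE,
                    seed = 7)
  sim <- simulate_plate(cfg)
  post_ttx <- sim$table$events %>%
    dplyr::filter(.data$recording_id == "R2",
                  .data$well %in% groups$well[groups$group == "ttx"])
  expect_identical(nrow(post_ttx), 0L)
  pre_ttx <- sim$table$events %>%
    dplyr::filter(.data$recording_id == "R1",
                  .data$well %in% groups$well[groups$group == "ttx"])
  expect_gt(nrow(pre_ttx), 0L)

  # amplitude multiplier: exact -0.074 log10 shift of true amplitudes
  effa <- tibble(group = "ttx", phase = "post", rate_mult = 1,
                 amp_mult = 10^-0.074)
  cfga <- sim_config(layout = tiny_layout(6, 2), recordings = recs,
                     groups = groups, effects = effa, waveforms = FALSE,
                     seed = 8)
  sima <- simulate_plate(cfga)
  r <- sima$truth$rates %>%
    dplyr::filter(.data$group == "ttx") %>%
    dplyr::group_by(.data$neuron_id) %>%
    dplyr::summarise(
      d = log10(.data$amplitude_uv[.data$phase == "post"]) -
        log10(.data$amplitude_uv[.data$phase == "pre"]),
      .groups = "drop")
  expect_equal(r$d, rep(-0.074, nrow(r)), tolerance = 1e-12)
  expect_error(
    simulate_plate(sim_config(layout = tiny_layout(6, 2),
                              recordings = recs, groups = groups,
                              effects = tibble(group = "nope",
                                               phase = "post",
                                               rate_mult = 1,
                                               amp_mult = 1))),
    "unknown group")
})

test_that("raw traces carry the planted spikes and respect the band-pass", {
  syn <- synth_raw_trace(rates = 1, amplitudes_uv = 80, duration = 5,
                         noise_sd = 0, seed = 9)
  det <- detect_spikes(syn$trace, 12500)
  expect_identical(nrow(det), nrow(syn$truth))
  expect_true(all(vapply(syn$truth$time_s, function(t)
    any(abs(det$timestamp_s - t) < 1e-3), TRUE)))
  # band-pass runs and preserves length
  bp <- synth_raw_trace(rates = 1, amplitudes_uv = 80, duration = 2,
                        noise_sd = 2.5, bandpass = c(200, 2500), seed = 10)
  expect_identical(length(bp$trace), as.integer(2 * 12500))
  expect_error(synth_raw_trace(1, 80, duration = 120), "60 s")
})

test_that("ground truth labels every emitted spike with a registered neuron", {
  cfg <- sim_config(layout = tiny_layout(6, 2), waveforms = TRUE, seed = 11,
                    recordings = tibble(recording_id = "R1",
                                        duration_s = 120, phase = "pre"))
  sim <- simulate_plate(cfg)
  expect_true(all(sim$table$events$truth_neuron %in%
                    sim$truth$neurons$neuron_id))
  amps <- sim$truth$neurons$amplitude_uv
  expect_true(all(amps > 1 & amps < 1000))  # plausible extracellular range
})
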