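# Fixtures and independent oracles used across the suite. Everything is
# generated in code; nothing is read from disk.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# --- tiny spike tables -------------------------------------------------------

tiny_layout <- function(n_wells = 6, electrodes = 2)
  plate_layout(n_wells = n_wells, electrodes_per_well = electrodes,
               n_rows = 2)

# hand-built table: n events in one well/electrode with constant waveforms
flat_table <- function(n = 5, thresholds = rep(10, n), well = "A1",
                       duration = 100) {
  wf_len <- waveform_samples(1, 2, 12500)
  spike_table(
    tibble(well = well, electrode = 1L, recording_id = "R1",
           timestamp_s = seq_len(n) * duration / (n + 1),
           crossing_threshold_uv = thresholds,
           waveform_uv = rep(list(rep(1, wf_len)), n)),
    tibble(recording_id = "R1", duration_s = duration),
    tiny_layout())
}

# one electrode, several neurons with well-separated template amplitudes,
# spikes spread over `n_rec` recordings: the separable sorting fixture
electrode_fixture <- function(n_per = c(60, 60, 60),
                              amps = c(15, 60, 240),
                              n_rec = 1, duration = 1800, noise_sd = 1,
                              seed = 1) {
  set.seed(seed)
  rate <- 12500
  widths <- c(0.08, 0.22, 0.45)
  rebounds <- c(0.2, 0.35, 0.5)
  reb_at <- c(0.5, 0.9, 1.4)
  ev <- purrr::map2(seq_along(n_per), n_per, function(j, n) {
    tmpl <- spike_template(amps[j], rate,
                           rebound_ratio = rebounds[(j - 1) %% 3 + 1],
                           trough_width_ms = widths[(j - 1) %% 3 + 1],
                           rebound_at_ms = reb_at[(j - 1) %% 3 + 1])
    tibble(well = "A1", electrode = 1L,
           recording_id = sample(paste0("R", seq_len(n_rec)), n,
                                 replace = TRUE),
           timestamp_s = sort(runif(n, 0, duration)),
           crossing_threshold_uv = 13.75,
           waveform_uv = purrr::map(seq_len(n), function(i)
             tmpl + rnorm(length(tmpl), 0, noise_sd)),
           truth_neuron = paste0("n", j))
  }) %>% bind_rows()
  spike_table(ev, tibble(recording_id = paste0("R", seq_len(n_rec)),
                         duration_s = duration),
              tiny_layout())
}

# --- independent STTC oracle -------------------------------------------------
# T by sweep-line occupancy over interval boundaries; P by full distance
# matrix. Deliberately a different algorithm from the package's merge/
# findInterval implementation.
sttc_oracle <- function(a, b, duration, dt = 0.1) {
  tile <- function(x) {
    lo <- pmax(x - dt, 0); hi <- pmin(x + dt, duration)
    pts <- sort(unique(c(lo, hi)))
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    covered <- vapply(mids, function(m) any(lo <= m & m <= hi), TRUE)
    sum((pts[-1] - pts[-length(pts)])[covered]) / duration
  }
  near_frac <- function(x, y) mean(apply(abs(outer(x, y, "-")), 1, min) <= dt)
  ta <- tile(a); tb <- tile(b)
  pa <- near_frac(a, b); pb <- near_frac(b, a)
  term <- function(p, t) if (1 - p * t == 0) 0 else (p - t) / (1 - p * t)
  0.5 * (term(pa, tb) + term(pb, ta))
}

# adjusted Rand index (independent oracle via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# amplitude LME simulation with a planted per-treatment recording shift
amplitude_sim <- function(effect_treated, n_exp = 3, n_elec = 6,
                          n_clus = 2, n_ev = 25, resid_sd = 0.05,
                          seed = 1) {
  set.seed(seed)
  exp_off <- rnorm(n_exp, 0, 0.05)
  grid <- tidyr::crossing(experiment = paste0("E", seq_len(n_exp)),
                          electrode = paste0("e", seq_len(n_elec)),
                          cluster_idx = seq_len(n_clus)) %>%
    mutate(cluster = paste(experiment, electrode, cluster_idx, sep = "_"),
           exp_off = exp_off[as.integer(factor(.data$experiment))],
           elec_off = rnorm(dplyr::n(), 0, 0.08),
           clus_base = log10(50) + rnorm(dplyr::n(), 0, 0.15),
           # treatments split across electrodes within each experiment
           treatment = ifelse(as.integer(factor(.data$electrode)) <=
                                n_elec / 2, "media", "treated"))
  tidyr::crossing(grid, recording = c("pre", "post"),
                  ev = seq_len(n_ev)) %>%
    mutate(shift = ifelse(.data$treatment == "treated" &
                            .data$recording == "post", effect_treated, 0),
           log10_uv = .data$clus_base + .data$exp_off + .data$elec_off +
             .data$shift + rnorm(dplyr::n(), 0, resid_sd),
           recording = factor(.data$recording, levels = c("pre", "post"))) %>%
    select("log10_uv", "treatment", "recording", "cluster", "electrode",
           "experiment")
}

# array-level frequency simulation with a planted treated post shift
frequency_sim <- function(effect_treated, n_exp = 3, n_arrays = 16,
                          sd_array = 0.4, resid_sd = 0.15, seed = 1) {
  set.seed(seed)
  exp_off <- rnorm(n_exp, 0, 0.2)
  tidyr::crossing(experiment = paste0("E", seq_len(n_exp)),
                  array = seq_len(n_arrays)) %>%
    mutate(
      exp_off = exp_off[as.integer(factor(.data$experiment))],
      base = -0.8 + .data$exp_off + rnorm(dplyr::n(), 0, sd_array),
      treatment = ifelse(.data$array <= n_arrays / 2, "media", "treated")) %>%
    tidyr::crossing(recording = c("pre", "post")) %>%
    mutate(shift = ifelse(.data$treatment == "treated" &
                            .data$recording == "post", effect_treated, 0),
           log10_hz = .data$base + .data$shift +
             rnorm(dplyr::n(), 0, resid_sd),
           recording = factor(.data$recording, levels = c("pre", "post"))) %>%
    select("log10_hz", "treatment", "recording", "experiment")
}
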