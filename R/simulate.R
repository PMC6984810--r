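#' Extracellular potential of a line current source
#'
#' A firing neuron modelled as a point source of current gives the Coulomb
#' potential V = I / (4 pi d sigma); because neurons are better approximated
#' by cylinders much longer than their radius, the linear source
#' approximation (LSA) refines this to
#' `V_e = I / (4 pi sigma ds) * log|(sqrt(h^2 + r^2) - h) /
#' (sqrt(l^2 + r^2) - l)|` with `l = h + ds`, where `ds` is the cylinder
#' length, `r` the radial distance from the cylinder and `h` the
#' longitudinal distance from its near end. For `r >> ds` the LSA converges
#' to the point-source value at distance `r`. The simulator uses this
#' geometry to set waveform amplitudes (~10-100 uV at realistic distances),
#' making amplitude independent of firing rate.
#'
#' @param i Source current, A.
#' @param sigma Extracellular conductivity, S/m (default 0.3).
#' @param delta_s Cylinder (source) length, m.
#' @param r Radial distance from the cylinder, m (> 0).
#' @param h Longitudinal distance from the cylinder end, m.
#' @return Extracellular potential, volts.
#' @export
lsa_amplitude <- function(i, sigma = 0.3, delta_s = 50e-6, r, h = 0) {
  if (any(r <= 0)) abort("`r` must be positive (the formula is singular at r = 0).")
  if (any(sigma <= 0) || any(delta_s <= 0))
    abort("`sigma` and `delta_s` must be positive.")
  l <- h + delta_s
  i / (4 * pi * sigma * delta_s) *
    abs(log((sqrt(h^2 + r^2) - h) / (sqrt(l^2 + r^2) - l)))
}

#' Biphasic spike waveform template
#'
#' Two-phase extracellular spike shape: a negative Gaussian trough shortly
#' after the crossing sample followed by a positive rebound. The
#' peak-to-valley amplitude equals `amplitude_uv`; `rebound_ratio` sets the
#' rebound height relative to the trough depth.
#'
#' @param amplitude_uv Peak-to-valley amplitude, uV.
#' @param rate Sampling rate, Hz.
#' @param pre_ms,post_ms Window convention (crossing sample at
#'   `floor(pre_ms * rate / 1000)`, 0-based).
#' @param rebound_ratio Rebound peak / trough depth (default 0.3).
#' @param trough_width_ms,rebound_width_ms Gaussian widths, ms.
#' @param trough_at_ms,rebound_at_ms Phase centres relative to the
#'   crossing, ms.
#' @return Numeric waveform vector of length
#'   [waveform_samples()]`(pre_ms, post_ms, rate)`.
#' @export
spike_template <- function(amplitude_uv, rate = 12500, pre_ms = 1,
                           post_ms = 2, rebound_ratio = 0.3,
                           trough_width_ms = 0.2, rebound_width_ms = 0.45,
                           trough_at_ms = 0.2, rebound_at_ms = 0.9) {
  n <- waveform_samples(pre_ms, post_ms, rate)
  i0 <- floor(pre_ms * rate / 1000)  # 0-based crossing index
  t_ms <- (seq_len(n) - 1 - i0) / rate * 1000
  depth <- amplitude_uv / (1 + rebound_ratio)
  -depth * exp(-(t_ms - trough_at_ms)^2 / (2 * trough_width_ms^2)) +
    depth * rebound_ratio *
      exp(-(t_ms - rebound_at_ms)^2 / (2 * rebound_width_ms^2))
}

#' Simulate spike trains with optional pairwise coupling
#'
#' Uncoupled neurons fire as homogeneous Poisson processes at their target
#' rates. A coupled group (assembly) shares a parent Poisson process whose
#' rate is the smallest target in the group: each parent event is copied
#' into each member's train with probability `parent_share` and Gaussian
#' timing jitter, and independent residual spikes top each train up to its
#' target rate. Because all members of an assembly share the same parent,
#' every within-assembly pair is coupled, so assemblies of three or more
#' neurons produce closed triangles in the inferred functional network.
#'
#' @param rates Numeric vector of target rates, Hz (>= 0).
#' @param duration Recording duration, seconds.
#' @param coupled_groups List of integer index vectors (each length >= 2),
#'   or a 2-column matrix of index pairs, or `NULL` for no coupling.
#' @param parent_share Probability a parent event appears in each member.
#' @param jitter_sd_ms SD of the copy-time jitter, ms.
#' @param seed Integer seed.
#' @return List with `trains` (list of sorted spike-time vectors) and
#'   `coupled_pairs` (tibble of all within-group index pairs).
#' @export
simulate_trains <- function(rates, duration, coupled_groups = NULL,
                            parent_share = 0.8, jitter_sd_ms = 5,
                            seed = 1) {
  if (any(rates < 0)) abort("rates must be >= 0.")
  if (is.matrix(coupled_groups))
    coupled_groups <- lapply(seq_len(nrow(coupled_groups)),
                             function(k) coupled_groups[k, ])
  n <- length(rates)
  trains <- vector("list", n)
  resid_rate <- rates
  withr_seed(seed, {
    for (grp in coupled_groups) {
      grp <- as.integer(grp)
      lam <- min(rates[grp])
      parent <- runif(rpois(1, lam * duration), 0, duration)
      for (child in grp) {
        keep <- parent[runif(length(parent)) < parent_share]
        keep <- keep + rnorm(length(keep), 0, jitter_sd_ms / 1000)
        keep <- pmin(pmax(keep, 0), duration)
        trains[[child]] <- c(trains[[child]], keep)
        resid_rate[child] <- max(0, resid_rate[child] - parent_share * lam)
      }
    }
    for (i in seq_len(n)) {
      extra <- runif(rpois(1, resid_rate[i] * duration), 0, duration)
      trains[[i]] <- sort(c(trains[[i]], extra))
    }
  })
  pairs <- NULL
  if (length(coupled_groups) > 0) {
    pairs <- purrr::map(coupled_groups, function(g) {
      cmb <- utils::combn(sort(as.integer(g)), 2)
      tibble(a = cmb[1, ], b = cmb[2, ])
    }) %>% bind_rows()
  }
  list(trains = trains, coupled_pairs = pairs)
}

#' Simulator configuration
#'
#' Collects every knob of the synthetic plate generator with defaults that
#' emulate a mature primary cortical culture on a 96-well, 8-electrode
#' plate sampled at 12.5 kHz: log-normal array firing rates (log10 Hz mean
#' -0.8, SD 0.55), 1-3 neurons per electrode with Gamma-weighted rate
#' shares, biphasic templates whose amplitudes come from LSA geometry
#' (independent of rate), Gaussian background noise, day-to-day latent rate
#' correlation 0.8, and optional per-group treatment multipliers by phase.
#'
#' @param ... Overrides for any default field (see `sim_config()` output).
#' @return A list of simulator settings (class `sim_config`).
#' @export
sim_config <- function(...) {
  cfg <- list(
    layout = plate_layout(),
    recordings = tibble(recording_id = "R1", duration_s = 1800,
                        phase = "pre"),
    neurons_per_electrode = 1:3,
    array_log_rate = c(mean = -0.8, sd = 0.55),
    within_array_shape = 1,
    coupling = list(fraction = 0, parent_share = 0.8, jitter_sd_ms = 5),
    day_correlation = 0.8,
    noise_sd = 2.5,
    k_sd = 5.5,
    pre_ms = 1, post_ms = 2,
    geometry = list(current_a = c(2e-9, 10e-9), sigma = 0.3,
                    delta_s = 50e-6, r = c(20e-6, 100e-6), h = c(0, 50e-6)),
    rebound_ratio = c(0.2, 0.5),
    trough_width_ms = c(0.12, 0.3),
    rebound_width_ms = c(0.3, 0.6),
    groups = NULL,            # tibble(well, group); NULL = no treatment
    effects = NULL,           # tibble(group, phase, rate_mult, amp_mult)
    waveforms = TRUE,
    seed = 1)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0)
    abort(paste0("unknown sim_config field(s): ", paste(bad, collapse = ", ")))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "sim_config"
  cfg
}

#' Apply treatment effects to the simulator's ground-truth rates
#'
#' Multiplies each neuron's per-recording rate and template amplitude by
#' its group's configured multipliers for the recording's phase; phases or
#' groups without an entry are untouched (multiplier 1). A washout phase
#' restores firing simply by configuring its multiplier back to 1.
#'
#' @param rates Tibble with `neuron_id`, `recording_id`, `phase`, `group`,
#'   `rate_hz`, `amplitude_uv`.
#' @param effects Tibble with `group`, `phase`, `rate_mult`, `amp_mult`, or
#'   `NULL` for no treatment.
#' @return `rates` with multipliers applied.
#' @export
apply_treatment <- function(rates, effects) {
  if (is.null(effects) || nrow(effects) == 0) return(rates)
  if (!all(effects$group %in% unique(rates$group)))
    abort("effects reference unknown group(s).")
  rates %>%
    left_join(effects, by = c("group", "phase")) %>%
    mutate(rate_mult = ifelse(is.na(.data$rate_mult), 1, .data$rate_mult),
           amp_mult = ifelse(is.na(.data$amp_mult), 1, .data$amp_mult),
           rate_hz = .data$rate_hz * .data$rate_mult,
           amplitude_uv = .data$amplitude_uv * .data$amp_mult) %>%
    select(-"rate_mult", -"amp_mult")
}

runif_in <- function(n, range) runif(n, range[1], range[2])

#' Simulate a multi-well MEA plate with ground truth
#'
#' Generates a complete synthetic experiment: per-array latent log10 rates
#' drawn from the configured normal, carried across recordings with the
#' residual-orthogonalization construction at the configured day-to-day
#' correlation; neuron-level rates partitioning each array's rate through
#' Gamma weights; spike times by (optionally coupled) Poisson processes;
#' waveforms as LSA-scaled biphasic templates plus Gaussian sample noise;
#' and treatment multipliers applied per group and phase. Every event is
#' labelled with its true neuron so each downstream stage can be scored
#' against ground truth.
#'
#' @param config A [sim_config()].
#' @return List with `table` (a `spike_table` carrying `truth_neuron`) and
#'   `truth` (list: `neurons`, `rates` per recording, `coupled_pairs`,
#'   `groups`).
#' @export
simulate_plate <- function(config = sim_config()) {
  lay <- config$layout
  recs <- config$recordings
  if (lay$n_wells < 1) abort("infeasible config: no wells.")
  wells <- lay$well_labels
  nw <- length(wells)
  rate <- lay$sampling_rate
  n_samp <- waveform_samples(config$pre_ms, config$post_ms, rate)
  seed <- config$seed

  # latent array log10 rates, correlated across recordings
  latent <- matrix(NA_real_, nw, nrow(recs))
  withr_seed(seed, {
    latent[, 1] <- rnorm(nw, config$array_log_rate["mean"],
                         config$array_log_rate["sd"])
  })
  if (nrow(recs) > 1) {
    for (k in 2:nrow(recs)) {
      if (sd(latent[, k - 1]) == 0) {
        latent[, k] <- latent[, k - 1]
      } else {
        latent[, k] <- correlated_followup(latent[, k - 1],
                                           config$day_correlation,
                                           seed = seed + 7919L * k)
      }
    }
  }

  # neuron registry
  neurons <- NULL
  coupled <- NULL
  assemblies <- NULL
  withr_seed(seed + 1L, {
    per_elec <- sample(config$neurons_per_electrode,
                       nw * lay$electrodes_per_well, replace = TRUE)
    reg <- tidyr::crossing(well = wells,
                           electrode = seq_len(lay$electrodes_per_well)) %>%
      arrange(.data$well, .data$electrode)
    reg <- reg[rep(seq_len(nrow(reg)), per_elec), ]
    nn <- nrow(reg)
    geo <- config$geometry
    amp_v <- lsa_amplitude(runif_in(nn, geo$current_a), geo$sigma,
                           geo$delta_s, runif_in(nn, geo$r),
                           runif_in(nn, geo$h))
    neurons <- reg %>% mutate(
      neuron_id = paste0(.data$well, "_", .data$electrode, "_n",
                         stats::ave(seq_len(nn),
                                    paste(.data$well, .data$electrode),
                                    FUN = seq_along)),
      amplitude_uv = amp_v * 1e6,
      rebound_ratio = runif_in(nn, config$rebound_ratio),
      trough_width_ms = runif_in(nn, config$trough_width_ms),
      rebound_width_ms = runif_in(nn, config$rebound_width_ms),
      weight = rgamma(nn, shape = config$within_array_shape))
    # a coupled assembly within each well: `fraction` of the well's neurons
    # share one parent process, so all within-assembly pairs are coupled
    if (config$coupling$fraction > 0) {
      assemblies <- lapply(split(neurons$neuron_id, neurons$well),
                           function(ids) {
        k <- round(config$coupling$fraction * length(ids))
        if (k >= 2) sample(ids, k) else character(0)
      })
      assemblies <- assemblies[lengths(assemblies) >= 2]
      if (length(assemblies) > 0) {
        coupled <- purrr::map(assemblies, function(ids) {
          cmb <- utils::combn(sort(ids), 2)
          tibble(neuron_a = cmb[1, ], neuron_b = cmb[2, ])
        }) %>% bind_rows()
      }
    }
  })

  groups <- config$groups
  if (is.null(groups)) groups <- tibble(well = wells, group = "none")

  # per-recording true neuron rates (well rate partitioned by weights)
  wsum <- neurons %>% group_by(.data$well) %>%
    summarise(wsum = sum(.data$weight), .groups = "drop")
  rates <- tidyr::crossing(neurons %>% select("neuron_id", "well",
                                              "electrode", "weight",
                                              "amplitude_uv"),
                           tibble(recording_id = recs$recording_id,
                                  phase = recs$phase,
                                  kk = seq_len(nrow(recs)))) %>%
    left_join(wsum, by = "well") %>%
    left_join(groups, by = "well") %>%
    mutate(well_rate = 10^latent[cbind(match(.data$well, wells), .data$kk)],
           rate_hz = .data$well_rate * .data$weight / .data$wsum) %>%
    select("neuron_id", "well", "electrode", "recording_id", "phase",
           "group", "rate_hz", "amplitude_uv")
  rates <- apply_treatment(rates, config$effects)

  # spike times per recording
  thr <- max(config$k_sd * config$noise_sd, 1)
  ev_list <- list()
  for (k in seq_len(nrow(recs))) {
    rk <- rates %>% filter(.data$recording_id == recs$recording_id[k])
    rk <- rk[match(neurons$neuron_id, rk$neuron_id), ]
    grp_idx <- NULL
    if (!is.null(assemblies) && length(assemblies) > 0)
      grp_idx <- lapply(assemblies, match, table = neurons$neuron_id)
    tr <- simulate_trains(rk$rate_hz, recs$duration_s[k],
                          coupled_groups = grp_idx,
                          parent_share = config$coupling$parent_share,
                          jitter_sd_ms = config$coupling$jitter_sd_ms,
                          seed = seed + 104729L * k)
    counts <- lengths(tr$trains)
    if (sum(counts) == 0) next
    ev <- tibble(
      well = rep(neurons$well, counts),
      electrode = rep(neurons$electrode, counts),
      recording_id = recs$recording_id[k],
      timestamp_s = unlist(tr$trains),
      crossing_threshold_uv = thr,
      truth_neuron = rep(neurons$neuron_id, counts))
    if (config$waveforms) {
      tmpl <- purrr::pmap(
        list(rep(rk$amplitude_uv, counts),
             rep(neurons$rebound_ratio, counts),
             rep(neurons$trough_width_ms, counts),
             rep(neurons$rebound_width_ms, counts)),
        function(a, rr, tw, rw)
          spike_template(a, rate, config$pre_ms, config$post_ms,
                         rebound_ratio = rr, trough_width_ms = tw,
                         rebound_width_ms = rw))
      withr_seed(seed + 224737L * k, {
        noise <- matrix(rnorm(length(tmpl) * n_samp, 0, config$noise_sd),
                        nrow = length(tmpl))
        ev$waveform_uv <- purrr::map(seq_along(tmpl), function(ii)
          tmpl[[ii]] + noise[ii, ])
      })
    } else {
      ev$waveform_uv <- rep(list(numeric(n_samp)), nrow(ev))
    }
    ev_list[[k]] <- ev
  }
  events <- bind_rows(ev_list)
  if (nrow(events) == 0) {
    events <- tibble(well = character(), electrode = integer(),
                     recording_id = character(), timestamp_s = numeric(),
                     crossing_threshold_uv = numeric(), waveform_uv = list(),
                     truth_neuron = character())
  }
  tab <- spike_table(events, recs, lay, pre_ms = config$pre_ms,
                     post_ms = config$post_ms)
  list(table = tab,
       truth = list(neurons = neurons, rates = rates,
                    coupled_pairs = coupled, groups = groups))
}

#' Synthesize a raw voltage trace for one electrode
#'
#' Sums template waveforms at Poisson spike times on a white Gaussian noise
#' floor, with an optional 2nd-order zero-phase Butterworth band-pass
#' mirroring acquisition filtering. Intended for exercising
#' [detect_spikes()]; event-level generation ([simulate_plate()]) is the
#' bulk path.
#'
#' @param rates Target firing rates, Hz (one per neuron).
#' @param amplitudes_uv Template amplitudes, uV (one per neuron).
#' @param duration Trace duration, seconds (<= 60).
#' @param noise_sd Background noise SD, uV.
#' @param rate Sampling rate, Hz.
#' @param bandpass `NULL` or `c(low_hz, high_hz)` (e.g. c(200, 2500)).
#' @param seed Integer seed.
#' @return List with `trace` (numeric vector) and `truth` (tibble of
#'   `neuron`, `time_s`).
#' @export
synth_raw_trace <- function(rates, amplitudes_uv, duration = 10,
                            noise_sd = 2.5, rate = 12500, bandpass = NULL,
                            seed = 1) {
  if (duration > 60) abort("raw-trace mode is capped at 60 s.")
  n <- as.integer(round(duration * rate))
  truth <- list()
  withr_seed(seed, {
    trace <- rnorm(n, 0, noise_sd)
    for (j in seq_along(rates)) {
      tmpl <- spike_template(amplitudes_uv[j], rate)
      times <- runif(rpois(1, rates[j] * duration), 0.005,
                     duration - 0.005)
      i0 <- floor(1 * rate / 1000)
      for (t in times) {
        s <- as.integer(round(t * rate)) - i0
        idx <- s + seq_along(tmpl)
        trace[idx] <- trace[idx] + tmpl
      }
      truth[[j]] <- tibble(neuron = j, time_s = sort(times))
    }
  })
  if (!is.null(bandpass)) {
    bf <- signal::butter(2, bandpass / (rate / 2), type = "pass")
    trace <- as.numeric(signal::filtfilt(bf, trace))
  }
  list(trace = trace, truth = bind_rows(truth))
}
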