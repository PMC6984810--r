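#' Remove spike events detected at aberrantly high crossing thresholds
#'
#' Sporadic electrical noise can transiently inflate the background potential,
#' so a dynamically computed crossing threshold occasionally calls spurious
#' "spikes" at very high threshold values. Within each recording (the noise
#' regime is recording-specific) the mean and SD of the crossing threshold
#' over all events are computed, and events whose threshold exceeds
#' mean + 3 SD are excluded.
#'
#' @param table A `spike_table`.
#' @param pool_recordings If `TRUE`, compute one mean/SD over all recordings
#'   pooled instead of per recording.
#' @return A list with `table` (filtered `spike_table`) and `qc`, a tibble of
#'   per-recording event counts, exclusions and the threshold limit applied.
#' @export
filter_high_noise_spikes <- function(table, pool_recordings = FALSE) {
  ev <- table$events
  if (nrow(ev) < 2) {
    qc <- tibble(recording_id = unique(ev$recording_id),
                 n_in = nrow(ev), n_excluded = 0L, limit_uv = NA_real_)
    return(list(table = table, qc = qc))
  }
  grp <- if (pool_recordings) rep("all", nrow(ev)) else ev$recording_id
  lim_by <- tapply(ev$crossing_threshold_uv, grp, function(v) {
    if (length(v) < 2) Inf else mean(v) + 3 * sd(v)
  })
  lim <- unname(lim_by[grp])
  keep <- ev$crossing_threshold_uv <= lim
  qc <- tibble(recording_id = ev$recording_id, kept = keep,
               limit_uv = lim) %>%
    group_by(.data$recording_id) %>%
    summarise(n_in = dplyr::n(), n_excluded = sum(!.data$kept),
              limit_uv = .data$limit_uv[1], .groups = "drop")
  table$events <- ev[keep, , drop = FALSE]
  list(table = table, qc = qc)
}

#' Array-level firing-rate metrics
#'
#' Aggregates all electrodes of each well within each recording: the mean
#' firing rate is MFR = n / s (total spikes over recording duration in
#' seconds) and its log transform uses log10((n + 1) / s) so that silent
#' arrays (n = 0) remain finite. Every well in the layout is reported for
#' every recording, including wells with zero spikes.
#'
#' @param table A `spike_table` (typically after
#'   [filter_high_noise_spikes()]).
#' @param wells Optional character vector restricting the reported wells;
#'   defaults to all wells in the layout.
#' @return Tibble with `well`, `recording_id`, `n_spikes`, `duration_s`,
#'   `mfr` (Hz) and `log_mfr` (log10 Hz).
#' @export
array_activity <- function(table, wells = NULL) {
  if (is.null(wells)) wells <- table$layout$well_labels
  counts <- table$events %>%
    filter(.data$well %in% wells) %>%
    count(.data$well, .data$recording_id, name = "n_spikes")
  tidyr::crossing(well = wells,
                  recording_id = table$recordings$recording_id) %>%
    left_join(counts, by = c("well", "recording_id")) %>%
    mutate(n_spikes = ifelse(is.na(.data$n_spikes), 0L, .data$n_spikes)) %>%
    left_join(table$recordings[, c("recording_id", "duration_s")],
              by = "recording_id") %>%
    mutate(mfr = .data$n_spikes / .data$duration_s,
           log_mfr = log10((.data$n_spikes + 1) / .data$duration_s)) %>%
    arrange(.data$recording_id, .data$well)
}

#' Compute the mean firing rate for one array
#'
#' @param n_spikes Total spike count across the well's electrodes.
#' @param duration_s Recording duration in seconds (> 0).
#' @return Tibble with `n_spikes`, `mfr` and `log_mfr`.
#' @examples
#' compute_mfr(1800, 1800) # mfr = 1 Hz
#' @export
compute_mfr <- function(n_spikes, duration_s) {
  if (any(duration_s <= 0)) abort("`duration_s` must be positive.")
  tibble(n_spikes = n_spikes,
         mfr = n_spikes / duration_s,
         log_mfr = log10((n_spikes + 1) / duration_s))
}

#' Select active arrays for an experiment
#'
#' Arrays firing far below the plate's typical level are excluded before
#' cohort assignment: the cut-off is 2 SD below the median log10 firing rate
#' of the sample set, and arrays at or above the cut survive.
#'
#' @param activity Tibble with at least `well` and `log_mfr` (one row per
#'   array; use [array_activity()] on a single baseline recording).
#' @param k_sd Number of SDs below the median (default 2).
#' @return The input tibble with a logical `active` column; the threshold is
#'   stored in attribute `"threshold"`.
#' @export
select_active_arrays <- function(activity, k_sd = 2) {
  if (nrow(activity) < 2) abort("need at least 2 arrays.")
  thr <- median(activity$log_mfr) - k_sd * sd(activity$log_mfr)
  out <- activity %>% mutate(active = .data$log_mfr >= thr)
  attr(out, "threshold") <- thr
  out
}

moving_rms <- function(v, w) {
  # Robust centred moving RMS: sqrt of the running median of the squared
  # signal, rescaled so that on pure Gaussian noise it estimates the noise
  # SD (median(x^2) = qchisq(0.5, 1) * sigma^2). The median (rather than
  # the mean) keeps a spike from inflating the background estimate inside
  # its own window, which would otherwise mask the spike it sits on.
  k <- if (w %% 2 == 1) w else w + 1
  med_sq <- stats::runmed(v^2, k, endrule = "median")
  sqrt(pmax(med_sq, 0) / stats::qchisq(0.5, df = 1))
}

#' Threshold-crossing spike detection on a raw voltage trace
#'
#' Detects spikes where the absolute voltage exceeds `k_sd` times the RMS of
#' the background potential, estimated over a centred 10-ms moving window.
#' The background RMS is computed robustly (running median of the squared
#' signal, rescaled to be unbiased for Gaussian noise) so that a spike does
#' not raise the threshold inside its own window. Crossings within `refractory_ms` of a
#' prior detection are suppressed, and the waveform window around each
#' crossing is extracted per the interchange convention. Intended for
#' synthetic traces from [synth_raw_trace()].
#'
#' @param trace Numeric voltage series, uV.
#' @param rate Sampling rate, Hz.
#' @param k_sd Threshold multiplier (default 5.5 SD of the RMS background).
#' @param rms_window_ms Moving-window length, ms (default 10).
#' @param pre_ms,post_ms Waveform window, ms.
#' @param refractory_ms Dead time after a detection, ms (default 1).
#' @return Tibble with `timestamp_s`, `crossing_threshold_uv` and
#'   `waveform_uv` (list-column).
#' @export
detect_spikes <- function(trace, rate, k_sd = 5.5, rms_window_ms = 10,
                          pre_ms = 1, post_ms = 2, refractory_ms = 1) {
  if (!all(is.finite(trace))) abort("trace contains non-finite samples.")
  w <- max(3L, as.integer(round(rms_window_ms / 1000 * rate)))
  if (length(trace) <= w) abort("trace shorter than the RMS window.")
  thr <- k_sd * moving_rms(trace, w)
  over <- abs(trace) > thr
  idx <- which(over & !c(FALSE, over[-length(over)]))  # rising edges
  n_pre <- as.integer(floor(pre_ms * rate / 1000))
  n_post <- as.integer(floor(post_ms * rate / 1000))
  refr <- refractory_ms / 1000 * rate
  kept <- integer(0)
  last <- -Inf
  for (i in idx) {
    if (i - last >= refr && i - n_pre >= 1 && i + n_post <= length(trace)) {
      kept <- c(kept, i)
      last <- i
    }
  }
  tibble(timestamp_s = (kept - 1) / rate,
         crossing_threshold_uv = thr[kept],
         waveform_uv = purrr::map(kept, function(i)
           trace[(i - n_pre):(i + n_post)]))
}
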