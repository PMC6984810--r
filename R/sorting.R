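#' Waveform shape features for spike sorting
#'
#' From each spike's voltage waveform the following metrics are computed:
#' maximum voltage (peak), minimum voltage (valley), amplitude (peak minus
#' valley), the time interval between peak and valley (ms), the signed
#' trapezoidal area under the curve (uV ms), and the non-linear energy (NLE),
#' a per-sample sharpness measure Psi(x_n) = x_n^2 - x_{n-1} x_{n+1}
#' summarized here by its maximum over the interior samples.
#'
#' @param waveform Numeric voltage vector, uV (length >= 3).
#' @param rate Sampling rate, Hz.
#' @param nle_summary `"max"` (default) or `"mean"` of Psi over interior
#'   samples.
#' @return One-row tibble with `peak`, `valley`, `amplitude`,
#'   `peak_valley_interval_ms`, `auc`, `nle`.
#' @export
extract_features <- function(waveform, rate, nle_summary = c("max", "mean")) {
  nle_summary <- match.arg(nle_summary)
  v <- as.numeric(waveform)
  n <- length(v)
  if (n < 3) abort("waveform must have length >= 3.")
  pk <- max(v)
  vl <- min(v)
  i_pk <- which.max(v)
  i_vl <- which.min(v)
  dt_ms <- 1000 / rate
  psi <- v[2:(n - 1)]^2 - v[1:(n - 2)] * v[3:n]
  tibble(peak = pk, valley = vl, amplitude = pk - vl,
         peak_valley_interval_ms = abs(i_pk - i_vl) * dt_ms,
         auc = sum((v[-1] + v[-n]) / 2) * dt_ms,
         nle = if (nle_summary == "max") max(psi) else mean(psi))
}

feature_matrix <- function(waveforms, rate, nle_summary = "max") {
  purrr::map(waveforms, extract_features, rate = rate,
             nle_summary = nle_summary) %>% bind_rows()
}

#' Log-PCA embedding of waveform features
#'
#' Builds the six-column shape-feature matrix for a set of spike events,
#' log-transforms each metric as log(|x| + eps) (natural log; magnitudes
#' are logged because valley, AUC and NLE can be non-positive),
#' mean-centres the columns, and projects the events onto the first two
#' principal components. The natural log keeps the embedding on the scale
#' at which the default mean-shift bandwidth h = 1.5 resolves distinct
#' waveform templates.
#'
#' @param features Tibble from [extract_features()] (one row per event).
#' @param eps Offset inside the log (default 1e-6).
#' @param scale. Scale columns to unit variance before PCA (default `FALSE`,
#'   centring only).
#' @return Matrix with `n` rows and 2 columns (`PC1`, `PC2` scores);
#'   `var(PC1) >= var(PC2)`.
#' @export
embed_features <- function(features, eps = 1e-6, scale. = FALSE) {
  m <- log(abs(as.matrix(features)) + eps)
  if (nrow(m) < 3) abort("need at least 3 events to embed.")
  if (scale.) {
    keep <- apply(m, 2, sd) > 0
    m[, !keep] <- 0
    if (any(keep)) m[, keep] <- scale(m[, keep])
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
  } else {
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
  }
  scores <- pc$x
  if (ncol(scores) == 1) scores <- cbind(scores, 0)
  out <- scores[, 1:2, drop = FALSE]
  colnames(out) <- c("PC1", "PC2")
  out
}

#' Gaussian mean-shift clustering
#'
#' Mode-seeking clustering on a kernel density estimate: each point is
#' iteratively shifted to the Gaussian-kernel-weighted mean of all points
#' (kernel exp(-d^2 / (2 h^2))) until its displacement falls below `tol` or
#' `max_iter` is reached. Converged positions within `h / 10` of one another
#' are merged into a single mode; every point receives exactly one label and
#' modes are numbered in discovery order. Unlike k-means, the number of
#' clusters is not specified in advance: the bandwidth `h` controls the
#' smoothing of the density, with small `h` proliferating modes and large
#' `h` collapsing everything onto a single maximum.
#'
#' @param points Numeric matrix (n x d) of embedded points.
#' @param bandwidth Kernel bandwidth `h` (default 1.5).
#' @param tol Convergence tolerance on per-iteration displacement.
#' @param max_iter Maximum shift iterations.
#' @return List with `labels` (integer per point) and `modes` (matrix of
#'   mode coordinates, one row per cluster).
#' @export
mean_shift <- function(points, bandwidth = 1.5, tol = 1e-6, max_iter = 300) {
  p <- as.matrix(points)
  if (!all(is.finite(p))) abort("points must be finite.")
  if (bandwidth <= 0) abort("bandwidth must be positive.")
  n <- nrow(p)
  x <- p
  denom <- 2 * bandwidth^2
  active <- rep(TRUE, n)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    xa <- x[active, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), rowSums(p^2), `+`) - 2 * tcrossprod(xa, p)
    w <- exp(-pmax(d2, 0) / denom)
    new_x <- (w %*% p) / rowSums(w)
    shift <- sqrt(rowSums((new_x - xa)^2))
    x[active, ] <- new_x
    active[active] <- shift >= tol
  }
  merge_r <- bandwidth / 10
  modes <- matrix(numeric(0), ncol = ncol(p))
  labels <- integer(n)
  for (i in seq_len(n)) {
    if (nrow(modes) > 0) {
      d <- sqrt(rowSums((modes - matrix(x[i, ], nrow(modes), ncol(p),
                                        byrow = TRUE))^2))
      j <- which(d < merge_r)
    } else j <- integer(0)
    if (length(j) > 0) {
      labels[i] <- j[1]
    } else {
      modes <- rbind(modes, x[i, ])
      labels[i] <- nrow(modes)
    }
  }
  list(labels = labels, modes = modes)
}

#' Map a cluster mode to its nearest member waveform
#'
#' A mean-shift mode occupies a position in principal-component space that
#' need not coincide with any observed waveform; the representative event of
#' a cluster is the member with minimum Euclidean distance to the mode
#' (ties broken by lowest index).
#'
#' @param mode Numeric vector (mode coordinates).
#' @param member_points Matrix of member coordinates (one row per member).
#' @return Index (into `member_points`) of the representative member.
#' @export
map_centroid <- function(mode, member_points) {
  m <- as.matrix(member_points)
  if (nrow(m) == 0) abort("no members.")
  d2 <- rowSums((m - matrix(mode, nrow(m), ncol(m), byrow = TRUE))^2)
  which.min(d2)  # which.min returns the first (lowest index) on ties
}

#' Recording-independent unsupervised spike sorting
#'
#' For each electrode, pools the spike events detected across *all*
#' recordings of the experiment, computes waveform shape features, embeds
#' them by log-PCA, clusters the embedding with Gaussian mean-shift, and
#' maps each mode to its representative waveform. Pooling across recordings
#' is essential for longitudinal experiments: sorting each recording
#' separately over-segregates sparse recordings and scrambles cluster
#' identities between sessions. Cluster ids are stable strings
#' `{well}_{electrode}_{k}`.
#'
#' @param table A filtered `spike_table`.
#' @param bandwidth Mean-shift bandwidth `h` (default 1.5).
#' @param by_recording If `TRUE`, sorts each recording separately
#'   (recording-dependent mode, provided for comparison only; cluster ids
#'   then carry the recording id).
#' @param min_events Electrodes with fewer events than this form a single
#'   flagged cluster (default 3).
#' @return List with `table` (the input with a `cluster_id` event column)
#'   and `clusters`, a tibble of per-cluster summaries: electrode key,
#'   `cluster_id`, `n_events`, PC-space centroid, representative event row
#'   and its amplitude, and a `flagged` marker for low-count electrodes.
#' @export
sort_spikes <- function(table, bandwidth = 1.5, by_recording = FALSE,
                        min_events = 3) {
  ev <- table$events
  rate <- table$layout$sampling_rate
  ev$.row <- seq_len(nrow(ev))
  key <- if (by_recording)
    paste(ev$well, ev$electrode, ev$recording_id, sep = "\r")
  else paste(ev$well, ev$electrode, sep = "\r")
  cluster_id <- character(nrow(ev))
  clusters <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    sub <- ev[rows, , drop = FALSE]
    prefix <- paste(sub$well[1], sub$electrode[1], sep = "_")
    if (by_recording) prefix <- paste(prefix, sub$recording_id[1], sep = "_")
    if (length(rows) < min_events) {
      feats <- feature_matrix(sub$waveform_uv, rate)
      cid <- paste0(prefix, "_1")
      cluster_id[rows] <- cid
      clusters[[length(clusters) + 1]] <- tibble(
        well = sub$well[1], electrode = sub$electrode[1], cluster_id = cid,
        n_events = length(rows), centroid_pc1 = NA_real_,
        centroid_pc2 = NA_real_, representative_row = sub$.row[1],
        representative_amplitude = feats$amplitude[1], flagged = TRUE)
      next
    }
    feats <- feature_matrix(sub$waveform_uv, rate)
    emb <- embed_features(feats)
    ms <- mean_shift(emb, bandwidth = bandwidth)
    for (j in seq_len(nrow(ms$modes))) {
      members <- which(ms$labels == j)
      rep_local <- map_centroid(ms$modes[j, ], emb[members, , drop = FALSE])
      rep_row <- sub$.row[members[rep_local]]
      cid <- paste0(prefix, "_", j)
      cluster_id[rows[members]] <- cid
      clusters[[length(clusters) + 1]] <- tibble(
        well = sub$well[1], electrode = sub$electrode[1], cluster_id = cid,
        n_events = length(members), centroid_pc1 = ms$modes[j, 1],
        centroid_pc2 = ms$modes[j, 2], representative_row = rep_row,
        representative_amplitude = feats$amplitude[members[rep_local]],
        flagged = FALSE)
    }
  }
  ev$cluster_id <- cluster_id
  ev$.row <- NULL
  table$events <- ev
  list(table = table, clusters = bind_rows(clusters))
}

#' Per-cluster firing frequency in each recording
#'
#' Counts the events attributed to each cluster in each recording and
#' divides by the recording duration; clusters silent in a recording are
#' reported with 0 Hz (the zero inflation of cluster rates is itself a
#' phenotype).
#'
#' @param sorted A `spike_table` carrying `cluster_id` (from
#'   [sort_spikes()]).
#' @return Tibble with `cluster_id`, `recording_id`, `n_spikes`,
#'   `duration_s`, `hz`.
#' @export
cluster_frequencies <- function(sorted) {
  ev <- sorted$events
  if (!"cluster_id" %in% names(ev)) abort("events carry no cluster_id; run sort_spikes().")
  counts <- ev %>% count(.data$cluster_id, .data$recording_id,
                         name = "n_spikes")
  tidyr::crossing(cluster_id = unique(ev$cluster_id),
                  recording_id = sorted$recordings$recording_id) %>%
    left_join(counts, by = c("cluster_id", "recording_id")) %>%
    mutate(n_spikes = ifelse(is.na(.data$n_spikes), 0L, .data$n_spikes)) %>%
    left_join(sorted$recordings[, c("recording_id", "duration_s")],
              by = "recording_id") %>%
    mutate(hz = .data$n_spikes / .data$duration_s)
}

#' Classify a cluster's longitudinal firing paradigm
#'
#' Across chronologically ordered recordings, a cluster's activity pattern
#' falls into one of four paradigms: `persistent` (active in every
#' recording), `lost` (active initially, then silent with no reactivation),
#' `recovering` (active initially, silent for one or more interim
#' recordings, then active again), or `emergent` (silent initially, active
#' later). A non-monotone pattern that starts silent (e.g. F,T,F) is
#' classified emergent by its onset; subsequent silence does not reclassify
#' it.
#'
#' @param active Logical vector (length >= 2) of per-recording activity,
#'   chronological; at least one element must be `TRUE`.
#' @return One of `"persistent"`, `"lost"`, `"recovering"`, `"emergent"`.
#' @export
classify_pattern <- function(active) {
  v <- as.logical(active)
  if (length(v) < 2) abort("need at least 2 recordings.")
  if (!any(v)) abort("all-silent vector: no such cluster exists.")
  if (!v[1]) return("emergent")
  if (all(v)) return("persistent")
  first_gap <- which(!v)[1]
  if (any(v[first_gap:length(v)])) "recovering" else "lost"
}

#' Longitudinal firing paradigms for all clusters
#'
#' Applies [classify_pattern()] to each cluster's per-recording activity
#' ("active" means at least one attributed spike), with recordings ordered
#' as in the table's recording metadata.
#'
#' @param sorted A `spike_table` with `cluster_id`.
#' @return Tibble with `cluster_id`, `pattern` and per-recording activity in
#'   list-column `active`.
#' @export
cluster_patterns <- function(sorted) {
  freq <- cluster_frequencies(sorted)
  rec_order <- sorted$recordings$recording_id
  freq %>%
    mutate(recording_id = factor(.data$recording_id, levels = rec_order)) %>%
    arrange(.data$cluster_id, .data$recording_id) %>%
    group_by(.data$cluster_id) %>%
    summarise(active = list(.data$n_spikes > 0), .groups = "drop") %>%
    mutate(pattern = purrr::map_chr(.data$active, classify_pattern))
}
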