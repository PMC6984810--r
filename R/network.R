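tiling_fraction <- function(times, dt, duration) {
  # total length of the union of [t - dt, t + dt], clipped to [0, duration]
  lo <- pmax(times - dt, 0)
  hi <- pmin(times + dt, duration)
  total <- 0
  cur_lo <- lo[1]
  cur_hi <- hi[1]
  if (length(times) > 1) {
    for (i in 2:length(times)) {
      if (lo[i] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[i])
      } else {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- lo[i]
        cur_hi <- hi[i]
      }
    }
  }
  (total + (cur_hi - cur_lo)) / duration
}

prop_within <- function(a, b, dt) {
  # fraction of a's spikes within +/- dt of any spike of b (b sorted)
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, length(b))
  near <- abs(a - b[lo]) <= dt | abs(a - b[hi]) <= dt
  mean(near)
}

#' Spike time tiling coefficient
#'
#' A correlation index for a pair of spike trains that is robust to firing
#' rate differences. With T_X the fraction of the recording tiled by +/- dt
#' windows around train X's spikes (overlapping windows merged, clipped to
#' the recording), and P_X the fraction of X's spikes falling within +/- dt
#' of any spike of the other train:
#' STTC = 1/2 * ((P_A - T_B) / (1 - P_A T_B) + (P_B - T_A) / (1 - P_B T_A)).
#' A term whose denominator is zero (a train's tiles cover the whole
#' recording) contributes 0.
#'
#' @param a,b Sorted spike-time vectors (seconds), both non-empty.
#' @param duration Recording duration, seconds.
#' @param dt Coincidence window, seconds (default 0.1, i.e. 100 ms).
#' @return STTC value in [-1, 1].
#' @export
sttc <- function(a, b, duration, dt = 0.1) {
  if (length(a) == 0 || length(b) == 0)
    abort("sttc is undefined for an empty spike train.")
  a <- sort(a)
  b <- sort(b)
  ta <- tiling_fraction(a, dt, duration)
  tb <- tiling_fraction(b, dt, duration)
  pa <- prop_within(a, b, dt)
  pb <- prop_within(b, a, dt)
  term <- function(p, t) {
    den <- 1 - p * t
    if (den == 0) 0 else (p - t) / den
  }
  0.5 * (term(pa, tb) + term(pb, ta))
}

#' Permutation null distribution for the STTC
#'
#' Generates `n_perm` pairs of random spike trains with the observed event
#' counts (uniform order statistics on [0, duration], the timing structure
#' of a homogeneous Poisson process conditioned on its count) and computes
#' the STTC of each pair; the requested empirical quantiles bound the STTC
#' values expected by chance for trains of these rates. A spike-time shuffle
#' null that permutes one train's inter-event intervals is available via
#' `method = "shuffle"`.
#'
#' @param n_a,n_b Event counts of the two trains (>= 1).
#' @param duration Recording duration, seconds.
#' @param dt Coincidence window, seconds.
#' @param n_perm Number of permutations (default 1000).
#' @param quantiles Two-sided quantile pair (default c(0.005, 0.995): total
#'   chance mass 1%).
#' @param seed Integer seed.
#' @param method `"uniform"` (default) or `"shuffle"`.
#' @param a,b Observed trains, required for `method = "shuffle"`.
#' @return List with `null_lo`, `null_hi` and the full `null_values` vector.
#' @export
sttc_null <- function(n_a, n_b, duration, dt = 0.1, n_perm = 1000,
                      quantiles = c(0.005, 0.995), seed = 1,
                      method = c("uniform", "shuffle"), a = NULL, b = NULL) {
  method <- match.arg(method)
  if (method == "uniform" && (n_a < 1 || n_b < 1))
    abort("event counts must be >= 1.")
  vals <- numeric(n_perm)
  withr_seed(seed, {
    for (i in seq_len(n_perm)) {
      if (method == "uniform") {
        ra <- sort(runif(n_a, 0, duration))
        rb <- sort(runif(n_b, 0, duration))
      } else {
        if (is.null(a) || is.null(b))
          abort("`a` and `b` are required for the shuffle null.")
        ra <- cumsum(sample(diff(c(0, sort(a)))))
        rb <- cumsum(sample(diff(c(0, sort(b)))))
      }
      vals[i] <- sttc(ra, rb, duration, dt)
    }
  })
  q <- quantile(vals, quantiles, names = FALSE)
  list(null_lo = q[1], null_hi = q[2], null_values = vals)
}

#' Call functional edges from observed STTC values and null bounds
#'
#' An observed STTC represents a functional connection when it falls outside
#' the central interval of its pair-specific null distribution — i.e. the
#' coupling (in-phase or out-of-phase) is stronger than expected by chance
#' with probability below the two-sided mass of the quantile pair.
#'
#' @param pairs Tibble with `cluster_a`, `cluster_b`, `sttc`, `null_lo`,
#'   `null_hi`.
#' @return The input with a logical `is_edge` column.
#' @export
call_edges <- function(pairs) {
  pairs %>% mutate(is_edge = .data$sttc < .data$null_lo |
                     .data$sttc > .data$null_hi)
}

#' Average local clustering coefficient of a functional network
#'
#' The Watts-Strogatz network cluster coefficient: the mean over nodes of
#' the local clustering coefficient (closed triangles through a node over
#' possible triangles), with isolates and degree-1 nodes contributing zero.
#'
#' @param nodes Character vector of node ids.
#' @param edges Tibble with `cluster_a`, `cluster_b` (undirected pairs), or
#'   a 2-column matrix/data frame.
#' @return Clustering coefficient in [0, 1]; 0 for an empty graph.
#' @export
clustering_coefficient <- function(nodes, edges) {
  if (length(nodes) == 0) return(0)
  ed <- as.data.frame(edges)[, 1:2, drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  if (igraph::ecount(g) == 0) return(0)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Infer per-array functional networks from sorted spike trains
#'
#' For each well and recording, forms the spike train of every cluster with
#' at least one attributed spike, computes all pairwise STTC values,
#' generates a count-matched permutation null for each pair (nulls are
#' cached per event-count pair within a recording), calls edges against the
#' null quantiles, and computes the network clustering coefficient.
#'
#' @param sorted A `spike_table` with `cluster_id` (from [sort_spikes()]).
#' @param dt Coincidence window, seconds (default 0.1).
#' @param n_perm Permutations per null (default 1000).
#' @param quantiles Two-sided null quantiles (default c(0.005, 0.995)).
#' @param seed Integer seed.
#' @return List with `edges` (tibble: well, recording_id, cluster pair,
#'   sttc, null bounds, `is_edge`) and `networks` (tibble: well,
#'   recording_id, `n_nodes`, `n_edges`, `cbar`).
#' @export
build_networks <- function(sorted, dt = 0.1, n_perm = 1000,
                           quantiles = c(0.005, 0.995), seed = 1) {
  ev <- sorted$events
  if (!"cluster_id" %in% names(ev)) abort("run sort_spikes() first.")
  recs <- sorted$recordings
  edge_rows <- list()
  net_rows <- list()
  combos <- ev %>% distinct(.data$well, .data$recording_id)
  for (i in seq_len(nrow(combos))) {
    w <- combos$well[i]
    r <- combos$recording_id[i]
    dur <- recs$duration_s[match(r, recs$recording_id)]
    sub <- ev %>% filter(.data$well == w, .data$recording_id == r)
    trains <- split(sub$timestamp_s, sub$cluster_id)
    trains <- trains[lengths(trains) > 0]
    ids <- names(trains)
    pair_list <- list()
    null_cache <- list()
    if (length(ids) >= 2) {
      cmb <- utils::combn(length(ids), 2)
      for (j in seq_len(ncol(cmb))) {
        ia <- cmb[1, j]; ib <- cmb[2, j]
        na <- length(trains[[ia]]); nb <- length(trains[[ib]])
        obs <- sttc(trains[[ia]], trains[[ib]], dur, dt)
        key <- paste(sort(c(na, nb)), collapse = "_")
        if (is.null(null_cache[[key]])) {
          null_cache[[key]] <- sttc_null(
            na, nb, dur, dt, n_perm = n_perm, quantiles = quantiles,
            seed = seed + i * 1000L + length(null_cache))
        }
        nl <- null_cache[[key]]
        pair_list[[j]] <- tibble(
          well = w, recording_id = r,
          cluster_a = ids[ia], cluster_b = ids[ib], sttc = obs,
          null_lo = nl$null_lo, null_hi = nl$null_hi,
          n_permutations = n_perm)
      }
    }
    pairs <- bind_rows(pair_list)
    if (nrow(pairs) > 0) pairs <- call_edges(pairs)
    edges_only <- if (nrow(pairs) > 0)
      pairs %>% filter(.data$is_edge) else pairs
    cbar <- clustering_coefficient(
      ids, if (nrow(edges_only) > 0)
        edges_only[, c("cluster_a", "cluster_b")]
      else tibble(cluster_a = character(), cluster_b = character()))
    edge_rows[[i]] <- pairs
    net_rows[[i]] <- tibble(well = w, recording_id = r,
                            n_nodes = length(ids),
                            n_edges = nrow(edges_only), cbar = cbar)
  }
  list(edges = bind_rows(edge_rows), networks = bind_rows(net_rows))
}
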