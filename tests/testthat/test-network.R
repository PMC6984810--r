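test_that("STTC matches hand-evaluated cases", {
  # identical trains with T < 1
  expect_equal(sttc(c(1, 2, 3), c(1, 2, 3), 10), 1)
  # far-apart singletons: P = 0, T = 0.02 each
  expect_equal(sttc(1.0, 5.0, 10, 0.1), -0.02)
  # coincident within dt: P = 1 both ways
  expect_equal(sttc(1.0, 1.05, 10, 0.1), 1)
  expect_error(sttc(numeric(0), 1, 10), "empty")
})

test_that("STTC agrees with a brute-force oracle and is symmetric and bounded", {
  set.seed(16)
  for (i in 1:30) {
    dur <- runif(1, 20, 120)
    a <- sort(runif(sample(2:100, 1), 0, dur))
    b <- sort(runif(sample(2:100, 1), 0, dur))
    v <- sttc(a, b, dur)
    expect_equal(v, sttc_oracle(a, b, dur), tolerance = 1e-12)
    expect_equal(v, sttc(b, a, dur), tolerance = 1e-12)
    expect_true(abs(v) <= 1)
  }
})

test_that("tiling merges overlapping windows instead of inflating T", {
  # a dense burst: union of windows, not their sum
  burst <- seq(1, 1.05, by = 0.001)   # 51 spikes in 50 ms
  v <- sttc(burst, 5, 10, dt = 0.1)
  expect_equal(v, sttc_oracle(burst, 5, 10), tolerance = 1e-12)
  # T for the burst is (0.05 + 0.2) / 10, far below 51 * 0.2 / 10
  one_term <- (0 - 0.25 / 10) / (1 - 0)
  expect_equal(v, 0.5 * (one_term + (0 - 0.02) / 1), tolerance = 1e-12)
})

test_that("the permutation null is centred, two-sided, and seed-deterministic", {
  n1 <- sttc_null(50, 50, 600, n_perm = 400, seed = 1)
  expect_lt(n1$null_lo, 0)
  expect_gt(n1$null_hi, 0)
  se <- sd(n1$null_values) / sqrt(length(n1$null_values))
  expect_lte(abs(mean(n1$null_values)), 3 * se)
  n2 <- sttc_null(50, 50, 600, n_perm = 400, seed = 1)
  expect_identical(n1$null_values, n2$null_values)
  expect_error(sttc_null(0, 10, 600), ">= 1")
})

test_that("edges are called outside the null band in either direction", {
  pairs <- tibble(cluster_a = c("a", "a", "b"), cluster_b = c("b", "c", "c"),
                  sttc = c(0.9, 0.1, -0.8),
                  null_lo = c(-0.3, -0.3, -0.2),
                  null_hi = c(0.3, 0.3, 0.2))
  out <- call_edges(pairs)
  expect_identical(out$is_edge, c(TRUE, FALSE, TRUE))
})

test_that("clustering coefficient matches hand-computed graphs", {
  k3 <- tibble(cluster_a = c("1", "2", "3"), cluster_b = c("2", "3", "1"))
  expect_equal(clustering_coefficient(c("1", "2", "3"), k3), 1)
  path <- tibble(cluster_a = c("1", "2"), cluster_b = c("2", "3"))
  expect_equal(clustering_coefficient(c("1", "2", "3"), path), 0)
  # isolates count as zeros: K3 plus an isolate
  expect_equal(clustering_coefficient(c("1", "2", "3", "4"), k3), 0.75)
  expect_equal(clustering_coefficient(character(0), k3[0, ]), 0)
})

test_that("coupled simulator trains yield high STTC and are recovered as edges", {
  sim <- simulate_trains(rates = c(2, 2), duration = 600,
                         coupled_groups = cbind(1, 2), parent_share = 1,
                         jitter_sd_ms = 0, seed = 2)
  expect_equal(sttc(sim$trains[[1]], sim$trains[[2]], 600), 1)

  # jittered, partial sharing: still far outside the null
  recall <- vapply(1:10, function(s) {
    sim <- simulate_trains(rates = c(1.5, 1.5), duration = 600,
                           coupled_groups = cbind(1, 2), parent_share = 0.8,
                           jitter_sd_ms = 5, seed = 10 + s)
    obs <- sttc(sim$trains[[1]], sim$trains[[2]], 600)
    nl <- sttc_null(length(sim$trains[[1]]), length(sim$trains[[2]]), 600,
                    n_perm = 300, seed = s)
    obs > nl$null_hi || obs < nl$null_lo
  }, TRUE)
  expect_gte(mean(recall), 0.8)
})

test_that("independent trains trigger edges at about the nominal 1% rate", {
  set.seed(17)
  n_pairs <- 150
  calls <- logical(n_pairs)
  cache <- list()
  for (k in seq_len(n_pairs)) {
    na <- sample(20:40, 1); nb <- sample(20:40, 1)
    a <- sort(runif(na, 0, 600)); b <- sort(runif(nb, 0, 600))
    key <- paste(sort(c(na, nb)), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- sttc_null(na, nb, 600, n_perm = 1000, seed = k)
    nl <- cache[[key]]
    obs <- sttc(a, b, 600)
    calls[k] <- obs < nl$null_lo || obs > nl$null_hi
  }
  se <- sqrt(0.01 * 0.99 / n_pairs)
  expect_lte(abs(mean(calls) - 0.01), 3 * se)
})

test_that("per-array networks assemble nodes, edges and C-bar", {
  # one well, one active cluster: trivial network
  tab <- electrode_fixture(n_per = c(20), amps = c(60), seed = 5)
  srt <- sort_spikes(tab)
  if (length(unique(srt$table$events$cluster_id)) == 1) {
    nets <- build_networks(srt$table, n_perm = 100, seed = 1)
    expect_identical(nets$networks$n_nodes, 1L)
    expect_identical(nets$networks$n_edges, 0L)
    expect_equal(nets$networks$cbar, 0)
  }

  # plate with coupled neurons: C-bar increases with coupling fraction
  cbar_at <- function(frac, seed) {
    cfg <- sim_config(
      layout = plate_layout(n_wells = 4, electrodes_per_well = 3,
                            n_rows = 2),
      recordings = tibble(recording_id = "R1", duration_s = 600,
                          phase = "pre"),
      neurons_per_electrode = 2,
      array_log_rate = c(mean = 0.4, sd = 0.1),
      coupling = list(fraction = frac, parent_share = 0.9,
                      jitter_sd_ms = 5),
      seed = seed)
    sim <- simulate_plate(cfg)
    # score against ground-truth neuron identity to isolate network recovery
    tab <- sim$table
    tab$events$cluster_id <- tab$events$truth_neuron
    nets <- build_networks(tab, n_perm = 300, seed = seed)
    mean(nets$networks$cbar)
  }
  lo <- mean(vapply(1:3, function(s) cbar_at(0, s), 0))
  hi <- mean(vapply(1:3, function(s) cbar_at(1, 100 + s), 0))
  expect_gt(hi, lo)
  expect_lt(lo, 0.1)
})

test_that("ground-truth coupled pairs are recovered as edges within wells", {
  recalls <- vapply(1:5, function(s) {
    cfg <- sim_config(
      layout = plate_layout(n_wells = 2, electrodes_per_well = 3,
                            n_rows = 1),
      recordings = tibble(recording_id = "R1", duration_s = 600,
                          phase = "pre"),
      neurons_per_electrode = 2,
      array_log_rate = c(mean = 0.5, sd = 0.1),
      coupling = list(fraction = 0.8, parent_share = 0.8, jitter_sd_ms = 5),
      seed = 200 + s)
    sim <- simulate_plate(cfg)
    tab <- sim$table
    tab$events$cluster_id <- tab$events$truth_neuron
    nets <- build_networks(tab, n_perm = 300, seed = s)
    cp <- sim$truth$coupled_pairs
    e <- nets$edges
    row <- purrr::map2_lgl(e$cluster_a, e$cluster_b, function(x, y) {
      any((cp$neuron_a == x & cp$neuron_b == y) |
            (cp$neuron_a == y & cp$neuron_b == x))
    })
    mean(e$is_edge[row])
  }, 0)
  expect_gte(mean(recalls), 0.8)
})
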