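test_that("closed-form one-way F agrees with aov on random pools", {
  set.seed(2)
  for (i in 1:5) {
    y <- rnorm(40)
    g <- sample(rep(1:4, 10))
    f_fast <- assignment_f(tibble(group = g, log_mfr = y))
    f_aov <- summary(aov(y ~ factor(g)))[[1]]$`F value`[1]
    expect_equal(f_fast, f_aov, tolerance = 1e-10)
  }
})

test_that("minimum-F assignment behaves on degenerate and structured pools", {
  # identical rates: F = 0 whatever the assignment
  pool0 <- tibble(well = paste0("w", 1:16), log_mfr = 0)
  p0 <- assign_groups(pool0, sizes = c(8, 8), iterations = 50, seed = 1)
  expect_equal(p0$f_statistic, 0)
  expect_identical(sort(table(tidy(p0)$group), decreasing = TRUE),
                   sort(table(c(rep("g1", 8), rep("g2", 8))),
                        decreasing = TRUE))
  # determinism
  p0b <- assign_groups(pool0, sizes = c(8, 8), iterations = 50, seed = 1)
  expect_identical(tidy(p0)$well, tidy(p0b)$well)
  # infeasible sizes
  expect_error(assign_groups(pool0, sizes = c(10, 10), iterations = 5),
               "exceeds")
})

test_that("selected F beats the plate-row assignment on a row-structured plate", {
  # plate with a strong row gradient, mirroring the 88-of-89, 8x11 scenario
  set.seed(9)
  lay <- plate_layout()
  rows <- substr(lay$well_labels, 1, 1)
  log_mfr <- -0.8 + 0.15 * (match(rows, LETTERS) - 4.5) + rnorm(96, 0, 0.3)
  pool <- tibble(well = lay$well_labels, log_mfr = log_mfr)[1:89, ][-89, ]
  plan <- assign_groups(pool, sizes = rep(11, 8), iterations = 2000,
                        seed = 42)
  row_assign <- tibble(group = substr(pool$well, 1, 1),
                       log_mfr = pool$log_mfr)
  expect_lte(plan$f_statistic, assignment_f(row_assign))
  # selected F is also <= the median F of fresh random candidates
  set.seed(10)
  rand_f <- vapply(1:200, function(i) {
    idx <- sample.int(88, 88)
    assignment_f(tibble(group = rep(paste0("g", 1:8), each = 11),
                        log_mfr = pool$log_mfr[idx]))
  }, 0)
  expect_lte(plan$f_statistic, median(rand_f))
})

test_that("correlated follow-up has exactly the requested sample correlation", {
  set.seed(4)
  A <- rnorm(200, -0.8, 0.55)
  expect_identical(correlated_followup(A, 1, seed = 2), A)
  for (rho in c(0, 0.5, 0.8, -0.6)) {
    B <- correlated_followup(A, rho, seed = 3)
    expect_equal(cor(A, B), rho, tolerance = 1e-6)
    expect_equal(sd(B), sd(A), tolerance = 1e-6)
  }
  # exactness holds for every seed, not merely in expectation
  for (s in 1:10)
    expect_equal(cor(A, correlated_followup(A, 0.8, seed = s)), 0.8,
                 tolerance = 1e-6)
  expect_error(correlated_followup(rep(1, 10), 0.5), "constant")
})

test_that("ANCOVA treatment test returns a Tukey-adjusted post contrast", {
  # identical groups: zero estimate, p = 1
  set.seed(5)
  pre <- rnorm(8, -0.8, 0.5)
  post <- rnorm(8, -0.8, 0.5)
  d <- tibble(log_hz = c(pre, post, pre, post),
              group = rep(c("control", "treatment"), each = 16),
              time = rep(rep(c("pre", "post"), each = 8), 2))
  r <- ancova_treatment_test(d)
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  # Tukey adjustment never undercuts the raw pairwise t on the same contrast
  set.seed(6)
  d2 <- d %>% mutate(log_hz = .data$log_hz + rnorm(32, 0, 0.2))
  r2 <- ancova_treatment_test(d2)
  fit <- aov(log_hz ~ group * time, data = d2)
  s2 <- sum(resid(fit)^2) / fit$df.residual
  tstat <- r2$estimate / sqrt(s2 * (1 / 8 + 1 / 8))
  raw_p <- 2 * stats::pt(-abs(tstat), fit$df.residual)
  expect_gte(r2$p_value, raw_p - 1e-12)
  expect_true(r2$p_value >= 0 && r2$p_value <= 1)
  expect_error(ancova_treatment_test(d[c(1, 9, 17, 25), ]), "at least 2")
})

test_that("a strong offset is detected in nearly every simulated experiment", {
  # Monte-Carlo oracle: n = 8/group, effect -2.0, within-group SD 0.5, rho 0.8
  set.seed(11)
  hits <- vapply(1:500, function(i) {
    A <- rnorm(16, -0.8, 0.5)
    B <- 0.8 * A + rnorm(16, 0, 0.5 * sqrt(1 - 0.64))
    d <- tibble(log_hz = c(A[1:8], B[1:8], A[9:16], B[9:16] - 2.0),
                group = rep(c("control", "treatment"), each = 16),
                time = rep(rep(c("pre", "post"), each = 8), 2))
    ancova_treatment_test(d)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("power grid is calibrated at zero effect and monotone in n and effect", {
  set.seed(12)
  baseline <- rnorm(600, -0.8, 0.55)
  pg0 <- power_grid(baseline, rho = 0.8, sample_sizes = 8,
                    effect_sizes = 0, iterations = 400, seed = 5)
  p0 <- pg0$grid$power
  se <- sqrt(0.05 * 0.95 / 400)
  # extracting one Tukey-adjusted contrast makes the test conservative at
  # the family level: the zero-effect rejection rate must not exceed alpha
  expect_lte(p0, 0.05 + 3 * se)
  expect_gte(p0, 0)

  pg <- power_grid(baseline, rho = 0.8, sample_sizes = c(4, 10),
                   effect_sizes = c(0.5, 1.5), iterations = 150, seed = 6)
  g <- pg$grid
  mc <- 3 * sqrt(0.25 / 150)   # worst-case Monte-Carlo SE
  for (e in unique(g$effect))
    expect_gte(g$power[g$n == 10 & g$effect == e] + mc,
               g$power[g$n == 4 & g$effect == e])
  for (n in unique(g$n))
    expect_gte(g$power[g$n == n & g$effect == 1.5] + mc,
               g$power[g$n == n & g$effect == 0.5])
  expect_true(all(g$power >= 0 & g$power <= 1))
  expect_error(power_grid(baseline, sample_sizes = integer(0),
                          effect_sizes = 0.5), "empty")
})

test_that("n = 3 reaches 80% power only for very large effects", {
  set.seed(13)
  baseline <- rnorm(600, -0.8, 0.55)
  pg <- power_grid(baseline, rho = 0.8, sample_sizes = 3,
                   effect_sizes = 2.0, iterations = 300, seed = 7)
  expect_gte(pg$grid$power, 0.8)
})

test_that("the full published grid enumerates 1.4e6 simulated treatments", {
  expect_equal(count_simulated_treatments(3:16, seq(0.1, 2.0, by = 0.1),
                                          5000), 1.4e6)
  expect_identical(nrow(power_grid_design(3:16, seq(0.1, 2, 0.1))), 280L)
})

test_that("duration-correlation curve saturates logarithmically", {
  # identical plates: rho = 1 at every interval
  cfg <- sim_config(layout = tiny_layout(12, 2), seed = 21,
                    waveforms = FALSE,
                    recordings = tibble(recording_id = "R1",
                                        duration_s = 600, phase = "pre"))
  day1 <- simulate_plate(cfg)$table
  cc <- duration_correlation_curve(day1, day1, step_minutes = 2)
  expect_true(all(abs(cc$curve$rho - 1) < 1e-12))

  # independent plates: correlations near zero
  day2 <- simulate_plate(sim_config(layout = tiny_layout(12, 2), seed = 99,
                                    waveforms = FALSE,
                                    recordings = cfg$recordings))$table
  cc0 <- duration_correlation_curve(day1, day2, step_minutes = 2)
  expect_lt(mean(abs(cc0$curve$rho)), 0.5)
})

test_that("shared latent rates reproduce the day-to-day correlation plateau", {
  # sparse firing so that short intervals are dominated by counting noise:
  # the curve then rises with accumulated duration, as in repeated-recording
  # experiments
  res <- purrr::map(1:8, function(s) {
    cfg <- sim_config(
      layout = plate_layout(n_wells = 48, electrodes_per_well = 2,
                            n_rows = 6),
      recordings = tibble(recording_id = c("D1", "D2"),
                          duration_s = 1800, phase = "pre"),
      array_log_rate = c(mean = -1.8, sd = 0.55),
      day_correlation = 0.8, waveforms = FALSE, seed = 300 + s)
    tab <- simulate_plate(cfg)$table
    one_day <- function(rid) {
      t2 <- tab
      t2$events <- tab$events %>% filter(.data$recording_id == rid)
      t2$recordings <- tab$recordings %>%
        filter(.data$recording_id == rid)
      t2
    }
    cc <- duration_correlation_curve(one_day("D1"), one_day("D2"),
                                     step_minutes = 3)
    list(slope = unname(cc$log_fit["slope"]),
         rho_first = cc$curve$rho[1],
         rho_last = cc$curve$rho[nrow(cc$curve)])
  })
  slopes <- purrr::map_dbl(res, "slope")
  rho30 <- purrr::map_dbl(res, "rho_last")
  rho_first <- purrr::map_dbl(res, "rho_first")
  expect_gt(median(slopes), 0)                  # increasing, concave in t
  expect_gt(median(rho30 - rho_first), 0)
  expect_gte(median(rho30), 0.7)                # plateau near the latent rho
})
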