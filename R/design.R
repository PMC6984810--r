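oneway_f <- function(y, g) {
  # closed-form one-way ANOVA F; g integer group codes 1..k
  n <- length(y)
  k <- max(g)
  ni <- tabulate(g, k)
  sums <- rowsum(y, g)
  mi <- sums / ni
  gm <- sum(y) / n
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[g])^2)
  if (ssw <= 0) return(if (ssb <= 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Minimum-F bootstrap assignment of treatment groups
#'
#' Firing rates vary widely and non-uniformly across the wells of a plate,
#' so assigning cohorts by plate row can produce groups that differ before
#' any treatment. Instead, `iterations` candidate assignments are generated
#' by randomly allocating wells to groups (without replacement), a one-way
#' ANOVA of `log_mfr` on group is evaluated for each, and the assignment
#' with the lowest F statistic (most comparable pre-treatment activity) is
#' selected. Unbalanced designs and multi-plate pools are supported.
#'
#' @param pool Tibble with columns `well` and `log_mfr`; typically the
#'   active arrays from [select_active_arrays()].
#' @param sizes Integer vector of group sizes (one entry per group); their
#'   sum must not exceed the pool size.
#' @param iterations Number of candidate assignments (default 1e4).
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param group_labels Optional labels, default `"g1"..`.
#' @return An `assignment_plan`: list with `assignment` (tibble of `well`,
#'   `group`, `log_mfr`), `f_statistic`, `iterations`, `seed`, `sizes`.
#' @export
assign_groups <- function(pool, sizes, iterations = 1e4, seed = 1,
                          group_labels = paste0("g", seq_along(sizes))) {
  sizes <- as.integer(sizes)
  if (sum(sizes) > nrow(pool))
    abort("sum of group sizes exceeds the pool size.")
  if (length(group_labels) != length(sizes))
    abort("`group_labels` must match `sizes` in length.")
  y <- pool$log_mfr
  n_assigned <- sum(sizes)
  gcode <- rep(seq_along(sizes), sizes)
  best_f <- Inf
  best_idx <- NULL
  withr_seed(seed, {
    for (i in seq_len(iterations)) {
      idx <- sample.int(nrow(pool), n_assigned)
      f <- oneway_f(y[idx], gcode)
      if (f < best_f) {
        best_f <- f
        best_idx <- idx
      }
    }
  })
  assignment <- tibble(well = pool$well[best_idx],
                       group = group_labels[gcode],
                       log_mfr = y[best_idx])
  structure(list(assignment = assignment, f_statistic = best_f,
                 iterations = iterations, seed = seed, sizes = sizes),
            class = "assignment_plan")
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  force(code)
}

#' @export
print.assignment_plan <- function(x, ...) {
  cat(sprintf("<assignment_plan> %d wells -> %d groups | F = %.4g (%d candidates, seed %d)\n",
              nrow(x$assignment), length(x$sizes), x$f_statistic,
              x$iterations, x$seed))
  invisible(x)
}

#' @export
tidy.assignment_plan <- function(x, ...) x$assignment

#' @export
glance.assignment_plan <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, n_groups = length(x$sizes),
         n_assigned = nrow(x$assignment), iterations = x$iterations,
         seed = x$seed)
}

#' One-way ANOVA F statistic of an assignment
#'
#' Convenience for comparing a candidate assignment (e.g. the plate-row
#' assignment) against a minimum-F plan on the same pool.
#'
#' @param assignment Tibble with `group` and `log_mfr`.
#' @return The F statistic.
#' @export
assignment_f <- function(assignment) {
  g <- as.integer(factor(assignment$group))
  oneway_f(assignment$log_mfr, g)
}

#' Construct a follow-up vector with an exact sample correlation
#'
#' Given baseline log10 firing rates `A` at time t0, a follow-up vector `B`
#' representing t1 is constructed as `B = rho * A + A_perp * sqrt(1 - rho^2)`
#' where `A_perp` is the residual of regressing an independent standard
#' normal draw on `A`, rescaled to zero mean and the SD of `A`. Because the
#' regression residuals are exactly orthogonal to `A` in sample, the sample
#' Pearson correlation cor(A, B) equals `rho` exactly (the rescaling step is
#' what makes the identity hold, not merely in expectation).
#'
#' @param baseline Numeric vector of log10 Hz (length >= 3, non-constant).
#' @param rho Target correlation in [-1, 1].
#' @param seed Integer seed for the normal draw.
#' @return Numeric vector `B` of the same length.
#' @export
correlated_followup <- function(baseline, rho, seed = 1) {
  if (length(baseline) < 3) abort("`baseline` must have length >= 3.")
  if (sd(baseline) == 0) abort("`baseline` is constant; correlation undefined.")
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  if (abs(rho) == 1) return(rho * baseline)
  withr_seed(seed, {
    z <- rnorm(length(baseline))
  })
  r <- resid(lm(z ~ baseline))
  a_perp <- r / sd(r) * sd(baseline)
  rho * baseline + a_perp * sqrt(1 - rho^2)
}

#' Repeated-measures ANCOVA treatment test
#'
#' Fits the two-factor linear model `log10Hz ~ group * time` on long-format
#' data (one row per array per time point), applies Tukey's honest
#' significant difference over the four group-by-time cell means, and
#' returns the adjusted p value and estimate for the control-vs-treatment
#' contrast at the post time point.
#'
#' @param data Long tibble with columns `log_hz`, `group` (levels
#'   "control"/"treatment") and `time` (levels "pre"/"post").
#' @return Tibble with `estimate` (treatment minus control at post),
#'   `p_value` (Tukey-adjusted) and `conf_low`/`conf_high`.
#' @export
ancova_treatment_test <- function(data) {
  data <- data %>%
    mutate(group = factor(.data$group, levels = c("control", "treatment")),
           time = factor(.data$time, levels = c("pre", "post")))
  cells <- data %>% count(.data$group, .data$time)
  if (nrow(cells) < 4 || any(cells$n < 2))
    abort("each group x time cell needs at least 2 observations.")
  fit <- aov(log_hz ~ group * time, data = data)
  tk <- TukeyHSD(fit, "group:time")[["group:time"]]
  row <- which(rownames(tk) %in% c("treatment:post-control:post",
                                   "control:post-treatment:post"))
  est <- tk[row, "diff"]
  if (rownames(tk)[row] == "control:post-treatment:post") est <- -est
  tibble(estimate = unname(est),
         p_value = unname(tk[row, "p adj"]),
         conf_low = unname(tk[row, "lwr"]),
         conf_high = unname(tk[row, "upr"]))
}

#' Grid layout for a power simulation
#'
#' @param sample_sizes Integer vector of per-group replicate counts.
#' @param effect_sizes Numeric vector of treatment offsets (delta log10 Hz).
#' @return Tibble of all sample-size by effect-size cells.
#' @export
power_grid_design <- function(sample_sizes = 3:16,
                              effect_sizes = seq(0.1, 2.0, by = 0.1)) {
  tidyr::crossing(n = as.integer(sample_sizes), effect = effect_sizes)
}

#' Count the simulated treatments implied by a power grid
#'
#' @inheritParams power_grid_design
#' @param iterations Iterations per cell.
#' @return Total number of simulated treatments (cells x iterations).
#' @examples
#' count_simulated_treatments(3:16, seq(0.1, 2, 0.1), 5000) # 1.4e6
#' @export
count_simulated_treatments <- function(sample_sizes, effect_sizes,
                                       iterations) {
  nrow(power_grid_design(sample_sizes, effect_sizes)) * iterations
}

#' Monte-Carlo power surface for a two-condition repeated-measures design
#'
#' For each sample-size by effect-size cell, experiments are simulated by
#' drawing paired (t0, t1) log10 firing rates from the baseline population
#' (`t1` generated with [correlated_followup()] at correlation `rho`),
#' offsetting the treatment group's post values by the effect size,
#' analysing each experiment with [ancova_treatment_test()], and recording
#' the fraction of iterations with p < `alpha`.
#'
#' @param baseline_pop Numeric vector of baseline log10 Hz values (the
#'   population arrays are drawn from).
#' @param rho Pre/post correlation (default 0.8).
#' @param sample_sizes,effect_sizes Grid axes.
#' @param iterations Iterations per cell (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; one substream per cell.
#' @return A `power_grid` object: list with `grid` (tibble of `n`, `effect`,
#'   `power`, `iterations`), plus the call parameters.
#' @export
power_grid <- function(baseline_pop, rho = 0.8, sample_sizes = 3:16,
                       effect_sizes = seq(0.1, 2.0, by = 0.1),
                       iterations = 5000, alpha = 0.05, seed = 1) {
  if (length(sample_sizes) == 0 || length(effect_sizes) == 0)
    abort("empty grid.")
  if (any(sample_sizes < 3)) abort("all sample sizes must be >= 3.")
  if (sd(baseline_pop) == 0) abort("`baseline_pop` is degenerate.")
  cells <- power_grid_design(sample_sizes, effect_sizes)
  npop <- length(baseline_pop)
  pw <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]
    eff <- cells$effect[ci]
    hits <- 0L
    withr_seed(seed + ci, {
      for (it in seq_len(iterations)) {
        b <- correlated_followup(baseline_pop, rho,
                                 seed = sample.int(2^30, 1))
        idx <- sample.int(npop, 2 * n)
        ctrl <- idx[seq_len(n)]
        trt <- idx[(n + 1):(2 * n)]
        d <- tibble(
          log_hz = c(baseline_pop[ctrl], b[ctrl],
                     baseline_pop[trt], b[trt] - eff),
          group = rep(c("control", "treatment"), each = 2 * n),
          time = rep(rep(c("pre", "post"), each = n), 2))
        p <- ancova_treatment_test(d)$p_value
        if (p < alpha) hits <- hits + 1L
      }
    })
    pw[ci] <- hits / iterations
  }
  structure(list(grid = cells %>% mutate(power = pw),
                 rho = rho, iterations = iterations, alpha = alpha,
                 seed = seed, n_pop = npop,
                 n_treatments = nrow(cells) * iterations),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("<power_grid> %d cells x %d iterations = %g simulated treatments (alpha %.3g, rho %.2f)\n",
              nrow(x$grid), x$iterations, x$n_treatments, x$alpha, x$rho))
  invisible(x)
}

#' @export
tidy.power_grid <- function(x, ...) x$grid

#' @export
glance.power_grid <- function(x, ...) {
  tibble(n_cells = nrow(x$grid), iterations = x$iterations,
         n_treatments = x$n_treatments, alpha = x$alpha, rho = x$rho,
         seed = x$seed)
}

#' Correlation of repeated recordings as a function of recording duration
#'
#' For two recordings of the same plate on consecutive days, computes the
#' across-well Pearson correlation of log10 firing rates over accumulating
#' intervals [0, k * step] and fits an ordinary least-squares line of the
#' correlation on the natural log of the interval length, reflecting the
#' empirical rho proportional to ln(time) behaviour: lengthening a recording
#' improves day-to-day reproducibility rapidly at first and only marginally
#' beyond ~30 min.
#'
#' @param day1,day2 `spike_table`s sharing a well set, each with a single
#'   recording (or pass `recording1`/`recording2` to select).
#' @param step_minutes Interval increment in minutes.
#' @param recording1,recording2 Optional recording ids.
#' @return A `correlation_curve`: list with `curve` (tibble of `minutes`,
#'   `rho`) and `log_fit` (intercept, slope of rho ~ ln(minutes)).
#' @export
duration_correlation_curve <- function(day1, day2, step_minutes = 1,
                                       recording1 = NULL, recording2 = NULL) {
  pick <- function(tab, rid) {
    if (is.null(rid)) rid <- tab$recordings$recording_id[1]
    list(ev = tab$events %>% filter(.data$recording_id == rid),
         dur = tab$recordings$duration_s[
           match(rid, tab$recordings$recording_id)])
  }
  d1 <- pick(day1, recording1)
  d2 <- pick(day2, recording2)
  wells <- intersect(day1$layout$well_labels, day2$layout$well_labels)
  if (length(wells) < 2) abort("need at least 2 common wells.")
  max_min <- floor(min(d1$dur, d2$dur) / 60 / step_minutes) * step_minutes
  minutes <- seq(step_minutes, max_min, by = step_minutes)
  if (length(minutes) < 2) abort("durations must cover at least 2 steps.")
  logmfr <- function(ev, tmax) {
    cnt <- ev %>% filter(.data$timestamp_s <= tmax) %>%
      count(.data$well, name = "n")
    n <- cnt$n[match(wells, cnt$well)]
    n[is.na(n)] <- 0
    log10((n + 1) / tmax)
  }
  rho <- vapply(minutes, function(m) {
    cor(logmfr(d1$ev, m * 60), logmfr(d2$ev, m * 60))
  }, 0)
  fit <- lm(rho ~ log(minutes))
  structure(list(curve = tibble(minutes = minutes, rho = rho),
                 log_fit = c(intercept = unname(coef(fit)[1]),
                             slope = unname(coef(fit)[2]))),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d intervals | rho(max) = %.3f | rho ~ %.3f + %.3f ln(min)\n",
              nrow(x$curve), x$curve$rho[nrow(x$curve)],
              x$log_fit["intercept"], x$log_fit["slope"]))
  invisible(x)
}

#' @export
tidy.correlation_curve <- function(x, ...) x$curve

#' @export
glance.correlation_curve <- function(x, ...) {
  tibble(intercept = x$log_fit["intercept"], slope = x$log_fit["slope"],
         rho_max = x$curve$rho[nrow(x$curve)])
}
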