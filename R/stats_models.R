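#' Gamma GLM for cluster firing-frequency distributions
#'
#' Cluster-level firing frequencies are zero-inflated and heavily
#' right-skewed, so a log transform does not normalize them the way it does
#' array-level rates. Positive frequencies are instead modelled with a
#' Gamma-family generalized linear model with the inverse (canonical) link,
#' treatment and recording entering as interacting categorical predictors.
#' Per-cell mean frequencies and their standard errors are recovered on the
#' response scale by the delta method.
#'
#' Zero frequencies are excluded before fitting (the Gamma support is
#' positive); pass `offset_mode = TRUE` to instead model
#' `(n + 1) / duration` style strictly positive rates computed upstream.
#'
#' @param data Tibble with columns `hz`, `treatment`, `recording`.
#' @param offset_mode If `FALSE` (default) any non-positive `hz` raises an
#'   error naming the offending rows; if `TRUE` the caller asserts rates
#'   were made positive upstream and the same check applies.
#' @param drop_zeros If `TRUE`, silently drop `hz == 0` rows before fitting
#'   rather than erroring.
#' @return A `gamma_freq_fit`: list with the underlying `glm` fit and
#'   `cell_means` (tibble of `treatment`, `recording`, `mu`, `se`, `n`).
#' @export
fit_gamma_glm <- function(data, drop_zeros = FALSE, offset_mode = FALSE) {
  data <- as_tibble(data)
  if (drop_zeros) data <- data %>% filter(.data$hz > 0)
  bad <- which(data$hz <= 0)
  if (length(bad) > 0)
    abort(sprintf(
      "non-positive firing frequencies at row(s) %s; exclude zero-rate clusters or use drop_zeros = TRUE.",
      paste(head(bad, 5), collapse = ", ")))
  data <- data %>%
    mutate(treatment = factor(.data$treatment),
           recording = factor(.data$recording))
  cells <- data %>% count(.data$treatment, .data$recording)
  if (any(cells$n < 2)) abort("every treatment x recording cell needs >= 2 observations.")
  if (sd(data$hz) == 0) abort("constant responses: Gamma dispersion is degenerate.")
  terms <- c(if (nlevels(data$treatment) > 1) "treatment",
             if (nlevels(data$recording) > 1) "recording")
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " * ")
  fit <- stats::glm(stats::as.formula(paste("hz ~", rhs)), data = data,
                    family = stats::Gamma(link = "inverse"))
  if (!fit$converged) warn("Gamma GLM did not converge.")
  grid <- data %>% distinct(.data$treatment, .data$recording)
  pr <- predict(fit, newdata = grid, type = "response", se.fit = TRUE)
  cell_means <- grid %>%
    mutate(mu = as.numeric(pr$fit), se = as.numeric(pr$se.fit)) %>%
    left_join(cells, by = c("treatment", "recording")) %>%
    rename(n_clusters = "n") %>%
    arrange(.data$treatment, .data$recording)
  structure(list(fit = fit, cell_means = cell_means),
            class = "gamma_freq_fit")
}

#' @export
print.gamma_freq_fit <- function(x, ...) {
  cat("<gamma_freq_fit> Gamma GLM (inverse link), treatment x recording\n")
  print(x$cell_means)
  invisible(x)
}

#' @export
tidy.gamma_freq_fit <- function(x, ...) x$cell_means

#' @export
glance.gamma_freq_fit <- function(x, ...) {
  tibble(n_obs = stats::nobs(x$fit),
         n_cells = nrow(x$cell_means),
         deviance = x$fit$deviance,
         dispersion = summary(x$fit)$dispersion,
         converged = x$fit$converged)
}

#' Restrict amplitude data to modellable clusters
#'
#' Changes in waveform amplitude can only be estimated on clusters that (a)
#' offer dynamic range — representative amplitude of at least `min_uv`
#' (default 30 uV) in the pre-treatment recording — and (b) fire in every
#' modelled recording (persistent clusters), since amplitude is undefined
#' for a silent cluster.
#'
#' @param data Tibble with `log10_uv`, `treatment`, `recording`, `cluster`,
#'   `electrode`, `experiment`.
#' @param pre_recording The label of the pre-treatment recording level.
#' @param min_uv Minimum pre-treatment representative amplitude, uV.
#' @return The filtered tibble.
#' @export
filter_amplitude_clusters <- function(data, pre_recording, min_uv = 30) {
  recs <- unique(data$recording)
  keep <- data %>%
    group_by(.data$cluster) %>%
    summarise(
      persistent = length(unique(.data$recording)) == length(recs),
      pre_amp_ok = any(.data$recording == pre_recording &
                         10^.data$log10_uv >= min_uv),
      .groups = "drop") %>%
    filter(.data$persistent, .data$pre_amp_ok) %>%
    pull(.data$cluster)
  data %>% filter(.data$cluster %in% keep)
}

lme_or_fallback <- function(fixed, data, random_formulas) {
  # try progressively simpler nested random structures; flag what was used
  for (i in seq_along(random_formulas)) {
    fit <- tryCatch(
      nlme::lme(fixed, random = random_formulas[[i]], data = data,
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, dropped = i - 1))
  }
  NULL
}

#' Nested mixed-effect model for waveform amplitude
#'
#' Models per-event `log10` amplitude (uV) with treatment and recording as
#' interacting fixed effects and nested random intercepts for experiment,
#' electrode-within-experiment and cluster-within-electrode, fitted by
#' REML. This hierarchy absorbs the amplitude variability between clusters,
#' the differing sensitivity of electrodes, and preparation-to-preparation
#' differences, so the fixed effects isolate the treatment-induced change.
#' If a variance component is singular the innermost level is dropped and
#' the fit flagged.
#'
#' @param data Tibble with `log10_uv`, `treatment`, `recording`, `cluster`,
#'   `electrode`, `experiment` (apply [filter_amplitude_clusters()] first).
#' @return A `mixed_model_fit` with per-treatment recording deltas.
#' @export
fit_amplitude_lme <- function(data) {
  data <- data %>%
    mutate(treatment = factor(.data$treatment),
           recording = factor(.data$recording),
           experiment = factor(.data$experiment),
           electrode = factor(.data$electrode),
           cluster = factor(.data$cluster))
  res <- lme_or_fallback(
    log10_uv ~ treatment * recording, data,
    list(~ 1 | experiment / electrode / cluster,
         ~ 1 | experiment / electrode,
         ~ 1 | experiment))
  if (is.null(res)) abort("mixed model could not be fitted.")
  if (res$dropped > 0)
    warn(sprintf("singular fit: dropped %d innermost random component(s).",
                 res$dropped))
  new_mixed_model_fit(res$fit, data, response = "log10_amplitude",
                      dropped = res$dropped)
}

#' Mixed-effect model for array-level firing frequency
#'
#' Models array-level `log10` firing rate with treatment and recording as
#' interacting fixed effects and a random intercept per experiment
#' (separate culture preparations differ in overall activity). With a
#' single experiment the model degrades to a fixed-effects linear model
#' with a warning.
#'
#' @param data Tibble with `log10_hz`, `treatment`, `recording`,
#'   `experiment`.
#' @return A `mixed_model_fit` with per-treatment recording deltas.
#' @export
fit_frequency_lme <- function(data) {
  data <- data %>%
    mutate(treatment = factor(.data$treatment),
           recording = factor(.data$recording),
           experiment = factor(.data$experiment))
  if (length(unique(data$experiment)) < 2) {
    warn("single experiment: falling back to a fixed-effects linear model.")
    fit <- lm(log10_hz ~ treatment * recording, data = data)
    return(new_mixed_model_fit(fit, data, response = "log10_mfr",
                               dropped = NA_integer_))
  }
  res <- lme_or_fallback(log10_hz ~ treatment * recording, data,
                         list(~ 1 | experiment))
  if (is.null(res)) abort("mixed model could not be fitted.")
  new_mixed_model_fit(res$fit, data, response = "log10_mfr", dropped = 0L)
}

new_mixed_model_fit <- function(fit, data, response, dropped) {
  structure(list(fit = fit, data = data, response = response,
                 dropped = dropped,
                 deltas = recording_deltas(fit, data)),
            class = "mixed_model_fit")
}

fixef_of <- function(fit) {
  if (inherits(fit, "lme")) nlme::fixef(fit) else coef(fit)
}

#' Per-treatment change across recordings
#'
#' For a treatment-by-recording interaction model, the quantity of interest
#' is each treatment's change from the pre recording to the post recording
#' (delta log10 units). Estimates and Wald standard errors are linear
#' combinations of the fixed effects.
#'
#' @param fit An `lme` or `lm` fit with `treatment * recording` fixed
#'   effects (or a `mixed_model_fit`).
#' @param data The model frame (needed for factor levels); optional for a
#'   `mixed_model_fit`.
#' @return Tibble with `treatment`, `estimate`, `se`.
#' @export
recording_deltas <- function(fit, data = NULL) {
  if (inherits(fit, "mixed_model_fit")) {
    data <- fit$data
    fit <- fit$fit
  }
  beta <- fixef_of(fit)
  V <- vcov(fit)
  tr_lev <- levels(data$treatment)
  rec_lev <- levels(data$recording)
  pre <- rec_lev[1]
  post <- rec_lev[length(rec_lev)]
  out <- purrr::map(tr_lev, function(tr) {
    l <- setNames(numeric(length(beta)), names(beta))
    rec_term <- paste0("recording", post)
    if (rec_term %in% names(l)) l[rec_term] <- 1
    int_term <- paste0("treatment", tr, ":recording", post)
    if (int_term %in% names(l)) l[int_term] <- 1
    est <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% as.matrix(V) %*% l))
    tibble(treatment = tr, estimate = est, se = se)
  })
  bind_rows(out)
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> response: %s%s\n", x$response,
              if (!is.na(x$dropped) && x$dropped > 0)
                sprintf(" (dropped %d random component(s))", x$dropped)
              else ""))
  print(x$deltas)
  invisible(x)
}

#' @export
tidy.mixed_model_fit <- function(x, ...) x$deltas

#' @export
glance.mixed_model_fit <- function(x, ...) {
  tibble(response = x$response, n_obs = nrow(x$data),
         mixed = inherits(x$fit, "lme"),
         dropped_components = x$dropped)
}

#' Multiplicity-adjusted general linear hypothesis tests
#'
#' Tests linear contrasts of a fitted model's coefficients, adjusting for
#' multiple comparisons with the single-step method: the adjusted p value
#' for each contrast is computed from the joint multivariate normal (or t)
#' distribution of all the contrast statistics, using the correlation
#' implied by the fit covariance. Bonferroni and no adjustment are also
#' available; the single-step adjusted p never exceeds Bonferroni's and
#' never falls below the raw p.
#'
#' @param fit A `gamma_freq_fit`, `mixed_model_fit`, or any model accepted
#'   by [multcomp::glht()].
#' @param linfct Contrast specification passed to [multcomp::glht()] (a
#'   matrix of coefficient weights, or an `mcp()` specification).
#' @param method `"single_step"` (default), `"bonferroni"` or `"none"`.
#' @param seed Seed for the deterministic quasi-randomized multivariate
#'   integration behind the single-step adjustment.
#' @return Tibble with `contrast`, `estimate`, `se`, `statistic`,
#'   `p_value`, `adjustment`.
#' @export
contrast_tests <- function(fit, linfct, method = c("single_step",
                                                   "bonferroni", "none"),
                           seed = 1) {
  method <- match.arg(method)
  model <- if (inherits(fit, c("gamma_freq_fit", "mixed_model_fit")))
    fit$fit else fit
  gl <- multcomp::glht(model, linfct = linfct)
  test <- switch(method,
                 single_step = multcomp::adjusted("single-step"),
                 bonferroni = multcomp::adjusted("bonferroni"),
                 none = multcomp::adjusted("none"))
  sm <- withr_seed(seed, summary(gl, test = test))
  tibble(contrast = names(sm$test$coefficients),
         estimate = as.numeric(sm$test$coefficients),
         se = as.numeric(sm$test$sigma),
         statistic = as.numeric(sm$test$tstat),
         p_value = as.numeric(sm$test$pvalues),
         adjustment = method)
}
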