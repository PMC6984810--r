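#' Plate layout description
#'
#' A plate layout records the geometry of a multi-well MEA plate: the number
#' of wells (arranged as row-letter by column-number, e.g. "A1".."H12" for a
#' 96-well plate), the number of recording electrodes embedded in each well,
#' and the acquisition sampling rate. One well's electrode set is referred to
#' as an "array" throughout.
#'
#' @param n_wells Number of wells; must factor into a letter-by-number grid
#'   (96 wells = 8 rows x 12 columns by default).
#' @param electrodes_per_well Electrodes per well (default 8).
#' @param sampling_rate Acquisition sampling rate in Hz (default 12500).
#' @param n_rows Number of plate rows; defaults to the standard layout for
#'   common plate sizes (8 rows for 96 wells, 4 for 24, 2 for 12).
#' @return An object of class `plate_layout`: a list with `n_wells`,
#'   `electrodes_per_well`, `sampling_rate`, `n_rows`, `n_cols`,
#'   `well_labels` and `n_channels`.
#' @examples
#' plate_layout()$n_channels # 768
#' @export
plate_layout <- function(n_wells = 96, electrodes_per_well = 8,
                         sampling_rate = 12500, n_rows = NULL) {
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (n_wells < 1 || electrodes_per_well < 1)
    abort("`n_wells` and `electrodes_per_well` must be positive.")
  if (is.null(n_rows)) {
    n_rows <- switch(as.character(n_wells),
                     "96" = 8L, "48" = 6L, "24" = 4L, "12" = 3L, "6" = 2L,
                     max(which(n_wells %% seq_len(min(26, n_wells)) == 0 &
                                 seq_len(min(26, n_wells)) <=
                                   ceiling(sqrt(n_wells)))))
  }
  if (n_wells %% n_rows != 0)
    abort("`n_wells` must be divisible by `n_rows`.")
  n_cols <- n_wells %/% n_rows
  labels <- as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols),
                              paste0)))
  structure(list(n_wells = as.integer(n_wells),
                 electrodes_per_well = as.integer(electrodes_per_well),
                 sampling_rate = sampling_rate,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 well_labels = labels,
                 n_channels = as.integer(n_wells * electrodes_per_well)),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d wells (%dx%d) x %d electrodes = %d channels @ %g Hz\n",
              x$n_wells, x$n_rows, x$n_cols, x$electrodes_per_well,
              x$n_channels, x$sampling_rate))
  invisible(x)
}

#' Number of samples in a spike waveform window
#'
#' The waveform retained for each detected spike spans `pre_ms` before and
#' `post_ms` after the threshold crossing, inclusive of the crossing sample
#' itself, so the vector length is
#' `floor(pre_ms * rate / 1000) + floor(post_ms * rate / 1000) + 1`.
#' At the instrument defaults (1 ms pre, 2 ms post, 12.5 kHz) this gives the
#' canonical 38-sample waveform (12 + 25 + 1). The crossing sample sits at
#' 0-based index `floor(pre_ms * rate / 1000)`.
#'
#' @param pre_ms,post_ms Window extent before/after the crossing, ms (>= 0).
#' @param rate Sampling rate in Hz (> 0).
#' @return Integer sample count.
#' @examples
#' waveform_samples(1, 2, 12500) # 38
#' @export
waveform_samples <- function(pre_ms = 1, post_ms = 2, rate = 12500) {
  if (rate <= 0) abort("`rate` must be positive.")
  if (pre_ms < 0 || post_ms < 0) abort("`pre_ms` and `post_ms` must be >= 0.")
  as.integer(floor(pre_ms * rate / 1000) + floor(post_ms * rate / 1000) + 1)
}

event_cols <- c("well", "electrode", "recording_id", "timestamp_s",
                "crossing_threshold_uv", "waveform_uv")

#' Assemble a spike table
#'
#' A spike table is the package's central container: a tibble of spike events
#' (one row per threshold crossing, with its waveform as a list-column)
#' together with the plate layout and per-recording metadata. All invariants
#' are validated on construction.
#'
#' @param events Tibble with columns `well`, `electrode`, `recording_id`,
#'   `timestamp_s` (seconds from recording start), `crossing_threshold_uv`
#'   and `waveform_uv` (list-column of equal-length numeric vectors, uV).
#'   Optional: `truth_neuron` (simulator ground truth), `cluster_id`.
#' @param recordings Tibble with `recording_id`, `duration_s` and optionally
#'   `div`, `condition`, `phase`.
#' @param layout A [plate_layout()].
#' @param pre_ms,post_ms Waveform window convention used when the events were
#'   extracted.
#' @return A `spike_table` object (list with `events`, `recordings`,
#'   `layout`, `pre_ms`, `post_ms`).
#' @export
spike_table <- function(events, recordings, layout = plate_layout(),
                        pre_ms = 1, post_ms = 2) {
  events <- as_tibble(events)
  recordings <- as_tibble(recordings)
  x <- structure(list(events = events, recordings = recordings,
                      layout = layout, pre_ms = pre_ms, post_ms = post_ms),
                 class = "spike_table")
  validate_spike_table(x)
}

#' Validate a spike table's invariants
#'
#' Checks mandatory columns, recording references, well/electrode membership
#' in the layout, timestamp bounds, threshold positivity, and that all
#' waveforms share the length implied by the window convention.
#'
#' @param x A `spike_table`.
#' @return `x`, invisibly sorted by (recording, well, electrode, timestamp).
#' @export
validate_spike_table <- function(x) {
  ev <- x$events
  rec <- x$recordings
  missing_cols <- setdiff(event_cols, names(ev))
  if (length(missing_cols) > 0)
    abort(paste0("spike table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (!all(c("recording_id", "duration_s") %in% names(rec)))
    abort("recordings must have columns `recording_id` and `duration_s`.")
  if (anyDuplicated(rec$recording_id))
    abort("recording_id must be unique within an experiment.")
  if (any(rec$duration_s <= 0)) abort("recording durations must be positive.")
  if (nrow(ev) > 0) {
    bad <- which(!ev$recording_id %in% rec$recording_id)
    if (length(bad) > 0)
      abort(sprintf("event row %d references unknown recording '%s'.",
                    bad[1], ev$recording_id[bad[1]]))
    bad <- which(!ev$well %in% x$layout$well_labels)
    if (length(bad) > 0)
      abort(sprintf("event row %d references well '%s' outside the layout.",
                    bad[1], ev$well[bad[1]]))
    bad <- which(ev$electrode < 1 |
                   ev$electrode > x$layout$electrodes_per_well)
    if (length(bad) > 0)
      abort(sprintf("event row %d has electrode index %d outside 1..%d.",
                    bad[1], ev$electrode[bad[1]],
                    x$layout$electrodes_per_well))
    dur <- rec$duration_s[match(ev$recording_id, rec$recording_id)]
    bad <- which(ev$timestamp_s < 0 | ev$timestamp_s > dur)
    if (length(bad) > 0)
      abort(sprintf("event row %d timestamp %.6f s outside [0, duration].",
                    bad[1], ev$timestamp_s[bad[1]]))
    bad <- which(!is.finite(ev$crossing_threshold_uv) |
                   ev$crossing_threshold_uv <= 0)
    if (length(bad) > 0)
      abort(sprintf("event row %d has non-positive crossing threshold.",
                    bad[1]))
    expect_len <- waveform_samples(x$pre_ms, x$post_ms,
                                   x$layout$sampling_rate)
    lens <- lengths(ev$waveform_uv)
    bad <- which(lens != expect_len)
    if (length(bad) > 0)
      abort(sprintf(
        "event row %d has waveform length %d; expected %d for this window.",
        bad[1], lens[bad[1]], expect_len))
  }
  ord <- order(ev$recording_id, ev$well, ev$electrode, ev$timestamp_s)
  x$events <- ev[ord, , drop = FALSE]
  x
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("<spike_table> %d events | %d recordings | %s\n",
              nrow(x$events), nrow(x$recordings),
              format(x$layout)[1]))
  invisible(x)
}

#' @export
format.plate_layout <- function(x, ...) {
  sprintf("%d wells x %d electrodes @ %g Hz", x$n_wells,
          x$electrodes_per_well, x$sampling_rate)
}

fmt_num <- function(x, digits) {
  out <- formatC(x, format = "f", digits = digits)
  # normalise "-0.000" to "0.000" so output bytes are stable across platforms
  sub("^-(0\\.?0*)$", "\\1", out)
}

#' Write a spike table to a delimited text file
#'
#' One row per spike, tab-separated, waveform serialized as a
#' semicolon-joined numeric list. Header lines record the schema version,
#' plate layout, window convention and recording metadata, so a file is
#' self-describing. Output is deterministic: timestamps are written to 1 us,
#' voltages to 0.001 uV.
#'
#' @param table A `spike_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(table, path) {
  table <- validate_spike_table(table)
  lay <- table$layout
  hdr <- c("#schema=meawell-spikes-1",
           sprintf("#rate_hz=%s", format(lay$sampling_rate, scientific = FALSE)),
           sprintf("#pre_ms=%s", format(table$pre_ms)),
           sprintf("#post_ms=%s", format(table$post_ms)),
           sprintf("#layout=n_wells:%d,electrodes_per_well:%d,n_rows:%d",
                   lay$n_wells, lay$electrodes_per_well, lay$n_rows))
  rec <- table$recordings
  for (i in seq_len(nrow(rec))) {
    extras <- ""
    for (f in c("div", "condition", "phase")) {
      if (f %in% names(rec) && !is.na(rec[[f]][i]))
        extras <- paste0(extras, sprintf(",%s:%s", f, rec[[f]][i]))
    }
    hdr <- c(hdr, sprintf("#recording=id:%s,duration_s:%s%s",
                          rec$recording_id[i],
                          fmt_num(rec$duration_s[i], 3), extras))
  }
  ev <- table$events
  opt <- intersect(c("truth_neuron", "cluster_id"), names(ev))
  cols <- c(event_cols, opt)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  body <- character(0)
  if (nrow(ev) > 0) {
    wf <- vapply(ev$waveform_uv,
                 function(v) paste(fmt_num(v, 3), collapse = ";"), "")
    mat <- cbind(ev$well, ev$electrode, ev$recording_id,
                 fmt_num(ev$timestamp_s, 6),
                 fmt_num(ev$crossing_threshold_uv, 3), wf)
    for (f in opt) mat <- cbind(mat, as.character(ev[[f]]))
    body <- apply(mat, 1, paste, collapse = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

parse_kv <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Read a spike table from the delimited interchange format
#'
#' Parses the header (schema, rate, window, layout, recordings) and the event
#' body written by [write_spike_table()], validating every invariant; schema
#' errors name the offending row.
#'
#' @param path Path to a `meawell-spikes-1` file.
#' @return A `spike_table`.
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || !identical(lines[1], "#schema=meawell-spikes-1"))
    abort("not a meawell-spikes-1 file (missing #schema header).")
  get1 <- function(key) {
    m <- grep(paste0("^#", key, "="), lines, value = TRUE)
    if (length(m) == 0) abort(paste0("missing header #", key, "="))
    sub(paste0("^#", key, "="), "", m[1])
  }
  rate <- as.numeric(get1("rate_hz"))
  pre_ms <- as.numeric(get1("pre_ms"))
  post_ms <- as.numeric(get1("post_ms"))
  lay_kv <- parse_kv(get1("layout"))
  layout <- plate_layout(n_wells = as.integer(lay_kv[["n_wells"]]),
                         electrodes_per_well =
                           as.integer(lay_kv[["electrodes_per_well"]]),
                         sampling_rate = rate,
                         n_rows = as.integer(lay_kv[["n_rows"]]))
  rec_lines <- grep("^#recording=", lines, value = TRUE)
  recs <- purrr::map(rec_lines, function(l) {
    kv <- parse_kv(sub("^#recording=", "", l))
    tibble(recording_id = kv[["id"]],
           duration_s = as.numeric(kv[["duration_s"]]),
           div = if ("div" %in% names(kv)) as.integer(kv[["div"]]) else NA_integer_,
           condition = if ("condition" %in% names(kv)) kv[["condition"]] else NA_character_,
           phase = if ("phase" %in% names(kv)) kv[["phase"]] else NA_character_)
  }) %>% bind_rows()
  body <- lines[setdiff(seq_along(lines), hdr)]
  header_row <- body[1]
  cols <- strsplit(header_row, "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(event_cols, cols)
  if (length(missing_cols) > 0)
    abort(paste0("spike table file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  body <- body[-1]
  if (length(body) > 0) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != length(cols))
    if (length(bad) > 0)
      abort(sprintf("row %d has %d fields; expected %d.", bad[1],
                    nf[bad[1]], length(cols)))
    m <- do.call(rbind, fields)
    colnames(m) <- cols
    ev <- tibble(
      well = m[, "well"],
      electrode = as.integer(m[, "electrode"]),
      recording_id = m[, "recording_id"],
      timestamp_s = as.numeric(m[, "timestamp_s"]),
      crossing_threshold_uv = as.numeric(m[, "crossing_threshold_uv"]),
      waveform_uv = purrr::map(m[, "waveform_uv"], function(s)
        as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])))
    if ("truth_neuron" %in% cols) ev$truth_neuron <- m[, "truth_neuron"]
    if ("cluster_id" %in% cols) ev$cluster_id <- m[, "cluster_id"]
  } else {
    ev <- tibble(well = character(), electrode = integer(),
                 recording_id = character(), timestamp_s = numeric(),
                 crossing_threshold_uv = numeric(), waveform_uv = list())
  }
  spike_table(ev, recs, layout, pre_ms = pre_ms, post_ms = post_ms)
}

#' Read or write a plate map
#'
#' A plate map assigns wells to treatment groups: a delimited table with
#' columns `well`, `group`, `include`.
#'
#' @param path File path.
#' @return `read_plate_map()`: a tibble; `write_plate_map()`: `path`,
#'   invisibly.
#' @export
read_plate_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("well", "group", "include") %in% names(df)))
    abort("plate map must have columns well, group, include.")
  as_tibble(df) %>% mutate(include = as.logical(.data$include))
}

#' @rdname read_plate_map
#' @param map Tibble with `well`, `group`, `include`.
#' @export
write_plate_map <- function(map, path) {
  utils::write.table(map[, c("well", "group", "include")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
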