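## Deterministic generator of EEG-like and generic containers with known
## ground truth. Default dimensions follow a small benchmark-style EEG
## collection: 32 channels, ~30k frames, 154 events over 2 distinct types,
## 4 modifier fields per event. The generator fixes the PRNG algorithm
## (Mersenne-Twister with inversion sampling) so the same (spec, seed)
## yields the identical container on every platform.

#' Specification for a synthetic container
#'
#' @param n_channels Number of channels (rows of the data matrix).
#' @param n_frames Number of frames (columns).
#' @param srate Sampling rate in Hz.
#' @param n_events Number of events.
#' @param n_event_types Number of distinct event types (at most `n_events`
#'   when events are present); type names are `type_00`, `type_01`, ...
#' @param event_attr_fields Number of numeric modifier fields per event.
#' @param certainty_mode `"all-one"` (hardware-marker style) or
#'   `"uniform-random"` certainties in \[0, 1\] (generic containers only;
#'   EEG events always carry certainty 1).
#' @param seed Integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_channels = 32, n_frames = 30504, srate = 128,
                       n_events = 154, n_event_types = 2,
                       event_attr_fields = 4,
                       certainty_mode = c("all-one", "uniform-random"),
                       seed = 42) {
  certainty_mode <- match.arg(certainty_mode)
  counts <- c(n_channels = n_channels, n_frames = n_frames,
              n_events = n_events, n_event_types = n_event_types,
              event_attr_fields = event_attr_fields)
  if (any(counts < 0))
    stop("all counts must be >= 0", call. = FALSE)
  if (srate <= 0) stop("srate must be positive", call. = FALSE)
  if (n_events > 0 && (n_event_types > n_events || n_event_types < 1))
    stop("need 1 <= n_event_types <= n_events", call. = FALSE)
  if (n_events > 0 && n_frames < 1)
    stop("events need at least one frame", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels),
                 n_frames = as.integer(n_frames), srate = srate,
                 n_events = as.integer(n_events),
                 n_event_types = as.integer(n_event_types),
                 event_attr_fields = as.integer(event_attr_fields),
                 certainty_mode = certainty_mode,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

with_spec_rng <- function(spec, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

type_vocab <- function(n) sprintf("type_%02d", seq_len(n) - 1L)

synth_events_core <- function(spec) {
  ## every type appears at least once; latencies are sorted, with
  ## replacement so event counts may exceed frame counts
  types <- type_vocab(spec$n_event_types)
  assign <- c(types,
              sample(types, max(0L, spec$n_events - spec$n_event_types),
                     replace = TRUE))[seq_len(spec$n_events)]
  lat <- sort(sample.int(spec$n_frames, spec$n_events, replace = TRUE))
  list(types = assign, latencies = lat)
}

synth_attrs <- function(spec) {
  if (spec$event_attr_fields == 0L) return(NULL)
  sprintf("attr_%02d", seq_len(spec$event_attr_fields) - 1L)
}

#' Generate an EEG-like container with ground truth
#'
#' Emits an EEGLAB-style structure: `data` (channels x frames Gaussian
#' noise), `srate`, `event` (type, 1-based latency, plus
#' `event_attr_fields` numeric modifier fields), `urevent` (type/latency
#' copies of the events) and `chanlocs` (label + unit-sphere coordinates
#' per channel). The accompanying ground truth records the counts and times
#' the container was built from, so storage and query layers can be checked
#' end-to-end against construction.
#'
#' @param spec A [synth_spec()].
#' @return List with `eeg` (the container) and `truth` (list: `n_events`,
#'   `n_types`, `attrs_per_event`, `event_times` in seconds, `event_types`).
#' @export
generate_eeg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_spec_rng(spec, {
    data <- matrix(stats::rnorm(spec$n_channels * spec$n_frames),
                   nrow = spec$n_channels)
    ev <- synth_events_core(spec)
    afields <- synth_attrs(spec)
    events <- lapply(seq_len(spec$n_events), function(i) {
      e <- list(type = ev$types[i], latency = as.double(ev$latencies[i]))
      for (f in afields) e[[f]] <- round(stats::runif(1) * 100, 4)
      e
    })
    urevents <- lapply(events, function(e) e[c("type", "latency")])
    theta <- stats::runif(spec$n_channels, 0, 2 * pi)
    phi <- stats::runif(spec$n_channels, -pi / 2, pi / 2)
    chanlocs <- lapply(seq_len(spec$n_channels), function(i)
      list(labels = sprintf("Ch%d", i),
           X = round(cos(phi[i]) * cos(theta[i]), 6),
           Y = round(cos(phi[i]) * sin(theta[i]), 6),
           Z = round(sin(phi[i]), 6)))
    eeg <- list(data = data, srate = spec$srate, event = events,
                urevent = urevents, chanlocs = chanlocs)
    truth <- list(n_events = spec$n_events,
                  n_types = if (spec$n_events) spec$n_event_types else 0L,
                  attrs_per_event = spec$event_attr_fields,
                  event_times = (ev$latencies - 1) / spec$srate,
                  event_types = ev$types)
    list(eeg = eeg, truth = truth)
  })
}

#' Generate a generic container with ground truth
#'
#' Emits a structure with `element`, `event`, `feature` and `metadata`
#' sections. Events carry explicit `start_time`/`end_time` seconds (about
#' half are instantaneous, `start == end`) and a `certainty`: all 1 under
#' `"all-one"` (hardware-marker style), uniform on \[0, 1\] under
#' `"uniform-random"` (detector-style output).
#'
#' @param spec A [synth_spec()].
#' @return List with `generic` and `truth` (adds `certainties`,
#'   `start_times`, `end_times`).
#' @export
generate_generic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_spec_rng(spec, {
    duration <- spec$n_frames / spec$srate
    ev <- synth_events_core(spec)
    start <- (ev$latencies - 1) / spec$srate
    inst <- stats::runif(spec$n_events) < 0.5
    end <- start + ifelse(inst, 0, stats::runif(spec$n_events) *
                            pmax(duration - start, 0) * 0.1)
    cert <- if (spec$certainty_mode == "all-one") rep(1, spec$n_events)
            else stats::runif(spec$n_events)
    afields <- synth_attrs(spec)
    events <- lapply(seq_len(spec$n_events), function(i) {
      e <- list(type = ev$types[i], start_time = start[i],
                end_time = end[i], certainty = cert[i])
      for (f in afields) e[[f]] <- round(stats::runif(1) * 100, 4)
      e
    })
    elements <- lapply(seq_len(spec$n_channels), function(i)
      list(label = sprintf("elem_%d", i),
           description = sprintf("element %d", i)))
    generic <- list(
      element = elements,
      event = events,
      feature = list(list(name = "mean_power",
                          value = round(stats::runif(1), 6))),
      metadata = list(list(origin = "synthetic",
                           duration_s = duration)))
    truth <- list(n_events = spec$n_events,
                  n_types = if (spec$n_events) spec$n_event_types else 0L,
                  attrs_per_event = spec$event_attr_fields,
                  event_times = start, event_types = ev$types,
                  start_times = start, end_times = end,
                  certainties = cert)
    list(generic = generic, truth = truth)
  })
}

#' Write a collection of synthetic EEG container files
#'
#' Materializes `n` containers sharing one type vocabulary as MAT-files
#' named `eeg_data_ch1.mat`, ..., `eeg_data_chN.mat` under `dir`, the shape
#' of an on-disk collection to be looped over and stored.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synth_spec()]; file `i` uses `seed + i - 1`.
#' @param n Number of files.
#' @return Character vector of file paths.
#' @export
generate_collection <- function(dir, spec, n = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    g <- generate_eeg(sp)
    path <- file.path(dir, sprintf("eeg_data_ch%d.mat", i))
    write_container(path, g$eeg)
    path
  }, character(1))
}
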