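## Modality registry and the built-in explosion handlers.
##
## A modality names the procedure that decomposes ("explodes") a dataset's
## container into EVENTS / EVENT_TYPES / ATTRIBUTES / ELEMENTS rows while the
## payload itself stays intact as a blob. SIMPLE archives without explosion;
## EEG understands the EEGLAB field layout (data, srate, event, urevent,
## chanlocs); GENERIC understands element/event/feature/metadata sections.

#' Map event type names to shared UUIDs
#'
#' Event types are UUID-identified strings shared across datasets so that
#' "the same" event is recognizable in data mining. Given a vector of type
#' names and a map of already-known types, every distinct name is resolved:
#' names present in `known` keep their UUID, new names are assigned fresh
#' ones. Numeric type codes should be stringified by the caller.
#'
#' @param type_names Character vector of type names (may repeat).
#' @param known Named character vector mapping type name to UUID.
#' @return List with `map` (extended named vector) and `created` (UUIDs newly
#'   allocated, in first-appearance order).
#' @export
map_event_types <- function(type_names, known = character(0)) {
  stopifnot(is.character(type_names))
  known <- stats::setNames(as.character(known), names(known))
  if (anyDuplicated(names(known)))
    stop("event type map must be injective on names", call. = FALSE)
  fresh <- setdiff(unique(type_names), names(known))
  created <- character(0)
  if (length(fresh)) {
    created <- vapply(fresh, function(x) new_uuid(), character(1),
                      USE.NAMES = FALSE)
    known <- c(known, stats::setNames(created, fresh))
  }
  list(map = known, created = created)
}

## Builds the name->uuid map for a vector of EVENT_TYPES keys, the form in
## which callers thread a type vocabulary through successive stores.
type_map_from_uuids <- function(con, uuids) {
  if (length(uuids) == 0L) return(character(0))
  qmarks <- paste(rep("?", length(uuids)), collapse = ",")
  df <- DBI::dbGetQuery(con$db,
    sprintf("SELECT event_type_uuid, event_type FROM event_types
             WHERE event_type_uuid IN (%s)", qmarks),
    params = as.list(uuids))
  stats::setNames(df$event_type_uuid, df$event_type)
}

write_event_types <- function(con, map, created) {
  if (length(created) == 0L) return(invisible(NULL))
  nm <- names(map)[match(created, map)]
  DBI::dbExecute(con$db,
    "INSERT INTO event_types (event_type_uuid, event_type, event_type_description)
     VALUES (:u, :t, :d)",
    params = list(u = created, t = nm, d = rep("", length(created))))
  invisible(NULL)
}

write_events <- function(con, dataset_uuid, type_uuids, start, end,
                         certainty) {
  n <- length(type_uuids)
  if (n == 0L) return(character(0))
  uuids <- new_uuid(n)
  DBI::dbExecute(con$db,
    "INSERT INTO events (event_uuid, event_dataset_uuid, event_type_uuid,
                         event_start_time, event_end_time, event_certainty)
     VALUES (:u, :d, :t, :s, :e, :c)",
    params = list(u = uuids, d = rep(dataset_uuid, n), t = type_uuids,
                  s = as.double(start), e = as.double(end),
                  c = as.double(certainty)))
  uuids
}

write_attribute_rows <- function(con, entity_uuids, entity_class, paths,
                                 values) {
  n <- length(paths)
  if (n == 0L) return(character(0))
  num <- vapply(values, function(v) is.numeric(v) && length(v) == 1L,
                logical(1))
  uuids <- new_uuid(n)
  DBI::dbExecute(con$db,
    "INSERT INTO attributes (attribute_uuid, attribute_entity_uuid,
       attribute_entity_class, attribute_path, attribute_numeric_value,
       attribute_value)
     VALUES (:u, :eu, :ec, :p, :nv, :sv)",
    params = list(
      u = uuids, eu = entity_uuids, ec = rep(entity_class, n), p = paths,
      nv = ifelse(num, vapply(values, function(v)
        if (is.numeric(v) && length(v) == 1L) as.double(v) else NA_real_,
        double(1)), NA_real_),
      sv = ifelse(num, NA_character_, vapply(values, function(v)
        paste(format(v, trim = TRUE), collapse = " "), character(1)))))
  uuids
}

stringify_type <- function(x) {
  if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE)
  else as.character(x)
}

#' Explode an EEG-style container into the database
#'
#' Writes one EVENTS row per entry of `eeg$event` with
#' `start = end = (latency - 1) / srate` seconds (1-based sample indexing)
#' and certainty 1.0, resolving types through [map_event_types()]. Entries of
#' `eeg$urevent` are stored the same way, flagged by an attribute
#' `'/urevent' = 1`. Every per-event field other than `type`/`latency`
#' becomes an attribute at path `'/event/<field>'`; each channel-location
#' field becomes an attribute at `'/chanlocs/<index>/<field>'` on the
#' dataset.
#'
#' Normally invoked automatically by [store_dataset()] for the EEG modality.
#'
#' @param con Open connection.
#' @param dataset_uuid UUID of the owning DATASETS row.
#' @param eeg EEG-like structure (see [generate_eeg()]).
#' @param known Named character vector mapping type names to UUIDs to reuse.
#' @return List with `event_uuids` (non-urevent rows) and `type_map`.
#' @export
explode_eeg <- function(con, dataset_uuid, eeg, known = character(0)) {
  assert_open(con)
  validate_eeg(eeg)
  with_txn(con, {
    n_frames <- if (is.matrix(eeg$data)) ncol(eeg$data) else length(eeg$data)
    events <- eeg$event %||% list()
    urevents <- eeg$urevent %||% list()
    types <- vapply(events, function(ev) stringify_type(ev$type),
                    character(1))
    urtypes <- vapply(urevents, function(ev) stringify_type(ev$type),
                      character(1))
    mt <- map_event_types(c(types, urtypes), known)
    write_event_types(con, mt$map, mt$created)

    lat <- vapply(events, function(ev) as.double(ev$latency), double(1))
    t0 <- (lat - 1) / eeg$srate
    ev_uuids <- write_events(con, dataset_uuid, unname(mt$map[types]),
                             t0, t0, rep(1.0, length(t0)))
    ## per-event modifier fields -> attributes on the event rows
    paths <- character(0); vals <- list(); owners <- character(0)
    for (i in seq_along(events)) {
      extra <- setdiff(names(events[[i]]), c("type", "latency"))
      for (f in extra) {
        paths <- c(paths, paste0("/event/", f))
        vals <- c(vals, list(events[[i]][[f]]))
        owners <- c(owners, ev_uuids[i])
      }
    }
    write_attribute_rows(con, owners, "events", paths, vals)

    urlat <- vapply(urevents, function(ev) as.double(ev$latency), double(1))
    urt0 <- (urlat - 1) / eeg$srate
    ur_uuids <- write_events(con, dataset_uuid, unname(mt$map[urtypes]),
                             urt0, urt0, rep(1.0, length(urt0)))
    write_attribute_rows(con, ur_uuids, "events",
                         rep("/urevent", length(ur_uuids)),
                         rep(list(1), length(ur_uuids)))

    chan <- eeg$chanlocs %||% list()
    cpaths <- character(0); cvals <- list()
    for (i in seq_along(chan)) {
      for (f in names(chan[[i]])) {
        cpaths <- c(cpaths, sprintf("/chanlocs/%d/%s", i, f))
        cvals <- c(cvals, list(chan[[i]][[f]]))
      }
    }
    write_attribute_rows(con, rep(dataset_uuid, length(cpaths)), "datasets",
                         cpaths, cvals)
    fault_point("explode_eeg")
    list(event_uuids = ev_uuids, type_map = mt$map)
  })
}

validate_eeg <- function(eeg) {
  if (!is.list(eeg) || is.null(eeg$data) || is.null(eeg$srate))
    stop("EEG container must have data and srate fields", call. = FALSE)
  if (!is.numeric(eeg$srate) || eeg$srate <= 0)
    stop("sampling rate must be positive", call. = FALSE)
  n_frames <- if (is.matrix(eeg$data)) ncol(eeg$data) else length(eeg$data)
  n_chan <- if (is.matrix(eeg$data)) nrow(eeg$data) else 1L
  if (length(eeg$chanlocs %||% list()) > 0L &&
      length(eeg$chanlocs) != n_chan)
    stop(sprintf("chanlocs length (%d) does not match channel count (%d)",
                 length(eeg$chanlocs), n_chan), call. = FALSE)
  for (ev in c(eeg$event %||% list(), eeg$urevent %||% list())) {
    if (is.null(ev$type) || is.null(ev$latency))
      stop("every event needs type and latency fields", call. = FALSE)
    if (ev$latency < 1 || ev$latency > n_frames)
      stop(sprintf("event latency %g outside data range [1, %d]",
                   ev$latency, n_frames), call. = FALSE)
  }
  invisible(eeg)
}

#' Explode a generic container into the database
#'
#' Generic containers carry explicit event timing: each record of the
#' `event` section has `type`, `start_time` and `end_time` in seconds from
#' dataset start (equal times mark an instantaneous event) and an optional
#' `certainty` in \[0, 1\] (defaulting to 1, the value of hardware-inserted
#' markers). `element` records become ELEMENTS rows; `feature` and
#' `metadata` records become attributes keyed by their section path.
#'
#' @inheritParams explode_eeg
#' @param g Generic structure (see [generate_generic()]).
#' @return List with `event_uuids` and `type_map`.
#' @export
explode_generic <- function(con, dataset_uuid, g, known = character(0)) {
  assert_open(con)
  events <- g$event %||% list()
  for (ev in events) {
    if (is.null(ev$type) || is.null(ev$start_time))
      stop("every generic event needs type and start_time", call. = FALSE)
    cert <- ev$certainty %||% 1.0
    if (!is.numeric(cert) || cert < 0 || cert > 1)
      stop(sprintf("event certainty %s outside [0, 1]", format(cert)),
           call. = FALSE)
    if ((ev$end_time %||% ev$start_time) < ev$start_time)
      stop("event end_time precedes start_time", call. = FALSE)
    if (ev$start_time < 0)
      stop("event times must be >= 0 seconds from dataset start",
           call. = FALSE)
  }
  with_txn(con, {
    types <- vapply(events, function(ev) stringify_type(ev$type),
                    character(1))
    mt <- map_event_types(types, known)
    write_event_types(con, mt$map, mt$created)
    st <- vapply(events, function(ev) as.double(ev$start_time), double(1))
    en <- vapply(events, function(ev)
      as.double(ev$end_time %||% ev$start_time), double(1))
    ce <- vapply(events, function(ev) as.double(ev$certainty %||% 1.0),
                 double(1))
    ev_uuids <- write_events(con, dataset_uuid, unname(mt$map[types]),
                             st, en, ce)
    ## extra event fields -> attributes, as for EEG
    paths <- character(0); vals <- list(); owners <- character(0)
    std <- c("type", "start_time", "end_time", "certainty")
    for (i in seq_along(events)) {
      for (f in setdiff(names(events[[i]]), std)) {
        paths <- c(paths, paste0("/event/", f))
        vals <- c(vals, list(events[[i]][[f]]))
        owners <- c(owners, ev_uuids[i])
      }
    }
    write_attribute_rows(con, owners, "events", paths, vals)

    elems <- g$element %||% list()
    if (length(elems)) {
      DBI::dbExecute(con$db,
        "INSERT INTO elements (element_uuid, element_dataset_uuid,
           element_label, element_position, element_description)
         VALUES (:u, :d, :l, :p, :de)",
        params = list(
          u = new_uuid(length(elems)),
          d = rep(dataset_uuid, length(elems)),
          l = vapply(elems, function(el)
            as.character(el$label %||% ""), character(1)),
          p = seq_along(elems),
          de = vapply(elems, function(el)
            as.character(el$description %||% ""), character(1))))
    }
    spaths <- character(0); svals <- list()
    for (section in c("feature", "metadata")) {
      recs <- g[[section]] %||% list()
      for (i in seq_along(recs)) {
        for (f in names(recs[[i]])) {
          spaths <- c(spaths, sprintf("/%s/%d/%s", section, i, f))
          svals <- c(svals, list(recs[[i]][[f]]))
        }
      }
    }
    write_attribute_rows(con, rep(dataset_uuid, length(spaths)), "datasets",
                         spaths, svals)
    fault_point("explode_generic")
    list(event_uuids = ev_uuids, type_map = mt$map)
  })
}

#' Explode handler for the SIMPLE modality
#'
#' SIMPLE archives the payload without decomposition: no EVENTS or
#' ATTRIBUTES rows are created. Tags, attributes and data maps can still be
#' attached to the dataset afterwards.
#'
#' @inheritParams explode_eeg
#' @return List with empty `event_uuids` and unchanged `type_map`.
#' @export
explode_simple <- function(con, dataset_uuid, known = character(0)) {
  assert_open(con)
  list(event_uuids = character(0), type_map = known)
}

#' Register a new modality
#'
#' Extensibility point: adds a row to the modality registry and installs an
#' explosion handler for datasets of that modality stored through this
#' connection. The handler is called as
#' `handler(con, dataset_uuid, struct, known)` and must return a list with
#' `event_uuids` and `type_map` (see [explode_eeg()] for the contract).
#'
#' @param con Open connection.
#' @param name Modality name, unique in the database.
#' @param handler Explosion function.
#' @param description Free-text description.
#' @return The new modality UUID.
#' @export
register_modality <- function(con, name, handler, description = "") {
  assert_open(con)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(handler))
  with_txn(con, {
    if (nrow(modality_by_name(con, name)) > 0L)
      stop(sprintf("modality '%s' is already registered", name),
           call. = FALSE)
    u <- new_uuid()
    DBI::dbExecute(con$db,
      "INSERT INTO modalities (modality_uuid, modality_name, modality_description)
       VALUES (:u, :n, :d)",
      params = list(u = u, n = name, d = description))
    fault_point("register_modality")
    con$handlers[[name]] <- handler
    u
  })
}

lookup_handler <- function(con, name) {
  if (!is.null(con$handlers[[name]])) return(con$handlers[[name]])
  switch(name,
    SIMPLE = function(con, uuid, struct, known)
      explode_simple(con, uuid, known),
    EEG = explode_eeg,
    GENERIC = explode_generic,
    stop(sprintf("no explosion handler registered for modality '%s' on this connection",
                 name), call. = FALSE))
}

## Payload codecs, keyed by modality. encode: structure -> raw bytes;
## decode: raw bytes -> structure. The store itself is format-agnostic.
modality_codec <- function(name) {
  if (name %in% c("EEG", "GENERIC")) {
    var <- if (name == "EEG") "EEG" else "x"
    list(
      encode = function(struct) mat_serialize(struct, name = var),
      decode = function(bytes) normalize_container(mat_deserialize(bytes)[[1L]])
    )
  } else {
    list(
      encode = function(struct) serialize(struct, NULL, xdr = FALSE),
      decode = function(bytes) unserialize(bytes)
    )
  }
}
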