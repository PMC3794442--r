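## Auxiliary data definitions: secondary data (feature vectors, spectra,
## alternative decompositions, ...) created independently of any dataset and
## associated with entities through data maps. Five formats are supported:
##   NUMERIC_VALUE  one vector of doubles
##   NUMERIC_STREAM time-stamped vectors of doubles (one row per column)
##   XML_VALUE      one XML string
##   XML_STREAM     time-stamped XML strings
##   EXTERNAL       an opaque blob, never exploded
## Stream timestamps are seconds from the start of the data itself: with a
## sampling rate fs they are 0, 1/fs, 2/fs, ...; otherwise explicit,
## strictly increasing timestamps are required and the stored rate is -1.

pack_doubles <- function(v) writeBin(as.double(v), raw(), size = 8L,
                                     endian = "little")
unpack_doubles <- function(r, n) readBin(r, "double", n = n, size = 8L,
                                         endian = "little")

#' Create a data definition
#'
#' Writes a DATADEFS row and, for non-EXTERNAL formats, explodes the data
#' into the matching value/stream table (one row per column for streams, so
#' individual time points are directly searchable and retrievable). The
#' definition is not yet associated with any entity — use [map_datadef()].
#'
#' @param con Open connection.
#' @param format One of `"NUMERIC_VALUE"`, `"NUMERIC_STREAM"`,
#'   `"XML_VALUE"`, `"XML_STREAM"`, `"EXTERNAL"`.
#' @param data Numeric vector (NUMERIC_VALUE), numeric matrix with time
#'   points in columns (NUMERIC_STREAM), XML string(s) (XML_VALUE /
#'   XML_STREAM), or raw bytes (EXTERNAL).
#' @param sampling_rate Sampling rate in Hz for uniformly sampled streams;
#'   `-1` (the stored sentinel) otherwise. Epoched data can be stored with a
#'   rate of 1 so that epochs get timestamps 0, 1, 2, ...
#' @param timestamps Explicit strictly increasing timestamps (seconds from
#'   the start of the data) for non-uniform streams; exclusive with a
#'   positive `sampling_rate`.
#' @param description Free-text description.
#' @return The new data definition UUID.
#' @export
create_datadef <- function(con, format, data, sampling_rate = -1,
                           timestamps = NULL, description = "") {
  assert_open(con)
  format <- match.arg(format, DATADEF_FORMATS)
  is_stream <- format %in% c("NUMERIC_STREAM", "XML_STREAM")
  if (is_stream) {
    if ((sampling_rate > 0) == !is.null(timestamps))
      stop("streams need a positive sampling_rate or explicit timestamps, not both",
           call. = FALSE)
  } else {
    if (sampling_rate > 0 || !is.null(timestamps))
      stop(sprintf("%s is not a stream format: no sampling rate or timestamps",
                   format), call. = FALSE)
  }
  with_txn(con, {
    u <- new_uuid()
    n_items <- switch(format,
      NUMERIC_STREAM = {
        if (!is.matrix(data)) data <- matrix(as.double(data), nrow = 1L)
        ncol(data)
      },
      XML_STREAM = length(data),
      1L)
    ts <- if (is_stream) {
      if (!is.null(timestamps)) {
        timestamps <- as.double(timestamps)
        if (length(timestamps) != n_items)
          stop("timestamps length must equal the number of stream items",
               call. = FALSE)
        if (n_items > 1L && any(diff(timestamps) <= 0))
          stop("stream timestamps must be strictly increasing",
               call. = FALSE)
        timestamps
      } else (seq_len(n_items) - 1L) / sampling_rate
    } else NULL

    DBI::dbExecute(con$db,
      "INSERT INTO datadefs (datadef_uuid, datadef_format,
         datadef_sampling_rate, datadef_description, datadef_oid, data)
       VALUES (:u, :f, :sr, :d, :o, :b)",
      params = list(
        u = u, f = format,
        sr = if (is_stream && sampling_rate > 0) sampling_rate else -1,
        d = description, o = u,
        b = if (format == "EXTERNAL") list(as.raw(data)) else list(raw(0))))
    fault_point("create_datadef")

    switch(format,
      NUMERIC_VALUE = {
        v <- as.double(data)
        DBI::dbExecute(con$db,
          "INSERT INTO numeric_values (numeric_value_uuid,
             numeric_value_datadef_uuid, numeric_value_length, numeric_value)
           VALUES (:vu, :du, :n, :v)",
          params = list(vu = new_uuid(), du = u, n = length(v),
                        v = list(pack_doubles(v))))
      },
      NUMERIC_STREAM = {
        for (i in seq_len(ncol(data))) {
          DBI::dbExecute(con$db,
            "INSERT INTO numeric_streams (numeric_stream_uuid,
               numeric_stream_datadef_uuid, numeric_stream_time,
               numeric_stream_length, numeric_stream)
             VALUES (:su, :du, :t, :n, :v)",
            params = list(su = new_uuid(), du = u, t = ts[i],
                          n = nrow(data),
                          v = list(pack_doubles(data[, i]))))
        }
      },
      XML_VALUE = {
        DBI::dbExecute(con$db,
          "INSERT INTO xml_values (xml_value_uuid, xml_value_datadef_uuid,
             xml_value) VALUES (:vu, :du, :x)",
          params = list(vu = new_uuid(), du = u,
                        x = as.character(data)[1L]))
      },
      XML_STREAM = {
        DBI::dbExecute(con$db,
          "INSERT INTO xml_streams (xml_stream_uuid,
             xml_stream_datadef_uuid, xml_stream_time, xml_stream)
           VALUES (:su, :du, :t, :x)",
          params = list(su = new_uuid(length(data)),
                        du = rep(u, length(data)), t = ts,
                        x = as.character(data)))
      },
      EXTERNAL = NULL)
    u
  })
}

#' Retrieve a data definition
#'
#' Reconstitutes the stored payload: element-exact for numeric data,
#' byte-/string-exact for EXTERNAL and XML. Stream columns are reassembled
#' in ascending-timestamp order regardless of insertion order.
#'
#' @param con Open connection.
#' @param uuid Data definition UUID.
#' @return List with `datadef_uuid`, `format`, `sampling_rate`,
#'   `description`, `data`, and (for streams) `timestamps`.
#' @export
retrieve_datadef <- function(con, uuid) {
  assert_open(con)
  row <- DBI::dbGetQuery(con$db,
    "SELECT * FROM datadefs WHERE datadef_uuid = :u", params = list(u = uuid))
  if (nrow(row) == 0L)
    stop(sprintf("data definition %s not found", uuid), call. = FALSE)
  fmt <- row$datadef_format[1L]
  out <- list(datadef_uuid = uuid, format = fmt,
              sampling_rate = row$datadef_sampling_rate[1L],
              description = row$datadef_description[1L],
              data = NULL, timestamps = NULL)
  if (fmt == "NUMERIC_VALUE") {
    v <- DBI::dbGetQuery(con$db,
      "SELECT numeric_value_length AS n, numeric_value AS v
       FROM numeric_values WHERE numeric_value_datadef_uuid = :u",
      params = list(u = uuid))
    out$data <- unpack_doubles(v$v[[1L]], v$n[1L])
  } else if (fmt == "NUMERIC_STREAM") {
    v <- DBI::dbGetQuery(con$db,
      "SELECT numeric_stream_time AS t, numeric_stream_length AS n,
              numeric_stream AS v
       FROM numeric_streams WHERE numeric_stream_datadef_uuid = :u
       ORDER BY numeric_stream_time", params = list(u = uuid))
    cols <- lapply(seq_len(nrow(v)),
                   function(i) unpack_doubles(v$v[[i]], v$n[i]))
    out$data <- if (nrow(v)) do.call(cbind, cols) else
      matrix(numeric(0), nrow = 0L, ncol = 0L)
    out$timestamps <- v$t
  } else if (fmt == "XML_VALUE") {
    v <- DBI::dbGetQuery(con$db,
      "SELECT xml_value AS x FROM xml_values
       WHERE xml_value_datadef_uuid = :u", params = list(u = uuid))
    out$data <- v$x[1L]
  } else if (fmt == "XML_STREAM") {
    v <- DBI::dbGetQuery(con$db,
      "SELECT xml_stream_time AS t, xml_stream AS x FROM xml_streams
       WHERE xml_stream_datadef_uuid = :u ORDER BY xml_stream_time",
      params = list(u = uuid))
    out$data <- v$x
    out$timestamps <- v$t
  } else {
    out$data <- row$data[[1L]]
  }
  out
}

#' Associate a data definition with an entity
#'
#' Writes one DATAMAPS row. Associations are many-to-many: one definition
#' may map to many entities (and an entity may carry many definitions), each
#' under a structure path saying where the data belongs in the entity's
#' structure (e.g. `'/dataEx'`).
#'
#' @param con Open connection.
#' @param datadef_uuid Data definition UUID; must exist.
#' @param entity An [entity_ref()]; must exist.
#' @param path Structure path for the association.
#' @return The new data map UUID.
#' @export
map_datadef <- function(con, datadef_uuid, entity, path) {
  assert_open(con)
  stopifnot(inherits(entity, "entity_ref"))
  with_txn(con, {
    assert_entity(con, entity_ref(datadef_uuid, "datadefs"))
    assert_entity(con, entity)
    u <- new_uuid()
    DBI::dbExecute(con$db,
      "INSERT INTO datamaps (datamap_uuid, datamap_datadef_uuid,
         datamap_entity_uuid, datamap_entity_class, datamap_path)
       VALUES (:u, :du, :eu, :ec, :p)",
      params = list(u = u, du = datadef_uuid, eu = entity$uuid,
                    ec = entity$class, p = path))
    fault_point("map_datadef")
    u
  })
}

#' Retrieve the data behind a set of data maps
#'
#' Given data map rows (as returned by [get_rows()] on `"datamaps"`),
#' reconstitutes each referenced definition, preserving input order, and
#' labels every result with its structure path.
#'
#' @param con Open connection.
#' @param maps Data frame with `datamap_datadef_uuid` and `datamap_path`
#'   columns, or a list of such records.
#' @return List of lists, each with `path` and `data` (a
#'   [retrieve_datadef()] result).
#' @export
retrieve_mapped <- function(con, maps) {
  assert_open(con)
  if (is.data.frame(maps)) {
    maps <- lapply(seq_len(nrow(maps)), function(i) as.list(maps[i, ]))
  }
  lapply(maps, function(m) {
    list(path = m$datamap_path,
         data = retrieve_datadef(con, m$datamap_datadef_uuid))
  })
}
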