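## Whole-dataset storage and retrieval. The payload always stays intact as a
## single binary object; the modality handler decides what gets exploded
## into searchable tables alongside it.

#' Next version for a (namespace, name) pair
#'
#' Versions for a fixed pair form the sequence 1, 2, 3, ... with no gaps;
#' this returns 1 when the pair is unused and one past the current maximum
#' otherwise. Matching is case-sensitive exact.
#'
#' @param con Open connection.
#' @param namespace Dataset namespace.
#' @param name Dataset name.
#' @return Positive integer.
#' @export
next_version <- function(con, namespace, name) {
  assert_open(con)
  mx <- DBI::dbGetQuery(con$db,
    "SELECT MAX(dataset_version) AS v FROM datasets
     WHERE dataset_namespace = :ns AND dataset_name = :n",
    params = list(ns = namespace, n = name))$v
  if (is.na(mx)) 1L else as.integer(mx) + 1L
}

#' Store a dataset
#'
#' Archives `data` as an opaque binary payload in a new DATASETS row, fills
#' unset fields with the documented defaults (namespace `"mobbed"`, contact
#' `"System"`, the fixed default parent UUID, modality `"EEG"`), dispatches
#' to the modality's explosion handler, and attaches any `tags` to the new
#' dataset. The whole call is one transaction.
#'
#' `data` may be a raw vector (stored verbatim) or a container structure
#' (encoded through the modality codec: the MAT-file layout for EEG and
#' GENERIC, native R serialization otherwise). With `is_unique = TRUE` (the
#' default) a second store of an existing (name, namespace) fails and writes
#' nothing; with `is_unique = FALSE` the version is incremented instead.
#'
#' @param con Open connection.
#' @param name Dataset name (required, non-empty).
#' @param data Payload: raw vector or container structure.
#' @param namespace Dataset namespace.
#' @param description Free-text description.
#' @param modality Modality name (`"SIMPLE"`, `"EEG"`, `"GENERIC"`, or a
#'   registered one).
#' @param parent_uuid Lineage pointer to the dataset this one derives from.
#' @param session_uuid Groups datasets acquired in one session.
#' @param contact Contact name resolved against the CONTACTS table.
#' @param tags Character vector of tags to attach to the dataset.
#' @param event_types Character vector of EVENT_TYPE_UUID keys whose type
#'   names should be reused during explosion.
#' @param is_unique Fail on an existing (name, namespace) instead of
#'   creating a new version.
#' @return List with `dataset_uuid` and `event_type_uuids` (the input list
#'   extended with any newly created types).
#' @export
store_dataset <- function(con, name, data, namespace = DEFAULT_NAMESPACE,
                          description = "", modality = "EEG",
                          parent_uuid = DEFAULT_PARENT_UUID,
                          session_uuid = NULL, contact = DEFAULT_CONTACT,
                          tags = character(0), event_types = character(0),
                          is_unique = TRUE) {
  assert_open(con)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("dataset name must be a non-empty string", call. = FALSE)
  if (missing(data) || is.null(data))
    stop("dataset data is required", call. = FALSE)
  with_txn(con, {
    mod <- modality_by_name(con, modality)
    if (nrow(mod) == 0L)
      stop(sprintf("unknown modality '%s'", modality), call. = FALSE)
    existing <- next_version(con, namespace, name) - 1L
    if (existing > 0L && is_unique)
      stop(sprintf("dataset ('%s', '%s') already exists and IsUnique is TRUE",
                   name, namespace), call. = FALSE)
    version <- existing + 1L

    codec <- modality_codec(modality)
    if (is.raw(data)) {
      payload <- data
      struct <- NULL
      if (modality %in% c("EEG", "GENERIC")) {
        struct <- tryCatch(codec$decode(payload), error = function(e)
          stop(sprintf("payload is not a readable %s container: %s",
                       modality, conditionMessage(e)), call. = FALSE))
      }
    } else {
      struct <- data
      payload <- codec$encode(struct)
    }

    uuid <- new_uuid()
    contact_row <- contact_by_name(con, contact)
    contact_uuid <- if (nrow(contact_row)) contact_row$contact_uuid[1L]
                    else NA_character_
    DBI::dbExecute(con$db,
      "INSERT INTO datasets (dataset_uuid, dataset_session_uuid,
         dataset_namespace, dataset_name, dataset_version,
         dataset_contact_uuid, dataset_creation_date, dataset_description,
         dataset_parent_uuid, dataset_modality_uuid, dataset_oid, data)
       VALUES (:u, :s, :ns, :n, :v, :c, :cd, :de, :p, :m, :o, :d)",
      params = list(u = uuid, s = session_uuid %||% NA_character_,
                    ns = namespace, n = name, v = version,
                    c = contact_uuid,
                    cd = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                                tz = "UTC"),
                    de = description, p = parent_uuid, m = mod$modality_uuid,
                    o = uuid, d = list(payload)))
    fault_point("store_dataset")

    known <- type_map_from_uuids(con, event_types)
    handler <- lookup_handler(con, modality)
    res <- if (modality == "SIMPLE") explode_simple(con, uuid, known)
           else handler(con, uuid, struct, known)

    if (length(tags))
      add_tags(con, entity_ref(uuid, "datasets"), tags)
    list(dataset_uuid = uuid,
         event_type_uuids = unique(c(event_types,
                                     unname(res$type_map))))
  })
}

#' Retrieve a dataset
#'
#' Returns every DATASETS column for `uuid` plus the payload, byte-identical
#' to what was stored. Retrieval is always whole-dataset; there are no
#' partial blob reads. With `as = "auto"` the payload is decoded back into a
#' container structure when it is recognizably one (MAT-file bytes for
#' EEG/GENERIC, native R serialization otherwise); `as = "raw"` always
#' returns the stored bytes.
#'
#' @param con Open connection.
#' @param uuid Dataset UUID.
#' @param as `"auto"` or `"raw"`.
#' @return Named list of dataset fields; payload in `$data`.
#' @export
retrieve_dataset <- function(con, uuid, as = c("auto", "raw")) {
  assert_open(con)
  as <- match.arg(as)
  row <- DBI::dbGetQuery(con$db,
    "SELECT * FROM datasets WHERE dataset_uuid = :u", params = list(u = uuid))
  if (nrow(row) == 0L)
    stop(sprintf("dataset %s not found", uuid), call. = FALSE)
  rec <- as.list(row[1L, setdiff(names(row), "data")])
  payload <- row$data[[1L]]
  rec$data <- payload
  if (as == "auto") {
    if (looks_like_mat(payload)) {
      rec$data <- tryCatch(
        normalize_container(mat_deserialize(payload)[[1L]]),
        error = function(e) payload)
    } else if (length(payload) >= 2L &&
               identical(payload[1:2], charToRaw("B\n"))) {
      rec$data <- tryCatch(unserialize(payload), error = function(e) payload)
    }
  }
  rec
}
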