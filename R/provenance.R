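## Provenance / caching: the TRANSFORMS table is a hash-table-like mapping
## from normalized command strings to the UUIDs of the datasets they
## produced. A cache hit means the result can be retrieved instead of
## recomputed; searching strings that contain an input UUID finds every
## dataset derived from it (forward provenance).

#' Normalize a transform string
#'
#' Builds the canonical command string stored in the TRANSFORMS table:
#' every placeholder in `substitutions` is replaced (whole-token) by its
#' UUID, then extra blanks are removed under a fixed rule — whitespace runs
#' collapse to single spaces and spaces adjacent to the delimiters
#' `( ) , [ ]` are deleted. The result is deterministic and the
#' normalization is idempotent.
#'
#' @param template Command string, e.g. `"pop_eegfilt(EEG, 1.0, 0, [], 0)"`.
#' @param substitutions Named character vector, placeholder name to UUID.
#' @return Normalized string.
#' @export
normalize_transform <- function(template, substitutions = character(0)) {
  stopifnot(is.character(template), length(template) == 1L)
  s <- template
  for (ph in names(substitutions)) {
    pat <- paste0("\\b", ph, "\\b")
    if (!grepl(pat, s))
      stop(sprintf("placeholder '%s' does not occur in the template", ph),
           call. = FALSE)
    s <- gsub(pat, substitutions[[ph]], s)
  }
  s <- gsub("\\s+", " ", s, perl = TRUE)
  s <- gsub(" *([(),\\[\\]]) *", "\\1", s, perl = TRUE)
  trimws(s)
}

#' Record a transform
#'
#' Stores one TRANSFORMS row linking the produced entity's UUID to the
#' command string that created it. Duplicate strings are tolerated —
#' [lookup_transform()] returns all of them.
#'
#' @param con Open connection.
#' @param produced_uuid UUID of the produced dataset; must exist.
#' @param transform_string Non-empty normalized command string.
#' @param description Free-text description of the processing step.
#' @return `produced_uuid`, invisibly.
#' @export
store_transform <- function(con, produced_uuid, transform_string,
                            description = "") {
  assert_open(con)
  if (!is.character(transform_string) || length(transform_string) != 1L ||
      !nzchar(transform_string))
    stop("transform string must be non-empty", call. = FALSE)
  invisible(with_txn(con, {
    assert_entity(con, entity_ref(produced_uuid, "datasets"))
    DBI::dbExecute(con$db,
      "INSERT INTO transforms (transform_uuid, transform_string,
         transform_description) VALUES (:u, :s, :d)",
      params = list(u = produced_uuid, s = transform_string,
                    d = description))
    fault_point("store_transform")
    produced_uuid
  }))
}

#' Look up a transform string
#'
#' Exact-string cache lookup: returns every TRANSFORMS row whose string
#' equals the query. An empty result is the cache-miss signal — recompute
#' and [store_transform()] the result.
#'
#' @param con Open connection.
#' @param transform_string String to look up.
#' @return Data frame with `transform_uuid`, `transform_string`,
#'   `transform_description` (zero rows on a miss).
#' @export
lookup_transform <- function(con, transform_string) {
  assert_open(con)
  DBI::dbGetQuery(con$db,
    "SELECT transform_uuid, transform_string, transform_description
     FROM transforms WHERE transform_string = :s",
    params = list(s = transform_string))
}
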