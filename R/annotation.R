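## Tags, attributes and collections: the semi-structured metadata layer.
## Tags are free-floating strings (plain or '/'-separated hierarchical
## paths, e.g. HED descriptors); attributes are typed values anchored at a
## structure path; collections are arbitrary groupings of entities. All
## three attach to rows of any table through (entity_uuid, entity_class).

#' Attach tags to an entity
#'
#' Stores one TAGS row per name. Names are stored verbatim (hierarchy and
#' case untouched — prefix semantics live entirely in the query layer);
#' re-adding an existing (name, entity) pair is a no-op that returns the
#' existing row's UUID.
#'
#' @param con Open connection.
#' @param entity An [entity_ref()]; must exist.
#' @param names Character vector of tag strings.
#' @return Character vector of tag UUIDs, one per name.
#' @export
add_tags <- function(con, entity, names) {
  assert_open(con)
  stopifnot(inherits(entity, "entity_ref"), is.character(names))
  if (any(!nzchar(names)))
    stop("tag names must be non-empty", call. = FALSE)
  if (length(names) == 0L) return(character(0))
  with_txn(con, {
    assert_entity(con, entity)
    vapply(names, function(nm) {
      ex <- DBI::dbGetQuery(con$db,
        "SELECT tag_uuid FROM tags WHERE tag_name = :n
           AND tag_entity_uuid = :eu AND tag_entity_class = :ec",
        params = list(n = nm, eu = entity$uuid, ec = entity$class))
      if (nrow(ex)) return(ex$tag_uuid[1L])
      u <- new_uuid()
      DBI::dbExecute(con$db,
        "INSERT INTO tags (tag_uuid, tag_name, tag_entity_uuid, tag_entity_class)
         VALUES (:u, :n, :eu, :ec)",
        params = list(u = u, n = nm, eu = entity$uuid, ec = entity$class))
      fault_point("add_tags")
      u
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Attach an attribute to an entity
#'
#' Attributes locate a value in the entity's original structure: the path
#' (e.g. `'/event/target_dist'`) says where the value lived. Numeric scalars
#' go to the numeric column, everything else to the string column — exactly
#' one of the two is set. Multiple rows per (entity, path) are allowed,
#' since per-channel and per-index attributes naturally repeat.
#'
#' @inheritParams add_tags
#' @param path `'/'`-separated structure path, starting with `'/'`.
#' @param value A numeric scalar or a string (XML strings welcome).
#' @return The new attribute UUID.
#' @export
add_attribute <- function(con, entity, path, value) {
  assert_open(con)
  stopifnot(inherits(entity, "entity_ref"))
  if (!is.character(path) || length(path) != 1L || !startsWith(path, "/"))
    stop("attribute path must be a single string starting with '/'",
         call. = FALSE)
  if (is.null(value) || length(value) != 1L ||
      !(is.numeric(value) || is.character(value)))
    stop("attribute value must be a single number or string", call. = FALSE)
  with_txn(con, {
    assert_entity(con, entity)
    u <- write_attribute_rows(con, entity$uuid, entity$class, path,
                              list(value))
    fault_point("add_attribute")
    u
  })
}

#' Create a collection of entities
#'
#' A collection is an arbitrary grouping of entities, possibly spanning
#' tables; the collection itself is an entity (class `"collections"`) and
#' can carry tags, attributes and data maps. Every member must exist; a
#' dangling member aborts the call with nothing written.
#'
#' @param con Open connection.
#' @param members List of [entity_ref()] objects (may be empty).
#' @return The new collection UUID.
#' @export
create_collection <- function(con, members = list()) {
  assert_open(con)
  stopifnot(is.list(members),
            all(vapply(members, inherits, logical(1), "entity_ref")))
  with_txn(con, {
    for (m in members) assert_entity(con, m)
    u <- new_uuid()
    ## anchor row: the collection exists even with no members
    DBI::dbExecute(con$db,
      "INSERT INTO collections (collection_uuid, collection_entity_uuid,
         collection_entity_class) VALUES (:u, NULL, NULL)",
      params = list(u = u))
    for (m in members) {
      DBI::dbExecute(con$db,
        "INSERT INTO collections (collection_uuid, collection_entity_uuid,
           collection_entity_class) VALUES (:u, :eu, :ec)",
        params = list(u = u, eu = m$uuid, ec = m$class))
      fault_point("create_collection")
    }
    u
  })
}

#' Members of a collection
#'
#' @param con Open connection.
#' @param collection_uuid Collection UUID.
#' @return Data frame with `entity_uuid` and `entity_class` columns.
#' @export
collection_members <- function(con, collection_uuid) {
  assert_open(con)
  df <- DBI::dbGetQuery(con$db,
    "SELECT collection_entity_uuid AS entity_uuid,
            collection_entity_class AS entity_class
     FROM collections
     WHERE collection_uuid = :u AND collection_entity_uuid IS NOT NULL",
    params = list(u = collection_uuid))
  df
}
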