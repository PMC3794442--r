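#' @importFrom DBI dbConnect dbDisconnect dbExecute dbGetQuery dbBegin dbCommit
#'   dbRollback dbListTables
NULL

## Canonical table registry. Column types drive both the DDL and the query
## layer's matching semantics ("uuid" and "text" are string-matched, "numeric"
## and "int" exactly, "blob" columns never cross the query surface).
.col <- function(...) c(...)

.schema_tables <- list(
  datasets = list(
    pk = "dataset_uuid",
    cols = c(dataset_uuid = "uuid", dataset_session_uuid = "uuid",
             dataset_namespace = "text", dataset_name = "text",
             dataset_version = "int", dataset_contact_uuid = "uuid",
             dataset_creation_date = "text", dataset_description = "text",
             dataset_parent_uuid = "uuid", dataset_modality_uuid = "uuid",
             dataset_oid = "uuid", data = "blob"),
    unique = list(c("dataset_name", "dataset_namespace", "dataset_version"))
  ),
  events = list(
    pk = "event_uuid",
    cols = c(event_uuid = "uuid", event_dataset_uuid = "uuid",
             event_type_uuid = "uuid", event_start_time = "numeric",
             event_end_time = "numeric", event_certainty = "numeric")
  ),
  event_types = list(
    pk = "event_type_uuid",
    cols = c(event_type_uuid = "uuid", event_type = "text",
             event_type_description = "text")
  ),
  tags = list(
    pk = "tag_uuid",
    cols = c(tag_uuid = "uuid", tag_name = "text",
             tag_entity_uuid = "uuid", tag_entity_class = "text"),
    unique = list(c("tag_name", "tag_entity_uuid", "tag_entity_class"))
  ),
  attributes = list(
    pk = "attribute_uuid",
    cols = c(attribute_uuid = "uuid", attribute_entity_uuid = "uuid",
             attribute_entity_class = "text", attribute_path = "text",
             attribute_numeric_value = "numeric", attribute_value = "text")
  ),
  datadefs = list(
    pk = "datadef_uuid",
    cols = c(datadef_uuid = "uuid", datadef_format = "text",
             datadef_sampling_rate = "numeric", datadef_description = "text",
             datadef_oid = "uuid", data = "blob")
  ),
  datamaps = list(
    pk = "datamap_uuid",
    cols = c(datamap_uuid = "uuid", datamap_datadef_uuid = "uuid",
             datamap_entity_uuid = "uuid", datamap_entity_class = "text",
             datamap_path = "text")
  ),
  numeric_values = list(
    pk = "numeric_value_uuid",
    cols = c(numeric_value_uuid = "uuid", numeric_value_datadef_uuid = "uuid",
             numeric_value_length = "int", numeric_value = "blob")
  ),
  numeric_streams = list(
    pk = "numeric_stream_uuid",
    cols = c(numeric_stream_uuid = "uuid",
             numeric_stream_datadef_uuid = "uuid",
             numeric_stream_time = "numeric",
             numeric_stream_length = "int", numeric_stream = "blob")
  ),
  xml_values = list(
    pk = "xml_value_uuid",
    cols = c(xml_value_uuid = "uuid", xml_value_datadef_uuid = "uuid",
             xml_value = "text")
  ),
  xml_streams = list(
    pk = "xml_stream_uuid",
    cols = c(xml_stream_uuid = "uuid", xml_stream_datadef_uuid = "uuid",
             xml_stream_time = "numeric", xml_stream = "text")
  ),
  collections = list(
    pk = NA_character_,
    cols = c(collection_uuid = "uuid", collection_entity_uuid = "uuid",
             collection_entity_class = "text")
  ),
  transforms = list(
    pk = NA_character_,
    cols = c(transform_uuid = "uuid", transform_string = "text",
             transform_description = "text")
  ),
  modalities = list(
    pk = "modality_uuid",
    cols = c(modality_uuid = "uuid", modality_name = "text",
             modality_description = "text"),
    unique = list("modality_name")
  ),
  comments = list(
    pk = "comment_uuid",
    cols = c(comment_uuid = "uuid", comment_entity_uuid = "uuid",
             comment_entity_class = "text", comment_value = "text")
  ),
  contacts = list(
    pk = "contact_uuid",
    cols = c(contact_uuid = "uuid", contact_name = "text",
             contact_description = "text")
  ),
  devices = list(
    pk = "device_uuid",
    cols = c(device_uuid = "uuid", device_entity_uuid = "uuid",
             device_entity_class = "text", device_description = "text")
  ),
  elements = list(
    pk = "element_uuid",
    cols = c(element_uuid = "uuid", element_dataset_uuid = "uuid",
             element_label = "text", element_position = "int",
             element_description = "text")
  ),
  subjects = list(
    pk = "subject_uuid",
    cols = c(subject_uuid = "uuid", subject_entity_uuid = "uuid",
             subject_entity_class = "text", subject_description = "text")
  )
)

## Parent UUID assigned to datasets stored without an explicit parent.
DEFAULT_PARENT_UUID <- "591df7dd-ce3e-47f8-bea5-6a632c6fcccb"
DEFAULT_NAMESPACE <- "mobbed"
DEFAULT_CONTACT <- "System"
BUILTIN_MODALITIES <- c("SIMPLE", "EEG", "GENERIC")
DATADEF_FORMATS <- c("NUMERIC_VALUE", "NUMERIC_STREAM", "XML_VALUE",
                     "XML_STREAM", "EXTERNAL")

.sql_type <- c(uuid = "TEXT", text = "TEXT", numeric = "REAL",
               int = "INTEGER", blob = "BLOB")

#' SQL DDL for the full schema
#'
#' Returns the idempotent `CREATE TABLE IF NOT EXISTS` statements defining all
#' nineteen tables of the data model. The same statements are bundled as
#' `inst/sql/schema.sql` for use outside R.
#'
#' @return Character vector of SQL statements.
#' @export
schema_ddl <- function() {
  vapply(names(.schema_tables), function(tn) {
    tb <- .schema_tables[[tn]]
    defs <- vapply(names(tb$cols), function(cn) {
      d <- paste(cn, .sql_type[[tb$cols[[cn]]]])
      if (!is.na(tb$pk) && identical(cn, tb$pk)) d <- paste(d, "PRIMARY KEY")
      d
    }, character(1))
    uq <- vapply(tb$unique %||% list(), function(u)
      sprintf("UNIQUE (%s)", paste(u, collapse = ", ")), character(1))
    sprintf("CREATE TABLE IF NOT EXISTS %s (\n  %s\n);",
            tn, paste(c(defs, uq), collapse = ",\n  "))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_uuid <- function(n = 1) tolower(uuid::UUIDgenerate(n = n))

is_uuid <- function(x) {
  is.character(x) & grepl(
    "^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$", x)
}

## Hook for fault-injection tests: an option-supplied function is called at
## named points inside write paths; if it throws, the surrounding transaction
## must roll back completely.
fault_point <- function(label) {
  hook <- getOption("eventstore.fault_hook")
  if (is.function(hook)) hook(label)
  invisible(NULL)
}

#' Describe a database
#'
#' Builds the configuration object used by [create_database()],
#' [delete_database()] and [connect_database()]. The default backend is an
#' embedded single-file SQLite engine, in which case `host` and credentials
#' are ignored and the database lives at `<dir>/<name>.sqlite`. A
#' client-server engine can be used by passing any DBI driver object as
#' `driver` (connection arguments are forwarded to [DBI::dbConnect()]).
#'
#' @param name Database name (non-empty string).
#' @param host Host name or address; ignored by the embedded backend.
#' @param backend `"embedded"` (default) or `"client-server"`.
#' @param user,password Credentials for a client-server backend.
#' @param dir Directory holding embedded database files. Defaults to the
#'   `eventstore.dir` option, falling back to the per-user data directory.
#' @param driver Optional DBI driver object for a client-server backend.
#' @return An object of class `eventstore_config`.
#' @export
db_config <- function(name, host = "localhost",
                      backend = c("embedded", "client-server"),
                      user = NULL, password = NULL, dir = NULL,
                      driver = NULL) {
  backend <- match.arg(backend)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("database name must be a non-empty string", call. = FALSE)
  if (is.null(dir))
    dir <- getOption("eventstore.dir",
                     tools::R_user_dir("eventstore", "data"))
  structure(list(name = name, host = host, backend = backend, user = user,
                 password = password, dir = dir, driver = driver),
            class = "eventstore_config")
}

#' @export
print.eventstore_config <- function(x, ...) {
  cat(sprintf("<eventstore database '%s' (%s backend)>\n", x$name, x$backend))
  invisible(x)
}

db_path <- function(config) file.path(config$dir, paste0(config$name, ".sqlite"))

raw_connect <- function(config) {
  if (config$backend == "embedded") {
    con <- DBI::dbConnect(RSQLite::SQLite(), db_path(config))
  } else {
    if (is.null(config$driver))
      stop("client-server backend requires a DBI driver in db_config(driver=)",
           call. = FALSE)
    con <- DBI::dbConnect(config$driver, dbname = config$name,
                          host = config$host, user = config$user,
                          password = config$password)
  }
  try(DBI::dbExecute(con, "PRAGMA busy_timeout = 10000"), silent = TRUE)
  con
}

## Registry of open embedded connections, used by delete_database()'s
## fail-fast refusal to delete under the caller's own open handles.
.open_registry <- new.env(parent = emptyenv())

registry_key <- function(config) {
  if (config$backend == "embedded") normalizePath(db_path(config),
                                                  mustWork = FALSE)
  else paste(config$host, config$name, sep = "/")
}

#' Create a database
#'
#' Creates a new, empty database with the full nineteen-table schema and
#' seeds the modality registry with the three built-in modalities (`SIMPLE`,
#' `EEG`, `GENERIC`) plus the default `System` contact. The database persists
#' until [delete_database()] is called, independently of the R process.
#'
#' @param config An [db_config()] object.
#' @return `config`, invisibly.
#' @export
create_database <- function(config) {
  stopifnot(inherits(config, "eventstore_config"))
  if (config$backend == "embedded") {
    if (file.exists(db_path(config)))
      stop(sprintf("database '%s' already exists", config$name),
           call. = FALSE)
    dir.create(config$dir, recursive = TRUE, showWarnings = FALSE)
  }
  con <- raw_connect(config)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  if (length(DBI::dbListTables(con)) > 0L)
    stop(sprintf("database '%s' already exists (tables present)",
                 config$name), call. = FALSE)
  DBI::dbBegin(con)
  ok <- FALSE
  tryCatch({
    for (stmt in schema_ddl()) DBI::dbExecute(con, stmt)
    for (m in BUILTIN_MODALITIES)
      DBI::dbExecute(con,
        "INSERT INTO modalities (modality_uuid, modality_name, modality_description)
         VALUES (:u, :n, :d)",
        params = list(u = new_uuid(), n = m,
                      d = paste(m, "modality (built-in)")))
    DBI::dbExecute(con,
      "INSERT INTO contacts (contact_uuid, contact_name, contact_description)
       VALUES (:u, :n, :d)",
      params = list(u = new_uuid(), n = DEFAULT_CONTACT,
                    d = "Default contact"))
    DBI::dbCommit(con)
    ok <- TRUE
  }, error = function(e) {
    DBI::dbRollback(con)
    stop(e)
  })
  if (ok && config$backend == "embedded" && !file.exists(db_path(config)))
    stop("database file was not created", call. = FALSE)
  invisible(config)
}

#' Delete a database
#'
#' Permanently removes a database and all of its contents. Deletion is
#' refused while this process holds an open connection to the database
#' (close the handles first); use with caution on shared databases.
#'
#' @inheritParams create_database
#' @return Invisibly `TRUE`.
#' @export
delete_database <- function(config) {
  stopifnot(inherits(config, "eventstore_config"))
  key <- registry_key(config)
  n_open <- .open_registry[[key]] %||% 0L
  if (n_open > 0L)
    stop(sprintf("refusing to delete '%s': %d open connection(s) held by this process",
                 config$name, n_open), call. = FALSE)
  if (config$backend == "embedded") {
    p <- db_path(config)
    if (!file.exists(p))
      stop(sprintf("database '%s' does not exist", config$name),
           call. = FALSE)
    unlink(p)
  } else {
    con <- raw_connect(config)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    for (tn in rev(names(.schema_tables)))
      DBI::dbExecute(con, paste("DROP TABLE IF EXISTS", tn))
  }
  invisible(TRUE)
}

#' Connect to a database
#'
#' Opens a handle to an existing database. Several handles may be open at
#' once, to the same or different databases; each public operation through a
#' handle executes as one atomic transaction.
#'
#' @inheritParams create_database
#' @return An `eventstore_connection` handle.
#' @export
connect_database <- function(config) {
  stopifnot(inherits(config, "eventstore_config"))
  if (config$backend == "embedded" && !file.exists(db_path(config)))
    stop(sprintf("database '%s' does not exist", config$name), call. = FALSE)
  db <- raw_connect(config)
  tabs <- DBI::dbListTables(db)
  if (!all(names(.schema_tables) %in% tabs)) {
    DBI::dbDisconnect(db)
    stop(sprintf("'%s' is not an eventstore database (schema missing)",
                 config$name), call. = FALSE)
  }
  conn <- new.env(parent = emptyenv())
  conn$db <- db
  conn$config <- config
  conn$open <- TRUE
  conn$in_txn <- FALSE
  conn$cursors <- new.env(parent = emptyenv())
  conn$handlers <- new.env(parent = emptyenv())
  class(conn) <- "eventstore_connection"
  key <- registry_key(config)
  .open_registry[[key]] <- (.open_registry[[key]] %||% 0L) + 1L
  conn
}

#' @export
print.eventstore_connection <- function(x, ...) {
  cat(sprintf("<eventstore connection to '%s' (%s)>\n", x$config$name,
              if (x$open) "open" else "closed"))
  invisible(x)
}

#' Close a connection
#'
#' Disconnects from the database and releases resources. Any further
#' operation through the handle (including a second `close`) signals an
#' error. Other handles to the same database are unaffected.
#'
#' @param con An `eventstore_connection`.
#' @param ... Ignored.
#' @return Invisibly `TRUE`.
#' @export
close.eventstore_connection <- function(con, ...) {
  assert_open(con)
  DBI::dbDisconnect(con$db)
  con$open <- FALSE
  rm(list = ls(con$cursors), envir = con$cursors)
  key <- registry_key(con$config)
  .open_registry[[key]] <- max(0L, (.open_registry[[key]] %||% 1L) - 1L)
  invisible(TRUE)
}

assert_open <- function(con) {
  if (!inherits(con, "eventstore_connection"))
    stop("not an eventstore connection", call. = FALSE)
  if (!isTRUE(con$open))
    stop("connection is closed", call. = FALSE)
  invisible(con)
}

## Every public operation runs inside exactly one transaction; nested public
## calls (e.g. store_dataset -> add_tags) join the outer transaction so that
## the whole call remains all-or-nothing.
with_txn <- function(con, expr) {
  assert_open(con)
  if (con$in_txn) return(force(expr))
  DBI::dbBegin(con$db)
  con$in_txn <- TRUE
  on.exit(con$in_txn <- FALSE, add = TRUE)
  res <- tryCatch(force(expr), error = function(e) {
    DBI::dbRollback(con$db)
    stop(e)
  })
  DBI::dbCommit(con$db)
  res
}

#' List the tables of a database
#'
#' @param con An open connection.
#' @return Character vector of table names.
#' @export
db_list_tables <- function(con) {
  assert_open(con)
  sort(intersect(DBI::dbListTables(con$db), names(.schema_tables)))
}

table_info <- function(table) {
  if (!table %in% names(.schema_tables))
    stop(sprintf("unknown table '%s'", table), call. = FALSE)
  .schema_tables[[table]]
}

## Metadata columns: everything except blobs (blobs never cross the query
## surface; whole payloads go through retrieve_dataset / retrieve_datadef).
meta_cols <- function(table) {
  tb <- table_info(table)
  names(tb$cols)[tb$cols != "blob"]
}

order_col <- function(table) {
  tb <- table_info(table)
  if (!is.na(tb$pk)) tb$pk else names(tb$cols)[1L]
}

#' Reference an entity
#'
#' Builds the (uuid, class) pair by which tags, attributes, data maps and
#' collections point at rows of any table.
#'
#' @param uuid Entity UUID.
#' @param class Table name the entity lives in (e.g. `"datasets"`).
#' @return An `entity_ref` object.
#' @export
entity_ref <- function(uuid, class) {
  class <- tolower(class)
  table_info(class)
  stopifnot(is.character(uuid), length(uuid) == 1L)
  structure(list(uuid = uuid, class = class), class = "entity_ref")
}

entity_exists <- function(con, ref) {
  tb <- table_info(ref$class)
  keycol <- if (!is.na(tb$pk)) tb$pk else names(tb$cols)[1L]
  n <- DBI::dbGetQuery(con$db,
    sprintf("SELECT COUNT(*) AS n FROM %s WHERE %s = :u", ref$class, keycol),
    params = list(u = ref$uuid))$n
  n > 0L
}

assert_entity <- function(con, ref) {
  if (!entity_exists(con, ref))
    stop(sprintf("entity %s not found in table '%s'", ref$uuid, ref$class),
         call. = FALSE)
  invisible(ref)
}

modality_by_name <- function(con, name) {
  DBI::dbGetQuery(con$db,
    "SELECT modality_uuid, modality_name FROM modalities WHERE modality_name = :n",
    params = list(n = name))
}

contact_by_name <- function(con, name) {
  DBI::dbGetQuery(con$db,
    "SELECT contact_uuid FROM contacts WHERE contact_name = :n",
    params = list(n = name))
}
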