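## SQL-free structured search. A query names a table and combines:
##   * column qualifications (direct value, set of choices, or regex),
##   * tag groups and attribute groups (AND across groups, OR within), and
##   * a row limit,
## and returns metadata rows only — payload blobs never cross this surface.
## Results are in a stable total order (ascending key column) so that limits
## are monotone and cursors paginate deterministically.

#' Build a query specification
#'
#' @param table Table to search.
#' @param limit Maximum rows: a non-negative integer, or `Inf` for all rows.
#'   `0` returns the empty template for the table.
#' @param where Named list of column qualifications. String/UUID columns
#'   take a single value or a vector of allowed choices; with
#'   `regexp = TRUE` string patterns are interpreted as regular expressions
#'   (UUID columns always match exactly). Numeric columns match exact
#'   values.
#' @param tags List of tag groups; each group is a single string or a
#'   character vector. Every group must match (AND); within a group one
#'   member suffices (OR).
#' @param attributes List of attribute groups, same shape as `tags`; a
#'   member matches an attribute's path or its stringified value.
#' @param regexp Interpret string qualifications and group members as
#'   regular expressions, anchored at the start of the candidate string.
#' @return A `query_spec` object.
#' @export
query_spec <- function(table, limit = Inf, where = list(),
                       tags = list(), attributes = list(),
                       regexp = FALSE) {
  tb <- table_info(table)
  if (!(is.numeric(limit) && length(limit) == 1L && limit >= 0))
    stop("limit must be a non-negative number or Inf", call. = FALSE)
  bad <- setdiff(names(where), meta_cols(table))
  if (length(bad))
    stop(sprintf("unknown column(s) for table '%s': %s", table,
                 paste(bad, collapse = ", ")), call. = FALSE)
  norm_groups <- function(g) {
    if (is.character(g)) g <- as.list(g)
    lapply(g, function(x) as.character(x))
  }
  structure(list(table = table, limit = limit, where = where,
                 tags = norm_groups(tags),
                 attributes = norm_groups(attributes),
                 regexp = isTRUE(regexp)),
            class = "query_spec")
}

#' Empty row template for a table
#'
#' Returns a one-row data frame whose fields correspond 1-to-1 to the
#' table's (metadata) columns, all unset — the structure a caller fills in
#' to describe a qualified search. Payload blob columns are not part of the
#' query surface.
#'
#' @param con Open connection.
#' @param table Table name.
#' @return One-row data frame of `NA`s with correctly typed columns.
#' @export
get_template <- function(con, table) {
  assert_open(con)
  tb <- table_info(table)
  cols <- meta_cols(table)
  out <- lapply(cols, function(cn) {
    switch(tb$cols[[cn]],
           numeric = NA_real_, int = NA_integer_, NA_character_)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Match a stored string against a qualification
#'
#' The three querying modes for string columns: a single value (direct
#' equality), a vector of allowed choices (membership), or — with
#' `regexp = TRUE` — one or more regular expressions of which at least one
#' must match. Patterns are anchored at the start of the stored string, so
#' `'eeg'` or `'eeg.*'` matches names beginning with "eeg".
#'
#' @param cell Stored string (length-1 character; `NA` never matches).
#' @param qual Character vector of values or patterns.
#' @param regexp Interpret `qual` as regular expressions.
#' @return Logical scalar.
#' @export
match_strings <- function(cell, qual, regexp = FALSE) {
  if (is.na(cell)) return(FALSE)
  qual <- as.character(qual)
  if (!regexp) return(cell %in% qual)
  any(vapply(qual, function(p)
    grepl(paste0("^(?:", p, ")"), cell, perl = TRUE), logical(1)))
}

#' Match an entity's tags against tag groups
#'
#' Conjunction over groups of disjunction over members: every group must be
#' matched (AND), and a group is matched when at least one of its members
#' matches at least one of the entity's tags (OR), using [match_strings()]
#' member semantics. An empty group list matches everything.
#'
#' @param entity_tags Character vector of the entity's tag names.
#' @param groups List of groups (single strings or character vectors).
#' @param regexp Interpret members as regular expressions.
#' @return Logical scalar.
#' @export
match_tag_groups <- function(entity_tags, groups, regexp = FALSE) {
  if (length(groups) == 0L) return(TRUE)
  all(vapply(groups, function(g) {
    g <- as.character(g)
    any(vapply(entity_tags, function(tg)
      match_strings(tg, g, regexp = regexp), logical(1)))
  }, logical(1)))
}

## Candidate strings an attribute row contributes to group matching:
## its path and its stringified value.
attribute_strings <- function(paths, num_vals, str_vals) {
  vals <- ifelse(is.na(num_vals),
                 str_vals,
                 vapply(num_vals, function(v)
                   format(v, trim = TRUE, scientific = FALSE), character(1)))
  c(paths, vals[!is.na(vals)])
}

fetch_entity_tags <- function(con, class, uuids) {
  if (length(uuids) == 0L) return(list())
  df <- DBI::dbGetQuery(con$db,
    "SELECT tag_entity_uuid AS u, tag_name AS n FROM tags
     WHERE tag_entity_class = :c", params = list(c = class))
  split(df$n, factor(df$u, levels = uuids))
}

fetch_entity_attr_strings <- function(con, class, uuids) {
  if (length(uuids) == 0L) return(list())
  df <- DBI::dbGetQuery(con$db,
    "SELECT attribute_entity_uuid AS u, attribute_path AS p,
            attribute_numeric_value AS nv, attribute_value AS sv
     FROM attributes WHERE attribute_entity_class = :c",
    params = list(c = class))
  out <- lapply(split(seq_len(nrow(df)), factor(df$u, levels = uuids)),
                function(idx)
                  attribute_strings(df$p[idx], df$nv[idx], df$sv[idx]))
  out
}

query_matches <- function(con, spec, rows) {
  tb <- table_info(spec$table)
  keep <- rep(TRUE, nrow(rows))
  for (cn in names(spec$where)) {
    qual <- spec$where[[cn]]
    ctype <- tb$cols[[cn]]
    cellv <- rows[[cn]]
    keep <- keep & if (ctype %in% c("numeric", "int")) {
      !is.na(cellv) & cellv %in% as.numeric(qual)
    } else if (ctype == "uuid") {
      !is.na(cellv) & cellv %in% as.character(qual)
    } else {
      vapply(cellv, match_strings, logical(1), qual = qual,
             regexp = spec$regexp)
    }
  }
  key <- rows[[order_col(spec$table)]]
  if (length(spec$tags)) {
    tagmap <- fetch_entity_tags(con, spec$table, unique(key))
    keep <- keep & vapply(key, function(k)
      match_tag_groups(tagmap[[k]] %||% character(0), spec$tags,
                       regexp = spec$regexp), logical(1))
  }
  if (length(spec$attributes)) {
    attrmap <- fetch_entity_attr_strings(con, spec$table, unique(key))
    keep <- keep & vapply(key, function(k)
      match_tag_groups(attrmap[[k]] %||% character(0), spec$attributes,
                       regexp = spec$regexp), logical(1))
  }
  keep
}

run_query <- function(con, spec) {
  cols <- meta_cols(spec$table)
  rows <- DBI::dbGetQuery(con$db,
    sprintf("SELECT %s FROM %s ORDER BY %s",
            paste(cols, collapse = ", "), spec$table,
            order_col(spec$table)))
  rows[query_matches(con, spec, rows), , drop = FALSE]
}

#' Retrieve rows matching a query
#'
#' The structure-based search: rows of `spec$table` satisfying the column
#' qualifications AND every tag group AND every attribute group, in
#' ascending key order, truncated at `spec$limit`. Only metadata columns are
#' returned; whole payloads are fetched with [retrieve_dataset()] /
#' [retrieve_datadef()].
#'
#' @param con Open connection.
#' @param spec A [query_spec()].
#' @return Data frame of matching rows (the empty template for limit 0).
#' @export
get_rows <- function(con, spec) {
  assert_open(con)
  stopifnot(inherits(spec, "query_spec"))
  if (spec$limit == 0) return(get_template(con, spec$table))
  res <- run_query(con, spec)
  if (is.finite(spec$limit) && nrow(res) > spec$limit)
    res <- res[seq_len(spec$limit), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Create or update rows of a table
#'
#' Generic row writer: rows whose primary-key column is unset are inserted
#' with fresh UUIDs; rows carrying an existing primary key update that row's
#' given fields. The batch is atomic — a type error or unknown column aborts
#' with nothing written. Tables without a single-column primary key
#' (COLLECTIONS, TRANSFORMS) are insert-only here.
#'
#' @param con Open connection.
#' @param table Table name.
#' @param rows Data frame or list of named lists; fields must be a subset
#'   of the table's metadata columns.
#' @return Character vector of the affected rows' key values.
#' @export
put_rows <- function(con, table, rows) {
  assert_open(con)
  tb <- table_info(table)
  if (is.data.frame(rows))
    rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))
  stopifnot(is.list(rows))
  with_txn(con, {
    vapply(rows, function(row) {
      row <- row[!vapply(row, function(v)
        is.null(v) || (length(v) == 1L && is.na(v)), logical(1))]
      bad <- setdiff(names(row), meta_cols(table))
      if (length(bad))
        stop(sprintf("unknown column(s) for table '%s': %s", table,
                     paste(bad, collapse = ", ")), call. = FALSE)
      for (cn in names(row)) {
        v <- row[[cn]]
        if (length(v) != 1L)
          stop("row fields must be scalar", call. = FALSE)
        if (tb$cols[[cn]] %in% c("numeric", "int") && !is.numeric(v))
          stop(sprintf("column '%s' expects a numeric value", cn),
               call. = FALSE)
        if (tb$cols[[cn]] %in% c("text", "uuid") && !is.character(v))
          stop(sprintf("column '%s' expects a string value", cn),
               call. = FALSE)
      }
      pk <- tb$pk
      keycol <- if (!is.na(pk)) pk else names(tb$cols)[1L]
      if (!is.na(pk) && !is.null(row[[pk]])) {
        exists <- DBI::dbGetQuery(con$db,
          sprintf("SELECT COUNT(*) AS n FROM %s WHERE %s = :u", table, pk),
          params = list(u = row[[pk]]))$n > 0L
        if (exists) {
          set_cols <- setdiff(names(row), pk)
          if (length(set_cols)) {
            DBI::dbExecute(con$db,
              sprintf("UPDATE %s SET %s WHERE %s = :pkval", table,
                      paste(sprintf("%s = :%s", set_cols, set_cols),
                            collapse = ", "), pk),
              params = c(row[set_cols], list(pkval = row[[pk]])))
          }
          fault_point("put_rows")
          return(row[[pk]])
        }
      }
      if (!is.na(pk) && is.null(row[[pk]])) row[[pk]] <- new_uuid()
      if (is.null(row[[keycol]]))
        stop(sprintf("rows for table '%s' must carry '%s'", table, keycol),
             call. = FALSE)
      DBI::dbExecute(con$db,
        sprintf("INSERT INTO %s (%s) VALUES (%s)", table,
                paste(names(row), collapse = ", "),
                paste(paste0(":", names(row)), collapse = ", ")),
        params = row)
      fault_point("put_rows")
      row[[keycol]]
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Open a data cursor
#'
#' Cursors fetch a query's results iteratively in batches of at most
#' `fetch_size` rows, in the same stable order as [get_rows()]. Batches are
#' disjoint and their concatenation equals the full (unlimited) result set
#' as of the time the cursor was opened; an exhausted cursor returns an
#' empty batch.
#'
#' @param con Open connection.
#' @param spec A [query_spec()] (its `limit` is ignored; cursors traverse
#'   the full result).
#' @param name Cursor name, unused on this connection.
#' @param fetch_size Positive batch size.
#' @return The first batch (data frame). The cursor state lives on the
#'   connection under `name`.
#' @export
open_cursor <- function(con, spec, name, fetch_size) {
  assert_open(con)
  stopifnot(inherits(spec, "query_spec"),
            is.character(name), length(name) == 1L, nzchar(name))
  if (!(is.numeric(fetch_size) && fetch_size >= 1))
    stop("fetch_size must be a positive integer", call. = FALSE)
  if (!is.null(con$cursors[[name]]))
    stop(sprintf("cursor '%s' is already open", name), call. = FALSE)
  result <- run_query(con, spec)
  rownames(result) <- NULL
  con$cursors[[name]] <- list(rows = result, pos = 0L,
                              fetch = as.integer(fetch_size))
  fetch_next(con, name)
}

#' Fetch the next batch from a cursor
#'
#' @param con Open connection.
#' @param name Cursor name.
#' @return Data frame with up to `fetch_size` rows; zero rows once the
#'   cursor is exhausted.
#' @export
fetch_next <- function(con, name) {
  assert_open(con)
  st <- con$cursors[[name]]
  if (is.null(st))
    stop(sprintf("no cursor named '%s'", name), call. = FALSE)
  from <- st$pos + 1L
  to <- min(st$pos + st$fetch, nrow(st$rows))
  if (from > nrow(st$rows)) {
    batch <- st$rows[0L, , drop = FALSE]
  } else {
    batch <- st$rows[from:to, , drop = FALSE]
    st$pos <- to
    con$cursors[[name]] <- st
  }
  rownames(batch) <- NULL
  batch
}

#' Close a cursor and discard its state
#'
#' @inheritParams fetch_next
#' @return Invisibly `TRUE`.
#' @export
close_cursor <- function(con, name) {
  assert_open(con)
  if (is.null(con$cursors[[name]]))
    stop(sprintf("no cursor named '%s'", name), call. = FALSE)
  rm(list = name, envir = con$cursors)
  invisible(TRUE)
}
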