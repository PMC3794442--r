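# Shared fixtures: throwaway databases, a small EEG container builder, an
# independent brute-force query evaluator, and table-dump helpers used by
# the atomicity (fault-injection) checks.

new_test_db <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  cfg <- db_config(sprintf("tdb%08x", sample.int(.Machine$integer.max, 1)),
                   dir = dir)
  create_database(cfg)
  con <- connect_database(cfg)
  withr::defer({
    if (isTRUE(con$open)) close(con)
  }, envir = env)
  list(cfg = cfg, con = con)
}

tiny_eeg <- function(n_events = 5, n_types = 2, n_channels = 3,
                     n_frames = 120, seed = 1) {
  generate_eeg(synth_spec(n_channels = n_channels, n_frames = n_frames,
                          srate = 100, n_events = n_events,
                          n_event_types = n_types, event_attr_fields = 1,
                          seed = seed))
}

count_rows <- function(con, table) {
  DBI::dbGetQuery(con$db, paste("SELECT COUNT(*) AS n FROM", table))$n
}

# Rows for a dataset excluding the urevent-flagged mirror rows.
count_primary_events <- function(con, dataset_uuid) {
  DBI::dbGetQuery(con$db,
    "SELECT COUNT(*) AS n FROM events e
     WHERE e.event_dataset_uuid = :d AND NOT EXISTS (
       SELECT 1 FROM attributes a WHERE a.attribute_entity_uuid = e.event_uuid
         AND a.attribute_entity_class = 'events'
         AND a.attribute_path = '/urevent')",
    params = list(d = dataset_uuid))$n
}

# Full-content snapshot of every table, in a canonical order, for
# before/after comparison under fault injection.
dump_all_tables <- function(con) {
  tabs <- db_list_tables(con)
  out <- lapply(tabs, function(tn) {
    df <- DBI::dbGetQuery(con$db, paste("SELECT * FROM", tn))
    blob_cols <- vapply(df, is.list, logical(1))
    for (bc in names(df)[blob_cols])
      df[[bc]] <- vapply(df[[bc]], function(x)
        paste(as.character(x), collapse = ""), character(1))
    if (nrow(df)) df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- tabs
  out
}

# Runs `expr` with a fault hook that throws at `label`; asserts the
# operation fails and every table is unchanged.
expect_atomic_failure <- function(con, label, expr) {
  before <- dump_all_tables(con)
  withr::local_options(eventstore.fault_hook = function(l) {
    if (l == label) stop("injected fault at ", l, call. = FALSE)
  })
  expect_error(expr, "injected fault")
  withr::local_options(eventstore.fault_hook = NULL)
  after <- dump_all_tables(con)
  expect_identical(after, before,
                   label = sprintf("tables after fault at '%s'", label))
}

# ---- independent query oracle ----
# A brute-force evaluator of the documented semantics (AND across groups,
# OR within a group, start-anchored regexes), written directly against SQL
# dumps so it shares no code with the package's query path.

oracle_member_match <- function(value, member, regexp) {
  if (is.na(value)) return(FALSE)
  if (regexp) {
    m <- regexpr(paste0("^(?:", member, ")"), value, perl = TRUE)
    m[1] == 1
  } else identical(value, member)
}

oracle_get_rows <- function(con, table, where = list(), tags = list(),
                            attributes = list(), regexp = FALSE,
                            limit = Inf) {
  df <- DBI::dbGetQuery(con$db, paste("SELECT * FROM", table))
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  keycol <- grep("_uuid$", names(df), value = TRUE)[1]
  df <- df[order(df[[keycol]]), , drop = FALSE]
  tagdf <- DBI::dbGetQuery(con$db,
    "SELECT tag_name, tag_entity_uuid FROM tags WHERE tag_entity_class = :c",
    params = list(c = table))
  attrdf <- DBI::dbGetQuery(con$db,
    "SELECT attribute_path, attribute_numeric_value, attribute_value,
            attribute_entity_uuid
     FROM attributes WHERE attribute_entity_class = :c",
    params = list(c = table))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (cn in names(where)) {
      qual <- where[[cn]]
      cell <- df[[cn]][i]
      hit <- if (is.numeric(qual) || grepl("uuid$", cn)) {
        !is.na(cell) && cell %in% qual
      } else {
        any(vapply(as.character(qual), function(m)
          oracle_member_match(cell, m, regexp), logical(1)))
      }
      if (!hit) { ok <- FALSE; break }
    }
    if (ok && length(tags)) {
      etags <- tagdf$tag_name[tagdf$tag_entity_uuid == df[[keycol]][i]]
      for (g in tags) {
        g <- as.character(g)
        hit <- any(vapply(g, function(m)
          any(vapply(etags, oracle_member_match, logical(1), member = m,
                     regexp = regexp)), logical(1)))
        if (!hit) { ok <- FALSE; break }
      }
    }
    if (ok && length(attributes)) {
      sel <- attrdf$attribute_entity_uuid == df[[keycol]][i]
      strs <- c(attrdf$attribute_path[sel],
                ifelse(is.na(attrdf$attribute_numeric_value[sel]),
                       attrdf$attribute_value[sel],
                       format(attrdf$attribute_numeric_value[sel],
                              trim = TRUE, scientific = FALSE)))
      strs <- strs[!is.na(strs)]
      for (g in attributes) {
        g <- as.character(g)
        hit <- any(vapply(g, function(m)
          any(vapply(strs, oracle_member_match, logical(1), member = m,
                     regexp = regexp)), logical(1)))
        if (!hit) { ok <- FALSE; break }
      }
    }
    keep[i] <- ok
  }
  out <- df[keep, , drop = FALSE]
  if (is.finite(limit) && nrow(out) > limit)
    out <- out[seq_len(limit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Populates a database with randomized datasets, tags and attributes for
# oracle-equivalence checks; returns the vocabularies used.
populate_random_db <- function(con, n_datasets = 40) {
  names_vocab <- c("eeg_data", "eeg_run", "meg_run", "sim_drive",
                   "pilot", "resting")
  ns_vocab <- c("mobbed", "www.cs.utsa.edu", "restricted")
  tag_vocab <- c("EyeTrack", "VisualTarget", "AudioLeft", "AudioRight",
                 "Driving", "Child", "Focused",
                 "/Context/Indoors/Simulator/Driving")
  rows <- lapply(seq_len(n_datasets), function(i) {
    list(dataset_name = paste0(sample(names_vocab, 1), "_", i),
         dataset_namespace = sample(ns_vocab, 1),
         dataset_version = 1,
         dataset_description = sample(c("raw", "filtered", "epoched"), 1))
  })
  uuids <- put_rows(con, "datasets", rows)
  for (u in uuids) {
    k <- sample(0:4, 1)
    if (k > 0)
      add_tags(con, entity_ref(u, "datasets"), sample(tag_vocab, k))
    if (stats::runif(1) < 0.5)
      add_attribute(con, entity_ref(u, "datasets"),
                    sample(c("/event/target_dist", "/quality"), 1),
                    if (stats::runif(1) < 0.5) round(stats::runif(1) * 20, 2)
                    else sample(c("good", "bad"), 1))
  }
  list(uuids = uuids, names = names_vocab, namespaces = ns_vocab,
       tags = tag_vocab)
}

random_query_spec <- function(vocab) {
  where <- list()
  if (stats::runif(1) < 0.5)
    where$dataset_namespace <- sample(vocab$namespaces,
                                      sample(1:2, 1))
  if (stats::runif(1) < 0.4)
    where$dataset_name <- if (stats::runif(1) < 0.5)
      sample(c("eeg.*", "sim.*", "pilot.*"), 1)
    else sample(vocab$names, 1)
  ngroups <- sample(0:3, 1)
  tags <- lapply(seq_len(ngroups), function(i)
    sample(c(vocab$tags, "Audio.*", "Visual.*"), sample(1:3, 1)))
  regexp <- stats::runif(1) < 0.5
  limit <- sample(c(Inf, 5, 20), 1)
  query_spec("datasets", limit = limit, where = where, tags = tags,
             regexp = regexp)
}
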