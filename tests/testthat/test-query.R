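test_that("templates mirror table columns and limit 0 returns them", {
  db <- new_test_db()
  tpl <- get_template(db$con, "datasets")
  expect_setequal(names(tpl),
                  c("dataset_uuid", "dataset_session_uuid",
                    "dataset_namespace", "dataset_name", "dataset_version",
                    "dataset_contact_uuid", "dataset_creation_date",
                    "dataset_description", "dataset_parent_uuid",
                    "dataset_modality_uuid", "dataset_oid"))
  expect_false("data" %in% names(tpl))   # payload is not query metadata
  expect_true(all(is.na(tpl[1, ])))
  expect_identical(get_rows(db$con, query_spec("datasets", limit = 0)), tpl)

  ev <- get_template(db$con, "events")
  expect_true(all(c("event_start_time", "event_end_time",
                    "event_certainty", "event_type_uuid") %in% names(ev)))
  expect_error(get_template(db$con, "nope"), "unknown table")
  expect_error(query_spec("datasets", where = list(bogus = 1)),
               "unknown column")
})

test_that("string cells match directly, by choice list, or by anchored regex", {
  expect_true(match_strings("www.cs.utsa.edu", "www.cs.utsa.edu"))
  expect_false(match_strings("www.cs.utsa.edu", "restricted"))
  expect_true(match_strings("restricted",
                            c("www.cs.utsa.edu", "restricted")))
  expect_true(match_strings("eeg_data_ch1", "eeg.*", regexp = TRUE))
  expect_false(match_strings("meg_data", "eeg.*", regexp = TRUE))
  # anchoring: pattern must match from the start of the stored string
  expect_false(match_strings("my_eeg_data", "eeg.*", regexp = TRUE))
  expect_false(match_strings(NA_character_, "x"))
  suppressWarnings(expect_error(match_strings("x", "(", regexp = TRUE)))
})

test_that("tag groups AND across groups, OR within a group", {
  tags <- c("EyeTrack", "AudioLeft")
  expect_true(match_tag_groups(tags,
                               list("EyeTrack",
                                    c("VisualTarget", "Audio.*")),
                               regexp = TRUE))
  expect_false(match_tag_groups(tags,
                                list("EyeTrack", "VisualTarget")))
  expect_true(match_tag_groups(tags, list()))
  expect_true(match_tag_groups(character(0), list()))

  # property: equivalence with an independent evaluator on random cases
  vocab <- c("A", "B", "C", "Audio", "AudioLeft", "Visual")
  set.seed(17)
  for (i in 1:200) {
    etags <- sample(vocab, sample(0:4, 1))
    groups <- lapply(seq_len(sample(0:3, 1)), function(j)
      sample(c(vocab, "Au.*", "Vis.*"), sample(1:3, 1)))
    rx <- runif(1) < 0.5
    brute <- all(vapply(groups, function(g)
      any(vapply(g, function(m) any(vapply(etags, function(tg)
        if (rx) regexpr(paste0("^(?:", m, ")"), tg, perl = TRUE) == 1
        else identical(tg, m), logical(1))), logical(1))), logical(1)))
    expect_identical(match_tag_groups(etags, groups, regexp = rx), brute)
  }
})

test_that("get_rows combines column, tag and attribute qualifications", {
  db <- new_test_db()
  u1 <- store_dataset(db$con, "eeg_data_ch1", as.raw(1),
                      modality = "SIMPLE",
                      tags = c("EyeTrack", "AudioLeft"))$dataset_uuid
  u2 <- store_dataset(db$con, "eeg_data_ch2", as.raw(2),
                      modality = "SIMPLE",
                      tags = c("EyeTrack", "VisualTarget"))$dataset_uuid
  u3 <- store_dataset(db$con, "meg_run", as.raw(3), modality = "SIMPLE",
                      tags = c("Driving", "Child", "Focused"))$dataset_uuid

  all_rows <- get_rows(db$con, query_spec("datasets"))
  expect_equal(nrow(all_rows), 3)

  # the worked example: EyeTrack AND (VisualTarget OR Audio*)
  hit <- get_rows(db$con, query_spec("datasets",
    tags = list("EyeTrack", c("VisualTarget", "Audio.*")), regexp = TRUE))
  expect_setequal(hit$dataset_uuid, c(u1, u2))

  # three separate groups: all three tags required
  hit3 <- get_rows(db$con, query_spec("datasets",
    tags = list("Driving", "Child", "Focused")))
  expect_equal(hit3$dataset_uuid, u3)

  # name prefix regex
  pre <- get_rows(db$con, query_spec("datasets",
    where = list(dataset_name = "eeg.*"), regexp = TRUE))
  expect_setequal(pre$dataset_uuid, c(u1, u2))

  # UUID columns accept a single value or a list
  expect_equal(get_rows(db$con, query_spec("datasets",
    where = list(dataset_uuid = u3)))$dataset_name, "meg_run")
  expect_equal(nrow(get_rows(db$con, query_spec("datasets",
    where = list(dataset_uuid = c(u1, u2))))), 2)

  # numeric columns match exact values
  expect_equal(nrow(get_rows(db$con, query_spec("datasets",
    where = list(dataset_version = 1)))), 3)
  expect_equal(nrow(get_rows(db$con, query_spec("datasets",
    where = list(dataset_version = 2)))), 0)

  # attribute groups match path or stringified value
  add_attribute(db$con, entity_ref(u1, "datasets"), "/quality", "good")
  qa <- get_rows(db$con, query_spec("datasets",
                                    attributes = list("/quality")))
  expect_equal(qa$dataset_uuid, u1)
  qv <- get_rows(db$con, query_spec("datasets",
                                    attributes = list("good")))
  expect_equal(qv$dataset_uuid, u1)
})

test_that("limits are monotone prefixes of the stable order", {
  db <- new_test_db()
  for (i in 1:7)
    store_dataset(db$con, sprintf("d%d", i), as.raw(i),
                  modality = "SIMPLE")
  full <- get_rows(db$con, query_spec("datasets"))
  expect_false(is.unsorted(full$dataset_uuid))
  for (k in 1:6) {
    a <- get_rows(db$con, query_spec("datasets", limit = k))
    b <- get_rows(db$con, query_spec("datasets", limit = k + 1))
    expect_identical(a, b[seq_len(k), , drop = FALSE])
  }
})

test_that("put_rows inserts fresh rows and updates by primary key", {
  db <- new_test_db()
  res <- store_dataset(db$con, "d", as.raw(1), modality = "SIMPLE")

  # batch of k inserts -> exactly k new rows
  before <- count_rows(db$con, "comments")
  ids <- put_rows(db$con, "comments", lapply(1:5, function(i)
    list(comment_value = sprintf("c%d", i))))
  expect_length(ids, 5)
  expect_equal(count_rows(db$con, "comments"), before + 5)
  expect_true(all(is_uuid(ids)))

  # update by primary key changes exactly that row
  put_rows(db$con, "datasets", list(list(
    dataset_uuid = res$dataset_uuid,
    dataset_description = "after manual edit")))
  rec <- retrieve_dataset(db$con, res$dataset_uuid)
  expect_equal(rec$dataset_description, "after manual edit")
  expect_equal(count_rows(db$con, "datasets"), 1)

  # a TRANSFORMS row via the generic writer
  put_rows(db$con, "transforms", list(list(
    transform_uuid = res$dataset_uuid,
    transform_string = "f(x)")))
  expect_equal(nrow(lookup_transform(db$con, "f(x)")), 1)

  # bad batches abort atomically
  snap <- dump_all_tables(db$con)
  expect_error(put_rows(db$con, "comments", list(
    list(comment_value = "ok"), list(bogus_col = "x"))), "unknown column")
  expect_error(put_rows(db$con, "datasets", list(
    list(dataset_name = "x", dataset_version = "not-a-number"))),
    "numeric")
  expect_identical(dump_all_tables(db$con), snap)
})

test_that("cursors partition the result into disjoint ordered batches", {
  db <- new_test_db()
  # 250 events across a handful of datasets
  for (i in 1:5) {
    g <- tiny_eeg(n_events = 25, n_types = 2, n_frames = 500, seed = i)
    g$eeg$urevent <- NULL
    store_dataset(db$con, sprintf("d%d", i), g$eeg)
  }
  expect_equal(count_rows(db$con, "events"), 125)
  spec <- query_spec("events")
  b1 <- open_cursor(db$con, spec, "mycursor", 50)
  b2 <- fetch_next(db$con, "mycursor")
  b3 <- fetch_next(db$con, "mycursor")
  b4 <- fetch_next(db$con, "mycursor")
  expect_equal(c(nrow(b1), nrow(b2), nrow(b3), nrow(b4)), c(50, 50, 25, 0))

  joined <- rbind(b1, b2, b3)
  expect_false(any(duplicated(joined$event_uuid)))
  expect_identical(joined, get_rows(db$con, spec))

  expect_error(open_cursor(db$con, spec, "mycursor", 50), "already open")
  close_cursor(db$con, "mycursor")
  expect_error(fetch_next(db$con, "mycursor"), "no cursor")
  expect_error(fetch_next(db$con, "never"), "no cursor")

  # zero matches: first batch already empty
  none <- open_cursor(db$con, query_spec("events",
    where = list(event_certainty = 0.123)), "empty", 10)
  expect_equal(nrow(none), 0)
})

test_that("get_rows agrees with the brute-force oracle on random databases", {
  db <- new_test_db()
  set.seed(23)
  vocab <- populate_random_db(db$con, n_datasets = 60)
  for (i in 1:100) {
    spec <- random_query_spec(vocab)
    mine <- get_rows(db$con, spec)
    ref <- oracle_get_rows(db$con, "datasets", where = spec$where,
                           tags = spec$tags,
                           attributes = spec$attributes,
                           regexp = spec$regexp, limit = spec$limit)
    expect_identical(mine[names(ref)], ref,
                     label = sprintf("query %d", i))
  }
})
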