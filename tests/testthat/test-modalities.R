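test_that("map_event_types reuses known names and mints fresh UUIDs", {
  # brute force: unique strings not already known get one UUID each
  r <- map_event_types(c("A", "B", "A"))
  expect_length(r$created, 2)
  expect_equal(unname(r$map[["A"]]), unname(r$map["A"]))
  expect_length(unique(r$map), 2)

  r2 <- map_event_types(c("A", "C"), known = r$map)
  expect_identical(r2$map[["A"]], r$map[["A"]])
  expect_length(r2$created, 1)
  expect_named(r2$map, c("A", "B", "C"))

  r3 <- map_event_types(character(0), known = r$map)
  expect_identical(r3$map, r$map)
  expect_length(r3$created, 0)
})

test_that("EEG explosion writes events, types, modifiers and channel attributes", {
  db <- new_test_db()
  g <- tiny_eeg(n_events = 5, n_types = 2, n_channels = 3)
  res <- store_dataset(db$con, "eeg_data", g$eeg)
  u <- res$dataset_uuid

  expect_equal(count_primary_events(db$con, u), 5)
  expect_equal(count_rows(db$con, "event_types"), 2)
  # urevents mirrored and flagged
  expect_equal(count_rows(db$con, "events"), 10)
  flagged <- DBI::dbGetQuery(db$con$db,
    "SELECT COUNT(*) AS n FROM attributes
     WHERE attribute_path = '/urevent' AND attribute_numeric_value = 1")$n
  expect_equal(flagged, 5)

  # event times follow (latency - 1) / srate
  ev <- DBI::dbGetQuery(db$con$db,
    "SELECT event_start_time, event_end_time, event_certainty FROM events e
     WHERE NOT EXISTS (SELECT 1 FROM attributes a
       WHERE a.attribute_entity_uuid = e.event_uuid
         AND a.attribute_path = '/urevent')
     ORDER BY event_start_time")
  expect_equal(ev$event_start_time, sort(g$truth$event_times))
  expect_equal(ev$event_end_time, ev$event_start_time)
  expect_true(all(ev$event_certainty == 1))
  expect_true(all(ev$event_start_time >= 0))

  # one modifier attribute per event at '/event/<field>'
  mods <- DBI::dbGetQuery(db$con$db,
    "SELECT COUNT(*) AS n FROM attributes
     WHERE attribute_path = '/event/attr_00'")$n
  expect_equal(mods, 5)

  # channel locations: one attribute per chanlocs field value
  chan <- DBI::dbGetQuery(db$con$db,
    "SELECT attribute_path FROM attributes
     WHERE attribute_entity_uuid = :u AND attribute_path LIKE '/chanlocs/%'",
    params = list(u = u))
  expect_equal(nrow(chan), 3 * 4)   # 3 channels x (labels, X, Y, Z)
  expect_true("/chanlocs/1/labels" %in% chan$attribute_path)
})

test_that("a named event modifier becomes a path-addressed attribute", {
  db <- new_test_db()
  eeg <- list(data = matrix(0, 1, 50), srate = 100,
              event = list(list(type = "passes", latency = 10,
                                target_dist = 12.5)))
  res <- store_dataset(db$con, "drive", eeg)
  att <- DBI::dbGetQuery(db$con$db,
    "SELECT attribute_numeric_value FROM attributes
     WHERE attribute_path = '/event/target_dist'")
  expect_equal(att$attribute_numeric_value, 12.5)
})

test_that("out-of-range latency aborts the whole store", {
  db <- new_test_db()
  before <- dump_all_tables(db$con)
  eeg <- list(data = matrix(0, 1, 50), srate = 100,
              event = list(list(type = "a", latency = 51)))
  expect_error(store_dataset(db$con, "bad", eeg), "latency")
  expect_identical(dump_all_tables(db$con), before)
})

test_that("threading the type map across stores reuses the vocabulary", {
  db <- new_test_db()
  types <- character(0)
  for (i in 1:4) {
    g <- tiny_eeg(n_events = 6, n_types = 3, seed = i)
    res <- store_dataset(db$con, sprintf("run%d", i), g$eeg,
                         event_types = types)
    types <- res$event_type_uuids
  }
  expect_equal(count_rows(db$con, "event_types"), 3)
  expect_length(types, 3)

  # re-exploding against the returned map creates zero new types
  g <- tiny_eeg(n_events = 6, n_types = 3, seed = 99)
  known <- type_map_from_uuids(db$con, types)
  r1 <- explode_eeg(db$con, store_dataset(db$con, "extra", as.raw(1),
                                          modality = "SIMPLE")$dataset_uuid,
                    g$eeg, known)
  n_before <- count_rows(db$con, "event_types")
  r2 <- explode_eeg(db$con, store_dataset(db$con, "extra2", as.raw(1),
                                          modality = "SIMPLE")$dataset_uuid,
                    g$eeg, r1$type_map)
  expect_equal(count_rows(db$con, "event_types"), n_before)
})

test_that("generic explosion honors explicit times and certainties", {
  db <- new_test_db()
  g <- list(event = list(
    list(type = "spindle", start_time = 2.0, end_time = 2.5,
         certainty = 0.8),
    list(type = "marker", start_time = 3.0, end_time = 3.0)))
  res <- store_dataset(db$con, "overlay", g, modality = "GENERIC")
  ev <- DBI::dbGetQuery(db$con$db,
    "SELECT * FROM events ORDER BY event_start_time")
  expect_equal(ev$event_start_time, c(2.0, 3.0))
  expect_equal(ev$event_end_time, c(2.5, 3.0))
  # hardware-style marker defaults to certainty 1; detector keeps its own
  expect_equal(ev$event_certainty, c(0.8, 1.0))

  bad <- list(event = list(list(type = "x", start_time = 1,
                                certainty = 1.2)))
  before <- dump_all_tables(db$con)
  expect_error(store_dataset(db$con, "bad", bad, modality = "GENERIC"),
               "certainty")
  expect_identical(dump_all_tables(db$con), before)
})

test_that("generic sections land in ELEMENTS and ATTRIBUTES", {
  db <- new_test_db()
  g <- generate_generic(synth_spec(n_channels = 4, n_frames = 100,
                                   n_events = 3, n_event_types = 2,
                                   seed = 5))
  res <- store_dataset(db$con, "gen", g$generic, modality = "GENERIC")
  expect_equal(count_rows(db$con, "elements"), 4)
  feat <- DBI::dbGetQuery(db$con$db,
    "SELECT attribute_path FROM attributes
     WHERE attribute_path LIKE '/feature/%'")
  expect_true("/feature/1/name" %in% feat$attribute_path)
})

test_that("modalities can be registered and dispatch to their handler", {
  db <- new_test_db()
  expect_setequal(get_rows(db$con, query_spec("modalities"))$modality_name,
                  c("SIMPLE", "EEG", "GENERIC"))
  calls <- 0L
  u <- register_modality(db$con, "XXX", function(con, uuid, struct, known) {
    calls <<- calls + 1L
    list(event_uuids = character(0), type_map = known)
  })
  expect_equal(count_rows(db$con, "modalities"), 4)
  store_dataset(db$con, "custom", list(payload = 1:3), modality = "XXX")
  expect_equal(calls, 1L)
  expect_error(register_modality(db$con, "XXX", identity),
               "already registered")
})
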