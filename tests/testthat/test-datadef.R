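test_that("uniform stream timestamps are exactly i / fs and reassembly is exact", {
  db <- new_test_db()
  fs <- 512
  m <- matrix(rnorm(4 * 25), nrow = 4)
  u <- create_datadef(db$con, "NUMERIC_STREAM", m, sampling_rate = fs)
  r <- retrieve_datadef(db$con, u)
  expect_identical(r$timestamps, (seq_len(25) - 1) / fs)  # double-exact
  expect_identical(r$data, m)
  expect_equal(r$sampling_rate, fs)

  # epoched data: columns as epochs at rate 1 -> timestamps 0, 1, 2, ...
  ep <- create_datadef(db$con, "NUMERIC_STREAM", matrix(1:6 * 1.0, nrow = 2),
                       sampling_rate = 1)
  expect_identical(retrieve_datadef(db$con, ep)$timestamps, c(0, 1, 2))
})

test_that("all five formats round-trip exactly", {
  db <- new_test_db()
  set.seed(3)
  nv <- rnorm(17)
  ns <- matrix(rnorm(3 * 8), nrow = 3)
  xv <- "<cfg><fs>512</fs></cfg>"
  xs <- sprintf("<frame t='%d'/>", 1:5)
  ex <- as.raw(sample(0:255, 999, replace = TRUE))

  u1 <- create_datadef(db$con, "NUMERIC_VALUE", nv)
  u2 <- create_datadef(db$con, "NUMERIC_STREAM", ns, sampling_rate = 100)
  u3 <- create_datadef(db$con, "XML_VALUE", xv)
  u4 <- create_datadef(db$con, "XML_STREAM", xs,
                       timestamps = c(0, 0.5, 0.9, 2, 7))
  u5 <- create_datadef(db$con, "EXTERNAL", ex)

  expect_identical(retrieve_datadef(db$con, u1)$data, nv)
  expect_identical(retrieve_datadef(db$con, u2)$data, ns)
  expect_identical(retrieve_datadef(db$con, u3)$data, xv)
  r4 <- retrieve_datadef(db$con, u4)
  expect_identical(r4$data, xs)
  expect_identical(r4$timestamps, c(0, 0.5, 0.9, 2, 7))
  expect_equal(r4$sampling_rate, -1)   # non-uniform sentinel
  expect_identical(retrieve_datadef(db$con, u5)$data, ex)

  # EXTERNAL never explodes into the value/stream tables
  expect_equal(count_rows(db$con, "numeric_values"), 1)
  expect_equal(count_rows(db$con, "numeric_streams"), 8)
  expect_equal(count_rows(db$con, "xml_values"), 1)
  expect_equal(count_rows(db$con, "xml_streams"), 5)

  expect_error(retrieve_datadef(db$con, new_uuid()), "not found")
})

test_that("format/sampling/timestamp inconsistencies are rejected", {
  db <- new_test_db()
  m <- matrix(1:4 * 1.0, nrow = 2)
  expect_error(create_datadef(db$con, "NUMERIC_STREAM", m), "sampling_rate")
  expect_error(create_datadef(db$con, "NUMERIC_STREAM", m,
                              sampling_rate = 10, timestamps = c(0, 1)),
               "not both")
  expect_error(create_datadef(db$con, "NUMERIC_STREAM", m,
                              timestamps = c(1, 0.5)), "increasing")
  expect_error(create_datadef(db$con, "NUMERIC_STREAM", m,
                              timestamps = c(0, 1, 2)), "length")
  expect_error(create_datadef(db$con, "NUMERIC_VALUE", 1:3,
                              sampling_rate = 10), "not a stream")
  expect_error(create_datadef(db$con, "BINARY", 1:3), "arg")
})

test_that("stream columns reassemble in timestamp order regardless of insertion order", {
  db <- new_test_db()
  u <- create_datadef(db$con, "NUMERIC_STREAM", matrix(0, 1, 1),
                      timestamps = 99)   # seed definition with one column
  # append columns directly, shuffled, below and above the existing one
  ts <- c(5, 1, 42, 7)
  for (i in seq_along(ts)) {
    DBI::dbExecute(db$con$db,
      "INSERT INTO numeric_streams (numeric_stream_uuid,
         numeric_stream_datadef_uuid, numeric_stream_time,
         numeric_stream_length, numeric_stream)
       VALUES (:u, :d, :t, 1, :v)",
      params = list(u = new_uuid(), d = u, t = ts[i],
                    v = list(writeBin(as.double(ts[i]), raw(), size = 8,
                                      endian = "little"))))
  }
  r <- retrieve_datadef(db$con, u)
  expect_identical(r$timestamps, sort(c(99, ts)))
  # each appended column holds its own timestamp as value; seed column is 0
  expect_equal(as.vector(r$data), c(sort(ts), 0))
})

test_that("data maps are many-to-many and order-preserving on retrieval", {
  db <- new_test_db()
  uuids <- vapply(1:10, function(i)
    store_dataset(db$con, sprintf("d%d", i), as.raw(i),
                  modality = "SIMPLE")$dataset_uuid, character(1))
  dd <- create_datadef(db$con, "NUMERIC_VALUE", c(1, 2, 3))
  for (u in uuids)
    map_datadef(db$con, dd, entity_ref(u, "datasets"), "/dataEx")
  expect_equal(count_rows(db$con, "datamaps"), 10)

  # same pair under two paths -> two rows
  map_datadef(db$con, dd, entity_ref(uuids[1], "datasets"), "/alt")
  expect_equal(count_rows(db$con, "datamaps"), 11)

  # events can carry data too
  g <- tiny_eeg(n_events = 1, n_types = 1)
  store_dataset(db$con, "withevents", g$eeg)
  ev <- DBI::dbGetQuery(db$con$db, "SELECT event_uuid FROM events LIMIT 1")
  expect_true(is_uuid(map_datadef(db$con, dd,
                                  entity_ref(ev$event_uuid, "events"),
                                  "/spectrum")))

  maps <- get_rows(db$con, query_spec("datamaps",
    where = list(datamap_entity_uuid = uuids[1], datamap_path = "/dataEx")))
  got <- retrieve_mapped(db$con, maps)
  expect_length(got, 1)
  expect_equal(got[[1]]$path, "/dataEx")
  expect_equal(got[[1]]$data$data, c(1, 2, 3))
  expect_length(retrieve_mapped(db$con, list()), 0)

  # k map rows come back in input order
  many <- get_rows(db$con, query_spec("datamaps",
    where = list(datamap_datadef_uuid = dd)))
  res <- retrieve_mapped(db$con, many)
  expect_equal(vapply(res, `[[`, character(1), "path"), many$datamap_path)

  expect_error(map_datadef(db$con, new_uuid(),
                           entity_ref(uuids[1], "datasets"), "/x"),
               "not found")
  expect_error(map_datadef(db$con, dd, entity_ref(new_uuid(), "datasets"),
                           "/x"), "not found")
})
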