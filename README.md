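# eventstore

Relational storage and SQL-free structured query of event-rich time
series, for researchers who work with annotated multichannel recordings —
EEG above all — and want a computational database inside their analysis
workflow rather than a pile of files.

Each recording ("dataset") is archived whole as an opaque binary payload,
while everything worth searching is *exploded* into relational tables:

* **events** with a type label, start/end times in seconds from dataset
  start, and a certainty in [0, 1] (hardware markers carry 1, detector
  outputs their confidence);
* **event types** identified by UUIDs and reusable across datasets, so
  "the same" event is recognizable when mining a collection;
* **tags** (free strings or `/`-separated hierarchies, HED-style) and
  **attributes** (values anchored at structure paths such as
  `/event/target_dist`), attachable to any entity;
* **auxiliary data definitions** in five formats — numeric value, numeric
  stream, XML value, XML stream, external blob — associated many-to-many
  with entities through data maps; uniform streams at rate *fs* carry
  timestamps exactly *i*/*fs*;
* **transform strings**: a provenance cache mapping normalized command
  strings to the datasets they produced, so expensive pipeline results are
  looked up instead of recomputed.

Queries never involve SQL. A `query_spec()` combines column
qualifications (direct value, choice list, or start-anchored regular
expression), tag groups and attribute groups — AND across groups, OR
within a group — plus a row limit, and `get_rows()` returns metadata rows
in a stable order. Data cursors page through large results in disjoint
batches. The default backend is embedded SQLite (one file per database);
any DBI driver can be substituted for a client-server deployment.

A deterministic synthetic generator (`generate_eeg()`,
`generate_generic()`) emits EEGLAB-style containers with known ground
truth, and a bundled MAT-file codec reads and writes them on disk.

## Worked example

```r
library(eventstore)

cfg <- db_config("dbmain", dir = "~/eventstore-data")
create_database(cfg)            # 19 tables, 3 built-in modalities
con <- connect_database(cfg)

# a synthetic 32-channel recording: 154 events over 2 types
g <- generate_eeg(synth_spec(seed = 42))
res <- store_dataset(con, "eeg_data", g$eeg,
                     tags = c("EyeTrack", "VisualTarget", "AudioLeft"))
res$dataset_uuid
#> [1] "a9094ac7-79ec-456b-9c59-f6f24ffc4495"
length(res$event_type_uuids)    # pass back to the next store to reuse types
#> [1] 2

get_rows(con, query_spec("events", limit = 3))[,
  c("event_start_time", "event_end_time", "event_certainty")]
#>   event_start_time event_end_time event_certainty
#> 1         50.46094       50.46094               1
#> 2         15.98438       15.98438               1
#> 3         66.78125       66.78125               1

# EyeTrack AND (VisualTarget OR a tag starting with "Audio")
hit <- get_rows(con, query_spec("datasets",
  tags = list("EyeTrack", c("VisualTarget", "Audio.*")), regexp = TRUE))
hit$dataset_name
#> [1] "eeg_data"

# provenance: cache a filtering step under its normalized command string
normalize_transform("pop_eegfilt(EEG, 1.0, 0, [], 0)",
                    c(EEG = res$dataset_uuid))
#> [1] "pop_eegfilt(a9094ac7-79ec-456b-9c59-f6f24ffc4495,1.0,0,[],0)"

close(con)
```

The event times are `(latency - 1) / srate` seconds; certainty 1 marks
hardware-style markers. `retrieve_dataset(con, uuid)` returns the whole
payload byte-identical to what was stored.

A thin command-line wrapper over the same functions lives at
`inst/cli/eventstore.R` (`createdb`, `store`, `query`, `tag`, `datadef-*`,
`transform-*`, `synth`, ...).

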