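---
title: "The eventstore data model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The eventstore data model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why a database for event-rich time series

Modern physiological monitoring experiments — think several hours of
multichannel EEG recorded alongside eye tracking, motion capture and a
simulated task environment — produce *event-rich time series*: a sensor
data matrix overlaid with many streams of time markers describing stimuli,
responses, environmental conditions and algorithmically detected phenomena.
Analysing one recording at a time from loose files does not scale to
questions like "across this collection, when does an event of type A occur
near an event of type B?", nor does it give a home to the intermediate
results of standardized processing pipelines.

`eventstore` keeps each recording whole, as an opaque binary payload, and
*explodes* everything worth searching — events, shared event types, channel
metadata, tags, typed attributes, auxiliary data streams, provenance
strings — into relational tables. Callers never write SQL: they fill in
row-shaped structures and combine tag/attribute groups through a small
query layer.

## The data model

Nineteen tables implement the model; the central ones are:

* **DATASETS** — one row per recording. Identity is a random 128-bit UUID;
  the triple (name, namespace, version) is unique database-wide, and
  versions for a fixed (namespace, name) form the gapless sequence
  1, 2, 3, ... The payload lives in a blob column of the same row, so a
  store is a single atomic insert. Four association mechanisms link derived
  data to an original: a new *version* (`is_unique = FALSE`), a *parent*
  UUID, a *data definition* plus data map, or a *transform* string.
* **EVENTS / EVENT_TYPES** — an event is a time marker with a start and an
  end in seconds from the start of its dataset (equal for instantaneous
  markers) and a *certainty* in [0, 1]: hardware-inserted markers carry 1,
  detector outputs carry the detector's confidence. Types are
  UUID-identified strings kept in their own table precisely so they can be
  reused across datasets; `store_dataset()` accepts the type-UUID list
  returned by the previous store and only creates types it has not seen.
* **TAGS / ATTRIBUTES** — the semi-structured metadata layer. A tag is a
  free-floating string (plain or a `/`-separated hierarchy in the style of
  HED descriptors) attachable to any entity via (uuid, table-name) pairs; a
  tag is stored verbatim, and all prefix/regex semantics live in the query
  layer. An attribute is a value anchored at a structure path such as
  `/event/target_dist`, stored in a numeric or a string column (exactly one
  of the two).
* **DATADEFS** plus four value/stream tables — auxiliary data in five
  formats (`NUMERIC_VALUE`, `NUMERIC_STREAM`, `XML_VALUE`, `XML_STREAM`,
  `EXTERNAL`). Streams are stored one row per column so individual time
  points are addressable; uniform streams at rate `fs` get timestamps
  exactly `i / fs` (double precision, `i` from 0, relative to the start of
  the data itself), non-uniform streams carry explicit strictly increasing
  timestamps and the stored rate sentinel −1.
* **TRANSFORMS** — maps a normalized command string to the UUID of the
  dataset it produced. Lookups are exact-string; a miss means "recompute".
* **COLLECTIONS, MODALITIES** and five minimal secondary tables
  (COMMENTS, CONTACTS, DEVICES, ELEMENTS, SUBJECTS).

## Modalities and explosion

A *modality* names the procedure that decomposes a container into rows.
Three are built in:

* **SIMPLE** archives any payload with no explosion (tags and attributes
  can still be attached later);
* **EEG** understands the EEGLAB field layout (`data`, `srate`, `event`,
  `urevent`, `chanlocs`). Event times are computed as
  `(latency − 1) / srate` with 1-based sample indexing — the container
  convention — and stored as double seconds with certainty 1. Every event
  field other than `type`/`latency` becomes an attribute at
  `/event/<field>`; channel-location fields become dataset attributes at
  `/chanlocs/<index>/<field>`.
* **GENERIC** takes explicit `start_time`/`end_time`/`certainty` per event
  and additionally stores `element` records as ELEMENTS rows and
  `feature`/`metadata` records as path-keyed attributes.

New modalities are a registry row plus a handler function
(`register_modality()`); storage dispatches by modality name.

Design choices in this area that the model itself left open:

* **urevents** (the container's original, pre-editing event list) have no
  dedicated table; they are stored as ordinary EVENTS rows flagged by an
  attribute `/urevent = 1`. Event-count invariants therefore count
  unflagged rows. The event and urevent lists are not cross-linked; both
  are stored independently.
* "Some event modifiers become attributes" is resolved as: *every*
  non-standard event field does, numerics into the numeric column,
  everything else stringified.

## The query layer

`get_rows()` evaluates a `query_spec()`: column qualifications AND every
tag group AND every attribute group, with OR within a group. String columns
match directly, by choice list, or — with `regexp = TRUE` — by regular
expressions **anchored at the start** of the stored string. The anchoring
is a documented choice: prefix searches ("names starting with eeg",
hierarchical tag prefixes) are the dominant use, and the original
environment's regex dialect is not reproducible bit-for-bit anyway. UUID
columns always match exactly (single value or list), numeric columns by
exact value; range queries are out of scope.

Attribute groups mirror tag groups; a member matches an entity if it
matches the *path* or the *stringified value* of any of the entity's
attributes, so `'/quality'` and `'good'` both find a dataset carrying
`/quality = "good"`.

Results are always in ascending key order. That stable total order makes
limits monotone (the limit-k result is a prefix of the limit-k+1 result)
and cursors deterministic. A cursor snapshots its filtered, ordered result
at open time and hands out disjoint batches of at most `fetch_size` rows
whose concatenation equals the full result — a guarantee that would be
forfeited under live keyset pagination if rows were inserted mid-iteration.

The tag/attribute matching primitives (`match_strings()`,
`match_tag_groups()`) are exported pure functions, so the documented
semantics can be checked directly against brute-force evaluation; the test
suite does exactly that on randomized databases.

## Transactions, atomicity, backends

Every public operation runs as one transaction; nested public calls (for
example `store_dataset()` invoking `add_tags()`) join the outer
transaction, so a failure anywhere — including one injected by the test
hook `options(eventstore.fault_hook = ...)` mid-write — rolls the database
back to its pre-call state. The test suite verifies this by comparing full
table dumps before and after induced failures on every write path.

The default backend is an embedded single-file SQLite engine through DBI:
zero installation, one file per database, durable across processes.
Because SQLite has no array column type, numeric vectors in the value and
stream tables are packed little-endian float64 blobs with an element-count
column; the contract is element-exact round-trip, which the tests assert
with `identical()`. A client-server engine can be substituted by passing
any DBI driver object to `db_config()`; all SQL in the package is
DBI-portable. `delete_database()` refuses to run while the calling process
holds open handles — failing fast beats silently invalidating connections.

Other storage decisions: creation dates are set at insert time in UTC;
name/namespace matching for versioning is case-sensitive exact; tag
storage is case-sensitive and duplicate (name, entity) pairs are no-ops;
attributes are deliberately *not* unique-keyed per (entity, path), since
per-channel attributes repeat by construction. A collection is represented
by an anchor row plus one row per member, which lets an empty collection
exist and carry tags. Transform strings are not unique-keyed either;
duplicates are surfaced to the caller, who may treat the table as a strict
hash table or not.

## Containers and the MAT codec

EEG and GENERIC payloads use the MAT-file (Level 5) container, the lingua
franca for EEGLAB-style structures, via a codec written for this package:
double arrays, char arrays, structs, struct arrays and cell arrays,
little-endian, uncompressed on write (zlib-compressed elements are
inflated on read). The subset is exactly what the supported containers
need; files written here load in scipy/MATLAB readers and vice versa, and
the test suite cross-checks both directions against an independent reader.
Payloads stored through the SIMPLE modality from non-raw R objects use
native R serialization instead.

## The synthetic generator

`generate_eeg()` / `generate_generic()` emit containers with known ground
truth so every layer can be tested end-to-end with no external data. The
defaults emulate a small benchmark-style EEG collection — 32 channels,
30 504 frames, 154 events over 2 distinct types, 4 modifier fields per
event — with a sampling rate of 128 Hz, a typical value for compact EEG
recordings. Data are Gaussian noise: only *structural* fidelity (counts,
times, types, attributes) matters here, and passing tests say nothing
about spectral or statistical realism of real EEG. Determinism is pinned
to a named PRNG (Mersenne-Twister, inversion sampling) rather than the
platform default, and the generator restores the caller's RNG state.

Test problem sizes are deliberately modest — containers of a few hundred
frames, randomized databases of ≤ 200 rows per table, hundreds of
randomized queries — chosen so the whole suite exercises every code path
in well under a minute of compute while the properties checked (exact
counts, byte identity, oracle equivalence) are size-independent.

## Known limitations

* No partial or streamed blob retrieval: datasets come back whole.
* No SQL passthrough, joins, or numeric range queries.
* No HED-schema validation of tag strings; tags are opaque paths.
* The client-server backend requires a caller-supplied DBI driver and a
  database created by the server's own tooling.
* Concurrency is the embedded engine's file locking plus per-operation
  transactions: concurrent writers serialize; there is no row-level
  locking.
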