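Package: eventstore
Title: Relational Storage and Structured Query of Event-Rich Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight computational database for collections of
    event-rich multichannel time series such as EEG. Recordings are
    archived whole as opaque binary payloads while their events, event
    types, channel metadata, tags, path-anchored attributes, auxiliary
    numeric/XML data streams, and provenance strings are exploded into
    relational tables for search. Provides an SQL-free structure-based
    query layer with tag/attribute group matching, regular expressions
    and paged data cursors; shared UUID-identified event types reusable
    across datasets; a transform-string cache for provenance and reuse
    of expensive computations; and a deterministic synthetic generator
    of EEG-like containers (with MAT-file I/O) for testing at scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    uuid,
    stats,
    tools
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
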