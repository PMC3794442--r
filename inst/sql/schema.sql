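-- eventstore relational schema (idempotent DDL).
-- Generated from the package table registry; see schema_ddl().

CREATE TABLE IF NOT EXISTS datasets (
  dataset_uuid TEXT PRIMARY KEY,
  dataset_session_uuid TEXT,
  dataset_namespace TEXT,
  dataset_name TEXT,
  dataset_version INTEGER,
  dataset_contact_uuid TEXT,
  dataset_creation_date TEXT,
  dataset_description TEXT,
  dataset_parent_uuid TEXT,
  dataset_modality_uuid TEXT,
  dataset_oid TEXT,
  data BLOB,
  UNIQUE (dataset_name, dataset_namespace, dataset_version)
);
CREATE TABLE IF NOT EXISTS events (
  event_uuid TEXT PRIMARY KEY,
  event_dataset_uuid TEXT,
  event_type_uuid TEXT,
  event_start_time REAL,
  event_end_time REAL,
  event_certainty REAL
);
CREATE TABLE IF NOT EXISTS event_types (
  event_type_uuid TEXT PRIMARY KEY,
  event_type TEXT,
  event_type_description TEXT
);
CREATE TABLE IF NOT EXISTS tags (
  tag_uuid TEXT PRIMARY KEY,
  tag_name TEXT,
  tag_entity_uuid TEXT,
  tag_entity_class TEXT,
  UNIQUE (tag_name, tag_entity_uuid, tag_entity_class)
);
CREATE TABLE IF NOT EXISTS attributes (
  attribute_uuid TEXT PRIMARY KEY,
  attribute_entity_uuid TEXT,
  attribute_entity_class TEXT,
  attribute_path TEXT,
  attribute_numeric_value REAL,
  attribute_value TEXT
);
CREATE TABLE IF NOT EXISTS datadefs (
  datadef_uuid TEXT PRIMARY KEY,
  datadef_format TEXT,
  datadef_sampling_rate REAL,
  datadef_description TEXT,
  datadef_oid TEXT,
  data BLOB
);
CREATE TABLE IF NOT EXISTS datamaps (
  datamap_uuid TEXT PRIMARY KEY,
  datamap_datadef_uuid TEXT,
  datamap_entity_uuid TEXT,
  datamap_entity_class TEXT,
  datamap_path TEXT
);
CREATE TABLE IF NOT EXISTS numeric_values (
  numeric_value_uuid TEXT PRIMARY KEY,
  numeric_value_datadef_uuid TEXT,
  numeric_value_length INTEGER,
  numeric_value BLOB
);
CREATE TABLE IF NOT EXISTS numeric_streams (
  numeric_stream_uuid TEXT PRIMARY KEY,
  numeric_stream_datadef_uuid TEXT,
  numeric_stream_time REAL,
  numeric_stream_length INTEGER,
  numeric_stream BLOB
);
CREATE TABLE IF NOT EXISTS xml_values (
  xml_value_uuid TEXT PRIMARY KEY,
  xml_value_datadef_uuid TEXT,
  xml_value TEXT
);
CREATE TABLE IF NOT EXISTS xml_streams (
  xml_stream_uuid TEXT PRIMARY KEY,
  xml_stream_datadef_uuid TEXT,
  xml_stream_time REAL,
  xml_stream TEXT
);
CREATE TABLE IF NOT EXISTS collections (
  collection_uuid TEXT,
  collection_entity_uuid TEXT,
  collection_entity_class TEXT
);
CREATE TABLE IF NOT EXISTS transforms (
  transform_uuid TEXT,
  transform_string TEXT,
  transform_description TEXT
);
CREATE TABLE IF NOT EXISTS modalities (
  modality_uuid TEXT PRIMARY KEY,
  modality_name TEXT,
  modality_description TEXT,
  UNIQUE (modality_name)
);
CREATE TABLE IF NOT EXISTS comments (
  comment_uuid TEXT PRIMARY KEY,
  comment_entity_uuid TEXT,
  comment_entity_class TEXT,
  comment_value TEXT
);
CREATE TABLE IF NOT EXISTS contacts (
  contact_uuid TEXT PRIMARY KEY,
  contact_name TEXT,
  contact_description TEXT
);
CREATE TABLE IF NOT EXISTS devices (
  device_uuid TEXT PRIMARY KEY,
  device_entity_uuid TEXT,
  device_entity_class TEXT,
  device_description TEXT
);
CREATE TABLE IF NOT EXISTS elements (
  element_uuid TEXT PRIMARY KEY,
  element_dataset_uuid TEXT,
  element_label TEXT,
  element_position INTEGER,
  element_description TEXT
);
CREATE TABLE IF NOT EXISTS subjects (
  subject_uuid TEXT PRIMARY KEY,
  subject_entity_uuid TEXT,
  subject_entity_class TEXT,
  subject_description TEXT
);
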