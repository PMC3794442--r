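## Minimal MAT-file (Level 5) codec.
##
## Covers the subset needed for EEGLAB-style containers: double arrays,
## character arrays, 1x1 structs, 1xN struct arrays, and cell arrays, all
## little-endian and uncompressed. R mapping:
##   named list            <-> 1x1 struct
##   unnamed list of named lists <-> 1xN struct array
##   unnamed list (other)  <-> cell array
##   character scalar      <-> char row vector
##   numeric vector/matrix <-> double array (1x1 / 1xN / MxN)
## zlib-compressed elements (miCOMPRESSED) are inflated on read where the
## platform's zlib supports it; the writer always emits uncompressed data.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L; MX_INT64 <- 14L; MX_UINT64 <- 15L

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                            endian = "little")
pad8 <- function(r) {
  rem <- length(r) %% 8L
  if (rem) c(r, raw(8L - rem)) else r
}

mat_element <- function(type, data) {
  c(u32(type), u32(length(data)), pad8(data))
}

mat_flags <- function(class) mat_element(MI_UINT32, c(u32(class), u32(0L)))
mat_dims <- function(d) mat_element(MI_INT32, writeBin(as.integer(d), raw(),
                                                       size = 4L,
                                                       endian = "little"))
mat_name <- function(nm) mat_element(MI_INT8, charToRaw(nm))

is_struct_array <- function(x) {
  is.list(x) && is.null(names(x)) &&
    (length(x) == 0L ||
       all(vapply(x, function(e) is.list(e) && !is.null(names(e)),
                  logical(1))))
}

mat_encode_value <- function(x, name = "") {
  if (is.null(x)) x <- numeric(0)
  if (is.logical(x) || is.integer(x)) x <- as.double(x)
  if (is.double(x)) {
    dims <- if (is.matrix(x)) dim(x)
            else if (length(x) == 0L) c(0L, 0L)
            else c(1L, length(x))
    body <- c(mat_flags(MX_DOUBLE), mat_dims(dims), mat_name(name),
              mat_element(MI_DOUBLE,
                          writeBin(as.vector(x), raw(), size = 8L,
                                   endian = "little")))
    return(mat_element(MI_MATRIX, body))
  }
  if (is.character(x)) {
    s <- paste(x, collapse = "")
    codes <- if (nzchar(s)) utf8ToInt(s) else integer(0)
    if (any(codes > 65535L))
      stop("characters outside the UTF-16 BMP are not supported",
           call. = FALSE)
    body <- c(mat_flags(MX_CHAR), mat_dims(c(1L, length(codes)) *
                                             c(length(codes) > 0L, 1L)),
              mat_name(name),
              mat_element(MI_UINT16,
                          writeBin(as.integer(codes), raw(), size = 2L,
                                   endian = "little")))
    return(mat_element(MI_MATRIX, body))
  }
  if (is.list(x) && !is.null(names(x))) {     # 1x1 struct
    return(mat_encode_struct(list(x), c(1L, 1L), name))
  }
  if (is_struct_array(x)) {                   # 1xN struct array
    dims <- if (length(x) == 0L) c(0L, 0L) else c(1L, length(x))
    return(mat_encode_struct(x, dims, name))
  }
  if (is.list(x)) {                           # cell array
    dims <- if (length(x) == 0L) c(0L, 0L) else c(1L, length(x))
    body <- c(mat_flags(MX_CELL), mat_dims(dims), mat_name(name),
              unlist(lapply(x, mat_encode_value), use.names = FALSE))
    return(mat_element(MI_MATRIX, body))
  }
  stop(sprintf("cannot encode object of class '%s' into a container",
               paste(class(x), collapse = "/")), call. = FALSE)
}

mat_encode_struct <- function(elems, dims, name) {
  fields <- unique(unlist(lapply(elems, names), use.names = FALSE))
  if (is.null(fields)) fields <- character(0)
  if (any(nchar(fields) > 31L))
    stop("struct field names are limited to 31 characters", call. = FALSE)
  fn_raw <- unlist(lapply(fields, function(f) {
    r <- charToRaw(f)
    c(r, raw(32L - length(r)))
  }), use.names = FALSE)
  if (is.null(fn_raw)) fn_raw <- raw(0)
  payload <- unlist(lapply(elems, function(el) {
    unlist(lapply(fields, function(f) {
      mat_encode_value(if (f %in% names(el)) el[[f]] else numeric(0))
    }), use.names = FALSE)
  }), use.names = FALSE)
  if (is.null(payload)) payload <- raw(0)
  body <- c(mat_flags(MX_STRUCT), mat_dims(dims), mat_name(name),
            mat_element(MI_INT32, u32(32L)),
            mat_element(MI_INT8, fn_raw),
            payload)
  mat_element(MI_MATRIX, body)
}

#' Serialize a container structure to MAT-file bytes
#'
#' @param struct Named list to store as a single struct variable.
#' @param name Variable name inside the file.
#' @return Raw vector holding a complete Level 5 MAT-file.
#' @export
mat_serialize <- function(struct, name = "EEG") {
  if (!is.list(struct) || is.null(names(struct)))
    stop("container structure must be a named list", call. = FALSE)
  desc <- sprintf("MATLAB 5.0 MAT-file, written by eventstore on %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr[seq_len(min(116L, length(hdr)))],
           rep(charToRaw(" "), max(0L, 116L - length(hdr))))
  header <- c(hdr, raw(8L),
              writeBin(c(256L), raw(), size = 2L, endian = "little"),
              charToRaw("IM"))
  c(header, mat_encode_value(struct, name = name))
}

## ---- reader ----

mat_reader <- function(r) {
  e <- new.env(parent = emptyenv())
  e$r <- r
  e$pos <- 1L
  e
}

rd_bytes <- function(e, n) {
  if (n == 0L) return(raw(0))
  out <- e$r[e$pos:(e$pos + n - 1L)]
  e$pos <- e$pos + n
  out
}

rd_u32 <- function(e) {
  v <- readBin(rd_bytes(e, 4L), "integer", size = 4L, endian = "little",
               signed = TRUE)
  if (v < 0) v <- v + 2^32
  v
}

rd_element <- function(e) {
  first <- rd_u32(e)
  if (first > 65535) {                       # small data element format
    type <- first %% 65536
    nbytes <- first %/% 65536
    data <- rd_bytes(e, 4L)[seq_len(nbytes)]
  } else {
    type <- first
    nbytes <- rd_u32(e)
    data <- rd_bytes(e, nbytes)
    rem <- nbytes %% 8L
    if (rem && type != MI_COMPRESSED) rd_bytes(e, 8L - rem)
  }
  list(type = type, data = data)
}

decode_numeric <- function(type, data) {
  switch(as.character(type),
    "9"  = readBin(data, "double", n = length(data) / 8L, size = 8L,
                   endian = "little"),
    "7"  = readBin(data, "double", n = length(data) / 4L, size = 4L,
                   endian = "little"),
    "5"  = as.double(readBin(data, "integer", n = length(data) / 4L,
                             size = 4L, endian = "little")),
    "6"  = {
      v <- readBin(data, "integer", n = length(data) / 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.double(v))
    },
    "3"  = as.double(readBin(data, "integer", n = length(data) / 2L,
                             size = 2L, endian = "little")),
    "4"  = as.double(readBin(data, "integer", n = length(data) / 2L,
                             size = 2L, endian = "little", signed = FALSE)),
    "1"  = as.double(readBin(data, "integer", n = length(data), size = 1L,
                             endian = "little")),
    "2"  = as.double(as.integer(data)),
    "12" = readBin(data, "double", n = length(data) / 8L, size = 8L,
                   endian = "little"),  # int64: read approximately
    stop(sprintf("unsupported numeric storage type %d", type),
         call. = FALSE))
}

decode_char <- function(type, data) {
  txt <- switch(as.character(type),
    "4"  = intToUtf8(readBin(data, "integer", n = length(data) / 2L,
                             size = 2L, endian = "little",
                             signed = FALSE)),
    "17" = intToUtf8(readBin(data, "integer", n = length(data) / 2L,
                             size = 2L, endian = "little",
                             signed = FALSE)),
    "1"  = , "2" = , "16" = rawToChar(data),
    stop(sprintf("unsupported char storage type %d", type), call. = FALSE))
  txt
}

mat_decode_matrix <- function(e) {
  flags <- rd_element(e)
  class <- as.integer(flags$data[1L])
  dims_el <- rd_element(e)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4L,
                  size = 4L, endian = "little")
  name <- rawToChar(rd_element(e)$data)
  n <- prod(dims)
  value <- if (class %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8,
                            MX_INT16, MX_UINT16, MX_INT32, MX_UINT32,
                            MX_INT64, MX_UINT64)) {
    pr <- rd_element(e)
    v <- decode_numeric(pr$type, pr$data)
    if (length(dims) == 2L && all(dims > 1L)) matrix(v, nrow = dims[1L])
    else as.vector(v)
  } else if (class == MX_CHAR) {
    pr <- rd_element(e)
    decode_char(pr$type, pr$data)
  } else if (class == MX_STRUCT) {
    fnl_el <- rd_element(e)                 # field name length (<= 32)
    fnl <- readBin(fnl_el$data, "integer", size = 4L, endian = "little")
    fn <- rd_element(e)$data
    nf <- length(fn) %/% fnl
    fields <- vapply(seq_len(nf), function(i) {
      chunk <- fn[((i - 1L) * fnl + 1L):(i * fnl)]
      rawToChar(chunk[chunk != as.raw(0L)])
    }, character(1))
    elems <- lapply(seq_len(n), function(i) {
      el <- lapply(seq_len(nf), function(j) mat_decode_element(e)$value)
      names(el) <- fields
      el
    })
    if (n == 1L) elems[[1L]]
    else elems                              # includes n == 0 -> list()
  } else if (class == MX_CELL) {
    lapply(seq_len(n), function(i) mat_decode_element(e)$value)
  } else {
    stop(sprintf("unsupported array class %d in container", class),
         call. = FALSE)
  }
  list(name = name, value = value)
}

mat_decode_element <- function(e) {
  el <- rd_element(e)
  if (el$type == MI_COMPRESSED) {
    inflated <- tryCatch(memDecompress(el$data, type = "gzip"),
                         error = function(err)
                           stop("compressed container element could not be inflated",
                                call. = FALSE))
    sub <- mat_reader(inflated)
    return(mat_decode_element(sub))
  }
  if (el$type != MI_MATRIX)
    stop(sprintf("unexpected top-level element type %d", el$type),
         call. = FALSE)
  if (length(el$data) == 0L) return(list(name = "", value = numeric(0)))
  mat_decode_matrix(mat_reader(el$data))
}

#' Parse MAT-file bytes into an R structure
#'
#' @param bytes Raw vector holding a Level 5 MAT-file.
#' @return Named list of the file's variables.
#' @export
mat_deserialize <- function(bytes) {
  if (length(bytes) < 128L)
    stop("not a MAT-file: truncated header", call. = FALSE)
  magic <- rawToChar(bytes[127:128])
  if (magic != "IM")
    stop("unsupported container byte order (big-endian)", call. = FALSE)
  e <- mat_reader(bytes)
  e$pos <- 129L
  vars <- list()
  while (e$pos <= length(bytes)) {
    v <- mat_decode_element(e)
    vars[[if (nzchar(v$name)) v$name else length(vars) + 1L]] <- v$value
  }
  vars
}

looks_like_mat <- function(bytes) {
  length(bytes) >= 128L &&
    identical(rawToChar(bytes[127:128]), "IM") &&
    grepl("^MATLAB 5.0", rawToChar(bytes[1:10]))
}

#' Write a container structure to a MAT-file
#'
#' @param path Output file path.
#' @param struct Named list (e.g. an EEG-like structure).
#' @param name Variable name stored in the file.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, struct, name = "EEG") {
  writeBin(mat_serialize(struct, name = name), path)
  invisible(path)
}

#' Read a container structure from a MAT-file
#'
#' Returns the first variable of the file as a named list. List-valued
#' sections (`event`, `urevent`, `chanlocs`, `element`, `feature`,
#' `metadata`) are normalized to unnamed lists of records; a recording
#' container (one with a `srate` field) lacking an `event` section yields an
#' empty event list with a warning.
#'
#' @param path MAT-file path.
#' @return Named list.
#' @export
read_container <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  vars <- mat_deserialize(bytes)
  if (length(vars) == 0L)
    stop("container holds no variables", call. = FALSE)
  normalize_container(vars[[1L]])
}

normalize_container <- function(x) {
  if (!is.list(x)) stop("container variable is not a structure",
                        call. = FALSE)
  sections <- c("event", "urevent", "chanlocs", "element", "feature",
                "metadata")
  for (s in intersect(sections, names(x))) {
    v <- x[[s]]
    if (is.list(v) && !is.null(names(v))) x[[s]] <- list(v)
    else if (!is.list(v) && length(v) == 0L) x[[s]] <- list()
  }
  if ("srate" %in% names(x) && !"event" %in% names(x)) {
    warning("container has no event section; using an empty event list",
            call. = FALSE)
    x$event <- list()
  }
  x
}
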