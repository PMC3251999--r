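# Tabular formats: sensor corpora and segment tables as CSV (1-based
# inclusive begin/end coordinates in files), event and decision streams as
# JSON lines with ISO-8601 timestamps, and a versioned structured-text
# (JSON) model archive whose floats round-trip bitwise.

#' Write / read a multi-axis sensor signal table
#'
#' CSV with a `time` column, one column per axis, and a `label` column.
#' Reading validates the header and that time is non-decreasing, citing the
#' offending row.
#'
#' @param signal data frame with `time`, axis columns, `label`.
#' @param path CSV path.
#' @return `write_sensor_csv` the path; `read_sensor_csv` the data frame.
#' @rdname sensor_csv
#' @export
write_sensor_csv <- function(signal, path) {
  check_that(all(c("time", "label") %in% names(signal)),
             "signal needs 'time' and 'label' columns")
  write.csv(signal, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sensor_csv
#' @export
read_sensor_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time", "label"))
    if (!col %in% names(df)) stop_format("missing column '", col, "' in ", path)
  bad <- which(diff(df$time) < 0)
  if (length(bad))
    stop_format("time not monotone at row ", bad[1] + 1, " of ", path)
  df
}

#' Write / read a segmentation table
#'
#' CSV with columns `label`, `begin`, `end`; coordinates are 1-based
#' inclusive. Reading rejects rows with `end < begin`, citing the row.
#'
#' @param segments segmentation data frame. @param path CSV path.
#' @param T sequence length to attach on read (optional).
#' @rdname segments_csv
#' @export
write_segments_csv <- function(segments, path) {
  write.csv(segments[, c("label", "begin", "end")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname segments_csv
#' @export
read_segments_csv <- function(path, T = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("label", "begin", "end"))
    if (!col %in% names(df)) stop_format("missing column '", col, "' in ", path)
  bad <- which(df$end < df$begin)
  if (length(bad)) stop_format("end < begin at row ", bad[1], " of ", path)
  if (is.null(T)) T <- if (nrow(df)) max(df$end) else 0L
  as_semi_segmentation(df, T)
}

iso8601 <- function(time) format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write / read activity events as JSON lines
#'
#' One JSON object per line with fields `id`, `name`, `type`, `time`
#' (ISO-8601), `person`, `location`. Reading rejects events without a name,
#' citing the line.
#'
#' @param events `activity_events`. @param path JSONL path.
#' @rdname events_jsonl
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i)
    jsonlite::toJSON(list(id = events$id[i], name = events$name[i],
                          type = events$type[i],
                          time = iso8601(events$time[i]),
                          person = events$person[i],
                          location = events$location[i]),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) stop_format("bad JSON at line ", i,
                                                  " of ", path))
    if (is.null(r$name) || !nzchar(r$name))
      stop_format("event missing name at line ", i, " of ", path)
    r
  })
  if (!length(recs))
    return(activity_events(character(), character(), as.POSIXct(character())))
  g <- function(f, default) vapply(recs, function(r)
    as.character(r[[f]] %||% default), character(1))
  activity_events(id = g("id", NA), name = g("name", NA),
                  time = as.POSIXct(g("time", NA), tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%SZ"),
                  person = g("person", "p1"), location = g("location", ""),
                  type = g("type", "Motion"))
}

#' Write / read rule decisions as JSON lines
#'
#' @param decisions decision data frame from [apply_rules()].
#' @param path JSONL path.
#' @rdname decisions_jsonl
#' @export
write_decisions_jsonl <- function(decisions, path) {
  lines <- vapply(seq_len(nrow(decisions)), function(i)
    jsonlite::toJSON(list(kind = decisions$kind[i],
                          payload = decisions$payload[i],
                          triggers = decisions$triggers[[i]],
                          time = iso8601(decisions$time[i])),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname decisions_jsonl
#' @export
read_decisions_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(kind = vapply(recs, `[[`, character(1), "kind"),
             payload = vapply(recs, `[[`, character(1), "payload"),
             triggers = I(lapply(recs, function(r) as.character(r$triggers))),
             time = as.POSIXct(vapply(recs, `[[`, character(1), "time"),
                               tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ"),
             stringsAsFactors = FALSE)
}

# ---- versioned model archive ----------------------------------------------

ARCHIVE_VERSION <- 1L

# recursively encode an R object into JSON-safe tagged nodes; doubles are
# printed as "%.17g" strings, which strtod parses back bitwise-identically
num_out <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else unname(x)
}

archive_encode <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.matrix(x)) return(list(t = "matrix", dim = dim(x),
                                mode = storage.mode(x),
                                dimnames = archive_encode(dimnames(x)),
                                data = num_out(as.vector(x))))
  if (is.numeric(x) || is.logical(x) || is.character(x) || is.integer(x))
    return(list(t = "vector", mode = storage.mode(x), names = names(x),
                data = num_out(unname(x))))
  if (is.list(x)) return(list(t = "list", class = class(x),
                              names = names(x),
                              items = lapply(unname(x), archive_encode)))
  stop_format("cannot archive object of class ", paste(class(x), collapse = "/"))
}

archive_decode <- function(node, field = "payload") {
  need <- function(f) {
    if (is.null(node[[f]])) stop_format("archive missing field '", f,
                                        "' under ", field)
    node[[f]]
  }
  switch(as.character(need("t")),
    null = NULL,
    matrix = {
      m <- matrix(unlist(need("data")), nrow = unlist(need("dim"))[1])
      storage.mode(m) <- node$mode %||% "numeric"
      dimnames(m) <- archive_decode(node$dimnames, paste0(field, ".dimnames"))
      m
    },
    vector = {
      v <- unlist(need("data")) %||% vector(node$mode %||% "numeric", 0)
      storage.mode(v) <- node$mode %||% "numeric"
      if (!is.null(node$names)) names(v) <- unlist(node$names)
      v
    },
    list = {
      items <- lapply(seq_along(node$items),
                      function(i) archive_decode(node$items[[i]],
                                                 paste0(field, "[", i, "]")))
      if (!is.null(node$names)) names(items) <- unlist(node$names)
      cls <- unlist(node$class)
      if (!is.null(cls) && !identical(cls, "list")) class(items) <- cls
      items
    },
    stop_format("unknown archive node type under ", field))
}

#' Save / load a model archive
#'
#' Versioned structured-text (JSON) serialization for the package's model
#' objects (codebooks, HMM banks, semi-Markov CRF weights with duration
#' statistics, rule configurations, ...). Floats are written with full
#' precision, so `load_model(save_model(x))` reproduces them bitwise; a
#' version mismatch or a missing field is rejected with a clear error.
#'
#' @param object model object (list-based S3 structure).
#' @param path archive path. @param kind stored kind tag (defaults to the
#'   object's class).
#' @rdname model_archive
#' @export
save_model <- function(object, path, kind = class(object)[1]) {
  doc <- list(schema_version = ARCHIVE_VERSION, kind = kind,
              payload = archive_encode(object))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname model_archive
#' @export
load_model <- function(path) {
  check_that(file.exists(path), "no such archive: ", path)
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  v <- doc$schema_version
  if (is.null(v) || !identical(as.integer(v), ARCHIVE_VERSION))
    stop_format("archive schema version ", v %||% "<missing>",
                " not supported (expected ", ARCHIVE_VERSION,
                "); no migration path")
  obj <- archive_decode(doc$payload)
  attr(obj, "kind") <- doc$kind
  obj
}
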