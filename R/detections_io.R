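# Canonical column sets for the four tables. The detection table is the atomic
# record of the pipeline: one classifier output event with a confidence score.
DETECTION_COLUMNS <- c(
  "detection_id", "dataset_id", "recorder_id", "species", "score",
  "timestamp_utc", "local_offset_minutes", "source_file",
  "start_offset_s", "end_offset_s"
)
RECORDER_COLUMNS <- c(
  "recorder_id", "dataset_id", "latitude", "longitude", "habitat",
  "local_offset_minutes", "deploy_start", "deploy_end"
)
LABEL_COLUMNS <- c("detection_id", "label", "labeler_id")
EFFORT_COLUMNS <- c("recorder_id", "date", "recorded_hours")

TS_FORMAT <- "%Y-%m-%dT%H:%M:%SZ"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a species name for matching
#'
#' Matching is exact after trimming and collapsing whitespace and folding
#' case; no fuzzy matching is attempted (misjoins are worse than misses).
#'
#' @param x character vector of species names.
#' @return normalized character vector usable as a join key.
#' @export
species_key <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

format_ts <- function(x) format(x, TS_FORMAT, tz = "UTC")

parse_ts <- function(x) {
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
}

#' Deterministic detection identifier
#'
#' When input rows carry no id, one is assigned from
#' (source_file, start_offset_s, species) so that validation labels can join
#' back to detections stably across re-reads of the same table.
#'
#' @param source_file,start_offset_s,species vectors of equal length.
#' @return character vector of ids.
#' @export
make_detection_id <- function(source_file, start_offset_s, species) {
  sprintf("%s:%.3f:%s", source_file, start_offset_s,
          gsub("\\s+", "_", trimws(species)))
}

validate_detection_rows <- function(df) {
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & !nzchar(reasons), why, reasons)
  }
  reasons <- bad(!nzchar(df$detection_id) | is.na(df$detection_id),
                 "missing detection_id")
  reasons <- bad(is.na(df$species) | !nzchar(df$species), "missing species")
  reasons <- bad(is.na(df$score), "unparseable score")
  reasons <- bad(df$score <= 0 | df$score > 1, "score outside (0, 1]")
  reasons <- bad(is.na(df$timestamp_utc), "unparseable timestamp")
  reasons <- bad(df$end_offset_s <= df$start_offset_s,
                 "end_offset_s not after start_offset_s")
  reasons <- bad(df$start_offset_s < 0, "negative start_offset_s")
  dup <- duplicated(paste(df$dataset_id, df$detection_id, sep = "\r"))
  reasons <- bad(dup, "duplicate detection_id within dataset")
  reasons
}

#' Read a detection table
#'
#' Reads classifier detections from CSV. The `canonical` dialect is the
#' package's own schema (see [DETECTION_COLUMNS]); the `birdnet_analyzer`
#' dialect maps the per-file result tables written by the BirdNET-Analyzer
#' tool (`Start (s)`, `End (s)`, `Scientific name`, `Common name`,
#' `Confidence`) onto the canonical fields. That dialect carries no absolute
#' timestamps, recorder or dataset identity, so these are supplied as
#' arguments.
#'
#' Rows violating the data-model invariants (score in (0,1], end after start,
#' unique id within dataset) are rejected, not repaired; the returned data
#' frame carries the rejects with row numbers and reasons in
#' `attr(x, "rejected")`, and `nrow(kept) + nrow(rejected)` always equals the
#' number of input rows.
#'
#' @param path CSV file path.
#' @param dialect `"canonical"` or `"birdnet_analyzer"`.
#' @param dataset_id,recorder_id identity to stamp on rows (birdnet dialect;
#'   ignored for canonical input).
#' @param timestamp_base POSIXct origin added to `Start (s)` to obtain
#'   absolute timestamps (birdnet dialect).
#' @param local_offset_minutes local clock offset from UTC, in minutes
#'   (birdnet dialect).
#' @param use_scientific take the species name from `Scientific name` instead
#'   of `Common name` (birdnet dialect).
#' @return data.frame of valid detections with attribute `"rejected"`.
#' @export
read_detections <- function(path,
                            dialect = c("canonical", "birdnet_analyzer"),
                            dataset_id = "default",
                            recorder_id = "unknown",
                            timestamp_base = as.POSIXct("1970-01-01",
                                                        tz = "UTC"),
                            local_offset_minutes = 0L,
                            use_scientific = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "canonical") {
    missing_cols <- setdiff(DETECTION_COLUMNS, names(raw))
    if (length(missing_cols)) {
      stop("schema error: missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    df <- data.frame(
      detection_id = raw$detection_id,
      dataset_id = raw$dataset_id,
      recorder_id = raw$recorder_id,
      species = raw$species,
      score = suppressWarnings(as.numeric(raw$score)),
      timestamp_utc = parse_ts(raw$timestamp_utc),
      local_offset_minutes = suppressWarnings(
        as.integer(raw$local_offset_minutes)),
      source_file = raw$source_file,
      start_offset_s = suppressWarnings(as.numeric(raw$start_offset_s)),
      end_offset_s = suppressWarnings(as.numeric(raw$end_offset_s)),
      stringsAsFactors = FALSE
    )
  } else {
    needed <- c("Start (s)", "End (s)", "Common name", "Confidence")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols)) {
      stop("schema error: missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    start <- suppressWarnings(as.numeric(raw[["Start (s)"]]))
    species <- if (use_scientific && "Scientific name" %in% names(raw)) {
      raw[["Scientific name"]]
    } else {
      raw[["Common name"]]
    }
    src <- if ("File" %in% names(raw)) raw[["File"]] else basename(path)
    df <- data.frame(
      detection_id = make_detection_id(src, start, species),
      dataset_id = dataset_id,
      recorder_id = recorder_id,
      species = species,
      score = suppressWarnings(as.numeric(raw[["Confidence"]])),
      timestamp_utc = timestamp_base + start,
      local_offset_minutes = as.integer(local_offset_minutes),
      source_file = src,
      start_offset_s = start,
      end_offset_s = suppressWarnings(as.numeric(raw[["End (s)"]])),
      stringsAsFactors = FALSE
    )
  }
  df$species <- gsub("\\s+", " ", trimws(df$species))
  reasons <- if (nrow(df)) validate_detection_rows(df) else character(0)
  keep <- !nzchar(reasons)
  rejected <- data.frame(row = which(!keep),
                         detection_id = df$detection_id[!keep],
                         reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a detection table in the canonical CSV dialect
#'
#' Scores are written with six decimal places and offsets with three; a table
#' produced at that precision round-trips field-for-field through
#' [read_detections()].
#'
#' @param detections data.frame of detections.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  df <- detections[, DETECTION_COLUMNS, drop = FALSE]
  out <- data.frame(
    detection_id = df$detection_id,
    dataset_id = df$dataset_id,
    recorder_id = df$recorder_id,
    species = df$species,
    score = formatC(df$score, format = "f", digits = 6),
    timestamp_utc = format_ts(df$timestamp_utc),
    local_offset_minutes = as.integer(df$local_offset_minutes),
    source_file = df$source_file,
    start_offset_s = formatC(df$start_offset_s, format = "f", digits = 3),
    end_offset_s = formatC(df$end_offset_s, format = "f", digits = 3),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read recorder metadata
#'
#' One row per (recorder, deployment interval); coordinates, habitat and the
#' local clock offset must be constant across a recorder's rows. Deployment
#' intervals must satisfy start < end and must not overlap within a recorder.
#'
#' @param path CSV with columns `recorder_id`, `dataset_id`, `latitude`,
#'   `longitude`, `habitat`, `local_offset_minutes`, `deploy_start`,
#'   `deploy_end`.
#' @return validated data.frame.
#' @export
read_recorders <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORDER_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$deploy_start <- parse_ts(raw$deploy_start)
  raw$deploy_end <- parse_ts(raw$deploy_end)
  validate_recorders(raw)
  raw
}

validate_recorders <- function(rec) {
  stopifnot(all(rec$latitude >= -90 & rec$latitude <= 90),
            all(rec$longitude >= -180 & rec$longitude <= 180))
  if (any(rec$deploy_end <= rec$deploy_start)) {
    stop("deployment interval with end <= start")
  }
  for (id in unique(rec$recorder_id)) {
    iv <- rec[rec$recorder_id == id, ]
    iv <- iv[order(iv$deploy_start), ]
    if (nrow(iv) > 1 &&
        any(iv$deploy_start[-1] < iv$deploy_end[-nrow(iv)])) {
      stop("overlapping deployment intervals for recorder ", id)
    }
    for (col in c("latitude", "longitude", "habitat",
                  "local_offset_minutes")) {
      if (length(unique(iv[[col]])) > 1) {
        stop("recorder ", id, " has inconsistent ", col)
      }
    }
  }
  invisible(rec)
}

#' @rdname read_recorders
#' @param recorders recorder data.frame.
#' @export
write_recorders <- function(recorders, path) {
  out <- recorders[, RECORDER_COLUMNS, drop = FALSE]
  out$deploy_start <- format_ts(out$deploy_start)
  out$deploy_end <- format_ts(out$deploy_end)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read or write validation labels
#'
#' Labels are expert true/false-positive judgments attached to detections by
#' id; the canonical on-disk values are `true_positive` and `false_positive`.
#'
#' @param path CSV with columns `detection_id`, `label`, `labeler_id`.
#' @return data.frame of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LABEL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !df$label %in% c("true_positive", "false_positive")
  if (any(bad)) {
    stop("unknown label value(s) at row(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (anyDuplicated(df[, c("detection_id", "labeler_id")])) {
    stop("more than one label per detection per labeler")
  }
  df
}

#' @rdname read_labels
#' @param labels label data.frame.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, LABEL_COLUMNS, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read or write recording-effort tables
#'
#' Effort is recorded hours per recorder per local calendar day, the
#' denominator of vocalization rates.
#'
#' @param path CSV with columns `recorder_id`, `date`, `recorded_hours`.
#' @return data.frame with `date` as `Date`.
#' @export
read_effort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EFFORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  if (any(df$recorded_hours < 0 | df$recorded_hours > 24)) {
    stop("recorded_hours outside [0, 24]")
  }
  df
}

#' @rdname read_effort
#' @param effort effort data.frame.
#' @export
write_effort <- function(effort, path) {
  out <- effort[, EFFORT_COLUMNS, drop = FALSE]
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Attach recorder metadata and local time to detections
#'
#' Joins coordinates and habitat by `recorder_id` and derives the local clock
#' fields used by the diel and seasonal summaries:
#' `local_hour` (0--23), `local_date`, and `local_doy` (day of year), all
#' computed from `timestamp_utc` shifted by `local_offset_minutes`. The
#' offset is data, not a timezone lookup, because diel analysis needs local
#' solar time wherever the recorder sits.
#'
#' @param detections detection data.frame.
#' @param recorders recorder data.frame (as from [read_recorders()]).
#' @param strict if `TRUE` (default), an unknown `recorder_id` is a
#'   referential-integrity error; otherwise such rows are kept, flagged by
#'   `recorder_known = FALSE`, with `NA` metadata.
#' @return detections with columns `latitude`, `longitude`, `habitat`,
#'   `recorder_known`, `local_hour`, `local_date`, `local_doy` appended.
#' @export
join_metadata <- function(detections, recorders, strict = TRUE) {
  meta <- recorders[!duplicated(recorders$recorder_id),
                    c("recorder_id", "latitude", "longitude", "habitat")]
  idx <- match(detections$recorder_id, meta$recorder_id)
  if (strict && anyNA(idx)) {
    stop("unknown recorder_id(s): ",
         paste(unique(detections$recorder_id[is.na(idx)]), collapse = ", "))
  }
  out <- detections
  out$latitude <- meta$latitude[idx]
  out$longitude <- meta$longitude[idx]
  out$habitat <- meta$habitat[idx]
  out$recorder_known <- !is.na(idx)
  local <- out$timestamp_utc + 60 * out$local_offset_minutes
  out$local_hour <- as.integer(format(local, "%H", tz = "UTC"))
  out$local_date <- as.Date(local, tz = "UTC")
  out$local_doy <- as.integer(format(local, "%j", tz = "UTC"))
  out
}
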