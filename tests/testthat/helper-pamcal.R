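# Shared fixture builders; everything is generated in code.

toy_detections <- function(n,
                           species = "Sp A",
                           dataset_id = "ds1",
                           recorder_id = "R1",
                           scores = NULL,
                           t0 = as.POSIXct("2022-06-01 06:00:00",
                                           tz = "UTC"),
                           local_offset_minutes = 0L,
                           id_prefix = NULL) {
  if (is.null(scores)) scores <- round(seq(0.80, 0.99, length.out = n), 6)
  prefix <- id_prefix %||% paste0(recorder_id, "-", gsub(" ", "_", species))
  data.frame(
    detection_id = sprintf("%s-%04d", prefix, seq_len(n)),
    dataset_id = dataset_id,
    recorder_id = recorder_id,
    species = species,
    score = scores,
    timestamp_utc = t0 + 60 * seq_len(n),
    local_offset_minutes = local_offset_minutes,
    source_file = sprintf("%s_f%03d.wav", recorder_id, seq_len(n)),
    start_offset_s = round(3 * seq_len(n) + 0.25, 3),
    end_offset_s = round(3 * seq_len(n) + 3.25, 3),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_recorders <- function(recorder_id = "R1", dataset_id = "ds1",
                          latitude = 60, longitude = 10,
                          habitat = "forest", local_offset_minutes = 0L) {
  data.frame(recorder_id = recorder_id, dataset_id = dataset_id,
             latitude = latitude, longitude = longitude, habitat = habitat,
             local_offset_minutes = as.integer(local_offset_minutes),
             deploy_start = as.POSIXct("2022-01-01", tz = "UTC"),
             deploy_end = as.POSIXct("2023-01-01", tz = "UTC"),
             stringsAsFactors = FALSE)
}

toy_labels <- function(detections, labels) {
  data.frame(detection_id = detections$detection_id,
             label = labels, labeler_id = "expert",
             stringsAsFactors = FALSE)
}

# single-recorder config with explicit deployment hours, for count checks
one_stream_config <- function(profile, hours = 100, export_floor = 0.80,
                              seed = 1, start = "2022-06-01") {
  rec <- toy_recorders()
  rec$deploy_start <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  rec$deploy_end <- rec$deploy_start + hours * 3600
  simulation_config(rec, list(profile), start,
                    as.Date(start) + ceiling(hours / 24) + 1,
                    export_floor = export_floor, seed = seed,
                    dataset_id = "ds1")
}

# ground-truth labels for a sampled subset of a simulation
truth_labels_for <- function(sample, truth) {
  data.frame(detection_id = sample$detection_id,
             label = truth$label[match(sample$detection_id,
                                       truth$detection_id)],
             labeler_id = "simulator", stringsAsFactors = FALSE)
}
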