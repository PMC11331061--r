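# Reliability filters. The pipeline default order is
# allowlist -> minimum raw detections -> calibrated thresholds; every dropped
# detection lands in exactly one drop report with a reason code, and each
# filter is idempotent.

#' Drop species with too few raw detections
#'
#' Species are retained per dataset when their raw detection count strictly
#' exceeds `min_count` ("over 50 detections"); the validation budget cannot
#' characterize rarer species.
#'
#' @param detections detection data.frame.
#' @param min_count strict lower bound on the per-(dataset, species) count.
#' @return list with `detections` (kept rows) and `report` (one row per
#'   (dataset, species) with its count and kept/dropped status).
#' @export
filter_min_raw_detections <- function(detections, min_count = 50) {
  key <- paste(detections$dataset_id, detections$species, sep = "\r")
  counts <- table(key)
  kept_key <- names(counts)[counts > min_count]
  keep <- key %in% kept_key
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  report <- data.frame(dataset_id = parts[, 1], species = parts[, 2],
                       n_detections = as.integer(counts),
                       kept = names(counts) %in% kept_key,
                       stringsAsFactors = FALSE)
  report <- report[order(report$dataset_id, report$species), ]
  rownames(report) <- NULL
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(detections = out, report = report)
}

#' Keep only detections passing their calibrated threshold
#'
#' A detection is kept iff its (species, dataset) pair is reliable (a
#' calibrated threshold exists), the pair retains more than the minimum
#' number of detections at that threshold, and the detection's score is at or
#' above the threshold (a score exactly at the threshold is kept, consistent
#' with precision being computed on `score >= threshold`).
#'
#' @param detections detection data.frame.
#' @param calibration a [calibrate()] result.
#' @param permissive if `FALSE` (default), a (species, dataset) pair present
#'   in `detections` but absent from the calibration is an error; if `TRUE`
#'   such detections are dropped with reason `no_calibration`.
#' @return list with `detections` (kept rows) and `drops` (`detection_id`,
#'   `reason` in `no_calibration` / `unreliable` / `too_few_surviving` /
#'   `below_threshold`).
#' @export
apply_calibrated_thresholds <- function(detections, calibration,
                                        permissive = FALSE) {
  stopifnot(inherits(calibration, "calibration"))
  r <- calibration$results
  rkey <- paste(r$dataset_id, r$species, sep = "\r")
  dkey <- paste(detections$dataset_id, detections$species, sep = "\r")
  idx <- match(dkey, rkey)
  if (!permissive && anyNA(idx)) {
    miss <- unique(dkey[is.na(idx)])
    stop("no calibration for: ",
         paste(gsub("\r", "/", miss), collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(detections))
  reason[is.na(idx)] <- "no_calibration"
  known <- !is.na(idx)
  reason[known & !r$reliable[idx]] <- "unreliable"
  gate <- known & r$reliable[idx] & !r$meets_min_detections[idx]
  reason[gate] <- "too_few_surviving"
  ok <- known & r$reliable[idx] & r$meets_min_detections[idx]
  below <- ok & detections$score < r$chosen_threshold[idx]
  reason[below] <- "below_threshold"
  keep <- is.na(reason)
  drops <- data.frame(detection_id = detections$detection_id[!keep],
                      reason = reason[!keep], stringsAsFactors = FALSE)
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(detections = out, drops = drops)
}

#' Keep only species expected at each recorder
#'
#' Re-exposes the classifier's geographic species filter as a data-driven
#' stage: the allowlist says which species are plausible at each recorder
#' (e.g. from range maps), and detections of other species there are dropped.
#' Species names match exactly after whitespace/case normalization.
#'
#' @param detections detection data.frame.
#' @param allowlist data.frame with columns `recorder_id` and `species`; may
#'   be empty.
#' @param permissive if `FALSE` (default) every recorder present in
#'   `detections` must appear in the allowlist; if `TRUE`, recorders absent
#'   from the allowlist keep all their detections.
#' @return list with `detections` (kept rows) and `drops` (`detection_id`,
#'   `reason = "not_in_allowlist"`).
#' @export
species_allowlist_filter <- function(detections, allowlist,
                                     permissive = FALSE) {
  listed <- unique(allowlist$recorder_id)
  if (!permissive) {
    miss <- setdiff(unique(detections$recorder_id), listed)
    if (length(miss)) {
      stop("allowlist missing recorder(s): ", paste(miss, collapse = ", "))
    }
  }
  akey <- paste(allowlist$recorder_id, species_key(allowlist$species),
                sep = "\r")
  dkey <- paste(detections$recorder_id, species_key(detections$species),
                sep = "\r")
  covered <- detections$recorder_id %in% listed
  keep <- !covered | dkey %in% akey
  drops <- data.frame(detection_id = detections$detection_id[!keep],
                      reason = rep("not_in_allowlist", sum(!keep)),
                      stringsAsFactors = FALSE)
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(detections = out, drops = drops)
}
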