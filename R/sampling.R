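# Expert-validation design: draw the detections to be labeled, write the
# label sheet, and read the expert's answers back in.

#' Sample detections for expert validation
#'
#' For every (dataset, species) group, draws a uniform random sample without
#' replacement of `min(n_per_species, available)` detections from all
#' detections at or above the export floor. The sampling frame is the
#' classifier's raw output at the floor (not the post-calibration set):
#' precision at higher thresholds is later computed on the surviving subset of
#' this one labeled sample. Group order and sampling are reproducible under
#' `seed`, independent of row order, via stable per-group sub-seeding.
#'
#' @param detections detection data.frame.
#' @param n_per_species target labels per (dataset, species); groups with
#'   fewer detections contribute all of them.
#' @param seed integer seed.
#' @param export_floor sampling-frame floor on the score.
#' @return data.frame of sampled detections (a row subset of `detections`),
#'   ordered by dataset, species, detection_id.
#' @export
sample_for_validation <- function(detections, n_per_species = 50, seed = 1,
                                  export_floor = 0.80) {
  stopifnot(n_per_species >= 1)
  if (nrow(detections) == 0) stop("no detections to sample from")
  frame <- detections[detections$score >= export_floor, , drop = FALSE]
  groups <- split(seq_len(nrow(frame)),
                  paste(frame$dataset_id, frame$species, sep = "\r"))
  picked <- integer(0)
  for (g in sort(names(groups))) {
    rows <- groups[[g]]
    ids <- frame$detection_id[rows]
    keyparts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    set.seed(stream_seed(seed, keyparts[1], keyparts[2]))
    take <- min(n_per_species, length(rows))
    # sample ids, not row positions, so the draw is row-order invariant
    chosen <- sample(sort(ids), take)
    picked <- c(picked, rows[match(chosen, ids)])
  }
  out <- frame[picked, , drop = FALSE]
  out <- out[order(out$dataset_id, out$species, out$detection_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a validation label sheet
#'
#' One row per sampled detection, ordered by (species, detection_id) so each
#' species forms a contiguous block matching the per-species labeling
#' workflow. The `label` column is left blank for the expert, who fills in
#' `tp` or `fp`.
#'
#' @param sample sampled detections, as from [sample_for_validation()].
#' @param path output CSV path.
#' @return the sheet data.frame, invisibly.
#' @export
make_label_sheet <- function(sample, path) {
  if (nrow(sample) == 0) stop("empty validation sample")
  sheet <- sample[order(sample$species, sample$detection_id),
                  c("detection_id", "species", "source_file",
                    "start_offset_s", "end_offset_s")]
  sheet$label <- ""
  utils::write.csv(sheet, path, row.names = FALSE)
  invisible(sheet)
}

#' Ingest a filled-in label sheet
#'
#' Rows labeled `tp`/`fp` (or the long forms `true_positive` /
#' `false_positive`) become validation labels; blank rows are reported in
#' `attr(x, "unlabeled")`; any other token is an error naming the row.
#'
#' @param sheet path to the filled sheet, or its data.frame.
#' @param labeler_id identity recorded on the labels.
#' @return label data.frame (`detection_id`, `label`, `labeler_id`) with the
#'   unlabeled detection ids as attribute `"unlabeled"`.
#' @export
ingest_labels <- function(sheet, labeler_id = "expert") {
  df <- if (is.character(sheet)) {
    utils::read.csv(sheet, stringsAsFactors = FALSE,
                    colClasses = "character")
  } else {
    sheet
  }
  if (!"label" %in% names(df)) stop("sheet has no label column")
  tok <- tolower(trimws(as.character(df$label)))
  tok[is.na(tok)] <- ""
  canon <- c(tp = "true_positive", true_positive = "true_positive",
             fp = "false_positive", false_positive = "false_positive")
  unknown <- nzchar(tok) & !tok %in% names(canon)
  if (any(unknown)) {
    stop("unknown label token(s) at sheet row(s): ",
         paste(which(unknown), collapse = ", "))
  }
  labeled <- nzchar(tok)
  if (anyDuplicated(df$detection_id[labeled])) {
    stop("conflicting duplicate detection_id(s) in sheet")
  }
  out <- data.frame(detection_id = df$detection_id[labeled],
                    label = unname(canon[tok[labeled]]),
                    labeler_id = labeler_id, stringsAsFactors = FALSE)
  attr(out, "unlabeled") <- df$detection_id[!labeled]
  out
}
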