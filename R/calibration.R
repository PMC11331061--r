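# Threshold calibration from expert-labeled subsamples.
#
# Precision is Tp/(Tp+Fp) among labeled detections scoring at or above a
# threshold; the calibrated threshold of a (species, dataset) pair is the
# lowest grid value whose estimated precision reaches the target (default
# 90%). Estimates at high thresholds rest on few surviving labels, so grid
# points with fewer than `min_labeled` labeled survivors are "undefined" and
# never chosen.

#' Default calibration threshold grid
#'
#' Twenty thresholds from 0.80 to 0.99 inclusive in steps of 0.01, matching
#' the two-decimal score convention of classifier output.
#'
#' @param from,to,by grid limits and step.
#' @return numeric vector of thresholds.
#' @export
calibration_grid <- function(from = 0.80, to = 0.99, by = 0.01) {
  round(seq(from, to, by = by), 10)
}

#' Wilson score interval for a binomial proportion
#'
#' Used for the confidence interval on precision; unlike the Wald interval it
#' keeps sensible coverage near precision 1, which calibrated species
#' commonly reach.
#'
#' @param x successes.
#' @param n trials.
#' @param conf_level confidence level.
#' @return `c(low, high)`.
#' @export
wilson_interval <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Precision estimate at one threshold
#'
#' Restricts the labeled detections of one (species, dataset) group to those
#' scoring at or above `threshold` and computes precision = Tp/(Tp+Fp) with a
#' Wilson interval. When fewer than `min_labeled` labeled detections survive,
#' the estimate is undefined (`NA`) and the grid point is ineligible for
#' threshold selection.
#'
#' @param labeled data.frame with columns `score` and `label`
#'   (`true_positive`/`false_positive`) for one group.
#' @param threshold threshold in `[0, 1]`.
#' @param min_labeled minimum surviving labels for a defined estimate.
#' @param conf_level Wilson interval level.
#' @return one-row data.frame: `threshold`, `tp`, `fp`,
#'   `n_labeled_at_threshold`, `precision`, `ci_low`, `ci_high`.
#' @export
precision_at_threshold <- function(labeled, threshold, min_labeled = 5,
                                   conf_level = 0.95) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold outside [0, 1]")
  }
  sel <- labeled$score >= threshold
  tp <- sum(labeled$label[sel] == "true_positive")
  fp <- sum(labeled$label[sel] == "false_positive")
  n <- tp + fp
  if (n >= max(min_labeled, 1)) {
    prec <- tp / n
    ci <- wilson_interval(tp, n, conf_level)
  } else {
    prec <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  data.frame(threshold = threshold, tp = tp, fp = fp,
             n_labeled_at_threshold = n, precision = prec,
             ci_low = ci[1], ci_high = ci[2])
}

#' Precision across a threshold grid
#'
#' @param labeled labeled detections of one group (see
#'   [precision_at_threshold()]).
#' @param grid strictly increasing thresholds.
#' @param min_labeled,conf_level passed through.
#' @return data.frame with one row per grid point.
#' @export
precision_curve <- function(labeled, grid = calibration_grid(),
                            min_labeled = 5, conf_level = 0.95) {
  if (length(grid) == 0) stop("empty threshold grid")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  do.call(rbind, lapply(grid, function(th) {
    precision_at_threshold(labeled, th, min_labeled, conf_level)
  }))
}

#' Select the calibrated threshold from a precision curve
#'
#' The lowest grid threshold whose defined precision reaches `target`;
#' `NA_real_` when no grid point qualifies. Undefined (too few surviving
#' labels) grid points are never chosen; plateaus resolve to the lowest
#' qualifying threshold.
#'
#' @param curve data.frame from [precision_curve()].
#' @param target target precision in `(0, 1]`; reaching it is inclusive
#'   (`>=`).
#' @return a grid threshold or `NA_real_`.
#' @export
select_threshold <- function(curve, target = 0.90) {
  if (target <= 0 || target > 1) stop("target outside (0, 1]")
  if (nrow(curve) == 0) stop("empty precision curve")
  ok <- which(!is.na(curve$precision) & curve$precision >= target)
  if (length(ok)) curve$threshold[min(ok)] else NA_real_
}

#' Calibrate classification thresholds per species and dataset
#'
#' The central fitting function of the package. Joins expert labels to
#' detections, estimates a precision curve over the threshold grid for every
#' (species, dataset) pair with labels, selects the lowest threshold reaching
#' the target precision, and counts how many detections of the full table
#' survive it. A pair is *reliable* when a threshold exists; it feeds
#' downstream summaries only if it additionally retains more than
#' `min_detections_post` detections (strict inequality). Calibration is
#' independent per dataset: a species occurring in two datasets gets two
#' results.
#'
#' @param detections full detection table (used both for label context and
#'   for the surviving-detection counts).
#' @param labels validation labels (`detection_id`, `label`, `labeler_id`).
#' @param grid threshold grid.
#' @param target target precision.
#' @param min_labeled minimum surviving labels for a defined estimate.
#' @param min_detections_post detections that must remain after thresholding
#'   (strict `>`).
#' @param conf_level Wilson interval level.
#' @return an object of class `"calibration"`: list with `results` (one row
#'   per species-dataset), `curves` (long-format precision curves), and the
#'   calibration parameters. Methods: `print`, `summary`, `coef`, `plot`,
#'   `predict` (filters a detection table, see
#'   [apply_calibrated_thresholds()]).
#' @export
calibrate <- function(detections, labels, grid = calibration_grid(),
                      target = 0.90, min_labeled = 5,
                      min_detections_post = 20, conf_level = 0.95) {
  idx <- match(labels$detection_id, detections$detection_id)
  if (anyNA(idx)) {
    stop("label(s) referencing unknown detection_id(s): ",
         paste(utils::head(labels$detection_id[is.na(idx)], 5),
               collapse = ", "))
  }
  lab <- data.frame(dataset_id = detections$dataset_id[idx],
                    species = detections$species[idx],
                    score = detections$score[idx],
                    label = labels$label, stringsAsFactors = FALSE)
  keys <- unique(lab[, c("dataset_id", "species")])
  keys <- keys[order(keys$dataset_id, keys$species), , drop = FALSE]
  res <- vector("list", nrow(keys))
  curves <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    ds <- keys$dataset_id[i]
    sp <- keys$species[i]
    grp <- lab[lab$dataset_id == ds & lab$species == sp, , drop = FALSE]
    curve <- precision_curve(grp, grid, min_labeled, conf_level)
    chosen <- select_threshold(curve, target)
    det_sp <- detections$dataset_id == ds & detections$species == sp
    surviving <- if (is.na(chosen)) NA_integer_ else {
      sum(det_sp & detections$score >= chosen)
    }
    at <- if (is.na(chosen)) {
      data.frame(precision = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, tp = NA_integer_, fp = NA_integer_)
    } else {
      curve[curve$threshold == chosen,
            c("precision", "ci_low", "ci_high", "tp", "fp")]
    }
    res[[i]] <- data.frame(
      dataset_id = ds, species = sp, n_labels = nrow(grp),
      chosen_threshold = chosen, reliable = !is.na(chosen),
      precision_at_chosen = at$precision,
      ci_low = at$ci_low, ci_high = at$ci_high,
      detections_surviving = surviving,
      meets_min_detections = !is.na(surviving) &&
        surviving > min_detections_post,
      stringsAsFactors = FALSE
    )
    curves[[i]] <- cbind(dataset_id = ds, species = sp, curve,
                         stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, res),
                 curves = do.call(rbind, curves),
                 grid = grid, target = target, min_labeled = min_labeled,
                 min_detections_post = min_detections_post,
                 conf_level = conf_level),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  r <- x$results
  cat("Calibrated classification thresholds\n")
  cat(sprintf("  grid: %.2f..%.2f (%d points), target precision %.2f\n",
              min(x$grid), max(x$grid), length(x$grid), x$target))
  cat(sprintf("  %d species-dataset pairs; %d reliable; %d usable (> %d detections)\n",
              nrow(r), sum(r$reliable),
              sum(r$reliable & r$meets_min_detections),
              x$min_detections_post))
  invisible(x)
}

#' @export
summary.calibration <- function(object, ...) {
  r <- object$results
  per <- lapply(split(r, r$dataset_id), function(d) {
    data.frame(dataset_id = d$dataset_id[1],
               species_considered = nrow(d),
               species_reliable = sum(d$reliable),
               species_usable = sum(d$reliable & d$meets_min_detections),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  structure(list(per_dataset = out, target = object$target),
            class = "summary.calibration")
}

#' @export
print.summary.calibration <- function(x, ...) {
  cat(sprintf("Species reaching %.0f%% precision, by dataset:\n",
              100 * x$target))
  for (i in seq_len(nrow(x$per_dataset))) {
    d <- x$per_dataset[i, ]
    cat(sprintf("  %s: %d/%d reliable (%d usable downstream)\n",
                d$dataset_id, d$species_reliable, d$species_considered,
                d$species_usable))
  }
  invisible(x)
}

#' @export
coef.calibration <- function(object, ...) {
  r <- object$results
  stats::setNames(r$chosen_threshold,
                  paste(r$dataset_id, r$species, sep = "/"))
}

#' @export
plot.calibration <- function(x, ...) {
  cv <- x$curves
  keys <- unique(cv[, c("dataset_id", "species")])
  n <- nrow(keys)
  mfrow <- grDevices::n2mfrow(n)
  op <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    d <- cv[cv$dataset_id == keys$dataset_id[i] &
              cv$species == keys$species[i], ]
    graphics::plot(d$threshold, d$precision, type = "b", ylim = c(0, 1),
                   xlab = "threshold", ylab = "precision",
                   main = paste(keys$species[i], keys$dataset_id[i],
                                sep = " / "), ...)
    graphics::abline(h = x$target, lty = 2)
    ch <- x$results$chosen_threshold[
      x$results$dataset_id == keys$dataset_id[i] &
        x$results$species == keys$species[i]]
    if (!is.na(ch)) graphics::abline(v = ch, col = 2)
  }
  invisible(x)
}

#' @export
as.data.frame.calibration <- function(x, ...) x$results

#' @export
predict.calibration <- function(object, newdata, permissive = FALSE, ...) {
  apply_calibrated_thresholds(newdata, object, permissive = permissive)
}
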