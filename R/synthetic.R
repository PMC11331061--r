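# Synthetic detection streams with known ground truth.
#
# Events are inhomogeneous Poisson streams per (recorder, species): the hourly
# intensity is base rate x diel kernel weight (mean 1 over the 24 local hours)
# x habitat multiplier x residency/migration indicator, applied identically to
# the true-positive and false-positive streams. Scores are Beta draws; only
# events scoring at or above the export floor are emitted, which is how
# BirdNET-style pipelines discard sub-floor output. Because both streams share
# the temporal modulation, the precision among detections scoring >= theta has
# the closed form used throughout the tests (see precision_oracle).

#' Species simulation profile
#'
#' Describes one species' detection stream: expected true/false-positive
#' vocal detection rates per recorded hour at reference conditions, the Beta
#' score distributions of each stream, and the temporal/spatial structure
#' (diel kernel, residency window, migratory presence band, habitat rate
#' multipliers).
#'
#' @param species species name.
#' @param tp_rate_per_hour,fp_rate_per_hour nonnegative expected event rates.
#' @param tp_score_params,fp_score_params length-2 `c(alpha, beta)` of the
#'   Beta score distribution of each stream.
#' @param diel_kernel `NULL` for a uniform diel profile, or a data.frame with
#'   columns `mean_hour` (0--24), `concentration` (von Mises kappa) and
#'   `weight` (mixture weights summing to 1).
#' @param residency_window `NULL` (always present) or `c(start_doy, end_doy)`;
#'   a window with `start > end` wraps around the year end (winter
#'   residents).
#' @param migration `NULL` or `c(start_latitude, speed_deg_per_week,
#'   band_halfwidth)`: the species is present only at recorders whose latitude
#'   is within `band_halfwidth` degrees of a band center that starts at
#'   `start_latitude` on the simulation start date and moves north at
#'   `speed_deg_per_week`.
#' @param habitat_multipliers `NULL` or a named numeric vector of nonnegative
#'   rate multipliers by habitat (habitats not named multiply by 1).
#' @return an object of class `"species_profile"`.
#' @export
species_profile <- function(species,
                            tp_rate_per_hour,
                            fp_rate_per_hour = 0,
                            tp_score_params = c(8, 2),
                            fp_score_params = c(2, 5),
                            diel_kernel = NULL,
                            residency_window = NULL,
                            migration = NULL,
                            habitat_multipliers = NULL) {
  stopifnot(tp_rate_per_hour >= 0, fp_rate_per_hour >= 0,
            all(tp_score_params > 0), all(fp_score_params > 0))
  if (!is.null(diel_kernel)) {
    stopifnot(is.data.frame(diel_kernel),
              all(c("mean_hour", "concentration", "weight") %in%
                    names(diel_kernel)))
    if (abs(sum(diel_kernel$weight) - 1) > 1e-8) {
      stop("diel kernel mixture weights must sum to 1")
    }
  }
  if (!is.null(habitat_multipliers)) {
    stopifnot(!is.null(names(habitat_multipliers)),
              all(habitat_multipliers >= 0))
  }
  structure(list(species = species,
                 tp_rate_per_hour = tp_rate_per_hour,
                 fp_rate_per_hour = fp_rate_per_hour,
                 tp_score_params = tp_score_params,
                 fp_score_params = fp_score_params,
                 diel_kernel = diel_kernel,
                 residency_window = residency_window,
                 migration = migration,
                 habitat_multipliers = habitat_multipliers),
            class = "species_profile")
}

#' Hourly diel weights of a species profile
#'
#' Evaluates the von Mises mixture at the 24 hour midpoints and normalizes to
#' mean 1, so multiplying the base hourly rate by these weights preserves the
#' daily total. A `NULL` kernel gives 24 ones.
#'
#' @param profile a `species_profile`.
#' @return numeric vector of 24 weights (local hours 0--23), mean 1.
#' @export
diel_weights <- function(profile) {
  k <- profile$diel_kernel
  if (is.null(k)) return(rep(1, 24))
  mids <- (0:23) + 0.5
  dens <- rep(0, 24)
  for (i in seq_len(nrow(k))) {
    ang <- (mids - k$mean_hour[i]) / 24 * 2 * pi
    dens <- dens + k$weight[i] *
      exp(k$concentration[i] * cos(ang)) /
      (2 * pi * besselI(k$concentration[i], 0))
  }
  dens / mean(dens)
}

residency_indicator <- function(profile, doy) {
  w <- profile$residency_window
  if (is.null(w)) return(rep(1, length(doy)))
  if (w[1] <= w[2]) {
    as.numeric(doy >= w[1] & doy <= w[2])
  } else {
    as.numeric(doy >= w[1] | doy <= w[2])
  }
}

migration_indicator <- function(profile, latitude, date, start_date) {
  m <- profile$migration
  if (is.null(m)) return(rep(1, length(date)))
  center <- m[1] + m[2] * as.numeric(date - start_date) / 7
  as.numeric(abs(latitude - center) <= m[3])
}

#' Simulation configuration
#'
#' @param recorders recorder data.frame (see [read_recorders()] for the
#'   columns); `deploy_start`/`deploy_end` default to the simulation span.
#' @param species_profiles list of [species_profile()] objects.
#' @param start_date,end_date `Date`s; the simulated span is
#'   `[start_date 00:00, end_date 00:00)` local clock time at each recorder.
#' @param export_floor minimum score emitted, in `[0, 1)`; 0.80 is the
#'   conventional export floor of BirdNET-style pipelines.
#' @param seed integer master seed; per-stream randomness is derived by
#'   stable sub-seeding from (seed, recorder, species), so output is
#'   invariant to iteration order.
#' @param dataset_id dataset identity stamped on emitted detections.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(recorders, species_profiles,
                              start_date, end_date,
                              export_floor = 0.80, seed = 1,
                              dataset_id = "synthetic") {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.null(recorders) || nrow(recorders) == 0) {
    stop("configuration error: empty recorder list")
  }
  stopifnot(export_floor >= 0, export_floor < 1, start_date < end_date,
            length(species_profiles) > 0)
  if (!all(vapply(species_profiles, inherits, TRUE, "species_profile"))) {
    stop("species_profiles must be species_profile objects")
  }
  rec <- recorders
  if (is.null(rec$dataset_id)) rec$dataset_id <- dataset_id
  if (is.null(rec$local_offset_minutes)) rec$local_offset_minutes <- 0L
  span_start <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  span_end <- as.POSIXct(paste(end_date, "00:00:00"), tz = "UTC")
  if (is.null(rec$deploy_start)) rec$deploy_start <- span_start
  if (is.null(rec$deploy_end)) rec$deploy_end <- span_end
  names(species_profiles) <- vapply(species_profiles, `[[`, "", "species")
  structure(list(recorders = rec, species_profiles = species_profiles,
                 start_date = start_date, end_date = end_date,
                 export_floor = export_floor, seed = as.integer(seed),
                 dataset_id = dataset_id),
            class = "simulation_config")
}

# Stable 31-bit sub-seed from the master seed and stream identity, so each
# (recorder, species) stream is reproducible independently of loop order.
stream_seed <- function(seed, recorder_id, species) {
  s <- paste(seed, recorder_id, species, sep = "\r")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483563
  as.integer(h)
}

#' Simulate a detection stream with ground truth
#'
#' Draws per-hour Poisson event counts for the true- and false-positive
#' streams of every (recorder, species) pair, scores each event from the
#' stream's Beta distribution (rounded to the 6-decimal score precision of
#' the canonical CSV), and emits only events scoring at or above the export
#' floor. Every emitted detection carries a ground-truth label.
#'
#' @param config a [simulation_config()].
#' @return list with elements `detections` (canonical detection data.frame),
#'   `truth` (a label data.frame covering every detection, labeler
#'   `"simulator"`), `recorders`, and `effort` (recorded hours per recorder
#'   per local day implied by the deployments).
#' @export
simulate_detections <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rec <- config$recorders
  span_start <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  span_end <- as.POSIXct(paste(config$end_date, "00:00:00"), tz = "UTC")
  pieces <- vector("list", nrow(rec) * length(config$species_profiles))
  k <- 0
  for (ri in seq_len(nrow(rec))) {
    r <- rec[ri, ]
    # local wall-clock hour grid over the deployment, clipped to the span
    utc0 <- max(as.POSIXct(r$deploy_start, tz = "UTC"), span_start)
    utc1 <- min(as.POSIXct(r$deploy_end, tz = "UTC"), span_end)
    if (utc1 <= utc0) next
    hours <- seq(utc0, utc1 - 1, by = 3600)
    local <- hours + 60 * r$local_offset_minutes
    lhour <- as.integer(format(local, "%H", tz = "UTC"))
    ldate <- as.Date(local, tz = "UTC")
    ldoy <- as.integer(format(local, "%j", tz = "UTC"))
    for (prof in config$species_profiles) {
      k <- k + 1
      set.seed(stream_seed(config$seed, r$recorder_id, prof$species))
      mult <- 1
      if (!is.null(prof$habitat_multipliers) &&
          r$habitat %in% names(prof$habitat_multipliers)) {
        mult <- prof$habitat_multipliers[[r$habitat]]
      }
      mod <- diel_weights(prof)[lhour + 1] * mult *
        residency_indicator(prof, ldoy) *
        migration_indicator(prof, r$latitude, ldate, config$start_date)
      n_tp <- stats::rpois(length(hours), prof$tp_rate_per_hour * mod)
      n_fp <- stats::rpois(length(hours), prof$fp_rate_per_hour * mod)
      emit <- function(n_per_hour, params, label) {
        tot <- sum(n_per_hour)
        if (tot == 0) return(NULL)
        hr <- rep(hours, n_per_hour)
        off <- round(stats::runif(tot) * 3599.999, 3)
        sc <- round(stats::rbeta(tot, params[1], params[2]), 6)
        keep <- sc >= config$export_floor & sc > 0
        if (!any(keep)) return(NULL)
        data.frame(hour_start = hr[keep], start_offset_s = off[keep],
                   score = sc[keep], label = label,
                   stringsAsFactors = FALSE)
      }
      ev <- rbind(emit(n_tp, prof$tp_score_params, "true_positive"),
                  emit(n_fp, prof$fp_score_params, "false_positive"))
      if (is.null(ev) || nrow(ev) == 0) next
      ev <- ev[order(ev$hour_start, ev$start_offset_s, ev$label), ]
      pieces[[k]] <- data.frame(
        detection_id = sprintf("%s|%s|%s|%05d", r$dataset_id, r$recorder_id,
                               gsub("\\s+", "_", prof$species),
                               seq_len(nrow(ev))),
        dataset_id = r$dataset_id,
        recorder_id = r$recorder_id,
        species = prof$species,
        score = ev$score,
        timestamp_utc = ev$hour_start + floor(ev$start_offset_s),
        local_offset_minutes = as.integer(r$local_offset_minutes),
        source_file = sprintf("%s_%s.wav", r$recorder_id,
                              format(ev$hour_start, "%Y%m%dT%H0000Z",
                                     tz = "UTC")),
        start_offset_s = ev$start_offset_s,
        end_offset_s = ev$start_offset_s + 3,
        label = ev$label,
        stringsAsFactors = FALSE
      )
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  det <- if (length(pieces)) do.call(rbind, pieces) else {
    empty_detections()
  }
  ord <- order(det$dataset_id, det$recorder_id, det$species,
               det$timestamp_utc, det$detection_id)
  det <- det[ord, , drop = FALSE]
  rownames(det) <- NULL
  if (is.null(det$label)) det$label <- character(0)
  truth <- data.frame(detection_id = det$detection_id, label = det$label,
                      labeler_id = rep("simulator", nrow(det)),
                      stringsAsFactors = FALSE)
  det$label <- NULL
  list(detections = det, truth = truth, recorders = rec,
       effort = simulated_effort(config))
}

empty_detections <- function() {
  data.frame(detection_id = character(0), dataset_id = character(0),
             recorder_id = character(0), species = character(0),
             score = numeric(0),
             timestamp_utc = as.POSIXct(character(0), tz = "UTC"),
             local_offset_minutes = integer(0), source_file = character(0),
             start_offset_s = numeric(0), end_offset_s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Effort table implied by a simulation's deployments
#'
#' @param config a [simulation_config()].
#' @return data.frame of recorded hours per recorder per local day.
#' @export
simulated_effort <- function(config) {
  rec <- config$recorders
  span_start <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  span_end <- as.POSIXct(paste(config$end_date, "00:00:00"), tz = "UTC")
  out <- list()
  for (ri in seq_len(nrow(rec))) {
    r <- rec[ri, ]
    utc0 <- max(as.POSIXct(r$deploy_start, tz = "UTC"), span_start)
    utc1 <- min(as.POSIXct(r$deploy_end, tz = "UTC"), span_end)
    if (utc1 <= utc0) next
    hours <- seq(utc0, utc1 - 1, by = 3600)
    ldate <- as.Date(hours + 60 * r$local_offset_minutes, tz = "UTC")
    tab <- table(ldate)
    out[[length(out) + 1]] <- data.frame(
      recorder_id = r$recorder_id,
      date = as.Date(names(tab)),
      recorded_hours = as.numeric(tab),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Analytic precision of a simulated species at a threshold
#'
#' Among emitted detections scoring at least `threshold`, the expected
#' fraction of true positives is
#' \deqn{p(\theta) = \frac{w_{tp} S_{tp}(\theta)}
#'   {w_{tp} S_{tp}(\theta) + w_{fp} S_{fp}(\theta)}}
#' where the S are Beta survival functions and the w the expected event
#' masses. Because the simulator modulates both streams identically, the
#' masses reduce to the configured rates, so the value is exact for any
#' recorder layout. This is the independent oracle the calibration tests
#' compare against.
#'
#' @param profile a [species_profile()].
#' @param threshold numeric vector of thresholds.
#' @return expected precision at each threshold (`NaN` where no events
#'   survive).
#' @export
precision_oracle <- function(profile, threshold) {
  stp <- stats::pbeta(threshold, profile$tp_score_params[1],
                      profile$tp_score_params[2], lower.tail = FALSE)
  sfp <- stats::pbeta(threshold, profile$fp_score_params[1],
                      profile$fp_score_params[2], lower.tail = FALSE)
  wtp <- profile$tp_rate_per_hour * stp
  wfp <- profile$fp_rate_per_hour * sfp
  wtp / (wtp + wfp)
}

#' Analytic optimal threshold of a simulated species
#'
#' The smallest grid threshold whose analytic precision reaches the target,
#' or `NA` if none does.
#'
#' @param profile a [species_profile()].
#' @param grid threshold grid.
#' @param target target precision.
#' @return a grid value or `NA_real_`.
#' @export
analytic_optimum <- function(profile, grid = calibration_grid(),
                             target = 0.90) {
  p <- precision_oracle(profile, grid)
  ok <- which(!is.nan(p) & p >= target)
  if (length(ok)) grid[min(ok)] else NA_real_
}
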