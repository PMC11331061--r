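# Biodiversity summaries computed from the trusted (post-filter) detections:
# diel activity profiles, habitat-stratified daily vocalization rates,
# migration fronts from detection latitudes, and clustered species-by-time
# occurrence matrices. All are deterministic functions of their inputs, and
# each summary's marginal conserves the species' trusted detection total.

#' Diel vocal activity profile
#'
#' Counts a species' detections per local hour of day (0--23). With an effort
#' vector, each hour's count is divided by the recorded hours at that hour of
#' day before normalization, turning the profile into a rate profile. The
#' normalized profile sums to 1 whenever the species has any detections.
#'
#' @param detections trusted detections carrying `local_hour` (see
#'   [join_metadata()]).
#' @param species species name (matched after whitespace/case
#'   normalization).
#' @param effort_by_hour optional numeric vector of 24 recorded-hour totals
#'   by hour of day.
#' @return object of class `"diel_profile"`: `species`, `counts` (24),
#'   `normalized` (24, summing to 1, or all `NA` for an empty profile),
#'   `effort_corrected`.
#' @export
diel_profile <- function(detections, species, effort_by_hour = NULL) {
  rows <- species_key(detections$species) == species_key(species)
  hours <- detections$local_hour[rows]
  counts <- tabulate(hours + 1, nbins = 24)
  x <- counts
  if (!is.null(effort_by_hour)) {
    stopifnot(length(effort_by_hour) == 24)
    if (any(counts > 0 & effort_by_hour <= 0)) {
      stop("detections at hour(s) with no recorded effort")
    }
    x <- ifelse(effort_by_hour > 0, counts / effort_by_hour, 0)
  }
  normalized <- if (sum(x) > 0) x / sum(x) else rep(NA_real_, 24)
  structure(list(species = species, counts = counts,
                 normalized = normalized, total = sum(counts),
                 effort_corrected = !is.null(effort_by_hour),
                 empty = sum(counts) == 0),
            class = "diel_profile")
}

#' Circular mean hour of a diel profile
#'
#' Treats the 24 hour bins (midpoints h + 0.5) as angles on the 24 h circle
#' and returns the circular mean in `[0, 24)`.
#'
#' @param profile a [diel_profile()].
#' @return mean hour, or `NA` for an empty profile.
#' @export
circular_mean_hour <- function(profile) {
  if (profile$empty) return(NA_real_)
  ang <- ((0:23) + 0.5) / 24 * 2 * pi
  w <- profile$normalized
  m <- atan2(sum(w * sin(ang)), sum(w * cos(ang)))
  (m / (2 * pi) * 24) %% 24
}

#' @export
print.diel_profile <- function(x, ...) {
  cat(sprintf("Diel profile of %s: %d detections%s%s\n", x$species, x$total,
              if (x$effort_corrected) " (effort-corrected)" else "",
              if (x$empty) " [empty]" else
                sprintf(", circular mean hour %.1f",
                        circular_mean_hour(x))))
  invisible(x)
}

#' @export
plot.diel_profile <- function(x, ...) {
  graphics::barplot(x$normalized, names.arg = 0:23,
                    xlab = "local hour", ylab = "share of detections",
                    main = x$species, ...)
  invisible(x)
}

#' Habitat-stratified daily vocalization rates
#'
#' The daily rate of a (recorder, day) is the species' detection count
#' divided by the recorded hours of that day; recorder-days with effort and
#' zero detections count as rate 0. The habitat mean averages daily rates
#' over all recorder-days in that habitat, and the display cap is the
#' empirical 90th percentile of the pooled daily rates (stored with the
#' summary so rate plots are reproducible).
#'
#' @param detections trusted detections carrying `local_date`.
#' @param species species name.
#' @param recorders recorder data.frame (habitat lookup).
#' @param effort effort data.frame (`recorder_id`, `date`, `recorded_hours`).
#' @return object of class `"habitat_rates"`: per-habitat data.frame
#'   (`habitat`, `n_recorder_days`, `mean_daily_rate`) plus `cap_p90` and the
#'   pooled `daily_rates`.
#' @export
habitat_rates <- function(detections, species, recorders, effort) {
  rows <- species_key(detections$species) == species_key(species)
  det <- detections[rows, , drop = FALSE]
  eff <- effort[effort$recorded_hours > 0, , drop = FALSE]
  ekey <- paste(eff$recorder_id, eff$date, sep = "\r")
  dkey <- paste(det$recorder_id, det$local_date, sep = "\r")
  missing_eff <- !dkey %in% ekey
  if (any(missing_eff)) {
    stop("detections on recorder-day(s) without effort: ",
         paste(utils::head(unique(gsub("\r", " ", dkey[missing_eff])), 5),
               collapse = ", "))
  }
  counts <- table(factor(dkey, levels = ekey))
  rate <- as.numeric(counts) / eff$recorded_hours
  meta <- recorders[!duplicated(recorders$recorder_id), ]
  habitat <- meta$habitat[match(eff$recorder_id, meta$recorder_id)]
  if (anyNA(habitat)) stop("effort for recorder(s) with unknown habitat")
  per <- lapply(split(rate, habitat), function(r) {
    data.frame(n_recorder_days = length(r), mean_daily_rate = mean(r))
  })
  tab <- do.call(rbind, per)
  tab <- data.frame(habitat = rownames(tab), tab, stringsAsFactors = FALSE,
                    row.names = NULL)
  cap <- if (length(rate)) unname(stats::quantile(rate, 0.90)) else 0
  structure(list(species = species, per_habitat = tab, cap_p90 = cap,
                 daily_rates = data.frame(recorder_id = eff$recorder_id,
                                          date = eff$date, habitat = habitat,
                                          rate = rate)),
            class = "habitat_rates")
}

#' @export
print.habitat_rates <- function(x, ...) {
  cat(sprintf("Daily vocalization rates of %s (cap p90 = %.3f/h):\n",
              x$species, x$cap_p90))
  print(x$per_habitat, row.names = FALSE)
  invisible(x)
}

#' Migration front from detection latitudes
#'
#' Bins a species' detections into consecutive windows of `bin_width_days`
#' (anchored at its first detection date) and summarizes the latitude
#' distribution per bin: detection count, median, and 25th/75th percentiles.
#' Bins without detections carry `NA` summaries. The least-squares slope of
#' median latitude against time is available via [migration_slope()] as a
#' diagnostic of front speed.
#'
#' @param detections trusted detections carrying `latitude` and `local_date`.
#' @param species species name.
#' @param bin_width_days time bin width in days.
#' @return object of class `"migration_track"`: data.frame `bins` with
#'   `bin_start`, `n`, `lat_median`, `lat_q25`, `lat_q75`.
#' @export
migration_front <- function(detections, species, bin_width_days = 7) {
  if (bin_width_days < 1) stop("bin_width_days must be >= 1")
  rows <- species_key(detections$species) == species_key(species)
  det <- detections[rows, , drop = FALSE]
  if (nrow(det) == 0) {
    bins <- data.frame(bin_start = as.Date(character(0)), n = integer(0),
                       lat_median = numeric(0), lat_q25 = numeric(0),
                       lat_q75 = numeric(0))
    return(structure(list(species = species, bins = bins,
                          bin_width_days = bin_width_days),
                     class = "migration_track"))
  }
  d0 <- min(det$local_date)
  bin <- as.integer(as.numeric(det$local_date - d0) %/% bin_width_days)
  all_bins <- 0:max(bin)
  summ <- lapply(all_bins, function(b) {
    lat <- det$latitude[bin == b]
    if (length(lat) == 0) {
      data.frame(bin_start = d0 + b * bin_width_days, n = 0L,
                 lat_median = NA_real_, lat_q25 = NA_real_,
                 lat_q75 = NA_real_)
    } else {
      q <- stats::quantile(lat, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(bin_start = d0 + b * bin_width_days, n = length(lat),
                 lat_median = q[2], lat_q25 = q[1], lat_q75 = q[3])
    }
  })
  structure(list(species = species, bins = do.call(rbind, summ),
                 bin_width_days = bin_width_days),
            class = "migration_track")
}

#' Least-squares speed of a migration front
#'
#' @param track a [migration_front()] result.
#' @return slope of median latitude over time, in degrees per week.
#' @export
migration_slope <- function(track) {
  b <- track$bins[track$bins$n > 0, ]
  if (nrow(b) < 2) return(NA_real_)
  weeks <- as.numeric(b$bin_start - b$bin_start[1]) / 7
  unname(stats::coef(stats::lm(b$lat_median ~ weeks))[2])
}

#' @export
print.migration_track <- function(x, ...) {
  cat(sprintf("Migration front of %s: %d bins of %d days, slope %.2f deg/week\n",
              x$species, nrow(x$bins), x$bin_width_days,
              migration_slope(x)))
  invisible(x)
}

#' Species-by-time occurrence matrix
#'
#' Bins all trusted detections into consecutive windows of `bin_width_days`
#' spanning the first to last detection date, one row per species. In
#' `count` mode, row sums equal the per-species trusted detection totals; in
#' `presence` mode cells are 0/1 indicators.
#'
#' @param detections trusted detections carrying `local_date`.
#' @param bin_width_days time bin width in days.
#' @param mode `"count"` or `"presence"`.
#' @return object of class `"occurrence_matrix"`: `values` (species x bin
#'   matrix, rows in alphabetical species order), `bin_starts`, `mode`,
#'   `bin_width_days`, and `row_order` (a permutation, identity until
#'   [cluster_species_order()] is applied).
#' @export
occurrence_matrix <- function(detections, bin_width_days = 7,
                              mode = c("count", "presence")) {
  mode <- match.arg(mode)
  if (bin_width_days < 1) stop("bin_width_days must be >= 1")
  if (nrow(detections) == 0) stop("no detections")
  d0 <- min(detections$local_date)
  bin <- as.integer(as.numeric(detections$local_date - d0) %/%
                      bin_width_days)
  nbin <- max(bin) + 1
  species <- sort(unique(detections$species))
  m <- matrix(0L, nrow = length(species), ncol = nbin,
              dimnames = list(species,
                              as.character(d0 + (0:(nbin - 1)) *
                                             bin_width_days)))
  tab <- table(detections$species, bin)
  m[rownames(tab), as.integer(colnames(tab)) + 1] <- as.integer(tab)
  if (mode == "presence") m <- (m >= 1) * 1L
  structure(list(values = m,
                 bin_starts = d0 + (0:(nbin - 1)) * bin_width_days,
                 bin_width_days = bin_width_days, mode = mode,
                 row_order = seq_along(species)),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("Occurrence matrix (%s): %d species x %d bins of %d days\n",
              x$mode, nrow(x$values), ncol(x$values), x$bin_width_days))
  invisible(x)
}

#' @export
plot.occurrence_matrix <- function(x, ...) {
  m <- x$values[x$row_order, , drop = FALSE]
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  axes = FALSE, xlab = "time bin", ylab = "", ...)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.6)
  invisible(x)
}

# Jaccard distance between binary rows; two all-empty rows are identical
# (distance 0) rather than undefined.
jaccard_distance <- function(m) {
  m <- (m > 0) * 1
  inter <- m %*% t(m)
  size <- rowSums(m)
  uni <- outer(size, size, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  stats::as.dist(d)
}

#' Order species by clustering their occurrence rows
#'
#' Agglomerative hierarchical clustering (average linkage) of the presence
#' rows under Jaccard distance; the returned order is the dendrogram leaf
#' order. Rows are pre-sorted alphabetically before clustering, which makes
#' tie-breaking deterministic and the result invariant to the input row
#' order. A single species yields the identity order.
#'
#' @param matrix an [occurrence_matrix()].
#' @return the `occurrence_matrix` with `row_order` set (a permutation of
#'   row indices of `values`).
#' @export
cluster_species_order <- function(matrix) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  m <- matrix$values
  if (nrow(m) < 2) {
    matrix$row_order <- seq_len(nrow(m))
    return(matrix)
  }
  ord_alpha <- order(rownames(m))
  mm <- m[ord_alpha, , drop = FALSE]
  hc <- stats::hclust(jaccard_distance(mm), method = "average")
  matrix$row_order <- ord_alpha[hc$order]
  matrix
}
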