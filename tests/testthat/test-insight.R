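enriched <- function(det, rec = NULL) {
  join_metadata(det, rec %||% toy_recorders())
}

test_that("diel profiles count detections by local hour and normalize", {
  t0 <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")
  det <- toy_detections(4)
  det$timestamp_utc <- t0 + c(5, 5, 6, 18) * 3600 + 30
  pr <- diel_profile(enriched(det), "Sp A")
  want <- rep(0, 24)
  want[c(6, 7, 19)] <- c(0.5, 0.25, 0.25)
  expect_equal(pr$normalized, want)
  expect_equal(sum(pr$normalized), 1)
  expect_equal(sum(pr$counts), nrow(det))  # conservation
})

test_that("uniform effort leaves a uniform profile unchanged", {
  t0 <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")
  det <- toy_detections(24)
  det$timestamp_utc <- t0 + (0:23) * 3600
  pr <- diel_profile(enriched(det), "Sp A", effort_by_hour = rep(1, 24))
  expect_equal(pr$normalized, rep(1 / 24, 24))
  expect_true(pr$effort_corrected)
})

test_that("absent species yield an empty flagged profile, not an error", {
  det <- toy_detections(3)
  pr <- diel_profile(enriched(det), "No Such Bird")
  expect_true(pr$empty)
  expect_true(all(is.na(pr$normalized)))
  expect_true(is.na(circular_mean_hour(pr)))
})

test_that("diel circular mean recovers the generating kernel mean", {
  kern <- data.frame(mean_hour = 6, concentration = 4, weight = 1)
  prof <- species_profile("Dawn Bird", tp_rate_per_hour = 10,
                          diel_kernel = kern)
  cfg <- one_stream_config(prof, hours = 1200, export_floor = 0, seed = 12)
  sim <- simulate_detections(cfg)
  expect_gte(nrow(sim$detections), 5000)
  pr <- diel_profile(enriched(sim$detections, cfg$recorders), "Dawn Bird")
  m <- circular_mean_hour(pr)
  expect_lt(min(abs(m - 6), 24 - abs(m - 6)), 1)
})

test_that("daily rates divide counts by recorded hours", {
  det <- toy_detections(4, t0 = as.POSIXct("2022-06-01 08:00:00",
                                           tz = "UTC"))
  eff <- data.frame(recorder_id = "R1", date = as.Date("2022-06-01"),
                    recorded_hours = 8)
  h <- habitat_rates(enriched(det), "Sp A", toy_recorders(), eff)
  expect_equal(h$per_habitat$mean_daily_rate, 0.5)
  expect_equal(h$per_habitat$n_recorder_days, 1)
})

test_that("zero detections give zero means and cap", {
  det <- toy_detections(1)[0, ]
  det$local_date <- as.Date(character(0))
  det$habitat <- character(0)
  eff <- data.frame(recorder_id = "R1",
                    date = as.Date("2022-06-01") + 0:4,
                    recorded_hours = 10)
  h <- habitat_rates(det, "Sp A", toy_recorders(), eff)
  expect_equal(h$per_habitat$mean_daily_rate, 0)
  expect_equal(h$cap_p90, 0)
})

test_that("detections without matching effort are an error naming the pair", {
  det <- toy_detections(2)
  eff <- data.frame(recorder_id = "R1", date = as.Date("2021-01-01"),
                    recorded_hours = 5)
  expect_error(habitat_rates(enriched(det), "Sp A", toy_recorders(), eff),
               "R1 2022-06-01")
})

test_that("habitat mean rates recover the simulated multiplier ratio", {
  cfg <- scenario_preset("habitat_gradient", seed = 23)
  sim <- simulate_detections(cfg)
  enr <- join_metadata(sim$detections, cfg$recorders)
  h <- habitat_rates(enr, "Yellow-throated Toucan", cfg$recorders,
                     sim$effort)
  tab <- h$per_habitat
  expect_gte(min(tab$n_recorder_days), 100)
  ratio <- tab$mean_daily_rate[tab$habitat == "old_growth"] /
    tab$mean_daily_rate[tab$habitat == "pasture"]
  expect_lt(abs(ratio - 4) / 4, 0.2)
  # the 90th percentile display cap is stored with the summary
  expect_equal(h$cap_p90, unname(quantile(h$daily_rates$rate, 0.9)))
})

test_that("migration summaries are per-bin latitude quantiles", {
  det <- toy_detections(10)
  det$timestamp_utc <- as.POSIXct("2022-04-01", tz = "UTC") +
    (0:9) * 86400 * 2
  tr <- migration_front(enriched(det, toy_recorders(latitude = 60)), "Sp A")
  nonempty <- tr$bins[tr$bins$n > 0, ]
  expect_true(all(nonempty$lat_median == 60))
  expect_true(all(nonempty$lat_q25 <= nonempty$lat_median &
                    nonempty$lat_median <= nonempty$lat_q75))
  expect_equal(sum(tr$bins$n), 10)  # conservation

  # single detection in a bin: median = lower = upper
  one <- migration_front(enriched(det[1, ], toy_recorders(latitude = 42.5)),
                         "Sp A")
  expect_equal(one$bins$lat_median, 42.5)
  expect_equal(one$bins$lat_q25, 42.5)
  expect_equal(one$bins$lat_q75, 42.5)
})

test_that("migration slope recovers the simulated northward speed", {
  cfg <- scenario_preset("migration_north", seed = 29)
  sim <- simulate_detections(cfg)
  enr <- join_metadata(sim$detections, cfg$recorders)
  tr <- migration_front(enr, "Willow Warbler")
  expect_lt(abs(migration_slope(tr) - 1.2) / 1.2, 0.15)
})

test_that("occurrence matrices bin detections and conserve counts", {
  det <- toy_detections(2)
  det$timestamp_utc <- as.POSIXct(c("2022-06-01 08:00:00",
                                    "2022-06-10 08:00:00"), tz = "UTC")
  m <- occurrence_matrix(enriched(det), bin_width_days = 7,
                         mode = "presence")
  expect_equal(unname(m$values["Sp A", ]), c(1, 1))

  set.seed(33)
  det2 <- rbind(toy_detections(40, species = "Sp A", id_prefix = "a"),
                toy_detections(25, species = "Sp B", id_prefix = "b"))
  det2$timestamp_utc <- as.POSIXct("2022-05-01", tz = "UTC") +
    runif(65, 0, 90 * 86400)
  mc <- occurrence_matrix(enriched(det2), mode = "count")
  expect_equal(unname(rowSums(mc$values)), c(40, 25))
  expect_error(occurrence_matrix(enriched(det2), bin_width_days = 0),
               "bin_width_days")
})

test_that("residency windows confine presence to overlapping bins", {
  cfg <- scenario_preset("seasonal_taiwan", seed = 41)
  sim <- simulate_detections(cfg)
  enr <- join_metadata(sim$detections, cfg$recorders)
  m <- occurrence_matrix(enr, mode = "presence")
  breeder <- m$values["Large Hawk-Cuckoo", ]
  doy <- as.integer(format(m$bin_starts, "%j"))
  # presence only in bins overlapping days 91..240
  outside <- doy + 6 < 91 | doy > 240
  expect_true(all(breeder[outside] == 0))
  expect_gt(sum(breeder), 0)
  # wrapped winter residency: absent in midsummer bins
  winterer <- m$values["Yellow-browed Warbler", ]
  midsummer <- doy > 96 & doy + 6 < 274
  expect_true(all(winterer[midsummer] == 0))
})

test_that("identical occurrence rows cluster adjacently", {
  m <- structure(list(
    values = rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1),
                   C = c(1, 1, 0, 0)),
    bin_starts = as.Date("2022-01-01") + c(0, 7, 14, 21),
    bin_width_days = 7, mode = "presence", row_order = 1:3),
    class = "occurrence_matrix")
  cl <- cluster_species_order(m)
  ord <- rownames(m$values)[cl$row_order]
  expect_true(abs(which(ord == "A") - which(ord == "C")) == 1)
  expect_true(all(sort(cl$row_order) == 1:3))  # permutation contract
})

test_that("clustering order is invariant to input row order", {
  set.seed(51)
  vals <- matrix(rbinom(8 * 12, 1, 0.4), nrow = 8,
                 dimnames = list(paste("Sp", 1:8), NULL))
  make <- function(v) structure(list(
    values = v, bin_starts = as.Date("2022-01-01") + 7 * (0:11),
    bin_width_days = 7, mode = "presence", row_order = seq_len(nrow(v))),
    class = "occurrence_matrix")
  ref <- cluster_species_order(make(vals))
  ref_species <- rownames(vals)[ref$row_order]
  for (i in 1:100) {
    perm <- sample(nrow(vals))
    shuffled <- cluster_species_order(make(vals[perm, , drop = FALSE]))
    got <- rownames(vals)[perm][shuffled$row_order]
    expect_equal(got, ref_species)
  }
})

test_that("single-species clustering is the identity, no error", {
  det <- toy_detections(5)
  m <- occurrence_matrix(enriched(det))
  expect_equal(cluster_species_order(m)$row_order, 1L)
})

test_that("jaccard distances agree with vegan on non-degenerate rows", {
  skip_if_not_installed("vegan")
  set.seed(61)
  m <- matrix(rbinom(6 * 10, 1, 0.5), nrow = 6)
  m[1, ] <- 1  # avoid all-zero rows, where conventions differ
  d1 <- pamcal:::jaccard_distance(m)
  d2 <- vegan::vegdist(m, method = "jaccard", binary = TRUE)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})
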