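test_that("the raw-count filter is strictly 'over min_count'", {
  det <- rbind(toy_detections(51, species = "A", id_prefix = "a"),
               toy_detections(50, species = "B", id_prefix = "b"))
  f <- filter_min_raw_detections(det, 50)
  expect_setequal(unique(f$detections$species), "A")
  expect_equal(f$report$kept[f$report$species == "A"], TRUE)
  expect_equal(f$report$kept[f$report$species == "B"], FALSE)
})

test_that("toy counts {A:60, B:50, C:3} keep only A", {
  det <- rbind(toy_detections(60, species = "A", id_prefix = "a"),
               toy_detections(50, species = "B", id_prefix = "b"),
               toy_detections(3, species = "C", id_prefix = "c"))
  f <- filter_min_raw_detections(det, 50)
  expect_setequal(unique(f$detections$species), "A")
  expect_equal(sum(f$report$kept), 1)
  expect_equal(sum(!f$report$kept), 2)
  expect_equal(nrow(f$report), 3)  # kept + dropped = all species
})

test_that("the raw-count filter works per dataset", {
  det <- rbind(toy_detections(60, species = "A", dataset_id = "d1",
                              id_prefix = "a1"),
               toy_detections(10, species = "A", dataset_id = "d2",
                              id_prefix = "a2"))
  f <- filter_min_raw_detections(det, 50)
  expect_equal(unique(f$detections$dataset_id), "d1")
})

make_calibration <- function(det, chosen = 0.85, reliable = TRUE,
                             meets = TRUE) {
  # fabricate a minimal calibration object for filter semantics tests
  structure(list(
    results = data.frame(dataset_id = unique(det$dataset_id),
                         species = unique(det$species),
                         chosen_threshold = ifelse(reliable, chosen,
                                                   NA_real_),
                         reliable = reliable,
                         meets_min_detections = meets,
                         stringsAsFactors = FALSE),
    grid = calibration_grid(), target = 0.9, min_labeled = 5,
    min_detections_post = 20, conf_level = 0.95),
    class = "calibration")
}

test_that("score exactly at the calibrated threshold is kept", {
  det <- toy_detections(2, scores = c(0.84, 0.85))
  cal <- make_calibration(det, chosen = 0.85)
  f <- apply_calibrated_thresholds(det, cal)
  expect_equal(f$detections$score, 0.85)
  expect_equal(f$drops$reason, "below_threshold")
})

test_that("unreliable species lose all detections", {
  det <- toy_detections(10, scores = rep(0.99, 10))
  cal <- make_calibration(det, reliable = FALSE, meets = FALSE)
  f <- apply_calibrated_thresholds(det, cal)
  expect_equal(nrow(f$detections), 0)
  expect_true(all(f$drops$reason == "unreliable"))
})

test_that("species failing the surviving-count gate lose all detections", {
  det <- toy_detections(10, scores = rep(0.99, 10))
  cal <- make_calibration(det, meets = FALSE)
  f <- apply_calibrated_thresholds(det, cal)
  expect_equal(nrow(f$detections), 0)
  expect_true(all(f$drops$reason == "too_few_surviving"))
})

test_that("missing calibration errors unless permissive", {
  det <- rbind(toy_detections(2, species = "A", id_prefix = "a"),
               toy_detections(2, species = "B", id_prefix = "b"))
  cal <- make_calibration(det[det$species == "A", ])
  expect_error(apply_calibrated_thresholds(det, cal), "no calibration")
  f <- apply_calibrated_thresholds(det, cal, permissive = TRUE)
  expect_true(all(f$drops$reason[f$drops$detection_id %in%
                                   det$detection_id[det$species == "B"]] ==
                    "no_calibration"))
})

test_that("allowlist filtering drops exactly the disallowed detections", {
  det <- rbind(toy_detections(5, species = "A", recorder_id = "R1",
                              id_prefix = "a"),
               toy_detections(5, species = "B", recorder_id = "R1",
                              id_prefix = "b"),
               toy_detections(5, species = "B", recorder_id = "R2",
                              id_prefix = "c"))
  allow <- data.frame(recorder_id = c("R1", "R2", "R2"),
                      species = c("A", "A", "B"))
  f <- species_allowlist_filter(det, allow)
  expect_equal(nrow(f$drops), 5)  # B at R1 only
  expect_true(all(f$drops$detection_id %in%
                    det$detection_id[det$species == "B" &
                                       det$recorder_id == "R1"]))

  # empty allowlist under permissive mode is a vacuous filter
  f2 <- species_allowlist_filter(det, allow[0, ], permissive = TRUE)
  expect_equal(nrow(f2$detections), nrow(det))
  expect_error(species_allowlist_filter(det, allow[0, ]), "missing recorder")

  # allowing every observed species is the identity
  allow_all <- unique(det[, c("recorder_id", "species")])
  f3 <- species_allowlist_filter(det, allow_all)
  expect_equal(f3$detections, det)
})

test_that("filters are idempotent", {
  set.seed(8)
  det <- rbind(toy_detections(60, species = "A", id_prefix = "a"),
               toy_detections(40, species = "B", id_prefix = "b"))
  f1 <- filter_min_raw_detections(det, 50)
  f2 <- filter_min_raw_detections(f1$detections, 50)
  expect_equal(f1$detections, f2$detections)

  cal <- make_calibration(toy_detections(1, species = "A"), chosen = 0.9)
  t1 <- apply_calibrated_thresholds(f1$detections, cal)
  t2 <- apply_calibrated_thresholds(t1$detections, cal)
  expect_equal(t1$detections, t2$detections)

  allow <- data.frame(recorder_id = "R1", species = "A")
  a1 <- species_allowlist_filter(det, allow)
  a2 <- species_allowlist_filter(a1$detections, allow)
  expect_equal(a1$detections, a2$detections)
})

test_that("recorder-uniform allowlists commute with the raw-count filter", {
  # when an allowlist bans a species everywhere (or nowhere) in a dataset,
  # the two filters reduce to intersecting row sets in either order
  set.seed(17)
  for (i in 1:10) {
    species <- paste("Sp", 1:4)
    det <- do.call(rbind, lapply(seq_along(species), function(k) {
      toy_detections(sample(c(10, 40, 60, 80), 1), species = species[k],
                     id_prefix = paste0("p", k))
    }))
    allowed <- sample(species, 2)
    allow <- data.frame(recorder_id = "R1", species = allowed)
    ab <- filter_min_raw_detections(
      species_allowlist_filter(det, allow)$detections, 50)$detections
    ba <- species_allowlist_filter(
      filter_min_raw_detections(det, 50)$detections, allow)$detections
    expect_equal(ab, ba)
  }
})

test_that("every dropped detection appears once with a reason code", {
  det <- rbind(toy_detections(60, species = "A",
                              scores = round(runif(60, 0.8, 1), 6),
                              id_prefix = "a"),
               toy_detections(30, species = "B", id_prefix = "b"))
  f1 <- filter_min_raw_detections(det, 50)
  dropped_raw <- setdiff(det$detection_id, f1$detections$detection_id)
  cal <- make_calibration(f1$detections, chosen = 0.9)
  f2 <- apply_calibrated_thresholds(f1$detections, cal)
  all_dropped <- c(dropped_raw, f2$drops$detection_id)
  expect_false(anyDuplicated(all_dropped) > 0)
  expect_setequal(c(all_dropped, f2$detections$detection_id),
                  det$detection_id)
  expect_true(all(nzchar(f2$drops$reason)))
})
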