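# Ready-made simulation scenarios. Each preset is a fixed, fully
# parameterized study condition; tests and the acceptance script treat these
# parameters as ground truth, so they are not knobs.

PRESET_NAMES <- c("diel_triptych", "migration_north", "seasonal_taiwan",
                  "habitat_gradient", "precision_ladder")

recorder_row <- function(recorder_id, dataset_id, latitude, longitude,
                         habitat, local_offset_minutes = 0L) {
  data.frame(recorder_id = recorder_id, dataset_id = dataset_id,
             latitude = latitude, longitude = longitude, habitat = habitat,
             local_offset_minutes = as.integer(local_offset_minutes),
             stringsAsFactors = FALSE)
}

# Scale tp/fp rates so a species emits about `emitted_per_hour` detections
# above the floor while keeping the tp:fp event-mass ratio `r` that fixes its
# precision curve.
ladder_rates <- function(r, tp_params, fp_params, emitted_per_hour = 7,
                         floor = 0.80) {
  stp <- stats::pbeta(floor, tp_params[1], tp_params[2], lower.tail = FALSE)
  sfp <- stats::pbeta(floor, fp_params[1], fp_params[2], lower.tail = FALSE)
  fp_rate <- emitted_per_hour / (r * stp + sfp)
  c(tp = r * fp_rate, fp = fp_rate)
}

ladder_species <- function() {
  flat <- function(name, p80) {
    # identical score distributions in both streams make p(theta) exactly
    # constant at the event-mass ratio
    rr <- ladder_rates(p80 / (1 - p80), c(6, 1.2), c(6, 1.2))
    species_profile(name, tp_rate_per_hour = rr["tp"],
                    fp_rate_per_hour = rr["fp"],
                    tp_score_params = c(6, 1.2), fp_score_params = c(6, 1.2))
  }
  cross <- function(name, r, tp_params, fp_params) {
    rr <- ladder_rates(r, tp_params, fp_params)
    species_profile(name, tp_rate_per_hour = rr["tp"],
                    fp_rate_per_hour = rr["fp"],
                    tp_score_params = tp_params, fp_score_params = fp_params)
  }
  list(
    flat("ladder_p05", 0.05),
    flat("ladder_p20", 0.20),
    flat("ladder_p35", 0.35),
    flat("ladder_p50", 0.50),
    # steep interior crossings: concentrated false-positive score
    # distributions collapse just above the crossing threshold
    cross("ladder_cross85", 0.9, c(10, 1), c(369, 81)),
    cross("ladder_cross89", 1.5, c(12, 1), c(250, 40)),
    cross("ladder_nearfloor", 5.0, c(12, 1), c(45, 13)),
    flat("ladder_p95", 0.95),
    flat("ladder_p975", 0.975),
    flat("ladder_p995", 0.995)
  )
}

#' Named simulation scenarios
#'
#' * `diel_triptych`: one Amazonian recorder, three species singing at dawn
#'   (06:00), midday (12:00) and dusk (18:00) (von Mises concentration 4).
#' * `migration_north`: a transect of recorders from 54 to 75 degrees N and a
#'   migrant whose presence band (halfwidth 2.5 deg) starts at 56 N and moves
#'   north at 1.2 deg/week through spring.
#' * `seasonal_taiwan`: one subtropical recorder over two full years with a
#'   summer breeder (days 91--240), a wintering visitor (days 274--90,
#'   wrapping the year end) and a year-round resident.
#' * `habitat_gradient`: six recorders across old-growth forest, secondary
#'   forest and pasture with rate multipliers 2.0 / 1.0 / 0.5.
#' * `precision_ladder`: ten species on one recorder whose true precision at
#'   the 0.80 export floor spans 0.05 to 0.995, including two species whose
#'   precision curve crosses 0.90 at an interior grid threshold (0.85 and
#'   0.89) and one that qualifies at the floor itself; [precision_oracle()]
#'   gives every curve in closed form.
#'
#' @param name one of `"diel_triptych"`, `"migration_north"`,
#'   `"seasonal_taiwan"`, `"habitat_gradient"`, `"precision_ladder"`.
#' @param seed master seed stored in the returned config.
#' @return a [simulation_config()].
#' @export
scenario_preset <- function(name, seed = 1) {
  if (!is.character(name) || length(name) != 1 || !name %in% PRESET_NAMES) {
    stop("unknown preset; available: ", paste(PRESET_NAMES, collapse = ", "))
  }
  switch(
    name,
    diel_triptych = {
      rec <- recorder_row("BR01", "brazil_synth", -3.2, -52.5, "terra_firme")
      kern <- function(h) data.frame(mean_hour = h, concentration = 4,
                                     weight = 1)
      prof <- list(
        species_profile("Pale-breasted Spinetail", 8, 0,
                        tp_score_params = c(5, 1), diel_kernel = kern(6)),
        species_profile("Blue-black Grassquit", 8, 0,
                        tp_score_params = c(5, 1), diel_kernel = kern(12)),
        species_profile("Great Kiskadee", 8, 0,
                        tp_score_params = c(5, 1), diel_kernel = kern(18))
      )
      simulation_config(rec, prof, "2022-09-01", "2022-10-16",
                        seed = seed, dataset_id = "brazil_synth")
    },
    migration_north = {
      lats <- 54:75
      rec <- recorder_row(sprintf("NO%02d", seq_along(lats)), "norway_synth",
                          lats, 10.5, "boreal_forest")
      prof <- list(
        species_profile("Willow Warbler", 2, 0, tp_score_params = c(5, 1),
                        migration = c(56, 1.2, 2.5))
      )
      simulation_config(rec, prof, "2022-04-01", "2022-07-01",
                        seed = seed, dataset_id = "norway_synth")
    },
    seasonal_taiwan = {
      rec <- recorder_row("TW01", "taiwan_synth", 23.8, 121.2,
                          "montane_forest", 480L)
      prof <- list(
        species_profile("Large Hawk-Cuckoo", 1.2, 0,
                        tp_score_params = c(5, 1),
                        residency_window = c(91, 240)),
        species_profile("Yellow-browed Warbler", 1.0, 0,
                        tp_score_params = c(5, 1),
                        residency_window = c(274, 90)),
        species_profile("Taiwan Bamboo-Partridge", 0.8, 0,
                        tp_score_params = c(5, 1),
                        diel_kernel = data.frame(mean_hour = 6,
                                                 concentration = 2,
                                                 weight = 1))
      )
      simulation_config(rec, prof, "2021-01-01", "2022-12-31",
                        seed = seed, dataset_id = "taiwan_synth")
    },
    habitat_gradient = {
      habs <- rep(c("old_growth", "secondary_forest", "pasture"), each = 2)
      rec <- recorder_row(sprintf("CR%02d", 1:6), "costarica_synth",
                          8.5 + (1:6) / 100, -83.3, habs)
      prof <- list(
        species_profile("Yellow-throated Toucan", 1.5, 0,
                        tp_score_params = c(5, 1),
                        habitat_multipliers = c(old_growth = 2.0,
                                                secondary_forest = 1.0,
                                                pasture = 0.5))
      )
      simulation_config(rec, prof, "2022-01-01", "2022-03-02",
                        seed = seed, dataset_id = "costarica_synth")
    },
    precision_ladder = {
      rec <- recorder_row("LD01", "ladder_synth", 45.0, 5.0, "forest")
      simulation_config(rec, ladder_species(), "2022-05-01", "2022-06-05",
                        seed = seed, dataset_id = "ladder_synth")
    }
  )
}
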