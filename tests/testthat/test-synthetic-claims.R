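test_that("cohort generation is deterministic and honours the empty case", {
  expect_equal(nrow(simulateCohort(cohortConfig(n_patients = 0))), 0L)
  c1 <- simulateCohort(cohortConfig(n_patients = 200, seed = 7))
  c2 <- simulateCohort(cohortConfig(n_patients = 200, seed = 7))
  expect_identical(c1, c2)
  c3 <- simulateCohort(cohortConfig(n_patients = 200, seed = 8))
  expect_false(identical(c1, c3))
  expect_true(all(c1$age_at_death >= 1 & c1$age_at_death <= 110))
  expect_true(all(c1$charlson_score >= 0))
  expect_true(all(is.na(c1$deprivation_quintile) |
                    c1$deprivation_quintile %in% 1:5))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohortConfig(female_fraction = 1.2), "configuration error")
  expect_error(cohortConfig(zero_spend_fraction = -0.1), "configuration error")
  expect_error(cohortConfig(deprivation_quintile_weights = rep(0.25, 4)),
               "configuration error")
  expect_error(cohortConfig(n_patients = -1), "configuration error")
})

test_that("cohort marginals are recovered within 3 SEs at n = 10,000", {
  co <- simulateCohort(cohortConfig(n_patients = 10000, seed = 20))
  se <- function(p) sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(co$sex == "female") - 0.506), 3 * se(0.506))
  expect_lt(abs(mean(co$dx_dementia) - 0.190), 3 * se(0.190))
  expect_lt(abs(mean(co$palliative_flag) - 0.27), 3 * se(0.27))
  expect_lt(abs(mean(co$zero_spend) - 0.05), 3 * se(0.05))
  expect_lt(abs(mean(co$age_at_death) - 78.5), 3 * 14.9 / 100 + 0.5)
  # sex-consistent cancers with the right marginals
  expect_true(all(co$sex[co$dx_breast_cancer] == "female"))
  expect_true(all(co$sex[co$dx_prostate_cancer] == "male"))
  expect_lt(abs(mean(co$dx_breast_cancer) - 0.023), 3 * se(0.023))
})

test_that("noiseless pathways equal their template expansion exactly", {
  co <- simulateCohort(cohortConfig(n_patients = 30, seed = 1))
  tpl <- defaultArchetypes()[2]
  pw <- simulatePathways(co, archetypeConfig(
    templates = tpl, mixture_weights = 1, per_day_noise = 0,
    hospital_death_fraction = NA, seed = 2))
  expansion <- rep(match(tpl[[1]]$state, careStates()), tpl[[1]]$duration)
  for (i in seq_len(30))
    expect_identical(unname(seqStates(pw$sequences)[i, ]), expansion)
  expect_identical(unname(pw$archetype), rep(1L, 30))
})

test_that("mixture weights drive ground-truth label counts", {
  co <- simulateCohort(cohortConfig(n_patients = 10000, seed = 3))
  pw <- simulatePathways(co, archetypeConfig(
    mixture_weights = c(0.67, 0.27, 0.06), seed = 4))
  counts <- tabulate(pw$archetype, 3)
  for (k in 1:3) {
    p <- c(0.67, 0.27, 0.06)[k]
    expect_lt(abs(counts[k] - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  }
  # degenerate mixture puts everyone in the last archetype
  deg <- simulatePathways(co[1:50, ], archetypeConfig(
    mixture_weights = c(0, 0, 1), seed = 5))
  expect_identical(unname(deg$archetype), rep(3L, 50))
})

test_that("template durations must sum to 365", {
  bad <- list(data.frame(state = c("HOME", "ACUTE"), duration = c(100, 100)))
  expect_error(archetypeConfig(templates = bad, mixture_weights = 1),
               "configuration error")
})

test_that("place-of-death calibration holds at the configured fraction", {
  co <- simulateCohort(cohortConfig(n_patients = 10000, seed = 31))
  pw <- simulatePathways(co, archetypeConfig(seed = 32))  # default 0.59
  pod <- placeOfDeathSummary(pw$sequences)
  hosp <- 1 - pod[["home"]]
  expect_lt(abs(hosp - 0.59), 3 * sqrt(0.59 * 0.41 / 10000))
})

test_that("claims generation is deterministic and respects its contracts", {
  co <- simulateCohort(cohortConfig(n_patients = 100, seed = 40))
  pw <- simulatePathways(co, archetypeConfig(seed = 41))
  cl1 <- simulateClaims(co, pw$sequences, costConfig(seed = 42))
  cl2 <- simulateClaims(co, pw$sequences, costConfig(seed = 42))
  expect_identical(cl1, cl2)
  expect_true(all(cl1$days_before_death >= 0 & cl1$days_before_death <= 364))
  expect_true(all(cl1$cost >= 0))
  expect_true(all(cl1$category %in% serviceCategories()))
  # zero-spend patients receive no claims at all
  expect_length(intersect(cl1$patient_id, co$patient_id[co$zero_spend]), 0)
  # claims-sequence consistency: every per-diem claim day has that state
  states <- seqStates(pw$sequences, "label")
  perdiem_map <- c(acute_hospital = "ACUTE", rehabilitation = "REHAB",
                   hospital_at_home = "HAH")
  pd <- cl1[cl1$category %in% names(perdiem_map), ]
  day_state <- states[cbind(match(pd$patient_id, co$patient_id),
                            365 - pd$days_before_death)]
  expect_identical(unname(perdiem_map[pd$category]), unname(day_state))
})

test_that("zero-spend fraction is recovered within 3 SEs at n = 10,000", {
  co <- simulateCohort(cohortConfig(n_patients = 10000, seed = 50))
  pw <- simulatePathways(co, archetypeConfig(seed = 51))
  cl <- simulateClaims(co, pw$sequences, costConfig(seed = 52))
  zero_share <- 1 - length(unique(cl$patient_id)) / 10000
  expect_lt(abs(zero_share - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("a pure per-diem configuration yields exact hospital totals", {
  co <- simulateCohort(cohortConfig(n_patients = 1, seed = 60))
  co$zero_spend <- FALSE
  ep <- data.frame(patient_id = co$patient_id, state = "ACUTE",
                   start_days_before_death = 9, end_days_before_death = 0)
  seqs <- encodeDailyStates(ep, ids = co$patient_id)
  amb <- costConfig()$ambulatory
  amb$rate <- 0
  cl <- simulateClaims(co, seqs, costConfig(
    per_diem = c(ACUTE = 123, REHAB = 0, HAH = 0, PSY = 0),
    ambulatory = amb, seed = 61))
  expect_equal(nrow(cl), 10L)
  expect_true(all(cl$category == "acute_hospital"))
  expect_equal(sum(cl$cost), 10 * 123)
})

test_that("negative cost configurations are rejected", {
  expect_error(costConfig(per_diem = c(ACUTE = -1, REHAB = 0, HAH = 0, PSY = 0)),
               "configuration error")
  amb <- costConfig()$ambulatory
  amb$rate[1] <- -2
  expect_error(costConfig(ambulatory = amb), "configuration error")
  expect_error(costConfig(last90_multiplier = 0.5), "configuration error")
})
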