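#' The nine diagnosis categories
#'
#' Diagnosis groups documented in the 12 months before death; in the
#' generator they are drawn as flags with configurable prevalences (the
#' claims-code mapping algorithms that define them in real data are out of
#' scope). Breast cancer is drawn among women only and prostate cancer
#' among men only, with the conditional probability scaled so the cohort
#' marginal matches the configured prevalence.
#'
#' @return character vector of the 9 diagnosis labels.
#' @export
diagnosisLabels <- function() {
  c("dementia", "cold", "breast_cancer", "lung_cancer", "prostate_cancer",
    "stroke", "acute_coronary_syndrome", "parkinson", "esrd")
}

.checkProp <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop("configuration error: ", what, " must be proportions in [0, 1]")
}

#' Cohort generator configuration
#'
#' Defaults reproduce the published marginals of the 2015 French decedent
#' cohort: 50.6% women, age at death 78.5 (SD 14.9) years truncated to
#' [1, 110], the nine diagnosis prevalences (dementia 19.0%, chronic
#' obstructive lung disease 17.3%, ...), Charlson index 4.3 (SD 3.7) drawn
#' as a discretized truncated normal, deprivation quintile weights
#' conditional on non-missing with 6.7% missing, 27% hospital palliative
#' care use, and a 5% zero-spend fraction.
#'
#' @param n_patients cohort size (>= 0).
#' @param female_fraction proportion of women.
#' @param age_mean,age_sd age-at-death distribution (years).
#' @param diagnosis_prevalences named proportions for [diagnosisLabels()].
#' @param charlson_mean,charlson_sd Charlson-score distribution parameters.
#' @param deprivation_quintile_weights 5 proportions summing to 1
#'   (conditional on the quintile being observed).
#' @param deprivation_missing_fraction proportion with missing quintile.
#' @param palliative_fraction proportion using hospital palliative care.
#' @param zero_spend_fraction proportion of patients with no claims at all.
#' @param seed integer seed.
#' @return a validated `cohort_config` list.
#' @export
cohortConfig <- function(n_patients = 1000L,
                         female_fraction = 0.506,
                         age_mean = 78.5, age_sd = 14.9,
                         diagnosis_prevalences = c(
                           dementia = 0.190, cold = 0.173,
                           breast_cancer = 0.023, lung_cancer = 0.050,
                           prostate_cancer = 0.023, stroke = 0.043,
                           acute_coronary_syndrome = 0.015,
                           parkinson = 0.035, esrd = 0.012),
                         charlson_mean = 4.3, charlson_sd = 3.7,
                         deprivation_quintile_weights =
                           c(16.0, 16.3, 19.1, 20.0, 21.9) / 93.3,
                         deprivation_missing_fraction = 0.067,
                         palliative_fraction = 0.27,
                         zero_spend_fraction = 0.05,
                         seed = 1L) {
  if (n_patients < 0) stop("configuration error: n_patients must be >= 0")
  .checkProp(female_fraction, "female_fraction")
  .checkProp(diagnosis_prevalences, "diagnosis_prevalences")
  if (!setequal(names(diagnosis_prevalences), diagnosisLabels()))
    stop("configuration error: diagnosis_prevalences must be named by diagnosisLabels()")
  .checkProp(deprivation_quintile_weights, "deprivation_quintile_weights")
  if (length(deprivation_quintile_weights) != 5L ||
      abs(sum(deprivation_quintile_weights) - 1) > 1e-9)
    stop("configuration error: deprivation weights must be 5 proportions summing to 1")
  .checkProp(deprivation_missing_fraction, "deprivation_missing_fraction")
  .checkProp(palliative_fraction, "palliative_fraction")
  .checkProp(zero_spend_fraction, "zero_spend_fraction")
  if (age_sd < 0 || charlson_sd < 0)
    stop("configuration error: standard deviations must be non-negative")
  structure(list(n_patients = as.integer(n_patients),
                 female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 diagnosis_prevalences =
                   diagnosis_prevalences[diagnosisLabels()],
                 charlson_mean = charlson_mean, charlson_sd = charlson_sd,
                 deprivation_quintile_weights = deprivation_quintile_weights,
                 deprivation_missing_fraction = deprivation_missing_fraction,
                 palliative_fraction = palliative_fraction,
                 zero_spend_fraction = zero_spend_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated-normal draws by rejection
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate a decedent cohort
#'
#' Draws one synthetic patient record per decedent with the marginals in
#' the configuration. Deterministic given the configuration seed; the
#' caller's RNG state is left untouched.
#'
#' @param config a [cohortConfig()].
#' @return a data.frame with columns `patient_id`, `sex`, `age_at_death`,
#'   `charlson_score`, `deprivation_quintile` (1-5 or `NA`),
#'   `palliative_flag`, `zero_spend` (generator-only), and one logical
#'   `dx_<label>` column per diagnosis.
#' @examples
#' head(simulateCohort(cohortConfig(n_patients = 5, seed = 42)))
#' @export
simulateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- .rtruncnorm(n, config$age_mean, config$age_sd, 1, 110)
  charlson <- as.integer(round(.rtruncnorm(n, config$charlson_mean,
                                           config$charlson_sd, 0, Inf)))
  w <- config$deprivation_quintile_weights
  dep <- sample.int(5L, n, replace = TRUE, prob = w)
  dep[stats::runif(n) < config$deprivation_missing_fraction] <- NA_integer_
  out <- data.frame(
    patient_id = sprintf("p%06d", seq_len(n)),
    sex = sex, age_at_death = age, charlson_score = charlson,
    deprivation_quintile = dep,
    palliative_flag = stats::runif(n) < config$palliative_fraction,
    zero_spend = stats::runif(n) < config$zero_spend_fraction,
    stringsAsFactors = FALSE
  )
  fem <- config$female_fraction
  for (dx in diagnosisLabels()) {
    p <- config$diagnosis_prevalences[[dx]]
    u <- stats::runif(n)
    flag <- if (dx == "breast_cancer" && fem > 0 && p / fem <= 1) {
      sex == "female" & u < p / fem
    } else if (dx == "prostate_cancer" && fem < 1 && p / (1 - fem) <= 1) {
      sex == "male" & u < p / (1 - fem)
    } else {
      u < p
    }
    out[[paste0("dx_", dx)]] <- flag
  }
  out
}

#' Default care-pathway archetype templates
#'
#' Three segment templates over the 365-day window, encoding the canonical
#' end-of-life pathway narratives:
#' \enumerate{
#'   \item few and late hospitalizations: at home for 351 days, then one
#'     two-week acute stay ending at death;
#'   \item acute care during the last 3 months of life: at home for 245
#'     days, then alternating acute and rehabilitation blocks;
#'   \item early and repeated hospitalizations: repeated acute,
#'     rehabilitation and hospital-at-home blocks starting within the first
#'     month of the window.
#' }
#' Each template is a data.frame of `(state, duration)` segments whose
#' durations sum to exactly 365.
#'
#' @return a list of three templates.
#' @export
defaultArchetypes <- function() {
  tpl <- function(states, durations)
    data.frame(state = states, duration = as.integer(durations),
               stringsAsFactors = FALSE)
  list(
    few_late = tpl(c("HOME", "ACUTE"), c(351, 14)),
    acute_last3m = tpl(c("HOME", "ACUTE", "REHAB", "ACUTE", "REHAB", "ACUTE"),
                       c(245, 30, 30, 30, 16, 14)),
    early_repeated = tpl(
      c("HOME", "ACUTE", "REHAB", "HOME", "HAH", "HOME", "ACUTE", "REHAB",
        "HOME", "ACUTE", "HAH", "ACUTE"),
      c(25, 25, 35, 25, 35, 25, 30, 35, 25, 35, 35, 35))
  )
}

#' Pathway generator configuration
#'
#' @param templates list of archetype templates (data.frames with `state`
#'   and `duration` columns; each template's durations must sum to 365).
#' @param mixture_weights archetype mixture proportions (sum to 1).
#' @param per_day_noise probability that any given day's state is
#'   resampled uniformly to one of the four other states.
#' @param hospital_death_fraction proportion of patients whose final day is
#'   in a hospital state (default 0.59). Applied after noise: home-death
#'   patients have the template's trailing non-HOME run (capped at 30 days)
#'   replaced by HOME; hospital-death patients keep the template's terminal
#'   state on the last day. Set to `NA` to disable the adjustment, in which
#'   case noiseless sequences equal their template expansion exactly.
#' @param seed integer seed.
#' @return a validated `archetype_config` list.
#' @export
archetypeConfig <- function(templates = defaultArchetypes(),
                            mixture_weights = c(0.67, 0.27, 0.06),
                            per_day_noise = 0.05,
                            hospital_death_fraction = 0.59,
                            seed = 1L) {
  if (length(templates) != length(mixture_weights))
    stop("configuration error: one mixture weight per template is required")
  for (t in templates) {
    if (!all(c("state", "duration") %in% names(t)))
      stop("configuration error: templates need 'state' and 'duration' columns")
    .stateToInt(t$state)
    if (sum(t$duration) != 365L)
      stop("configuration error: template durations must sum to exactly 365")
    if (any(t$duration < 1L))
      stop("configuration error: segment durations must be positive")
  }
  .checkProp(mixture_weights, "mixture_weights")
  if (abs(sum(mixture_weights) - 1) > 1e-9)
    stop("configuration error: mixture weights must sum to 1")
  .checkProp(per_day_noise, "per_day_noise")
  if (!is.na(hospital_death_fraction))
    .checkProp(hospital_death_fraction, "hospital_death_fraction")
  structure(list(templates = templates,
                 mixture_weights = as.numeric(mixture_weights),
                 per_day_noise = per_day_noise,
                 hospital_death_fraction = hospital_death_fraction,
                 seed = as.integer(seed)),
            class = "archetype_config")
}

.expandTemplate <- function(tpl) {
  rep(.stateToInt(tpl$state), times = tpl$duration)
}

#' Simulate care-state sequences as noisy archetype realizations
#'
#' Assigns each patient a ground-truth archetype by the mixture weights,
#' expands the archetype template to a 365-day sequence, applies
#' independent per-day noise (each day resampled with probability
#' `per_day_noise` to a uniformly chosen other state), and finally applies
#' the place-of-death adjustment (see [archetypeConfig()]).
#'
#' The ground-truth archetype labels are returned separately from the
#' sequences and are never consumed by any analysis stage; they exist only
#' to validate cluster recovery.
#'
#' @param cohort a cohort data.frame (non-empty).
#' @param config an [archetypeConfig()].
#' @return a list with `sequences` (a [CareSequences-class]) and
#'   `archetype` (integer ground-truth labels named by patient id).
#' @export
simulatePathways <- function(cohort, config = archetypeConfig()) {
  stopifnot(inherits(config, "archetype_config"))
  n <- nrow(cohort)
  if (n == 0L) stop("cohort must be non-empty")
  ids <- as.character(cohort$patient_id)
  K <- length(config$templates)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed)
  lab <- sample.int(K, n, replace = TRUE, prob = config$mixture_weights)
  expansions <- lapply(config$templates, .expandTemplate)
  m <- do.call(rbind, expansions)[lab, , drop = FALSE]
  eps <- config$per_day_noise
  if (eps > 0) {
    flip <- which(matrix(stats::runif(n * 365L) < eps, n, 365L))
    if (length(flip)) {
      # uniform over the four states other than the current one
      shift <- sample.int(.N_STATES - 1L, length(flip), replace = TRUE)
      m[flip] <- 1L + (m[flip] - 1L + shift) %% .N_STATES
    }
  }
  hdf <- config$hospital_death_fraction
  if (!is.na(hdf)) {
    tail_len <- vapply(expansions, function(e) {
      r <- rle(rev(e) != .HOME)
      if (r$values[1]) min(r$lengths[1], 30L) else 0L
    }, integer(1))
    term_state <- vapply(expansions, function(e) {
      s <- e[365L]
      if (s == .HOME) 1L else s  # default terminal hospital state: ACUTE
    }, integer(1))
    hosp <- stats::runif(n) < hdf
    for (i in which(!hosp)) {
      tl <- tail_len[lab[i]]
      if (tl > 0L) m[i, (365L - tl + 1L):365L] <- .HOME
      m[i, 365L] <- .HOME
    }
    m[hosp, 365L] <- term_state[lab[hosp]]
  }
  list(sequences = new("CareSequences", ids = ids, states = m),
       archetype = stats::setNames(lab, ids))
}

#' Claims generator configuration
#'
#' Cost model for synthetic service claims: constant per-diem costs for
#' inpatient states (psychiatry days are costed into the
#' "physiotherapy and other services" category, which folds in psychiatric
#' services), and zero-inflated-by-rate lognormal event costs for the
#' ambulatory categories drawn from a time-inhomogeneous Poisson process
#' whose rate is multiplied in the last 90 days before death. Default
#' per-diem and event parameters are calibrated so that category means land
#' in the range of published last-year-of-life expenditure tables (acute
#' hospital care the dominant category, pharmacy the largest ambulatory
#' one, heavy right skew with mean far above median).
#'
#' @param per_diem named costs per inpatient day (euros) for `ACUTE`,
#'   `REHAB`, `HAH`, `PSY`.
#' @param ambulatory data.frame with columns `category`, `rate` (events per
#'   patient-year), `meanlog`, `sdlog` (lognormal event cost).
#' @param last90_multiplier multiplier (>= 1) on ambulatory event rates
#'   during the last 90 days before death.
#' @param seed integer seed.
#' @return a validated `cost_config` list.
#' @export
costConfig <- function(per_diem = c(ACUTE = 420, REHAB = 215, HAH = 235,
                                    PSY = 300),
                       ambulatory = data.frame(
                         category = c("nursing_services", "outpatient_visits",
                                      "physio_other", "equipment_devices",
                                      "pharmacy", "expensive_hospital_drugs",
                                      "transportation", "procedures_imaging"),
                         rate = c(40, 10, 8, 6, 24, 0.3, 8, 10),
                         meanlog = log(c(30, 31, 50, 200, 100, 2500, 120, 110)) - 0.5,
                         sdlog = 1,
                         stringsAsFactors = FALSE),
                       last90_multiplier = 3,
                       seed = 1L) {
  if (any(per_diem < 0))
    stop("configuration error: per-diem costs must be non-negative")
  if (!all(c("ACUTE", "REHAB", "HAH", "PSY") %in% names(per_diem)))
    stop("configuration error: per_diem must name ACUTE, REHAB, HAH, PSY")
  if (any(ambulatory$rate < 0))
    stop("configuration error: ambulatory event rates must be non-negative")
  if (!all(ambulatory$category %in% serviceCategories()))
    stop("configuration error: unknown ambulatory category")
  if (last90_multiplier < 1)
    stop("configuration error: last90_multiplier must be >= 1")
  structure(list(per_diem = per_diem, ambulatory = ambulatory,
                 last90_multiplier = last90_multiplier,
                 seed = as.integer(seed)),
            class = "cost_config")
}

# inpatient state -> claimed service category
.PERDIEM_CATEGORY <- c(ACUTE = "acute_hospital", REHAB = "rehabilitation",
                       HAH = "hospital_at_home", PSY = "physio_other")

#' Simulate costed service claims
#'
#' Emits one per-diem claim for every inpatient day of every sequence (in
#' the category matching the state) and ambulatory event claims drawn from
#' the configured time-inhomogeneous counting process. Patients flagged
#' `zero_spend` in the cohort receive no claims at all.
#'
#' @param cohort a cohort data.frame (with the generator's `zero_spend`
#'   column; if absent, no patient is suppressed).
#' @param sequences the patients' [CareSequences-class] (365 days).
#' @param config a [costConfig()].
#' @return a claims data.frame: `patient_id`, `days_before_death` (0-364),
#'   `category`, `cost`.
#' @export
simulateClaims <- function(cohort, sequences, config = costConfig()) {
  stopifnot(inherits(config, "cost_config"), is(sequences, "CareSequences"))
  ids <- as.character(cohort$patient_id)
  if (!identical(seqIds(sequences), ids))
    stop("sequences must be aligned to the cohort (same ids, same order)")
  n <- length(ids)
  L <- seqDays(sequences)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed)
  # inpatient per-diem claims
  inpat <- which(sequences@states != .HOME, arr.ind = TRUE)
  st <- careStates()[sequences@states[inpat]]
  perdiem <- data.frame(
    patient_id = ids[inpat[, 1L]],
    days_before_death = L - inpat[, 2L],
    category = unname(.PERDIEM_CATEGORY[st]),
    cost = unname(config$per_diem[st]),
    stringsAsFactors = FALSE
  )
  # ambulatory events: piecewise-constant rate, multiplied in last 90 days
  m <- config$last90_multiplier
  amb <- lapply(seq_len(nrow(config$ambulatory)), function(r) {
    a <- config$ambulatory[r, ]
    n_early <- stats::rpois(n, a$rate * 275 / 365)
    n_late <- stats::rpois(n, a$rate * m * 90 / 365)
    pid <- c(rep(ids, n_early), rep(ids, n_late))
    if (!length(pid)) return(NULL)
    days <- c(sample(90:364, sum(n_early), replace = TRUE),
              sample(0:89, sum(n_late), replace = TRUE))
    data.frame(patient_id = pid, days_before_death = days,
               category = a$category,
               cost = stats::rlnorm(length(pid), a$meanlog, a$sdlog),
               stringsAsFactors = FALSE)
  })
  claims <- rbind(perdiem, do.call(rbind, amb))
  if (!is.null(cohort$zero_spend) && nrow(claims)) {
    zero <- ids[cohort$zero_spend]
    claims <- claims[!(claims$patient_id %in% zero), , drop = FALSE]
  }
  claims <- claims[order(claims$patient_id, -claims$days_before_death,
                         claims$category, claims$cost), , drop = FALSE]
  rownames(claims) <- NULL
  claims
}
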