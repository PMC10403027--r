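#' Charlson comorbidity classes
#'
#' Bins a non-negative integer Charlson index into the four reporting
#' classes 0, 1-2, 3-4 and >=5. The classes partition the non-negative
#' integers.
#'
#' @param score integer vector of Charlson scores (>= 0).
#' @return factor with levels `"0"`, `"1-2"`, `"3-4"`, `">=5"`.
#' @examples
#' charlsonClass(c(0, 2, 4, 12))
#' @export
charlsonClass <- function(score) {
  if (any(score < 0)) stop("Charlson scores must be non-negative")
  cut(score, breaks = c(-0.5, 0.5, 2.5, 4.5, Inf),
      labels = c("0", "1-2", "3-4", ">=5"))
}

.AGE_BREAKS <- c(-Inf, 20, 30, 40, 50, 60, 70, 80, 90, Inf)
.AGE_LABELS <- c("<20", "[20;30)", "[30;40)", "[40;50)", "[50;60)",
                 "[60;70)", "[70;80)", "[80;90)", ">=90")

#' Cohort characteristics table
#'
#' Counts and percentages of the cohort by sex, nine age bands at death
#' (half-open `[lower, upper)` bands, first `<20`, last `>=90`), social
#' deprivation quintile (missing as a first-class category), Charlson
#' class, and each diagnosis flag, plus means and SDs for age and Charlson.
#'
#' @param cohort a cohort data.frame (as from [simulateCohort()]): columns
#'   `patient_id`, `sex`, `age_at_death`, `charlson_score`,
#'   `deprivation_quintile` (1-5 or NA) and logical `dx_*` diagnosis flags.
#' @return a list: `$counts`, a data.frame (`section`, `level`, `n`, `pct`)
#'   where each exclusive section sums to the cohort size; `$age_mean`,
#'   `$age_sd`, `$charlson_mean`, `$charlson_sd`, `$n`.
#' @export
characteristicsTable <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort")
  bin <- function(section, f) {
    tab <- table(f)
    data.frame(section = section, level = names(tab),
               n = as.integer(tab), pct = 100 * as.integer(tab) / n,
               stringsAsFactors = FALSE)
  }
  sex <- bin("sex", factor(cohort$sex, levels = c("male", "female")))
  age <- bin("age_band",
             cut(cohort$age_at_death, breaks = .AGE_BREAKS,
                 labels = .AGE_LABELS, right = FALSE))
  dep <- bin("deprivation_quintile",
             factor(ifelse(is.na(cohort$deprivation_quintile), "missing",
                           as.character(cohort$deprivation_quintile)),
                    levels = c(1:5, "missing")))
  chl <- bin("charlson_class", charlsonClass(cohort$charlson_score))
  dxcols <- grep("^dx_", names(cohort), value = TRUE)
  dx <- if (length(dxcols)) {
    data.frame(section = "diagnosis", level = sub("^dx_", "", dxcols),
               n = vapply(dxcols, function(cl) sum(cohort[[cl]]), integer(1)),
               pct = vapply(dxcols, function(cl) 100 * mean(cohort[[cl]]),
                            numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else NULL
  list(counts = rbind(sex, age, dep, chl, dx),
       age_mean = mean(cohort$age_at_death),
       age_sd = if (n > 1) stats::sd(cohort$age_at_death) else 0,
       charlson_mean = mean(cohort$charlson_score),
       charlson_sd = if (n > 1) stats::sd(cohort$charlson_score) else 0,
       n = n)
}

#' Place-of-death distribution
#'
#' Classifies each patient by the state on the final day of the sequence
#' (the day of death) and returns the distribution over the five places of
#' care.
#'
#' @param seqs a [CareSequences-class].
#' @return named numeric vector of proportions over
#'   `hospital_acute`, `rehabilitation`, `hospital_at_home`, `psychiatry`,
#'   `home`; sums to 1.
#' @export
placeOfDeathSummary <- function(seqs) {
  final <- seqs@states[, seqDays(seqs)]
  tab <- tabulate(final, nbins = .N_STATES)
  stats::setNames(tab / length(final),
                  c("hospital_acute", "rehabilitation", "hospital_at_home",
                    "psychiatry", "home"))
}

#' Palliative-care use summary
#'
#' Overall proportion of patients with the hospital palliative-care flag,
#' and the proportion by sex and by age band, with counts.
#'
#' @inheritParams characteristicsTable
#' @return a list: `$overall` (proportion), `$n_palliative`, `$by_sex` and
#'   `$by_age_band` (data.frames with `level`, `n`, `n_palliative`,
#'   `proportion`).
#' @export
palliativeSummary <- function(cohort) {
  p <- as.logical(cohort$palliative_flag)
  grp <- function(f) {
    lv <- levels(f)
    data.frame(level = lv,
               n = as.integer(table(f)),
               n_palliative = as.integer(tapply(p, f, sum, default = 0)),
               proportion = as.numeric(tapply(p, f, mean, default = 0)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(overall = mean(p), n_palliative = sum(p),
       by_sex = grp(factor(cohort$sex, levels = c("male", "female"))),
       by_age_band = grp(cut(cohort$age_at_death, breaks = .AGE_BREAKS,
                             labels = .AGE_LABELS, right = FALSE)))
}

#' Odds ratios for pathway-cluster membership
#'
#' Maximum-likelihood logistic regression of membership in a designated
#' pathway cluster (e.g. "early and repeated hospitalizations") versus the
#' rest, on patient features, reporting exponentiated coefficients with
#' Wald 95% confidence intervals.
#'
#' @param cohort cohort data.frame; `features` name its columns.
#' @param typology a [ClusterTypology-class] labelling the cohort.
#' @param target_cluster the cluster defining the outcome (id in `1:k`).
#' @param features character vector of feature columns (default: age, sex,
#'   Charlson score and all `dx_*` flags).
#' @return data.frame with `feature`, `or`, `ci_low`, `ci_high`, `n`;
#'   attribute `converged` reports fit convergence.
#' @export
pathwayAssociation <- function(cohort, typology, target_cluster,
                               features = NULL) {
  lab <- clusterLabels(typology)
  idx <- match(names(lab), cohort$patient_id)
  if (anyNA(idx)) stop("typology labels patients absent from the cohort")
  co <- cohort[idx, , drop = FALSE]
  y <- as.integer(lab == target_cluster)
  if (length(unique(y)) < 2L)
    stop("outcome has no variation: every patient is ",
         if (y[1] == 1L) "in" else "outside", " the target cluster")
  if (is.null(features))
    features <- intersect(c("age_at_death", "sex", "charlson_score",
                            grep("^dx_", names(co), value = TRUE)),
                          names(co))
  df <- co[, features, drop = FALSE]
  df$.y <- y
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  probs <- stats::fitted(fit)
  eps <- 1e-8
  if (!fit$converged || all(probs < eps | probs > 1 - eps) ||
      any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
    stop("logistic fit indicates (quasi-)perfect separation; ",
         "odds ratios are not identified")
  est <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  out <- data.frame(feature = names(est),
                    or = exp(est),
                    ci_low = exp(est - 1.959963984540054 * se),
                    ci_high = exp(est + 1.959963984540054 * se),
                    n = nrow(df),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "converged") <- fit$converged
  out
}
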