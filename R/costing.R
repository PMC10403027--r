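#' The eleven service categories
#'
#' Service categories used to decompose last-year-of-life spending: four
#' hospital categories (acute care, rehabilitation, hospital at home,
#' expensive hospital drugs billed on top of stays) and seven ambulatory
#' ones (nursing services, outpatient visits, physiotherapy and other
#' services, medical equipment and devices, pharmacy, transportation,
#' procedures/imaging).
#'
#' @return character vector of the 11 category codes.
#' @export
serviceCategories <- function() {
  c("acute_hospital", "rehabilitation", "hospital_at_home",
    "nursing_services", "outpatient_visits", "physio_other",
    "equipment_devices", "pharmacy", "expensive_hospital_drugs",
    "transportation", "procedures_imaging")
}

.checkClaims <- function(claims, cohort = NULL) {
  req <- c("patient_id", "days_before_death", "category", "cost")
  if (!all(req %in% names(claims)))
    stop("claims must have columns: ", paste(req, collapse = ", "))
  if (nrow(claims)) {
    if (any(claims$cost < 0)) stop("claim costs must be non-negative")
    d <- claims$days_before_death
    if (any(d < 0L) || any(d > 364L))
      stop("days_before_death must lie in [0, 364]")
    if (!all(claims$category %in% serviceCategories()))
      stop("unknown service category")
    if (!is.null(cohort) &&
        !all(claims$patient_id %in% cohort$patient_id))
      stop("claim references a patient absent from the cohort")
  }
  invisible(TRUE)
}

#' Per-patient spending totals
#'
#' Sums claim costs per patient over a window of days before death; every
#' cohort patient appears, zero-spend patients included.
#'
#' @param claims claims data.frame (`patient_id`, `days_before_death`,
#'   `category`, `cost`).
#' @param cohort cohort data.frame with `patient_id`.
#' @param window_days count claims with `days_before_death < window_days`.
#' @return named numeric vector of totals, one per cohort patient.
#' @export
patientTotals <- function(claims, cohort, window_days = 365L) {
  .checkClaims(claims, cohort)
  ids <- as.character(cohort$patient_id)
  tot <- stats::setNames(numeric(length(ids)), ids)
  sel <- claims$days_before_death < window_days
  if (any(sel)) {
    agg <- tapply(claims$cost[sel], as.character(claims$patient_id[sel]), sum)
    tot[names(agg)] <- as.numeric(agg)
  }
  tot
}

#' Service-category expenditure summary table
#'
#' For each of the 11 service categories (and a total row): the percentage
#' of patients with any claim in the category, the mean cost per patient
#' with its SD, the category's share of total expenditure, and the median
#' and IQR width of per-patient costs. Means, SDs, medians and quartiles
#' are taken over ALL cohort patients, zero-spend patients included; the
#' IQR is reported as the single width Q3 - Q1 with linear-interpolation
#' quartiles (`stats::quantile` type 7). Category means therefore sum
#' exactly to the total-row mean.
#'
#' @inheritParams patientTotals
#' @return a data.frame with 12 rows (11 categories + `"total"`) and
#'   columns `category`, `pct_users`, `mean`, `sd`, `pct_of_total`,
#'   `median`, `iqr`; the cohort size is attached as attribute `n`.
#' @export
serviceCostTable <- function(claims, cohort, window_days = 365L) {
  .checkClaims(claims, cohort)
  ids <- as.character(cohort$patient_id)
  n <- length(ids)
  if (n == 0L) stop("empty cohort")
  cats <- serviceCategories()
  # n x 11 per-patient, per-category totals within the window
  M <- matrix(0, nrow = n, ncol = length(cats),
              dimnames = list(ids, cats))
  sel <- claims$days_before_death < window_days
  if (any(sel)) {
    cl <- claims[sel, ]
    i <- match(as.character(cl$patient_id), ids)
    j <- match(cl$category, cats)
    agg <- tapply(cl$cost, list(i, j), sum)
    ii <- as.integer(rownames(agg)); jj <- as.integer(colnames(agg))
    for (c2 in seq_along(jj)) {
      v <- agg[, c2]
      ok <- !is.na(v)
      M[ii[ok], jj[c2]] <- v[ok]
    }
  }
  grand <- rowSums(M)
  total_sum <- sum(grand)
  one <- function(v, users) {
    data.frame(
      pct_users = 100 * mean(users),
      mean = mean(v),
      sd = if (n > 1) stats::sd(v) else 0,
      pct_of_total = if (total_sum > 0) 100 * sum(v) / total_sum else 0,
      median = as.numeric(stats::median(v)),
      iqr = as.numeric(diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)))
    )
  }
  rows <- lapply(cats, function(ct) one(M[, ct], M[, ct] > 0))
  out <- cbind(category = c(cats, "total"),
               rbind(do.call(rbind, rows), one(grand, grand > 0)))
  out$pct_of_total[out$category == "total"] <- if (total_sum > 0) 100 else 0
  rownames(out) <- NULL
  attr(out, "n") <- n
  out
}

#' Share of spending in a short terminal window
#'
#' Total spending with `days_before_death < short_window` divided by total
#' spending over the full year; 0/0 is 0 by convention.
#'
#' @param claims claims data.frame.
#' @param short_window window in days before death (default 90, the "last
#'   3 months").
#' @return a proportion in [0, 1].
#' @export
windowShare <- function(claims, short_window = 90L) {
  .checkClaims(claims)
  stopifnot(short_window <= 365L)
  denom <- sum(claims$cost[claims$days_before_death < 365L])
  if (denom == 0) return(0)
  sum(claims$cost[claims$days_before_death < short_window]) / denom
}

#' Top expenditure decile summary
#'
#' The highest-spending decile of the cohort, with the convention
#' `count = N - floor(0.9 N)`. Membership is decided by ranking totals in
#' decreasing order with ties at the threshold broken by a stable order on
#' patient id; the threshold is the smallest total inside the decile.
#'
#' @param totals per-patient 12-month totals, one per cohort patient
#'   (zeros included), named by patient id (names optional).
#' @return a list with `count`, `threshold` and `share` (decile spending /
#'   total spending; 0 if total spending is 0).
#' @export
topDecileSummary <- function(totals) {
  N <- length(totals)
  if (N == 0L) stop("empty input: one total per cohort patient is required")
  count <- N - floor(0.9 * N)
  ids <- names(totals) %||% as.character(seq_len(N))
  o <- order(-totals, ids)
  top <- o[seq_len(count)]
  tot <- sum(totals)
  list(count = as.integer(count),
       threshold = min(totals[top]),
       share = if (tot > 0) sum(totals[top]) / tot else 0)
}

#' Per-cluster cost summaries
#'
#' Exact summary statistics of per-patient 12-month totals within each
#' pathway cluster. Empty clusters are dropped with a warning.
#'
#' @param typology a [ClusterTypology-class].
#' @param totals named per-patient totals (names are patient ids).
#' @return data.frame with columns `cluster`, `name`, `n`, `mean`, `sd`,
#'   `median`, `iqr`.
#' @export
clusterCostSummary <- function(typology, totals) {
  lab <- clusterLabels(typology)
  idx <- match(names(lab), names(totals))
  if (anyNA(idx)) stop("every labelled patient needs a total")
  v <- as.numeric(totals[idx])
  rows <- lapply(seq_len(nClusters(typology)), function(k) {
    g <- v[lab == k]
    if (!length(g)) {
      warning("cluster ", k, " is empty; excluded")
      return(NULL)
    }
    data.frame(cluster = k, name = clusterNames(typology)[k], n = length(g),
               mean = mean(g), sd = if (length(g) > 1) stats::sd(g) else 0,
               median = as.numeric(stats::median(g)),
               iqr = as.numeric(diff(stats::quantile(g, c(.25, .75), names = FALSE))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster shares of total cost
#'
#' From cluster sizes and per-patient mean costs, each cluster's share of
#' the cohort's total spending: `share_k = n_k m_k / sum_j n_j m_j`.
#'
#' @param cluster_sizes non-negative cluster sizes.
#' @param cluster_means non-negative per-patient mean costs.
#' @return numeric vector of shares summing to 1.
#' @examples
#' # three pathway clusters: sizes and mean 12-month costs
#' clusterCostShare(c(6725, 2664, 611), c(16139, 42045, 76759))
#' @export
clusterCostShare <- function(cluster_sizes, cluster_means) {
  stopifnot(length(cluster_sizes) == length(cluster_means),
            all(cluster_sizes >= 0), all(cluster_means >= 0))
  tot <- cluster_sizes * cluster_means
  if (sum(tot) <= 0) stop("all cluster totals are zero")
  tot / sum(tot)
}
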