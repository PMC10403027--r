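#' Published 2015 French decedent-cohort reference values
#'
#' Summary statistics published for the national cohort of 501,121 French
#' decedents of 2015: per-service-category last-12-month expenditures for
#' the whole population and for three disease populations (dementia, breast
#' cancer, chronic obstructive lung disease; each on a 10,000-patient random
#' sample), per-cluster cost summaries from the care-pathway cluster
#' analysis, and headline per-capita quantities. These are the inputs for
#' the package's arithmetic-consistency checks (category means summing to
#' the total mean, cluster cost shares, terminal-window spending share,
#' top-decile count); they are not produced by the generator.
#'
#' @param population for `referenceCosts()`: `"total"`, `"dementia"`,
#'   `"breast_cancer"` or `"cold"`.
#' @return data.frames: `referenceCosts()` has one row per service category
#'   plus a total row; `referenceClusters()` one row per disease x cluster
#'   (`n`, `mean`, `sd`, `median`, `iqr`); `referencePerCapita()` a named
#'   numeric vector of headline values.
#' @examples
#' rc <- referenceCosts("total")
#' sum(rc$mean[rc$category != "total"])  # equals the total-row mean
#' @export
referenceCosts <- function(population = c("total", "dementia",
                                          "breast_cancer", "cold")) {
  population <- match.arg(population)
  f <- system.file("extdata", "reference_costs_2015.csv",
                   package = "CarePathways", mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  df[df$population == population, -1, drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' @rdname referenceCosts
#' @export
referenceClusters <- function() {
  f <- system.file("extdata", "reference_clusters_2015.csv",
                   package = "CarePathways", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname referenceCosts
#' @export
referencePerCapita <- function() {
  f <- system.file("extdata", "reference_percapita_2015.csv",
                   package = "CarePathways", mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}
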