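#' Ward hierarchical ascending classification of a dissimilarity matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion applied
#' through the Lance-Williams update on the dissimilarity matrix. The
#' default variant (`"squared"`) applies Ward's update to squared
#' dissimilarities and reports merge heights on the original scale
#' (`stats::hclust` method `"ward.D2"`); on Euclidean input its greedy merge
#' order coincides with the classical minimum increase in within-cluster
#' sum of squares. The `"raw"` variant (`"ward.D"`) applies the update to
#' the dissimilarities as given.
#'
#' @param D a symmetric non-negative dissimilarity matrix with zero
#'   diagonal (as from [dissimilarityMatrix()]), or a `stats::dist`.
#' @param variant `"squared"` (default) or `"raw"`.
#' @return an object of class `hclust`: `$merge` (n-1 x 2 merge list),
#'   `$height`, `$order`, `$labels`.
#' @export
wardLinkage <- function(D, variant = c("squared", "raw")) {
  variant <- match.arg(variant)
  if (!inherits(D, "dist")) {
    if (!is.matrix(D) || nrow(D) != ncol(D))
      stop("D must be a square matrix or a 'dist' object")
    if (any(D < 0)) stop("dissimilarities must be non-negative")
    if (any(abs(D - t(D)) > 1e-9)) stop("dissimilarity matrix must be symmetric")
    D <- stats::as.dist(D)
  }
  if (attr(D, "Size") < 2L) stop("at least 2 observations are required")
  stats::hclust(D, method = if (variant == "squared") "ward.D2" else "ward.D")
}

#' Cut a linkage tree into a pathway typology
#'
#' Undoes the last `k - 1` merges of the tree, yielding `k` non-empty
#' clusters. Labels are renumbered 1..k in order of first appearance over
#' the leaves.
#'
#' @param tree an `hclust` object from [wardLinkage()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param clusterNames optional descriptive names (length `k`).
#' @return a [ClusterTypology-class].
#' @export
cutTypology <- function(tree, k, clusterNames = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels %||% seq_len(nrow(tree$merge) + 1L))
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  # renumber in order of first appearance for stable labels
  first <- unique(raw)
  lab <- match(raw, first)
  names(lab) <- names(raw) %||% as.character(seq_along(raw))
  ClusterTypology(lab, k = k, clusterNames = clusterNames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the number of clusters from the dendrogram
#'
#' Elbow rule on merge heights: for each candidate `k`, the ratio between
#' the height of the merge that would reduce `k` clusters to `k - 1` and
#' the height of the last merge performed within `k` clusters. The `k`
#' maximizing this relative drop is returned. Degenerate trees (all
#' candidate heights zero, e.g. identical sequences) and exact ties fall
#' back to `default`.
#'
#' @param tree an `hclust` object.
#' @param k_min,k_max candidate range, `1 <= k_min <= k_max < n`.
#' @param default the fallback (default `k_min`).
#' @return the selected number of clusters.
#' @export
selectK <- function(tree, k_min = 2L, k_max = 8L, default = k_min) {
  stopifnot(inherits(tree, "hclust"))
  h <- tree$height
  n <- length(h) + 1L
  if (k_min < 1L || k_min > k_max || k_max >= n)
    stop("need 1 <= k_min <= k_max < n")
  ks <- seq.int(k_min, k_max)
  # merge n-k+1 reduces k to k-1 clusters; merge n-k is the last within k
  num <- h[n - ks + 1L]
  den <- h[n - ks]
  if (all(num < .Machine$double.eps)) return(as.integer(default))
  ratio <- ifelse(den < .Machine$double.eps, Inf, num / den)
  best <- which(ratio == max(ratio))
  if (length(best) > 1L) return(as.integer(default))
  as.integer(ks[best])
}

#' Chronogram: per-day state distribution by cluster
#'
#' For each cluster and each day of the window, the frequency of each care
#' state among the cluster's members — the data behind the state
#' distribution plot.
#'
#' @param seqs a [CareSequences-class].
#' @param typology a [ClusterTypology-class] labelling every sequence.
#' @return a named list with one `days x 5` matrix of frequencies per
#'   cluster; every row sums to 1.
#' @export
chronogram <- function(seqs, typology) {
  lab <- clusterLabels(typology)
  idx <- match(seqIds(seqs), names(lab))
  if (anyNA(idx)) stop("typology does not label every sequence")
  lab <- lab[idx]
  out <- lapply(seq_len(nClusters(typology)), function(k) {
    m <- seqs@states[lab == k, , drop = FALSE]
    f <- vapply(seq_len(.N_STATES), function(s) colMeans(m == s),
                numeric(ncol(m)))
    colnames(f) <- careStates()
    f
  })
  names(out) <- paste0("cluster", seq_len(nClusters(typology)))
  out
}

#' Sequence index-plot ordering
#'
#' Within each cluster, orders patients for rendering a sequence index plot:
#' by first non-HOME day (patients never leaving home sort last), then by
#' total non-HOME days, then by patient id — a stable total order.
#'
#' @inheritParams chronogram
#' @return a named list of character id vectors, one per cluster.
#' @export
indexPlotOrder <- function(seqs, typology) {
  lab <- clusterLabels(typology)
  idx <- match(seqIds(seqs), names(lab))
  if (anyNA(idx)) stop("typology does not label every sequence")
  lab <- lab[idx]
  m <- seqs@states
  nonhome <- m != .HOME
  first <- apply(nonhome, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1] else ncol(m) + 1L
  })
  total <- rowSums(nonhome)
  ids <- seqIds(seqs)
  out <- lapply(seq_len(nClusters(typology)), function(k) {
    sel <- which(lab == k)
    sel[order(first[sel], total[sel], ids[sel])] |> (\(o) ids[o])()
  })
  names(out) <- paste0("cluster", seq_len(nClusters(typology)))
  out
}

#' Per-cluster patient characteristics
#'
#' Descriptive statistics of each cluster: size, mean and SD of age at
#' death, percentage of women, mean and SD of the Charlson index.
#'
#' @param typology a [ClusterTypology-class].
#' @param cohort a cohort data.frame with columns `patient_id`, `sex`,
#'   `age_at_death`, `charlson_score`.
#' @return a data.frame with one row per cluster.
#' @export
clusterProfile <- function(typology, cohort) {
  lab <- clusterLabels(typology)
  idx <- match(names(lab), cohort$patient_id)
  if (anyNA(idx)) stop("typology labels patients absent from the cohort")
  co <- cohort[idx, ]
  ks <- sort(unique(lab))
  rows <- lapply(ks, function(k) {
    g <- co[lab == k, ]
    data.frame(
      cluster = k,
      name = clusterNames(typology)[k],
      n = nrow(g),
      age_mean = mean(g$age_at_death),
      age_sd = if (nrow(g) > 1) stats::sd(g$age_at_death) else 0,
      pct_female = 100 * mean(g$sex == "female"),
      charlson_mean = mean(g$charlson_score),
      charlson_sd = if (nrow(g) > 1) stats::sd(g$charlson_score) else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Name pathway clusters from chronogram features
#'
#' Maps clusters to the three canonical end-of-life pathway narratives using
#' two chronogram features: the mean share of days spent in any hospital
#' state over the whole year (`hospShare`) and over the early part of the
#' window (days before the last 90, `earlyShare`). A cluster with a
#' substantial early hospital presence is labelled
#' "early and repeated hospitalizations"; otherwise a cluster with a
#' substantial overall hospital presence (concentrated, by elimination, in
#' the last 3 months) is "acute care during the last 3 months of life";
#' the rest are "few and late hospitalizations".
#'
#' @param chron a chronogram as returned by [chronogram()].
#' @param early_threshold early hospital-share threshold (default 0.20; comfortably above the share that per-day noise alone induces at its default rate).
#' @param hosp_threshold overall hospital-share threshold (default 0.15).
#' @param short_window the late window in days (default 90).
#' @return a character vector of cluster names.
#' @export
nameClusters <- function(chron, early_threshold = 0.20, hosp_threshold = 0.15,
                         short_window = 90L) {
  vapply(chron, function(f) {
    hosp <- 1 - f[, "HOME"]
    early <- seq_len(max(0L, nrow(f) - short_window))
    hospShare <- mean(hosp)
    earlyShare <- if (length(early)) mean(hosp[early]) else 0
    if (earlyShare > early_threshold)
      "early and repeated hospitalizations"
    else if (hospShare > hosp_threshold)
      "acute care during the last 3 months of life"
    else
      "few and late hospitalizations"
  }, character(1))
}
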