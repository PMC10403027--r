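#' Pipeline configuration
#'
#' A single hierarchical configuration drives the whole pipeline; one
#' global `seed` governs every stochastic stage (sub-stage seeds are
#' derived from it by small fixed offsets). Serializable to/from YAML,
#' where the `seed` key is mandatory.
#'
#' @param seed global integer seed (mandatory).
#' @param cohort a [cohortConfig()] (its seed is overridden by `seed`).
#' @param archetypes an [archetypeConfig()] (seed overridden by `seed + 1`).
#' @param costs a [costConfig()] (seed overridden by `seed + 2`).
#' @param cost_scheme a [CostScheme-class] for the sequence dissimilarity.
#' @param sample_size number of patients sampled for the pairwise sequence
#'   analysis (the reference analysis uses 10,000; scale down for demos).
#' @param k fixed number of clusters, or `NA` to select by [selectK()].
#' @param k_min,k_max candidate range for [selectK()].
#' @param ward_variant `"squared"` or `"raw"` (see [wardLinkage()]).
#' @param short_window terminal window in days (default 90).
#' @return a `pipeline_config` list.
#' @export
pipelineConfig <- function(seed = 1L,
                           cohort = cohortConfig(),
                           archetypes = archetypeConfig(),
                           costs = costConfig(),
                           cost_scheme = costScheme(),
                           sample_size = 1000L,
                           k = NA_integer_,
                           k_min = 2L, k_max = 6L,
                           ward_variant = "squared",
                           short_window = 90L) {
  if (is.null(seed) || is.na(seed)) stop("configuration error: seed is mandatory")
  cohort$seed <- as.integer(seed)
  archetypes$seed <- as.integer(seed) + 1L
  costs$seed <- as.integer(seed) + 2L
  structure(list(seed = as.integer(seed), cohort = cohort,
                 archetypes = archetypes, costs = costs,
                 cost_scheme = cost_scheme,
                 sample_size = as.integer(sample_size),
                 k = as.integer(k), k_min = as.integer(k_min),
                 k_max = as.integer(k_max),
                 ward_variant = ward_variant,
                 short_window = as.integer(short_window)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()] and its blocks
#' (`cohort:`, `archetypes:` with `templates` as named lists of
#' `state`/`duration` vectors, `costs:`, `cost_scheme:` with `indel` and
#' `substitution`). Missing keys fall back to the defaults; `seed` must be
#' present.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("configuration error: seed is mandatory in the config file")
  co <- do.call(cohortConfig, utils::modifyList(
    list(), c(y$cohort %||% list())))
  ar <- y$archetypes %||% list()
  if (!is.null(ar$templates))
    ar$templates <- lapply(ar$templates, function(t)
      data.frame(state = t$state, duration = as.integer(t$duration),
                 stringsAsFactors = FALSE))
  ac <- do.call(archetypeConfig, ar)
  cc <- do.call(costConfig, {
    z <- y$costs %||% list()
    if (!is.null(z$per_diem)) z$per_diem <- unlist(z$per_diem)
    if (!is.null(z$ambulatory)) z$ambulatory <- as.data.frame(z$ambulatory)
    z
  })
  cs <- if (is.null(y$cost_scheme)) costScheme() else
    costScheme(y$cost_scheme$indel %||% 1, y$cost_scheme$substitution %||% 2)
  pipelineConfig(seed = y$seed, cohort = co, archetypes = ac, costs = cc,
                 cost_scheme = cs,
                 sample_size = y$sample_size %||% 1000L,
                 k = y$k %||% NA_integer_,
                 k_min = y$k_min %||% 2L, k_max = y$k_max %||% 6L,
                 ward_variant = y$ward_variant %||% "squared",
                 short_window = y$short_window %||% 90L)
}

.configDigest <- function(config) {
  ser <- jsonlite::serializeJSON(config, digits = 12)
  tf <- tempfile()
  writeLines(as.character(ser), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

.writeManifest <- function(out_dir, config, files) {
  paths <- file.path(out_dir, files)
  manifest <- list(
    package = "CarePathways",
    version = as.character(utils::packageVersion("CarePathways")),
    seed = config$seed,
    config_digest = .configDigest(config),
    files = as.list(stats::setNames(unname(tools::md5sum(paths)), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.stage <- function(name, expr) {
  tryCatch(withCallingHandlers(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)),
    error = function(e) stop(conditionMessage(e), call. = FALSE))
}

.ndjson <- function(df, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                             auto_unbox = TRUE, digits = NA,
                                             na = "null")), con)
  invisible(file)
}

#' Run the simulation stage
#'
#' Generates the cohort, the care-state sequences and the claims under the
#' pipeline configuration, and writes the three flat tables (plus the
#' run-length-encoded sequence serialization) and a manifest recording the
#' seed, the package version and the config digest. The ground-truth
#' archetype labels are written to their own file, consumed only by
#' validation code, never by [runAnalyze()].
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
runSimulate <- function(config = pipelineConfig(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- .stage("simulate_cohort", simulateCohort(config$cohort))
  files <- "cohort.csv"
  data.table::fwrite(cohort, file.path(out_dir, "cohort.csv"))
  if (nrow(cohort)) {
    pw <- .stage("simulate_pathways",
                 simulatePathways(cohort, config$archetypes))
    claims <- .stage("simulate_claims",
                     simulateClaims(cohort, pw$sequences, config$costs))
    writeSequences(pw$sequences, file.path(out_dir, "sequences.csv"), "wide")
    writeSequences(pw$sequences, file.path(out_dir, "sequences_rle.csv"), "rle")
    data.table::fwrite(data.frame(patient_id = names(pw$archetype),
                                  true_archetype = unname(pw$archetype)),
                       file.path(out_dir, "ground_truth.csv"))
    data.table::fwrite(claims, file.path(out_dir, "claims.csv"))
    files <- c(files, "sequences.csv", "sequences_rle.csv",
               "ground_truth.csv", "claims.csv")
  } else {
    # empty cohort: write empty downstream tables so the contract holds
    data.table::fwrite(data.frame(patient_id = character(), states = character()),
                       file.path(out_dir, "sequences.csv"))
    data.table::fwrite(data.frame(patient_id = character(),
                                  days_before_death = integer(),
                                  category = character(), cost = numeric()),
                       file.path(out_dir, "claims.csv"))
    files <- c(files, "sequences.csv", "claims.csv")
  }
  invisible(.writeManifest(out_dir, config, files))
}

#' Run the analysis stage
#'
#' Reads the simulated (or externally supplied) tables and executes the
#' full analysis in order: patient sampling, pairwise optimal-matching
#' dissimilarities, Ward linkage, tree cut (fixed `k` or elbow selection),
#' cluster naming, chronograms and index-plot order, cost tables
#' (service-category summary, terminal-window share, top decile,
#' per-cluster costs and shares), cohort descriptives and the
#' cluster-membership odds-ratio model. All outputs are written as
#' delimited text (plus NDJSON for the cost table) with a manifest.
#'
#' @param config a `pipeline_config`.
#' @param in_dir directory holding `cohort.csv`, `sequences.csv`,
#'   `claims.csv`.
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
runAnalyze <- function(config = pipelineConfig(), in_dir, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- .stage("read_inputs", {
    f <- file.path(in_dir, "cohort.csv")
    if (!file.exists(f)) stop("missing input table: ", f)
    as.data.frame(data.table::fread(f))
  })
  seqs <- .stage("read_inputs", readSequences(file.path(in_dir, "sequences.csv")))
  claims <- .stage("read_inputs", {
    as.data.frame(data.table::fread(file.path(in_dir, "claims.csv"),
                                    colClasses = list(character = "patient_id")))
  })
  sample_ids <- .stage("sample",
    samplePatients(seqIds(seqs), config$sample_size, seed = config$seed + 3L))
  sub <- seqs[sample_ids]
  D <- .stage("distances", dissimilarityMatrix(sub, config$cost_scheme))
  writeDissimilarity(D, file.path(out_dir, "dissimilarity.csv"))
  tree <- .stage("linkage", wardLinkage(D, variant = config$ward_variant))
  k <- if (is.na(config$k))
    .stage("select_k", selectK(tree, config$k_min, config$k_max))
  else config$k
  typ <- .stage("cut", cutTypology(tree, k))
  chron <- .stage("chronogram", chronogram(sub, typ))
  clusterNames(typ) <- nameClusters(chron)
  merges <- data.frame(node_a = tree$merge[, 1], node_b = tree$merge[, 2],
                       height = tree$height,
                       new_size = .mergeSizes(tree$merge))
  data.table::fwrite(merges, file.path(out_dir, "tree.csv"))
  data.table::fwrite(data.frame(patient_id = names(clusterLabels(typ)),
                                cluster = unname(clusterLabels(typ)),
                                name = clusterNames(typ)[clusterLabels(typ)]),
                     file.path(out_dir, "typology.csv"))
  long <- do.call(rbind, lapply(seq_along(chron), function(kk) {
    f <- chron[[kk]]
    data.frame(cluster = kk, day = rep(seq_len(nrow(f)), times = ncol(f)),
               state = rep(colnames(f), each = nrow(f)),
               frequency = as.vector(f))
  }))
  data.table::fwrite(long, file.path(out_dir, "chronogram.csv"))
  ord <- indexPlotOrder(sub, typ)
  data.table::fwrite(data.frame(
    cluster = rep(seq_along(ord), lengths(ord)),
    rank = unlist(lapply(ord, seq_along), use.names = FALSE),
    patient_id = unlist(ord, use.names = FALSE)),
    file.path(out_dir, "index_plot_order.csv"))
  # cost analytics on the full cohort
  cost_tab <- .stage("cost_tables", serviceCostTable(claims, cohort))
  data.table::fwrite(cost_tab, file.path(out_dir, "service_cost_table.csv"))
  .ndjson(cost_tab, file.path(out_dir, "service_cost_table.ndjson"))
  totals <- patientTotals(claims, cohort)
  dec <- topDecileSummary(totals)
  share90 <- windowShare(claims, config$short_window)
  jsonlite::write_json(list(window_share = share90,
                            top_decile = dec,
                            n = nrow(cohort)),
                       file.path(out_dir, "spending_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  sample_totals <- totals[sample_ids]
  ccs <- .stage("cluster_costs", clusterCostSummary(typ, sample_totals))
  ccs$cost_share <- clusterCostShare(ccs$n, ccs$mean)
  data.table::fwrite(ccs, file.path(out_dir, "cluster_cost_summary.csv"))
  prof <- .stage("cluster_profile", clusterProfile(typ, cohort))
  data.table::fwrite(prof, file.path(out_dir, "cluster_profile.csv"))
  chars <- .stage("descriptives", characteristicsTable(cohort))
  data.table::fwrite(chars$counts, file.path(out_dir, "characteristics.csv"))
  pod <- placeOfDeathSummary(seqs)
  pal <- palliativeSummary(cohort)
  jsonlite::write_json(list(
    age_mean = chars$age_mean, age_sd = chars$age_sd,
    charlson_mean = chars$charlson_mean, charlson_sd = chars$charlson_sd,
    place_of_death = as.list(pod),
    palliative_overall = pal$overall),
    file.path(out_dir, "descriptives_summary.json"),
    auto_unbox = TRUE, digits = NA)
  # odds ratios for membership in the high-use cluster
  target <- which(clusterNames(typ) == "early and repeated hospitalizations")
  if (!length(target)) target <- which.max(ccs$mean)
  assoc <- tryCatch(
    .stage("association", pathwayAssociation(cohort, typ, target[1])),
    error = function(e) {
      warning(conditionMessage(e))
      data.frame(feature = character(), or = numeric(), ci_low = numeric(),
                 ci_high = numeric(), n = integer())
    })
  data.table::fwrite(assoc, file.path(out_dir, "association.csv"))
  .writeManifest(out_dir, config,
                 c("dissimilarity.csv", "tree.csv", "typology.csv",
                   "chronogram.csv", "index_plot_order.csv",
                   "service_cost_table.csv", "cluster_cost_summary.csv",
                   "cluster_profile.csv", "characteristics.csv",
                   "association.csv"))
  invisible(list(dissimilarity = D, tree = tree, typology = typ,
                 chronogram = chron, cost_table = cost_tab,
                 cluster_costs = ccs, window_share = share90,
                 top_decile = dec, association = assoc))
}

.mergeSizes <- function(merge) {
  sizes <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    a <- merge[i, 1]; b <- merge[i, 2]
    sizes[i] <- (if (a < 0) 1L else sizes[a]) + (if (b < 0) 1L else sizes[b])
  }
  sizes
}

#' Render report tables
#'
#' Reads the analysis outputs and renders display tables with rounding
#' applied only at this layer: whole euros, one-decimal percentages. The
#' service-category table keeps its 11 category rows plus the total row in
#' the published layout (`% users`, `mean (SD)`, `% of total`,
#' `median (IQR)`); cluster cost and profile tables are rendered likewise.
#'
#' @param in_dir directory with [runAnalyze()] outputs.
#' @param out_dir output directory.
#' @return invisibly, the list of rendered data.frames.
#' @export
runReport <- function(in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(f) {
    p <- file.path(in_dir, f)
    if (!file.exists(p)) stop("[stage report] missing analysis output: ", p)
    as.data.frame(data.table::fread(p))
  }
  typ <- need("typology.csv")
  if (nrow(typ) == 0L) stop("[stage report] typology is empty")
  ct <- need("service_cost_table.csv")
  eur <- function(x) formatC(round(x), format = "d", big.mark = ",")
  cost_render <- data.frame(
    service_type = ct$category,
    pct_users = sprintf("%.1f%%", ct$pct_users),
    mean_sd = sprintf("%s (%s)", eur(ct$mean), eur(ct$sd)),
    pct_of_total = sprintf("%.1f", ct$pct_of_total),
    median_iqr = sprintf("%s (%s)", eur(ct$median), eur(ct$iqr))
  )
  data.table::fwrite(cost_render, file.path(out_dir, "table_costs.csv"))
  chars <- need("characteristics.csv")
  chars$pct <- sprintf("%.1f", chars$pct)
  data.table::fwrite(chars, file.path(out_dir, "table_characteristics.csv"))
  ccs <- need("cluster_cost_summary.csv")
  cc_render <- data.frame(
    cluster = ccs$cluster, name = ccs$name, n = ccs$n,
    mean_sd = sprintf("%s (%s)", eur(ccs$mean), eur(ccs$sd)),
    median_iqr = sprintf("%s (%s)", eur(ccs$median), eur(ccs$iqr)),
    pct_of_total_cost = sprintf("%.1f", 100 * ccs$cost_share)
  )
  data.table::fwrite(cc_render, file.path(out_dir, "table_clusters.csv"))
  prof <- need("cluster_profile.csv")
  prof_render <- data.frame(
    cluster = prof$cluster, name = prof$name, n = prof$n,
    age = sprintf("%.1f (%.1f)", prof$age_mean, prof$age_sd),
    pct_female = sprintf("%.1f", prof$pct_female),
    charlson = sprintf("%.1f (%.1f)", prof$charlson_mean, prof$charlson_sd)
  )
  data.table::fwrite(prof_render, file.path(out_dir, "table_cluster_profiles.csv"))
  chron <- need("chronogram.csv")
  data.table::fwrite(chron, file.path(out_dir, "chronogram_plot_data.csv"))
  invisible(list(costs = cost_render, characteristics = chars,
                 clusters = cc_render, profiles = prof_render))
}
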