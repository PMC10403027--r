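euclid <- function(X) as.matrix(stats::dist(X)) |>
  (\(m) { dimnames(m) <- list(rownames(X), rownames(X)); m })()

test_that("two observations produce a single merge of the two leaves", {
  D <- euclid(cbind(c(0, 3)))
  tree <- wardLinkage(D)
  expect_equal(nrow(tree$merge), 1L)
  expect_setequal(tree$merge[1, ], c(-1, -2))
})

test_that("the closest 1-D pair is merged first (SSQ oracle)", {
  X <- cbind(c(0, 0.1, 10))
  tree <- wardLinkage(euclid(X))
  expect_identical(hclust_merge_sets(tree)[[1]], c(1L, 2L))
  expect_identical(oracle_ward_merges(X)[[1]], c(1L, 2L))
})

test_that("greedy merge order equals the exhaustive sum-of-squares oracle", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(3:7, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    tree <- wardLinkage(euclid(X))
    expect_identical(hclust_merge_sets(tree), oracle_ward_merges(X))
    expect_true(all(diff(tree$height) >= -1e-9))  # Ward monotonicity
  }
})

test_that("asymmetric or negative dissimilarities are rejected", {
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(wardLinkage(M), "symmetric")
  M2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(wardLinkage(M2), "non-negative")
})

test_that("cutTypology yields the expected partitions at the extremes", {
  set.seed(22)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  tree <- wardLinkage(euclid(X))
  all_one <- cutTypology(tree, 1)
  expect_identical(unname(clusterLabels(all_one)), rep(1L, 6))
  singletons <- cutTypology(tree, 6)
  expect_identical(sort(unique(clusterLabels(singletons))), 1:6)
  expect_error(cutTypology(tree, 0), "k must lie")
  expect_error(cutTypology(tree, 7), "k must lie")
})

test_that("the 3-point toy tree cuts into {0, 0.1} vs {10} at k = 2", {
  X <- cbind(c(0, 0.1, 10)); rownames(X) <- c("a", "b", "c")
  typ <- cutTypology(wardLinkage(euclid(X)), 2)
  lab <- clusterLabels(typ)
  expect_identical(lab[["a"]], lab[["b"]])
  expect_false(lab[["a"]] == lab[["c"]])
})

test_that("selectK finds well-separated group counts and degenerate defaults", {
  set.seed(23)
  # three tight blobs far apart
  X3 <- rbind(matrix(rnorm(20, 0, .1), 10), matrix(rnorm(20, 10, .1), 10),
              matrix(rnorm(20, 20, .1), 10))
  expect_identical(selectK(wardLinkage(euclid(X3)), 2, 6), 3L)
  X2 <- rbind(matrix(rnorm(20, 0, .1), 10), matrix(rnorm(20, 10, .1), 10))
  expect_identical(selectK(wardLinkage(euclid(X2)), 2, 6), 2L)
  # all identical points: every height 0, fall back to the default
  X0 <- matrix(1, 8, 2)
  expect_identical(selectK(wardLinkage(euclid(X0)), 2, 5), 2L)
  expect_identical(selectK(wardLinkage(euclid(X0)), 2, 5, default = 3), 3L)
})

test_that("clustering is invariant to input permutation", {
  # continuous dissimilarities (no tied merge costs): same partition at
  # every k after permuting the input order
  set.seed(24)
  X <- matrix(rnorm(30 * 2), 30, 2,
              dimnames = list(sprintf("p%02d", 1:30), NULL))
  D <- euclid(X)
  perm <- sample(30)
  for (k in 2:6) {
    a <- clusterLabels(cutTypology(wardLinkage(D), k))
    b <- clusterLabels(cutTypology(wardLinkage(D[perm, perm]), k))[names(a)]
    expect_equal(ari(a, b), 1)
    expect_identical(sort(names(a)), sort(rownames(X)))  # partition of leaves
  }
  # structured sequence data: the k = 3 pathway partition is order-invariant
  co <- simulateCohort(cohortConfig(n_patients = 60, seed = 25))
  pw <- simulatePathways(co, archetypeConfig(per_day_noise = 0.05,
                                             mixture_weights = c(.4, .4, .2),
                                             seed = 26))
  Ds <- dissimilarityMatrix(pw$sequences)
  p2 <- sample(60)
  a <- clusterLabels(cutTypology(wardLinkage(Ds), 3))
  b <- clusterLabels(cutTypology(wardLinkage(Ds[p2, p2]), 3))[names(a)]
  expect_equal(ari(a, b), 1)
})

test_that("chronogram frequencies match hand computation and normalize", {
  # three length-5 sequences in one cluster, hand-tabulated frequencies
  m <- rbind(c("ACUTE", "ACUTE", "HOME", "HOME", "HOME"),
             c("ACUTE", "REHAB", "REHAB", "HOME", "HOME"),
             c("HOME",  "HOME",  "REHAB", "HAH",  "HOME"))
  cs <- CareSequences(m, ids = c("a", "b", "c"))
  typ <- ClusterTypology(stats::setNames(c(1L, 1L, 1L), c("a", "b", "c")), 1)
  ch <- chronogram(cs, typ)[[1]]
  hand <- rbind(c(2, 0, 0, 0, 1), c(1, 1, 0, 0, 1), c(0, 2, 0, 0, 1),
                c(0, 0, 1, 0, 2), c(0, 0, 0, 0, 3)) / 3
  colnames(hand) <- careStates()
  expect_equal(ch, hand)
  expect_equal(rowSums(ch), rep(1, 5))

  home <- CareSequences(matrix("HOME", 4, 6), ids = letters[1:4])
  th <- ClusterTypology(stats::setNames(rep(1L, 4), letters[1:4]), 1)
  expect_equal(chronogram(home, th)[[1]][, "HOME"], rep(1, 6))
})

test_that("index-plot order applies the first-day/total/id rule", {
  m <- rbind(c("HOME", "HOME", "HOME", "HOME"),   # never hospitalized
             c("HOME", "ACUTE", "ACUTE", "HOME"), # first day 2, 2 days
             c("ACUTE", "HOME", "HOME", "HOME"),  # first day 1, 1 day
             c("ACUTE", "ACUTE", "HOME", "HOME")) # first day 1, 2 days
  cs <- CareSequences(m, ids = c("d", "c", "b", "a"))
  typ <- ClusterTypology(stats::setNames(rep(1L, 4), c("d", "c", "b", "a")), 1)
  expect_identical(indexPlotOrder(cs, typ)[[1]], c("b", "a", "c", "d"))

  # identical sequences tie-break on patient id
  twin <- CareSequences(rbind(m[2, ], m[2, ]), ids = c("z", "y"))
  tt <- ClusterTypology(stats::setNames(c(1L, 1L), c("z", "y")), 1)
  expect_identical(indexPlotOrder(twin, tt)[[1]], c("y", "z"))
})

test_that("clusterProfile reproduces hand-computed summaries", {
  cohort <- data.frame(
    patient_id = paste0("p", 1:6),
    sex = c("female", "male", "female", "female", "male", "male"),
    age_at_death = c(80, 70, 90, 60, 75, 85),
    charlson_score = c(2L, 5L, 0L, 8L, 3L, 6L))
  lab <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), cohort$patient_id)
  typ <- ClusterTypology(lab, 2)
  prof <- clusterProfile(typ, cohort)
  expect_equal(prof$n, c(3L, 3L))
  expect_equal(prof$age_mean, c(80, 220 / 3))
  expect_equal(prof$age_sd[1], sd(c(80, 70, 90)))
  expect_equal(prof$pct_female, c(200 / 3, 100 / 3))
  expect_equal(prof$charlson_mean, c(7 / 3, 17 / 3))

  # single cluster equals the whole-cohort summary; singleton has SD 0
  one <- clusterProfile(ClusterTypology(stats::setNames(rep(1L, 6),
                                                        cohort$patient_id), 1),
                        cohort)
  expect_equal(one$age_mean, mean(cohort$age_at_death))
  single <- clusterProfile(
    ClusterTypology(stats::setNames(c(1L, rep(2L, 5)), cohort$patient_id), 2),
    cohort)
  expect_equal(single$age_sd[1], 0)
})

test_that("cluster naming maps chronogram features to the three narratives", {
  arcs <- defaultArchetypes()
  cfg <- archetypeConfig(per_day_noise = 0, hospital_death_fraction = NA,
                         mixture_weights = c(1, 1, 1) / 3, seed = 9)
  cohort <- simulateCohort(cohortConfig(n_patients = 60, seed = 9))
  pw <- simulatePathways(cohort, cfg)
  typ <- ClusterTypology(pw$archetype, 3)
  nm <- nameClusters(chronogram(pw$sequences, typ))
  expect_identical(unname(nm),
                   c("few and late hospitalizations",
                     "acute care during the last 3 months of life",
                     "early and repeated hospitalizations"))
})
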