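empty_claims <- function() {
  data.frame(patient_id = character(), days_before_death = integer(),
             category = character(), cost = numeric())
}

fixture_claims <- function() {
  # 3 patients: p1 mixed spending, p2 hospital-heavy, p3 no claims at all
  data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    days_before_death = c(300L, 45L, 10L, 100L, 20L),
    category = c("pharmacy", "acute_hospital", "pharmacy",
                 "acute_hospital", "rehabilitation"),
    cost = c(100, 2000, 50, 5000, 1200))
}

fixture_cohort <- data.frame(patient_id = c("p1", "p2", "p3"))

test_that("serviceCostTable matches hand computation on a small fixture", {
  tab <- serviceCostTable(fixture_claims(), fixture_cohort)
  expect_equal(nrow(tab), 12L)
  expect_equal(attr(tab, "n"), 3L)
  ph <- tab[tab$category == "pharmacy", ]
  # per-patient pharmacy totals: 150, 0, 0
  expect_equal(ph$mean, 50)
  expect_equal(ph$pct_users, 100 / 3)
  expect_equal(ph$median, 0)  # zero-claim patient pulls the median down
  ac <- tab[tab$category == "acute_hospital", ]
  expect_equal(ac$mean, 7000 / 3)
  expect_equal(ac$sd, sd(c(2000, 5000, 0)))
  tot <- tab[tab$category == "total", ]
  # grand totals 2150, 6200, 0
  expect_equal(tot$mean, 8350 / 3)
  expect_equal(tot$median, 2150)
  expect_equal(tot$pct_users, 200 / 3)
  o <- oracle_summary(c(2150, 6200, 0))
  expect_equal(tot$sd, o$sd)
  expect_equal(tot$iqr, o$iqr)
  # additivity: category means sum exactly to the total mean
  expect_equal(sum(tab$mean[tab$category != "total"]), tot$mean)
  expect_equal(sum(tab$pct_of_total[tab$category != "total"]), 100)
})

test_that("windows restrict the table and empty claims give all-zero rows", {
  tab90 <- serviceCostTable(fixture_claims(), fixture_cohort, window_days = 90)
  # only claims with days_before_death < 90: p1 2000+50, p2 1200
  expect_equal(tab90$mean[tab90$category == "total"], 3250 / 3)
  tab0 <- serviceCostTable(empty_claims(), fixture_cohort)
  expect_true(all(tab0$mean == 0) && all(tab0$pct_users == 0) &&
                all(tab0$median == 0))
  expect_error(serviceCostTable(
    data.frame(patient_id = "ghost", days_before_death = 1L,
               category = "pharmacy", cost = 1), fixture_cohort), "absent")
})

test_that("windowShare follows its analytic cases and is monotone", {
  cl <- fixture_claims()
  late <- cl[cl$days_before_death < 90, ]
  expect_equal(windowShare(late, 90), 1)
  # constant daily spend: share = 90/365
  daily <- data.frame(patient_id = "p1", days_before_death = 0:364,
                      category = "pharmacy", cost = 1)
  expect_equal(windowShare(daily, 90), 90 / 365)
  expect_equal(windowShare(empty_claims(), 90), 0)
  shares <- vapply(c(1, 30, 90, 180, 365), function(w) windowShare(daily, w),
                   numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[length(shares)], 1)
})

test_that("top-decile count, threshold and share follow the ranking rules", {
  s <- topDecileSummary(rep(5, 10))
  expect_identical(s$count, 1L)
  expect_equal(s$share, 0.1)
  s20 <- topDecileSummary(stats::setNames(1:20, sprintf("p%02d", 1:20)))
  expect_identical(s20$count, 2L)
  expect_equal(s20$threshold, 19)
  expect_equal(s20$share, (19 + 20) / 210)
  expect_error(topDecileSummary(numeric(0)), "empty")
  # count convention N - floor(0.9 N), property over a range of N
  set.seed(55)
  for (N in c(1:25, sample(26:10000, 60))) {
    expect_identical(topDecileSummary(rep(1, N))$count,
                     as.integer(N - floor(0.9 * N)))
  }
})

test_that("per-cluster cost summaries are exact", {
  totals <- stats::setNames(c(10, 20, 30, 100, 200, 300, 1000, 2000, 4000),
                            paste0("p", 1:9))
  typ <- ClusterTypology(stats::setNames(rep(1:3, each = 3), paste0("p", 1:9)), 3)
  cc <- clusterCostSummary(typ, totals)
  expect_equal(cc$mean, c(20, 200, 7000 / 3))
  expect_equal(cc$median, c(20, 200, 2000))
  expect_equal(cc$sd, c(10, 100, sd(c(1000, 2000, 4000))))
  expect_equal(cc$iqr[1], oracle_summary(c(10, 20, 30))$iqr)
  # degenerate inputs
  one <- ClusterTypology(stats::setNames(1:2, c("p1", "p2")), 2)
  cc1 <- clusterCostSummary(one, totals[1:2])
  expect_equal(cc1$sd, c(0, 0))
  flat <- clusterCostSummary(typ, stats::setNames(rep(7, 9), paste0("p", 1:9)))
  expect_true(all(flat$sd == 0) && all(flat$iqr == 0))
})

test_that("cluster cost shares reproduce the published ratios", {
  ref <- referenceClusters()
  dem <- ref[ref$disease == "dementia", ]
  sh <- clusterCostShare(dem$n, dem$mean)
  expect_equal(round(100 * sh[3], 1), 17.5)
  expect_equal(round(100 * dem$n[1] / sum(dem$n)), 67)  # cluster-1 population share
  cold <- ref[ref$disease == "cold", ]
  expect_equal(round(100 * clusterCostShare(cold$n, cold$mean)[2]), 34)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(clusterCostShare(c(3, 3, 3), c(5, 5, 5)), rep(1 / 3, 3))
  expect_error(clusterCostShare(c(1, 1), c(0, 0)), "zero")
})

test_that("patientTotals includes zero-spend patients and respects windows", {
  tot <- patientTotals(fixture_claims(), fixture_cohort)
  expect_equal(unname(tot), c(2150, 6200, 0))
  tot90 <- patientTotals(fixture_claims(), fixture_cohort, window_days = 90)
  expect_equal(unname(tot90), c(2050, 1200, 0))
})
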