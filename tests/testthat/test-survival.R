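test_that("median split stratifies deterministically with ties low", {
  rec <- data.frame(predictor = 1:64)
  sp <- medianSplit(rec)
  expect_equal(nrow(sp$low), 32L)
  expect_equal(nrow(sp$high), 32L)

  rec2 <- data.frame(predictor = c(0, 0, 5, 9))
  sp2 <- medianSplit(rec2)
  expect_equal(sp2$median, 2.5)
  expect_equal(sp2$low$predictor, c(0, 0))
  expect_equal(sp2$high$predictor, c(5, 9))

  rec3 <- data.frame(predictor = c(1, 2, 2, 2, 9))  # median value tied
  sp3 <- medianSplit(rec3)
  expect_equal(nrow(sp3$low), 4L)   # ties at the median go low
  expect_error(medianSplit(data.frame(predictor = rep(3, 5))),
               "identical")
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # no events: survival identically 1
  km0 <- kaplanMeier(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # 4 subjects, all events: S = 3/4, 1/2, 1/4, 0
  km1 <- kaplanMeier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km1$survival, c(0.75, 0.5, 0.25, 0))

  # heavy censoring life table worked by hand:
  # t=1: 6 at risk, 1 event -> 5/6; t=2: 4 at risk, 1 event -> 0.625;
  # t=3: 3 at risk, 1 event -> 0.41667; censoring afterwards flat
  km2 <- kaplanMeier(c(1, 1, 2, 3, 3, 5), c(1, 0, 1, 0, 1, 0))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$time, c(1, 2, 3))
  expect_equal(ev$survival, c(5 / 6, 0.625, 5 / 12))
  expect_true(!is.unsorted(rev(km2$survival)))
  expect_lte(max(km2$survival), 1)
})

test_that("log-rank matches manual observed-minus-expected arithmetic", {
  # identical groups: statistic 0, p 1
  tm <- c(2, 4, 6, 2, 4, 6); ev <- c(1, 1, 0, 1, 1, 0)
  g <- rep(c("a", "b"), each = 3)
  lr0 <- logrankTest(tm, ev, g)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 6-subject example, frozen from manual O-E computation
  tA <- c(1, 2, 4); eA <- c(1, 1, 0)
  tB <- c(3, 5, 6); eB <- c(1, 1, 1)
  lr <- logrankTest(c(tA, tB), c(eA, eB), rep(1:2, each = 3))
  expect_equal(lr$chisq, 1.0664206642, tolerance = 1e-9)
  expect_equal(lr$p, 0.3017553348, tolerance = 1e-9)
  expect_equal(lr$chisq,
               logrankOracle(c(tA, tB), c(eA, eB), rep(1:2, each = 3)))

  # group relabeling leaves the statistic unchanged; p in (0, 1]
  lrSwap <- logrankTest(c(tB, tA), c(eB, eA), rep(1:2, each = 3))
  expect_equal(lrSwap$chisq, lr$chisq)
  expect_gt(lr$p, 0); expect_lte(lr$p, 1)

  expect_error(logrankTest(c(1, 2), c(0, 0), c(1, 2)), "events")
  expect_error(logrankTest(1:3, c(1, 1, 1), c(1, 1, 1)), "2 groups")
})

test_that("AUC equals brute-force pairwise concordance, ties by midrank", {
  # perfect separation
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12),
                      c(0, 0, 0, 1, 1, 1))$auc, 1)
  # 8-record toy set with ties
  pred <- c(3, 5, 5, 7, 2, 5, 9, 7)
  out <- c(0, 0, 1, 1, 0, 1, 1, 0)
  res <- rocAuc(pred, out)
  expect_equal(res$auc, aucOracle(pred, out))
  # ROC endpoints
  expect_equal(min(res$roc$fpr), 0)
  expect_equal(max(res$roc$tpr), 1)

  # invariance under strictly monotone transform
  expect_equal(rocAuc(exp(pred), out)$auc, res$auc)
  expect_equal(rocAuc(rank(pred, ties.method = "average"), out)$auc,
               res$auc)

  # independent predictor: AUC near 1/2 at large n
  set.seed(14)
  p <- runif(4000); o <- rbinom(4000, 1, 0.4)
  expect_lt(abs(rocAuc(p, o)$auc - 0.5), 0.03)

  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("KM with no censoring equals the empirical survivor function", {
  set.seed(33)
  tm <- sample(1:50, 20, replace = TRUE)
  km <- kaplanMeier(tm, rep(1, 20))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(tm > km$time[i]))
})

test_that("median-split log-rank detects burden-driven hazard", {
  # hazard increasing with true MATV: a majority of cohorts reject
  rej <- logical(60)
  for (i in seq_along(rej)) {
    co <- generateCohort(n = 64, seed = 5000 + i, beta = 0.5)
    rec <- data.frame(months = co$survival$months,
                      event = co$survival$event,
                      predictor = co$patients$true_matv_ml)
    sa <- survivalAssociation(rec)
    rej[i] <- sa$logrank$p < 0.05
  }
  expect_gt(mean(rej), 0.5)
})

test_that("the full survival association report is coherent", {
  co <- generateCohort(n = 64, seed = 77, beta = 0.5)
  rec <- data.frame(months = co$survival$months,
                    event = co$survival$event,
                    predictor = co$patients$true_matv_ml)
  sa <- survivalAssociation(rec)
  expect_equal(nrow(sa$km_low) + nrow(sa$km_high), length(unique(
    c(sa$km_low$time, sa$km_high$time))) +
    sum(duplicated(c(sa$km_low$time, sa$km_high$time))))
  expect_gte(sa$auc, 0); expect_lte(sa$auc, 1)
  expect_equal(sa$auc, aucOracle(rec$predictor, rec$event))
  expect_gt(sa$logrank$p, 0); expect_lte(sa$logrank$p, 1)
})
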