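# Behavioral clocks, aging rates, lifespan forecasting, survival
# comparison, and differential usage.

# synthetic factor series with a monotone age -> factor mapping
monotoneSeries <- function(nAnimals = 8, noiseSd = 0, seed = 2, R = 5) {
  set.seed(seed)
  rows <- lapply(seq_len(nAnimals), function(i) {
    L <- sample(100:200, 1)
    ages <- seq(5, L, by = 5)
    f <- outer(ages, seq_len(R), function(a, r) (a / 200)^r) +
      matrix(rnorm(length(ages) * R, 0, noiseSd), length(ages), R)
    list(f = abs(f), id = sprintf("f%02d", i), ages = ages, L = L)
  })
  ageFactorSeries(
    do.call(rbind, lapply(rows, `[[`, "f")),
    unlist(lapply(rows, function(r) rep(r$id, length(r$ages)))),
    unlist(lapply(rows, `[[`, "ages")),
    stats::setNames(vapply(rows, `[[`, numeric(1), "L"),
                    vapply(rows, `[[`, character(1), "id")))
}

test_that("trajectory PCA: fan-out variance and completeness", {
  # identical animals: zero across-animal variance at every age
  ages <- seq(10, 100, by = 10)
  f <- outer(ages, 1:4, function(a, r) a / (10 * r))
  ser <- ageFactorSeries(rbind(f, f),
                         rep(c("a", "b"), each = length(ages)),
                         rep(ages, 2), c(a = 100, b = 100))
  tp <- trajectoryPCA(ser, nPcs = 2, smoothingSd = 0)
  expect_true(all(tp$varianceByAge$variance == 0))

  # when all components are retained the scores reproduce the z-scored data
  set.seed(4)
  f2 <- matrix(abs(rnorm(60 * 3)), 60, 3)
  ser2 <- ageFactorSeries(f2, rep(c("a", "b", "c"), each = 20),
                          rep(1:20, 3), c(a = 20, b = 20, c = 20))
  tp2 <- trajectoryPCA(ser2, nPcs = 3, smoothingSd = 0)
  z <- behaviorome:::zscoreCols(f2)
  pc <- stats::prcomp(z, center = FALSE)
  recon <- as.matrix(tp2$scores[, c("PC1", "PC2", "PC3")]) %*% t(pc$rotation)
  expect_equal(unname(recon), unname(z[, , drop = FALSE]), tolerance = 1e-8)
  expect_equal(sum(tp2$explainedVar), 1, tolerance = 1e-8)

  # diverging groups: across-animal variance grows with age
  ages3 <- 1:80
  up <- outer(ages3, 1:3, function(a, r) 1 + a / 80 * r)
  down <- matrix(1, 80, 3)
  ser3 <- ageFactorSeries(abs(rbind(up, down)),
                          rep(c("u", "d"), each = 80), rep(ages3, 2),
                          c(u = 80, d = 80))
  v <- trajectoryPCA(ser3, nPcs = 2)$varianceByAge
  expect_gt(stats::cor(v$age, v$variance), 0.9)
})

test_that("behavior clock recovers a noiseless monotone mapping", {
  ser <- monotoneSeries(noiseSd = 0)
  ck <- fitBehaviorClock(ser, nTrees = 60, seed = 1)
  expect_gt(ck$pearsonR, 0.99)
  expect_true(all(ck$importance >= 0))
  expect_equal(sum(ck$importance), 1, tolerance = 1e-9)
  # leakage freedom, asserted structurally: the held-out animal is never in
  # its own training set
  for (a in names(ck$trainAnimals))
    expect_false(a %in% ck$trainAnimals[[a]])
  # MAE grows with noise (clock calibration property)
  maeAt <- function(sd_) {
    s <- monotoneSeries(noiseSd = sd_, seed = 3)
    p <- fitBehaviorClock(s, nTrees = 40, seed = 1)$predictions
    stats::median(abs(p$estimate - p$age))
  }
  maes <- vapply(c(0, 0.05, 0.2), maeAt, numeric(1))
  expect_true(all(diff(maes) > 0))
})

test_that("clock on age-independent factors carries no signal", {
  set.seed(9)
  nA <- 6
  ages <- seq(10, 150, by = 10)
  f <- matrix(abs(rnorm(nA * length(ages) * 4)), nA * length(ages), 4)
  ser <- ageFactorSeries(f, rep(sprintf("n%02d", 1:nA), each = length(ages)),
                         rep(ages, nA),
                         stats::setNames(rep(150, nA), sprintf("n%02d", 1:nA)))
  ck <- fitBehaviorClock(ser, nTrees = 40, seed = 2)
  expect_lt(abs(ck$pearsonR), 0.3)
  # predictions concentrate near the training-age mean
  expect_lt(abs(mean(ck$predictions$estimate) - mean(ages)), 15)
})

test_that("aging rate slopes and group comparison", {
  # construct a ClockResult directly: slope semantics are exact
  preds <- rbind(
    data.frame(animal = "a", age = 1:10, estimate = 1:10),
    data.frame(animal = "b", age = 1:10, estimate = 0.5 * (1:10) + 3))
  ck <- structure(list(predictions = preds), class = "ClockResult")
  ar <- agingRate(ck)
  expect_equal(ar$slopes$slope[ar$slopes$animal == "a"], 1)
  expect_equal(ar$slopes$slope[ar$slopes$animal == "b"], 0.5)

  # a time-dilated (2x slower) group halves the fitted slope and the
  # rank test detects it
  mk <- function(id, dilate) {
    ages <- seq(10, 120, by = 10)
    data.frame(animal = id, age = ages, estimate = ages / dilate +
                 rnorm(length(ages), 0, 1))
  }
  set.seed(5)
  preds2 <- do.call(rbind, c(lapply(sprintf("n%d", 1:5), mk, dilate = 1),
                             lapply(sprintf("s%d", 1:5), mk, dilate = 2)))
  ck2 <- structure(list(predictions = preds2), class = "ClockResult")
  groups <- stats::setNames(rep(c("normal", "slow"), each = 5),
                            c(sprintf("n%d", 1:5), sprintf("s%d", 1:5)))
  ar2 <- agingRate(ck2, groups)
  g <- groups[ar2$slopes$animal]
  ratio <- mean(ar2$slopes$slope[g == "slow"]) /
    mean(ar2$slopes$slope[g == "normal"])
  expect_equal(ratio, 0.5, tolerance = 0.1)
  expect_lt(ar2$test$p.value, 0.05)
})

forecastSeries <- function(sepShift, seed = 3, nPerGroup = 10) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(2 * nPerGroup))
  ls <- stats::setNames(c(rep(150, nPerGroup), rep(250, nPerGroup)), ids)
  ages <- 61:70
  f <- matrix(abs(rnorm(length(ids) * length(ages) * 3)),
              length(ids) * length(ages), 3)
  long <- rep(ls >= 200, each = length(ages))
  f[long, 1] <- f[long, 1] + sepShift
  ageFactorSeries(f, rep(ids, each = length(ages)),
                  rep(ages, length(ids)), ls)
}

test_that("lifespan forecasting: labels, separability, permutation null", {
  ser <- forecastSeries(sepShift = 10)
  fc <- forecastLifespan(ser, predictionAge = 70, nTrees = 60, seed = 2)
  expect_equal(fc$auc, 1)
  expect_gte(fc$accuracy, 0.95)
  expect_lt(fc$survival$p, 0.01)

  # an animal living exactly 200 days is long-lived
  expect_true(all(fc$predicted$label[fc$predicted$lifespan == 250]))
  ser200 <- forecastSeries(sepShift = 10)
  ser200$lifespans[1] <- 200
  fc200 <- forecastLifespan(ser200, predictionAge = 70, nTrees = 20,
                            seed = 2)
  expect_true(fc200$predicted$label[fc200$predicted$animal ==
                                      names(ser200$lifespans)[1]])

  # extreme agers (> 300 d) are excluded
  serX <- forecastSeries(sepShift = 10)
  serX$lifespans[20] <- 320
  fcX <- forecastLifespan(serX, predictionAge = 70, nTrees = 20, seed = 2)
  expect_false(names(serX$lifespans)[20] %in% fcX$predicted$animal)

  # labels shuffled: AUC near the chance level
  serNull <- forecastSeries(sepShift = 0, seed = 8)
  fcN <- forecastLifespan(serNull, predictionAge = 70, nTrees = 40,
                          seed = 3)
  expect_gt(fcN$auc, 0.2)
  expect_lt(fcN$auc, 0.8)

  # feature-scaling invariance: z-scoring inside the folds makes rescaled
  # inputs give identical predictions
  serS <- forecastSeries(sepShift = 10)
  serS$factors <- serS$factors * 37
  fcS <- forecastLifespan(serS, predictionAge = 70, nTrees = 60, seed = 2)
  expect_equal(fcS$predicted$score, fc$predicted$score, tolerance = 1e-10)
})

test_that("survival comparison matches hand-worked log-rank tables", {
  # toy groups {2,4,6} vs {8,10,12}: O_A = 3, E_A = 1.15, V = 0.6775
  sv <- survivalCompare(c(2, 4, 6, 8, 10, 12), rep(TRUE, 6),
                        rep(c("A", "B"), each = 3))
  expect_equal(sv$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-10)
  expect_equal(sv$p, 1 - stats::pchisq((3 - 1.15)^2 / 0.6775, 1),
               tolerance = 1e-10)

  # identical groups: statistic 0, p = 1
  sv0 <- survivalCompare(rep(c(3, 5, 9), 2), rep(TRUE, 6),
                         rep(c("A", "B"), 3))
  expect_equal(sv0$chisq, 0, tolerance = 1e-12)
  expect_equal(sv0$p, 1)

  # no censoring: KM equals the empirical survival function, so the KM
  # median equals the sample median
  times <- c(10, 20, 30, 40, 50)
  fit <- survivalCompare(times, rep(TRUE, 5), rep("A", 5))$fit
  expect_equal(unname(summary(fit)$table["median"]), 30)
  km <- summary(fit, times = times)$surv
  emp <- 1 - seq_along(times) / length(times)
  expect_equal(km, emp, tolerance = 1e-12)

  # all censored: test undefined, reported as such
  expect_message(svc <- survivalCompare(c(5, 6, 7, 8), rep(FALSE, 4),
                                        rep(c("A", "B"), 2)), "censored")
  expect_true(is.na(svc$p))
})

test_that("differential usage: specificity, sensitivity, Bonferroni", {
  set.seed(12)
  ids <- sprintf("d%02d", 1:12)
  ls <- stats::setNames(rep(100, 12), ids)
  groups <- stats::setNames(rep(c("x", "y"), each = 6), ids)
  ages <- c(50, 60)
  R <- 6
  mkFac <- function(shift1) {
    f <- matrix(abs(rnorm(12 * 2 * R)), 24, R)
    rows <- rep(groups == "x", each = 2)
    f[rows, 1] <- f[rows, 1] + shift1
    f
  }
  # identical groups over replicates: type-I controlled after correction
  falseHits <- 0
  for (rep_ in 1:10) {
    f <- mkFac(0)
    ser <- ageFactorSeries(f, rep(ids, each = 2), rep(ages, 12), ls)
    du <- differentialUsage(ser, groups)
    falseHits <- falseHits + sum(du$pAdjusted < 0.05)
  }
  expect_lte(falseHits, 2)

  # one factor shifted by ~5 pooled SDs: it and only it is significant
  f <- mkFac(5)
  ser <- ageFactorSeries(f, rep(ids, each = 2), rep(ages, 12), ls)
  du <- differentialUsage(ser, groups)
  sig <- unique(du$factor[du$pAdjusted < 0.05])
  expect_identical(sig, "factor1")

  # Bonferroni arithmetic: adjusted p = min(1, m * p) with m = factors/age
  expect_equal(du$pAdjusted, pmin(1, du$p * R))
})
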