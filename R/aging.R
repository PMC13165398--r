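# Aging analyses built on the per-animal-day age factors: trajectory PCA,
# leave-one-fish-out behavioral clocks, per-animal aging rates, age-fixed
# lifespan forecasting, survival comparison of predicted groups, and
# differential factor usage between groups.

#' Bundle age factors with animal metadata
#'
#' @param factors animal-days x R matrix of non-negative age-factor weights
#'   (third CP mode).
#' @param animal character vector, one id per row.
#' @param age numeric age in days, one per row.
#' @param lifespans named numeric vector of lifespans (days) per animal.
#' @param censored named logical vector; TRUE when the animal was removed
#'   before natural death (right-censoring). Defaults to all FALSE.
#' @param group optional named character vector of group labels per animal.
#' @return a list of class `AgeFactorSeries`.
#' @export
ageFactorSeries <- function(factors, animal, age, lifespans,
                            censored = NULL, group = NULL) {
  factors <- as.matrix(factors)
  stopifnot(nrow(factors) == length(animal), length(age) == length(animal))
  ids <- unique(animal)
  stopifnot(all(ids %in% names(lifespans)))
  if (is.null(censored))
    censored <- stats::setNames(rep(FALSE, length(ids)), ids)
  bad <- vapply(ids, function(a) {
    ag <- age[animal == a]
    any(ag <= 0) || any(ag > lifespans[a])
  }, logical(1))
  if (any(bad)) stop("ages must lie in (0, lifespan] for every animal")
  structure(list(factors = factors, animal = as.character(animal),
                 age = as.numeric(age), lifespans = lifespans,
                 censored = censored, group = group),
            class = "AgeFactorSeries")
}

#' Build an AgeFactorSeries from a CP model and its usage tensor
#'
#' @param model a [CPModel-class] fitted to `tensor`.
#' @param tensor the [UsageTensor-class] the model was fitted to.
#' @param lifespans named lifespans per animal (days).
#' @param censored,group passed to [ageFactorSeries()].
#' @export
ageFactorSeriesFromCP <- function(model, tensor, lifespans, censored = NULL,
                                  group = NULL) {
  ad <- animalDays(tensor)
  ageFactorSeries(ageFactors(model), ad$animal, ad$age, lifespans,
                  censored = censored, group = group)
}

#' Aging trajectories: PCA of z-scored age factors
#'
#' Age factors are z-scored over all animal-days and projected on the top
#' `nPcs` principal components; per-animal trajectories are optionally
#' Gaussian-smoothed along age. Also reports the across-animal variance at
#' each age, summed over all factors — the trajectory fan-out measure.
#'
#' @param series an [ageFactorSeries()].
#' @param nPcs retained components (default 3).
#' @param smoothingSd Gaussian smoothing SD along age, in days (0 = none).
#' @return list with `scores` (data.frame animal, age, PCs),
#'   `trajectories` (per-animal smoothed score matrices),
#'   `explainedVar`, and `varianceByAge` (data.frame age, variance).
#' @export
trajectoryPCA <- function(series, nPcs = 3L, smoothingSd = 2) {
  X <- series$factors
  if (nrow(X) < nPcs) stop("fewer animal-days than requested components")
  z <- zscoreCols(X)
  nPcs <- min(nPcs, ncol(z))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  sc <- pc$x[, seq_len(nPcs), drop = FALSE]
  scores <- data.frame(animal = series$animal, age = series$age, sc)
  trajectories <- lapply(split(seq_len(nrow(sc)), series$animal), function(i) {
    o <- i[order(series$age[i])]
    m <- sc[o, , drop = FALSE]
    if (smoothingSd > 0 && nrow(m) > 2)
      m <- apply(m, 2, gaussSmooth1d, sigma = smoothingSd)
    rownames(m) <- series$age[o]
    m
  })
  ages <- sort(unique(series$age))
  varByAge <- vapply(ages, function(a) {
    rows <- series$age == a
    if (sum(rows) < 2) return(NA_real_)
    sum(apply(X[rows, , drop = FALSE], 2, stats::var))
  }, numeric(1))
  list(scores = scores, trajectories = trajectories,
       explainedVar = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nPcs)],
       varianceByAge = data.frame(age = ages, variance = varByAge))
}

#' Leave-one-fish-out behavioral clock
#'
#' For each animal, an ensemble-of-trees regressor is trained on all other
#' animals' (age factors, age) pairs and used to estimate the held-out
#' animal's age for every recorded day — so no prediction is ever made by a
#' model that saw any day of that animal. Reports the pooled Pearson
#' correlation of estimated versus true age, the per-age median absolute
#' error across animals, and mean-decrease-in-impurity feature importances
#' from a model trained on all animals.
#'
#' @param series an [ageFactorSeries()].
#' @param nTrees trees per forest (500 reproduces full-scale runs; smaller
#'   values keep desk-scale runs fast).
#' @param seed RNG seed.
#' @return list of class `ClockResult`: `predictions` (animal, age,
#'   estimate), `pearsonR`, `maeByAge`, `importance` (non-negative, sums to
#'   1), `trainAnimals` (per-fold training sets, for leakage audits).
#' @export
fitBehaviorClock <- function(series, nTrees = 100L, seed = 1L) {
  ids <- unique(series$animal)
  if (length(ids) < 3) stop("need at least 3 animals")
  preds <- vector("list", length(ids))
  trainAnimals <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    a <- ids[i]
    tr <- series$animal != a
    te <- !tr
    if (!any(te)) { warning("animal ", a, " has no days; skipped"); next }
    trainAnimals[[a]] <- setdiff(ids, a)
    f <- bagForest(series$factors[tr, , drop = FALSE], series$age[tr],
                   nTrees = nTrees, seed = seed + i)
    preds[[i]] <- data.frame(animal = a, age = series$age[te],
                             estimate = predictForest(
                               f, series$factors[te, , drop = FALSE]))
  }
  predictions <- do.call(rbind, preds)
  r <- stats::cor(predictions$age, predictions$estimate)
  err <- abs(predictions$estimate - predictions$age)
  maeByAge <- stats::aggregate(err, list(age = predictions$age),
                               stats::median)
  names(maeByAge)[2] <- "medianAbsError"
  full <- bagForest(series$factors, series$age, nTrees = nTrees, seed = seed)
  imp <- full$importance
  names(imp) <- colnames(series$factors)
  structure(list(predictions = predictions, pearsonR = r,
                 maeByAge = maeByAge, importance = imp,
                 trainAnimals = trainAnimals,
                 meta = list(nTrees = nTrees, seed = seed)),
            class = "ClockResult")
}

#' Per-animal aging rate from clock predictions
#'
#' Ordinary least-squares slope of estimated versus true age per animal; a
#' slope below 1 reads as slowed behavioral aging. When two groups are
#' given, slopes are compared by a two-sided Mann-Whitney (Wilcoxon rank
#' sum) test.
#'
#' @param clock a `ClockResult` from [fitBehaviorClock()].
#' @param groups optional named character vector mapping animals to two
#'   groups.
#' @return list with `slopes` (data.frame animal, slope, nDays) and, when
#'   groups are supplied, `test` (the wilcox.test result).
#' @export
agingRate <- function(clock, groups = NULL) {
  sp <- split(clock$predictions, clock$predictions$animal)
  slopes <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) < 2)
      return(data.frame(animal = d$animal[1], slope = NA_real_,
                        nDays = nrow(d)))
    fit <- stats::lm(estimate ~ age, data = d)
    data.frame(animal = d$animal[1], slope = unname(stats::coef(fit)[2]),
               nDays = nrow(d))
  }))
  rownames(slopes) <- NULL
  out <- list(slopes = slopes)
  if (!is.null(groups)) {
    g <- groups[slopes$animal]
    lv <- unique(stats::na.omit(g))
    stopifnot(length(lv) == 2)
    out$test <- stats::wilcox.test(slopes$slope[g == lv[1]],
                                   slopes$slope[g == lv[2]], exact = FALSE)
  }
  out
}

#' Age-fixed lifespan forecast
#'
#' Classifies animals as short- or long-lived at a fixed prediction age.
#' Features are the mean age factors over the window of ages in
#' (predictionAge - window, predictionAge], z-scored by the training
#' statistics of each fold. Animals are long-lived when lifespan >=
#' `threshold` (200 days); extreme agers (> `excludeAbove`, 300 days) are
#' excluded, as are animals dead before the prediction age or without a
#' recorded day in the window. Predictions are leave-one-fish-out.
#'
#' @param series an [ageFactorSeries()].
#' @param predictionAge age (days) at which the forecast is made.
#' @param window width of the trailing feature window, days.
#' @param threshold long-lived lifespan cutoff, days (inclusive).
#' @param excludeAbove lifespan above which animals are excluded, days.
#' @param nTrees trees per forest.
#' @param seed RNG seed.
#' @return list of class `LifespanForecast`: per-animal `predicted`
#'   data.frame (animal, lifespan, label, score, predictedLabel),
#'   `accuracy`, `auc`, `survival` (Kaplan-Meier + log-rank comparison of
#'   the predicted groups), `predictionAge`.
#' @export
forecastLifespan <- function(series, predictionAge, window = 5,
                             threshold = 200, excludeAbove = 300,
                             nTrees = 100L, seed = 1L) {
  ids <- unique(series$animal)
  rows <- lapply(ids, function(a) {
    L <- series$lifespans[a]
    if (L < predictionAge || L > excludeAbove) return(NULL)
    sel <- series$animal == a & series$age > predictionAge - window &
      series$age <= predictionAge
    if (!any(sel)) return(NULL)
    list(animal = a, lifespan = unname(L),
         x = colMeans(series$factors[sel, , drop = FALSE]),
         label = unname(L >= threshold))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < 3) stop("too few animals alive at the prediction age")
  X <- do.call(rbind, lapply(rows, `[[`, "x"))
  label <- vapply(rows, `[[`, logical(1), "label")
  animal <- vapply(rows, `[[`, character(1), "animal")
  lifespan <- vapply(rows, `[[`, numeric(1), "lifespan")
  score <- rep(NA_real_, length(rows))
  p <- ncol(X)
  for (i in seq_along(rows)) {
    tr <- setdiff(seq_along(rows), i)
    if (length(unique(label[tr])) < 2) {
      warning("a class is absent from training for fold ", animal[i],
              "; fold skipped")
      next
    }
    ztr <- zscoreCols(X[tr, , drop = FALSE])
    zte <- zscoreCols(X[i, , drop = FALSE],
                      center = attr(ztr, "center"), scale = attr(ztr, "scale"))
    f <- bagForest(ztr, as.numeric(label[tr]), nTrees = nTrees,
                   mtry = max(1L, floor(sqrt(p))), seed = seed + i)
    score[i] <- predictForest(f, zte)
  }
  predictedLabel <- score >= 0.5
  ok <- !is.na(score)
  accuracy <- mean(predictedLabel[ok] == label[ok])
  auc <- rocAuc(score[ok], label[ok])
  surv <- tryCatch(
    survivalCompare(lifespan[ok],
                    event = !series$censored[animal[ok]],
                    group = ifelse(predictedLabel[ok], "pred_long",
                                   "pred_short")),
    error = function(e) { warning(conditionMessage(e)); NULL })
  structure(list(
    predicted = data.frame(animal = animal, lifespan = lifespan,
                           label = label, score = score,
                           predictedLabel = predictedLabel),
    accuracy = accuracy, auc = auc, survival = surv,
    predictionAge = predictionAge,
    meta = list(window = window, threshold = threshold,
                excludeAbove = excludeAbove, nTrees = nTrees, seed = seed)),
    class = "LifespanForecast")
}

#' Kaplan-Meier curves and log-rank comparison of groups
#'
#' Product-limit survival estimates with right-censoring and the log-rank
#' test, delegated to the survival package.
#'
#' @param time lifespans (or censoring times), days.
#' @param event TRUE when death was observed, FALSE when censored.
#' @param group group label per animal.
#' @return list with `fit` (survfit), `chisq`, `df`, `p`, and the per-group
#'   observed/expected table; `p` is NA with a message when every event is
#'   censored.
#' @export
survivalCompare <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (length(unique(group)) < 1) stop("need at least one group")
  d <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(d$event) == 0) {
    message("all events censored; log-rank test undefined")
    return(list(fit = fit, chisq = NA_real_, df = NA_integer_, p = NA_real_,
                table = NULL))
  }
  if (length(unique(group)) < 2)
    return(list(fit = fit, chisq = NA_real_, df = NA_integer_, p = NA_real_,
                table = NULL))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       p = 1 - stats::pchisq(sd_$chisq, df),
       table = data.frame(group = names(sd_$n), n = as.vector(sd_$n),
                          observed = sd_$obs, expected = sd_$exp))
}

#' Differential factor usage between groups across ages
#'
#' For every (age, factor) pair within the age range, the difference of
#' group means of the age-factor weights and a two-sided Mann-Whitney U
#' test, Bonferroni-adjusted over the factors tested at that age.
#'
#' @param series an [ageFactorSeries()].
#' @param groups named character vector mapping animals to two groups.
#' @param ages ages (days) to test; defaults to every age at which both
#'   groups have data.
#' @return data.frame with age, factor, meanDiff (group1 - group2), U,
#'   p, pAdjusted.
#' @export
differentialUsage <- function(series, groups, ages = NULL) {
  g <- groups[series$animal]
  lv <- unique(stats::na.omit(g))
  stopifnot(length(lv) == 2)
  if (is.null(ages)) {
    ages <- sort(unique(series$age))
    ages <- ages[vapply(ages, function(a)
      length(unique(g[series$age == a])) == 2, logical(1))]
  }
  R <- ncol(series$factors)
  fn <- colnames(series$factors)
  if (is.null(fn)) fn <- paste0("factor", seq_len(R))
  out <- list()
  for (a in ages) {
    rows <- series$age == a
    g1 <- rows & g == lv[1]
    g2 <- rows & g == lv[2]
    if (!any(g1) || !any(g2)) stop("a group is empty at age ", a)
    for (r in seq_len(R)) {
      x1 <- series$factors[g1, r]
      x2 <- series$factors[g2, r]
      wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        age = a, factor = fn[r], meanDiff = mean(x1) - mean(x2),
        U = unname(wt$statistic), p = wt$p.value)
    }
  }
  res <- do.call(rbind, out)
  res$pAdjusted <- pmin(1, res$p * R)   # Bonferroni over factors per age
  res
}
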