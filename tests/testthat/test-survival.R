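test_that("median dichotomization: odd n, even n, ties at the median", {
  g17 <- dichotomizeByMedian(1:17)
  expect_identical(sum(g17 == "low"), 9L)   # values <= 9
  expect_identical(sum(g17 == "high"), 8L)

  g4 <- dichotomizeByMedian(1:4)            # median 2.5
  expect_identical(as.character(g4), c("low", "low", "high", "high"))

  gt <- dichotomizeByMedian(c(1, 2, 2, 3))  # median 2; both 2s go low
  expect_identical(as.character(gt), c("low", "low", "low", "high"))

  expect_error(dichotomizeByMedian(rep(4, 6)), "identical")
  co <- data.frame(MTV = c(1, 2, 3))
  expect_identical(as.character(dichotomizeByMedian(co, "MTV")),
                   c("low", "low", "high"))
})

test_that("Kaplan-Meier: two-year survival fractions and counting oracle", {
  dfs <- followupTable(k = 4)
  expect_equal(survivalAt(kaplanMeier(dfs$time, dfs$event), 24), 13 / 17,
               tolerance = 1e-12)
  os <- followupTable(k = 3)
  expect_equal(survivalAt(kaplanMeier(os$time, os$event), 24), 14 / 17,
               tolerance = 1e-12)

  # no events: survival stays at 1
  fitN <- kaplanMeier(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_equal(survivalAt(fitN, 20), 1)

  # all n fail at distinct times: S after k-th event = (n-k)/n
  set.seed(20)
  tm <- sort(sample(1:100, 8))
  fitA <- kaplanMeier(tm, rep(TRUE, 8))
  for (k in 1:8)
    expect_equal(survivalAt(fitA, tm[k]), kmCountingOracle(8, k),
                 tolerance = 1e-12)

  # without censoring, KM equals the empirical survival function
  set.seed(21)
  tm2 <- rexp(25)
  fitE <- kaplanMeier(tm2, rep(TRUE, 25))
  for (t in c(0.2, 0.7, 1.5))
    expect_equal(survivalAt(fitE, t), mean(tm2 > t), tolerance = 1e-12)
  expect_error(kaplanMeier(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("log-rank: degenerate, hand-computed and label-swap cases", {
  # identical event experience in both groups
  tm <- c(1, 2, 3, 1, 2, 3); ev <- rep(TRUE, 6)
  g <- rep(c("a", "b"), each = 3)
  out <- logrankTest(tm, ev, g)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)

  # 6-subject worked example: A events at 1, 2; B events at 3, 4,
  # censored at 5, 6. Per event time (O1, E1, V):
  # t=1: (1, 2/6, 2/6*4/6) t=2: (1, 1/5, 1/5*4/5) t=3,4: group A absent.
  # chi2 = (2 - 8/15)^2 / (2/9 + 4/25) = 5.6279070
  h <- logrankTest(c(1, 2, 3, 4, 5, 6), c(T, T, T, T, F, F),
                   c("A", "A", "B", "B", "B", "B"))
  expect_equal(h$chi2, (2 - 8 / 15)^2 / (2 / 9 + 4 / 25), tolerance = 1e-12)
  expect_equal(h$chi2, 5.6279070, tolerance = 1e-6)
  expect_equal(unname(h$observed), c(2, 2))
  expect_equal(unname(h$expected)[1], 8 / 15, tolerance = 1e-12)

  # invariant to swapping group labels; agrees with survival::survdiff
  set.seed(22)
  tm3 <- rexp(30); ev3 <- runif(30) < 0.7; g3 <- rep(c("a", "b"), 15)
  o1 <- logrankTest(tm3, ev3, g3)
  o2 <- logrankTest(tm3, ev3, ifelse(g3 == "a", "b", "a"))
  expect_equal(o1$chi2, o2$chi2, tolerance = 1e-12)
  sd3 <- survival::survdiff(survival::Surv(tm3, ev3) ~ g3)
  expect_equal(o1$chi2, sd3$chisq, tolerance = 1e-9)
  expect_error(logrankTest(tm3, ev3, rep("a", 30)), "2 groups")
})

test_that("log-rank type-I error is calibrated under the null outcome model", {
  set.seed(23)
  g <- rep(c("a", "b"), c(8, 9))
  rej <- replicate(2000, {
    o <- simulateOutcomes(rep(c(FALSE, TRUE), c(8, 9)), 0.0058, beta = 0)
    logrankTest(o$time, o$event, g)$p < 0.05
  })
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("Cox: symmetry, divergence guard, reciprocal swap, CI shape", {
  tm <- c(1, 2, 3, 1, 2, 3); ev <- rep(TRUE, 6)
  g <- rep(c("a", "b"), each = 3)
  cx <- coxUnivariate(tm, ev, g)
  expect_equal(cx$beta, 0, tolerance = 1e-9)
  expect_equal(cx$hr, 1, tolerance = 1e-9)
  expect_false(cx$diverged)
  expect_true(cx$ci[1] <= cx$hr && cx$hr <= cx$ci[2])

  # all events in one group before any in the other: monotone likelihood
  expect_warning(
    dv <- coxUnivariate(c(1, 2, 3, 10, 11, 12), rep(TRUE, 6),
                        rep(c("a", "b"), each = 3)),
    "diverges")
  expect_true(dv$diverged)
  expect_true(is.na(dv$hr))

  # swapping labels inverts the hazard ratio
  set.seed(24)
  tm4 <- rexp(40, rate = c(0.5, 1.5)); ev4 <- rep(TRUE, 40)
  g4 <- rep(c("lo", "hi"), 20)
  c1 <- coxUnivariate(tm4, ev4, factor(g4, levels = c("lo", "hi")))
  c2 <- coxUnivariate(tm4, ev4, factor(g4, levels = c("hi", "lo")))
  expect_equal(c1$hr, 1 / c2$hr, tolerance = 1e-9)
  expect_error(coxUnivariate(tm4, rep(FALSE, 40), g4), "no events")
})

test_that("Cox beta matches brute-force partial-likelihood maximization", {
  set.seed(25)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    tm <- sample(seq_len(50), n)  # distinct times, no ties
    ev <- runif(n) < 0.8
    if (sum(ev) == 0) ev[1] <- TRUE
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) == 1) x[1] <- 1 - x[1]
    # skip monotone configurations where the maximum is at the boundary
    bOra <- coxBruteForceBeta(tm, ev, x)
    if (abs(bOra) > 5) next
    cx <- coxUnivariate(tm, ev, factor(x))
    expect_lt(abs(cx$beta - bOra), 1e-6)
  }
})

test_that("Cox score test at beta = 0 equals the log-rank statistic on tie-free data", {
  set.seed(26)
  for (i in 1:50) {
    n <- sample(10:25, 1)
    tm <- rexp(n); ev <- runif(n) < 0.8
    if (sum(ev) == 0) ev[1] <- TRUE
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) == 1) g[1] <- 1 - g[1]
    lr <- logrankTest(tm, ev, g)
    cx <- suppressWarnings(coxUnivariate(tm, ev, factor(g)))
    expect_equal(cx$scoreChi2, lr$chi2, tolerance = 1e-6)
  }
})

test_that("Cox recovers a known hazard ratio from simulated cohorts", {
  set.seed(27)
  hrs <- replicate(30, {
    g <- rep(c(FALSE, TRUE), each = 100)
    o <- simulateOutcomes(g, lambda0 = 0.01, beta = log(3),
                          censorMin = 0, censorMax = 300)
    coxUnivariate(o$time, o$event, g)$hr
  })
  expect_lt(abs(median(hrs) - 3), 0.5)
})

test_that("survivalTable produces one stratification row per metric", {
  set.seed(28)
  co <- data.frame(
    MTV = runif(17, 10, 60), SUVmax = runif(17, 5, 15),
    r = runif(17, -0.6, 0.1),
    dfs_time = rexp(17, 0.02), dfs_event = runif(17) < 0.6)
  tab <- survivalTable(co, metrics = c("MTV", "SUVmax", "r"))
  expect_identical(nrow(tab), 3L)
  expect_true(all(c("hr", "ciLow", "ciHigh", "waldP", "logrankP") %in%
                    names(tab)))
  ok <- !tab$diverged
  expect_true(all(tab$hr[ok] > 0))
  expect_true(all(tab$ciLow[ok] <= tab$hr[ok] & tab$hr[ok] <= tab$ciHigh[ok]))
  expect_true(all(tab$logrankP > 0 & tab$logrankP <= 1))
})
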