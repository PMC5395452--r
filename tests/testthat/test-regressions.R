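test_that("OLS matches closed-form simple-regression formulas", {
  expect_s4_class(olsFit(1:10, 2 * (1:10) + 1), "OLSFit")
  perfect <- olsFit(1:10, 2 * (1:10) + 1)
  expect_equal(perfect@slope, 2)
  expect_equal(perfect@intercept, 1)
  expect_equal(perfect@r2, 1)

  flat <- olsFit(1:10, rep(3, 10))
  expect_true(flat@degenerate)
  expect_equal(c(flat@slope, flat@r2, flat@p), c(0, 0, 1))
  expect_equal(flat@intercept, 3)

  expect_error(olsFit(rep(1, 5), 1:5), "zero-variance x")
  expect_error(olsFit(1:2, 1:2), "at least 3")

  # closed-form oracle: slope = cov/var, t-test on the slope
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- 0.5 * x + rnorm(15)
    f <- olsFit(x, y)
    slope <- cov(x, y) / var(x)
    intercept <- mean(y) - slope * mean(x)
    r2 <- cor(x, y)^2
    se <- sqrt(sum((y - intercept - slope * x)^2) / 13 / sum((x - mean(x))^2))
    p <- 2 * pt(abs(slope / se), df = 13, lower.tail = FALSE)
    expect_equal(f@slope, slope, tolerance = 1e-10)
    expect_equal(f@intercept, intercept, tolerance = 1e-10)
    expect_equal(f@r2, r2, tolerance = 1e-10)
    expect_equal(f@p, p, tolerance = 1e-10)
  }
})

test_that("family relationships recover exact linear structure and reject noise", {
  set.seed(7)
  d <- data.frame(apparency = 10^runif(120, 0, 4),
                  PD_min = runif(120, 0, 300))
  d$UR <- 0.2 * log10(d$apparency) - 0.07
  fr <- familyRelationships(d)
  expect_equal(fr$urApparency@slope, 0.2, tolerance = 1e-10)
  expect_equal(fr$urApparency@intercept, -0.07, tolerance = 1e-10)
  expect_equal(fr$urApparency@r2, 1, tolerance = 1e-10)

  # permutation null: a shuffled response loses the association
  set.seed(8)
  r2perm <- vapply(1:500, function(i) {
    olsFit(log10(d$apparency), sample(d$UR))@r2
  }, numeric(1))
  r2shuf <- vapply(1:20, function(i) {
    dShuf <- d; dShuf$UR <- sample(d$UR)
    familyRelationships(dShuf)$urApparency@r2
  }, numeric(1))
  expect_lt(median(r2shuf), quantile(r2perm, 0.95) + 1e-12)
  expect_error(familyRelationships(data.frame(UR = 1:5, apparency = 0:4,
                                              PD_min = 1:5)),
               "positive")
})

test_that("group relationships screen invalid fits and log exclusions", {
  g <- data.frame(
    group = paste0("g", 1:8),
    HF = c(20, 40, 60, 80, 100, 120, 140, 160),
    a = c(0.002, 0.001, 0.003, -0.001, 0.002, 0.004, 0.001, 0.002),
    converged = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    separated = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    PA_05 = c(1000, 900, -5, 800, 700, 600, 500, 400),
    PA_095 = c(3000, 2700, 1500, 2400, 2100, 1800, 1500, 1200),
    UP_0 = c(0.05, 0.08, 0.1, 0.12, 0.15, 0.18, 0.2, 0.22),
    D = c(1.1, 0.9, -0.2, 0.7, 0.6, 0.5, 0.8, 0.4),
    stringsAsFactors = FALSE)
  res <- groupRelationships(g)
  # g4 (a<0), g5 (not converged), g6 (separated) excluded everywhere
  expect_true(all(c("g4", "g5", "g6") %in%
                    res$exclusions$group[res$exclusions$regression == "all"]))
  # g3 excluded from log(PA_05) and from log10(D)
  expect_true("g3" %in%
    res$exclusions$group[res$exclusions$regression == "logPa05Hf"])
  expect_true("g3" %in%
    res$exclusions$group[res$exclusions$regression == "up0LogD"])
  expect_equal(res$fits$up0Hf@n, 5L)
  expect_equal(res$fits$logPa05Hf@n, 4L)
  expect_equal(res$fits$up0LogD@n, 4L)

  tooFew <- g[1:3, ]; tooFew$a <- -1
  expect_error(groupRelationships(tooFew), "fewer than 3")
})

test_that("groups with identical fits but varying prevalence give a flat UP_0", {
  # UP_0 comes only from the intercept; simulate groups sharing (a, b) so
  # UP_0 is constant and its regression on HF has slope ~ 0
  set.seed(10)
  apparencyTab <- simulateApparency(420, seed = 2)
  pa <- apparencyTab$n_species
  rows <- lapply(1:10, function(j) {
    y <- rbinom(420, 1, plogis(0.0018 * pa - 2.15))
    fit <- fitBinomialLogit(pa, y)
    dq <- derivedQuantities(fit)
    data.frame(group = paste0("g", j), HF = sum(y), a = fit@slope,
               converged = fit@converged, separated = fit@separated,
               PA_05 = dq$PA_05, PA_095 = dq$PA_095, UP_0 = dq$UP_0,
               D = 0.8 + 0.04 * j)   # D plays no role in the UP_0 ~ HF fit
  })
  res <- groupRelationships(do.call(rbind, rows))
  expect_lt(abs(res$fits$up0Hf@slope), 0.005)
})

test_that("randomized baseline centers the slope at 0 and UP_0 at p", {
  set.seed(4)
  pa <- simulateApparency(200, seed = 3)$n_species
  base <- randomizedBaseline(pa, probs = c(0.3, 0.5), nReps = 60, seed = 6)
  expect_equal(nrow(base), 120L)
  ok <- base$converged & !base$separated & !base$degenerate
  expect_gt(mean(ok), 0.9)
  expect_lt(abs(mean(base$a[ok])), 0.002)
  expect_lt(abs(mean(base$UP_0[base$p == 0.5 & ok], na.rm = TRUE) - 0.5),
            0.05)
  expect_lt(abs(mean(base$UP_0[base$p == 0.3 & ok], na.rm = TRUE) - 0.3),
            0.05)
})
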