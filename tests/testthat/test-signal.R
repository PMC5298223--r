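test_that("re-referencing satisfies its contracts", {
  x <- cbind(a = sin(1:100), b = sin(1:100))
  rec <- new("Recording", samples = x, rate = 1024, channels = c("a", "b"),
             band = c(1, 344))
  car <- rereference(rec, "CAR")
  expect_equal(max(abs(sampleMatrix(car))), 0)

  x2 <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  rec2 <- new("Recording", samples = x2, rate = 1024,
              channels = c("a", "b", "c"), band = c(1, 344))
  single <- rereference(rec2, "single:a")
  expect_equal(unname(sampleMatrix(single)[, 1]), rep(0, 50))

  once <- rereference(rec2, "CAR")
  twice <- rereference(once, "CAR")
  expect_equal(sampleMatrix(once), sampleMatrix(twice))
  expect_error(rereference(rec2, "single:zz"), "missing reference")
})

test_that("trial excerption is center-aligned with fixed length", {
  set.seed(1)
  x <- matrix(rnorm(20 * 1024 * 2), ncol = 2)
  rec <- new("Recording", samples = x, rate = 1024, channels = c("a", "b"),
             band = c(1, 344))
  ts <- centeredTrialSet(c(6, 10, 14))
  tens <- excerptTrials(rec, ts, span = c(-2, 2))
  expect_identical(dim(tens), c(4096L, 2L, 3L))
  ## trial at center 10 s starts at sample 8192 + 1
  expect_equal(tens[, 1, 2], x[8193:(8192 + 4096), 1])

  none <- new("TrialSet", events = data.frame(onset = numeric(0),
                                              end = numeric(0),
                                              center = numeric(0),
                                              baseline_start = numeric(0)),
              baselineDur = 0.2)
  empty <- excerptTrials(rec, none)
  expect_identical(dim(empty)[3], 0L)

  clipped <- centeredTrialSet(c(1, 10, 19.5))
  expect_warning(t2 <- excerptTrials(rec, clipped), "dropped")
  expect_identical(dim(t2)[3], 1L)
})

test_that("relative spectra are null-centered, calibrated and peak at the burst band", {
  rate <- 1024
  ## null: trials drawn from the same process as baselines; the baseline
  ## excerpt is long enough (2 s) that the median-across-bins estimator of
  ## the skewed per-bin power distribution is calibrated
  set.seed(7)
  mk <- function(len, n) array(rnorm(len * n), dim = c(len, 1, n),
                               dimnames = list(NULL, "a", NULL))
  trials <- mk(512, 200); baselines <- mk(2048, 200)
  attr(trials, "time") <- (seq_len(512) - 256) / rate
  attr(trials, "rate") <- rate; attr(trials, "channels") <- "a"
  sp <- relativeSpectra(trials, baselines)
  expect_lt(abs(median(sp$logPower)), 0.05)

  ## a bin with tenfold power -> +1.0 log relative power
  f0 <- 200
  t <- (seq_len(512) - 1) / rate
  sine <- function(a) a * sqrt(2) * sin(2 * pi * f0 * t)
  trials2 <- array(sine(sqrt(10)), dim = c(512, 1, 8),
                   dimnames = list(NULL, "a", NULL))
  base2 <- array(sine(1), dim = c(512, 1, 8))
  attr(trials2, "time") <- t - 0.25; attr(trials2, "rate") <- rate
  attr(trials2, "channels") <- "a"
  sp2 <- relativeSpectra(trials2, base2)
  bin <- which.min(abs(sp2$freq - f0))
  expect_equal(median(sp2$logPower[1, , , bin]), 1.0, tolerance = 1e-6)

  ## a strong burst on a noise floor peaks in the bin containing its frequency
  set.seed(8)
  trials3 <- mk(512, 12) + array(sine(20), dim = c(512, 1, 12))
  base3 <- mk(2048, 12)
  attr(trials3, "time") <- (seq_len(512) - 256) / rate
  attr(trials3, "rate") <- rate; attr(trials3, "channels") <- "a"
  sp3 <- relativeSpectra(trials3, base3)
  avg <- apply(sp3$logPower, 4, mean)
  expect_identical(which.max(avg), as.integer(bin))
})

test_that("the exact sign test matches closed-form binomial tails", {
  expect_equal(signTestP(20, 20), 2 * 0.5^20)
  expect_equal(signTestP(0, 20), 2 * 0.5^20)
  expect_equal(signTestP(10, 20), 1, tolerance = 1e-12)
  expect_equal(signTestP(0, 0), 1)
  ## cross-check against binom.test on asymmetric counts
  expect_equal(signTestP(15, 20),
               stats::binom.test(15, 20, 0.5)$p.value, tolerance = 1e-9)
})

test_that("significance mask applies the FDR threshold (m = 1 reduces to q)", {
  mk <- function(vals) {
    n <- length(vals)
    lp <- array(rep(vals, each = 12) + rnorm(12 * n, 0, 1e-3),
                dim = c(1, 12, 1, n))
    structure(list(logPower = lp, time = 0, freq = seq_len(n),
                   channels = "a", baseline = matrix(1, 1, n),
                   params = spectralParams()), class = "RelativeSpectra")
  }
  ## single strongly positive bin: p = 2 * 0.5^12 = 0.00049 <= q = 0.001
  sp <- mk(1)
  out <- signTestMap(sp)
  expect_true(out$mask[1, 1, 1])
  expect_equal(out$p[1, 1, 1], 2 * 0.5^12)
})

test_that("band topography averages the requested band and localizes sources", {
  lp <- array(1.0, dim = c(3, 5, 4, 10))
  sp <- structure(list(logPower = lp, time = seq(-0.3, 0.3, length.out = 4),
                       freq = seq(0, 450, length.out = 10),
                       channels = c("a", "b", "c"),
                       baseline = matrix(1, 3, 10),
                       params = spectralParams()), class = "RelativeSpectra")
  topo <- bandTopography(sp, band = c(32, 400))
  expect_equal(unname(topo), rep(1, 3))
  expect_error(bandTopography(sp, band = c(460, 500)), "empty")

  ## burst nearest one channel dominates that channel's gamma topography
  gen <- recordingFixture()
  el <- electrodesFixture()
  trials <- excerptTrials(gen$recording, gen$trials, span = c(-0.5, 0.5))
  bases <- excerptTrials(gen$recording, gen$trials, span = c(-0.25, 0.25),
                         align = "baseline")
  sp2 <- relativeSpectra(trials, bases)
  topo2 <- bandTopography(sp2, band = c(32, 400), window = c(-0.15, 0.15))
  sca <- electrodeKinds(el) == "scalp"
  ## strongest scalp channel is the one closest to the muscle reference point
  scp <- electrodePositions(el)[sca, , drop = FALSE]
  src <- 0.95 * scp[which.max(scp[, 1]), ]
  d <- sqrt(rowSums(sweep(electrodePositions(el), 2, src)^2))
  expect_identical(names(which.max(topo2[sca])),
                   electrodeLabels(el)[sca][which.min(d[sca])])
})

test_that("sign-test type-I error matches its exact attainable level", {
  n <- 25; nBins <- 2000
  set.seed(101)
  k <- rbinom(nBins, n, 0.5)
  p <- signTestP(k, rep(n, nBins))
  rate <- mean(p <= 0.05)
  exact <- sum(dbinom(0:n, n, 0.5)[signTestP(0:n, rep(n, n + 1)) <= 0.05])
  se <- sqrt(exact * (1 - exact) / nBins)
  expect_lt(abs(rate - exact), 3 * se + 1e-12)
})

test_that("BY correction bounds the false discovery proportion under correlation", {
  nRep <- 300; m <- 150; n <- 30; q <- 0.001
  set.seed(202)
  anyRej <- logical(nRep)
  for (r in seq_len(nRep)) {
    shared <- rnorm(n)
    x <- 0.6 * matrix(shared, n, m) + 0.8 * matrix(rnorm(n * m), n, m)
    k <- colSums(x > 0)
    p <- signTestP(k, rep(n, m))
    anyRej[r] <- any(p.adjust(p, "BY") <= q)
  }
  ## all bins are null, so FDP = 1{any rejection}; E[FDP] <= q under BY
  expect_lte(mean(anyRej), q + 3 * sqrt(q * (1 - q) / nRep))
})

test_that("contact significance summary rounds to the nearest percent", {
  expect_identical(significantContactPercent(406, 410), 99)
  expect_identical(significantContactPercent(0, 10), 0)
  expect_error(significantContactPercent(11, 10))
})
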