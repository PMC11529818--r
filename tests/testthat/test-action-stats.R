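test_that("frame classification follows the threshold rules with strict bounds", {
  obs <- constantObservables(1, left_pitch = 50, right_pitch = 48,
                             offset_angle = wingOffsetAngle(50, 48),
                             speed = 3, elevation = 5)
  expect_equal(unname(actionFlags(classifyFrames(obs))[1, ]),
               c(TRUE, FALSE, FALSE, FALSE))

  obs <- constantObservables(1, left_pitch = 60, right_pitch = 5,
                             offset_angle = wingOffsetAngle(60, 5),
                             speed = 3, elevation = 5)
  expect_equal(unname(actionFlags(classifyFrames(obs))[1, ]),
               c(FALSE, TRUE, FALSE, FALSE))

  # low wing threat, with alert co-occurring (slow and pitched up)
  obs <- constantObservables(1, left_pitch = 40, right_pitch = 38,
                             offset_angle = wingOffsetAngle(40, 38),
                             speed = 0.5, elevation = 30)
  expect_equal(unname(actionFlags(classifyFrames(obs))[1, ]),
               c(FALSE, FALSE, TRUE, TRUE))

  # boundary values get no label: all inequalities are strict
  obs <- constantObservables(1, left_pitch = 45, right_pitch = 45,
                             offset_angle = 0, speed = 1, elevation = 22.5)
  expect_equal(unname(actionFlags(classifyFrames(obs))[1, ]),
               c(FALSE, FALSE, FALSE, FALSE))

  # invalid observables make the dependent labels indeterminate
  m <- cbind(left_pitch = NA_real_, right_pitch = 50, offset_angle = NA_real_,
             speed = 0.5, elevation = 30)
  et <- classifyFrames(observableSeries(m, 100))
  expect_true(all(is.na(actionFlags(et)[1, 1:3])))
  expect_true(actionFlags(et)[1, "alert"])
  expect_true(unknownMask(et)[1])
})

test_that("bout extraction matches a run-length-encoding oracle", {
  flags <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  b <- extractBouts(flags, frameRate = 100)
  expect_equal(b$start_s, 0.03)
  expect_equal(b$end_s, 0.07)
  expect_equal(b$duration_s, 0.04)

  # 2-frame run at 100 Hz is 20 ms: dropped at a 30 ms minimum
  expect_equal(nrow(extractBouts(c(FALSE, TRUE, TRUE, FALSE), 100,
                                 minDurationMs = 30)), 0)

  # unknown frames terminate runs
  b2 <- extractBouts(c(TRUE, TRUE, NA, TRUE), 100)
  expect_equal(nrow(b2), 2)

  set.seed(41)
  for (k in 1:10) {
    f <- sample(c(TRUE, FALSE, NA), 200, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
    b <- extractBouts(f, 100)
    # oracle: independent scan
    g <- !is.na(f) & f
    r <- rle(g)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    expect_equal(b$start_s, (starts[r$values] - 1) / 100)
    expect_equal(b$end_s, ends[r$values] / 100)
  }
})

test_that("first-bout latency requires onset-after-stimulus and min duration", {
  n <- 1000; fps <- 100
  lab <- matrix(FALSE, n, 4, dimnames = list(NULL, actionNames()))
  onset <- 2.0
  # qualifying bout at onset + 0.12 s lasting 50 ms
  lab[213:217, "wing_threat"] <- TRUE
  et <- ethogram(lab, fps)
  expect_equal(firstBoutLatency(et, "wing_threat", onset), 0.12)

  # only a 20 ms bout: none
  lab2 <- lab; lab2[, "wing_threat"] <- FALSE
  lab2[213:214, "wing_threat"] <- TRUE
  expect_true(is.na(firstBoutLatency(ethogram(lab2, fps), "wing_threat", onset)))

  # bout straddling the onset is skipped; the next qualifying one counts
  lab3 <- lab
  lab3[190:210, "wing_threat"] <- TRUE   # begins before onset
  expect_equal(firstBoutLatency(ethogram(lab3, fps), "wing_threat", onset),
               0.12)
})

test_that("proportion time course averages trials and excludes unknowns", {
  fps <- 100; n <- 100
  mk <- function(flag_vec) {
    lab <- matrix(FALSE, n, 4, dimnames = list(NULL, actionNames()))
    lab[, "wing_threat"] <- flag_vec
    ethogram(lab, fps)
  }
  always <- replicate(5, mk(rep(TRUE, n)), simplify = FALSE)
  expect_equal(proportionTimecourse(always, "wing_threat"), rep(1, n))

  # 3 of 15 trials on, no smoothing
  trials <- c(replicate(3, mk(rep(TRUE, n)), simplify = FALSE),
              replicate(12, mk(rep(FALSE, n)), simplify = FALSE))
  expect_equal(proportionTimecourse(trials, "wing_threat", smoothMs = 0),
               rep(0.2, n))

  # unknown trials leave numerator and denominator: 3 TRUE, 2 NA, 10 FALSE
  nas <- replicate(2, mk(rep(NA, n)), simplify = FALSE)
  trials2 <- c(trials[1:3], nas, trials[4:13])
  expect_equal(proportionTimecourse(trials2, "wing_threat", smoothMs = 0),
               rep(3 / 13, n))

  # impulse at one frame smooths to 1/25 over the 25-frame window
  imp <- rep(FALSE, n); imp[50] <- TRUE
  sm <- proportionTimecourse(list(mk(imp)), "wing_threat", smoothMs = 250)
  expect_equal(sm[50], 1 / 25)
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # mass preserved mid-series

  # complementary actions sum to one when nothing is unknown
  set.seed(42)
  f <- runif(n) < 0.3
  lab <- matrix(FALSE, n, 4, dimnames = list(NULL, actionNames()))
  lab[, "wing_threat"] <- f; lab[, "alert"] <- !f
  e <- ethogram(lab, fps)
  expect_equal(proportionTimecourse(list(e), "wing_threat", 250) +
                 proportionTimecourse(list(e), "alert", 250),
               rep(1, n), tolerance = 1e-12)
})

test_that("binned rank-sum tests use the exact small-sample distribution", {
  fps <- 10
  # identical per-fly values: nothing can be significant
  A <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), 10), 4, 10)
  out <- binnedGroupTest(A, A, fps, binS = 0.5, alpha = 0.01)
  expect_true(all(!out$significant))

  # {0,0,0,0} vs {1,1,1,1}: exact two-sided p = 2/70, not significant at 0.01
  B0 <- matrix(0, 4, 5); B1 <- matrix(1, 4, 5)
  out2 <- binnedGroupTest(B0, B1, fps, binS = 0.5, alpha = 0.01)
  expect_equal(out2$p[1], 0.0286, tolerance = 1e-3)
  expect_false(out2$significant[1])

  # a clear shift with larger groups is detected only where it exists
  set.seed(43)
  n_fly <- 12; nf <- 40
  base <- matrix(runif(n_fly * nf, 0, 0.2), n_fly, nf)
  shift <- base; shift[, 21:40] <- shift[, 21:40] + 0.5
  out3 <- binnedGroupTest(base, shift, fps, binS = 0.5, alpha = 0.01)
  first_half <- out3$bin_start_s < 2
  expect_true(all(!out3$significant[first_half]))
  expect_true(all(out3$significant[!first_half]))
})

test_that("wingspan metrics: sex-specific first peak, baseline shift, habituation", {
  fps <- 25
  stim_on <- 15; stim_off <- 30
  n <- 65 * fps
  t <- (seq_len(n) - 1) / fps
  flat <- rep(0, n)
  m0 <- wingspanMetrics(flat, fps, stim_on, stim_off, "male")
  expect_true(is.na(m0$first_peak_latency_s))
  expect_equal(m0$baseline_shift, 0)
  expect_equal(m0$habituation, 0)

  # single triangular peak of 0.4 mm at onset + 0.8 s
  tri <- flat
  pk <- which.min(abs(t - (stim_on + 0.8)))
  ramp <- 10
  tri[(pk - ramp):pk] <- seq(0, 0.4, length.out = ramp + 1)
  tri[pk:(pk + ramp)] <- seq(0.4, 0, length.out = ramp + 1)
  mf <- wingspanMetrics(tri, fps, stim_on, stim_off, "female")
  expect_equal(mf$first_peak_latency_s, 0.8, tolerance = 1 / fps)

  # a 0.23 mm peak clears the male threshold but not the female one
  small <- tri * (0.23 / 0.4)
  expect_false(is.na(wingspanMetrics(small, fps, stim_on, stim_off,
                                     "male")$first_peak_latency_s))
  expect_true(is.na(wingspanMetrics(small, fps, stim_on, stim_off,
                                    "female")$first_peak_latency_s))

  # windowed means: +0.3 during the stimulus decaying to +0.1, post at +0.05
  tr <- flat
  tr[t >= stim_on & t < stim_on + 2] <- 0.3
  tr[t >= stim_off - 2 & t < stim_off] <- 0.1
  tr[t >= stim_off + 20 & t < stim_off + 30] <- 0.05
  m <- wingspanMetrics(tr, fps, stim_on, stim_off, "male")
  expect_equal(m$habituation, 0.2, tolerance = 1e-9)
  expect_equal(m$baseline_shift, 0.05, tolerance = 1e-9)
})

test_that("ethograms round-trip through CSV", {
  set.seed(44)
  lab <- matrix(sample(c(TRUE, FALSE, NA), 120, replace = TRUE,
                       prob = c(0.2, 0.7, 0.1)), 30, 4,
                dimnames = list(NULL, actionNames()))
  lab[, "wing_extension"] <- FALSE  # keep wing labels mutually exclusive
  lab[, "low_wing_threat"] <- FALSE
  et <- ethogram(lab, 100)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEthogramCsv(et, path)
  back <- readEthogramCsv(path, 100)
  expect_equal(actionFlags(back), actionFlags(et))
})
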