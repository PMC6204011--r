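# shared covariate layout for the smooth-fit tests
si_frame <- function(n_subj = 30, per = 8, seed = 1) {
  set.seed(seed)
  subject <- rep(sprintf("S%02d", seq_len(n_subj)), each = per)
  gab <- rep(runif(n_subj, 24, 41), each = per)
  wol <- as.numeric(replicate(n_subj, sort(sample(0:60, per))))
  data.frame(subject, gab, wol)
}

test_that("a constant outcome yields a flat surface", {
  d <- si_frame(seed = 2)
  f <- fit_occurrence_surface(rep(0.3, nrow(d)), d$wol, d$gab, d$subject)
  grid <- expand.grid(wol = seq(0, 60, by = 5), gab = seq(24, 41, by = 2))
  expect_lt(max(abs(predict(f, grid) - 0.3)), 0.02)
})

test_that("a WOL-only signal leaves the gestational-age direction flat", {
  d <- si_frame(n_subj = 40, per = 10, seed = 3)
  p <- plogis(0.5 * d$wol - 10) + rnorm(nrow(d), 0, 0.05)
  f <- fit_occurrence_surface(p, d$wol, d$gab, d$subject)
  # partial dependence on gab at fixed wol
  for (w in c(10, 25, 40)) {
    grid <- data.frame(wol = w, gab = seq(25, 40, length.out = 12))
    expect_lt(diff(range(predict(f, grid))), 0.05)
  }
  # and the surface does vary along wol
  grid_w <- data.frame(wol = seq(5, 50, length.out = 12), gab = 32)
  expect_gt(diff(range(predict(f, grid_w))), 0.5)
})

test_that("noiseless linear truth is reproduced exactly at training points", {
  d <- si_frame(seed = 4)
  p <- 0.01 * d$wol + 0.002 * d$gab  # lies in the smooth's null space
  # REML warns about the zero-residual limit; the fit itself is exact
  f <- suppressWarnings(fit_occurrence_surface(p, d$wol, d$gab, d$subject))
  pred <- predict(f, data.frame(wol = d$wol, gab = d$gab))
  expect_lt(max(abs(pred - p)), 1e-6)
})

test_that("the profiled criterion is no worse than fixed-angle fits", {
  d <- si_frame(n_subj = 25, per = 8, seed = 5)
  p <- plogis(0.3 * (d$wol + d$gab) - 15) + rnorm(nrow(d), 0, 0.05)
  fit <- single_index(p, d$wol, d$gab, d$subject, grid_n = 31)
  # grid containment: optimum criterion <= profile at angles near 0/45/90 deg
  for (deg in c(0, 45, 89)) {
    th <- deg * pi / 180
    nearest <- which.min(abs(fit$profile$theta - th))
    expect_lte(fit$criterion, fit$profile$score[nearest] + 1e-8)
  }
  # a = b truth: estimated angle within 10 degrees of 45
  expect_lt(abs(180 * fit$theta / pi - 45), 10)
})

test_that("occurrence logistic test handles separation and degeneracy", {
  set.seed(6)
  gab <- runif(200, 24, 41)
  # separation: occurrence iff full-term
  r <- occurrence_logistic_test(gab > 37, gab)
  expect_true(r$separation)
  expect_lt(r$p_value, 1e-6)
  # no variation
  expect_equal(occurrence_logistic_test(rep(TRUE, 10), gab[1:10])$p_value, 1)
  # null calibration
  rej <- mean(replicate(1000, {
    g <- runif(120, 24, 41)
    occurrence_logistic_test(runif(120) < 0.4, g)$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("pattern classification implements the binning rule exactly", {
  expect_equal(classify_pattern(1, 1, 0.2)$class, "convergent")
  expect_equal(classify_pattern(1, 0.2, 0.5)$class, "chronological")
  expect_equal(classify_pattern(1, 0.2, 0.01)$class, "idiosyncratic")
  expect_equal(classify_pattern(1, 4, 0.5)$class, "idiosyncratic")
  expect_equal(classify_pattern(1, -0.3, 0.5)$class, "chronological")
  expect_equal(classify_pattern(1, -0.3, 0.01)$class, "idiosyncratic")
  expect_equal(classify_pattern(0, 1, 0.5)$class, "idiosyncratic")
  expect_error(classify_pattern(0, 0, 0.5), "time dependence")
  expect_error(classify_pattern(-1, 1, 0.5), "a >= 0")
  # the three classes partition the valid domain
  set.seed(7)
  for (i in 1:200) {
    a <- abs(rnorm(1)); b <- rnorm(1); p <- runif(1)
    if (a == 0 && b == 0) next
    if (a == 0 && b <= 0) next  # outside orientation convention
    cls <- classify_pattern(a, b, p)$class
    expect_true(cls %in% c("chronological", "convergent", "idiosyncratic"))
  }
})

test_that("sequence summaries quantize and split intervals at midpoints", {
  samples <- data.frame(sample_id = "x1", subject_id = "S1", site = "gut",
                        pma = 39.6)
  s <- sequence_index_summary(3L, samples)
  expect_equal(s, data.frame(subject_id = "S1", site = "gut",
                             pma_week = 39, cst = 3L))

  samples2 <- data.frame(sample_id = c("x1", "x2"),
                         subject_id = "S1", site = "gut", pma = c(30, 34))
  s2 <- sequence_index_summary(c(1L, 2L), samples2)
  expect_equal(s2$pma_week, 30:34)
  expect_equal(s2$cst, c(1L, 1L, 2L, 2L, 2L))  # split at week 32

  # duplicate week: later sample wins, with a warning
  samples3 <- data.frame(sample_id = c("x1", "x2", "x3"),
                         subject_id = "S1", site = "gut",
                         pma = c(30.2, 30.9, 32))
  expect_warning(s3 <- sequence_index_summary(c(1L, 2L, 2L), samples3),
                 "later sample wins")
  expect_equal(s3$cst[s3$pma_week == 30], 2L)
})
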