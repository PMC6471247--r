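test_that("fractional conversion model evaluates its closed form", {
  # constant when C0 == Cinf; C0 at t = 0; half-conversion at ln(2)/K
  expect_equal(fractional_conversion(10, 10, 0.5, 7), 10)
  expect_equal(fractional_conversion(0, 60, 0.131, 0), 0)
  expect_equal(fractional_conversion(0, 60, 0.131, log(2) / 0.131), 30)
  expect_error(fractional_conversion(0, 60, -0.1, 1), "non-negative")
  expect_error(fractional_conversion(0, 60, 0.1, -1), "non-negative")
})

test_that("model curves are monotone in t and pinned between C0 and Cinf", {
  set.seed(11)
  tt <- seq(0, 48, by = 0.5)
  for (i in 1:25) {
    C0 <- runif(1, 0, 5); Cinf <- runif(1, 0, 70); K <- runif(1, 0.01, 0.5)
    y <- fractional_conversion(C0, Cinf, K, tt)
    expect_equal(y[1], C0)
    d <- diff(y)
    if (Cinf >= C0) expect_true(all(d >= -1e-12)) else expect_true(all(d <= 1e-12))
    # first-order approach: |C(t) - Cinf| decays exactly exponentially
    expect_equal(abs(y - Cinf), abs(C0 - Cinf) * exp(-K * tt))
  }
})

test_that("noiseless parameter recovery is exact across the plausible K range", {
  for (K in c(0.01, 0.05, 0.131, 0.211, 0.35, 0.5)) {
    up <- fit_fractional_conversion(t9, fractional_conversion(0, 60, K, t9))
    dn <- fit_fractional_conversion(t9, fractional_conversion(0.8, 0.1, K, t9))
    expect_true(up$converged)
    expect_true(dn$converged)
    expect_lt(abs(up$K - K) / K, 1e-4)
    expect_lt(abs(dn$K - K) / K, 1e-4)
    expect_lt(abs(up$Cinf - 60) / 60, 1e-4)
    expect_identical(up$direction, "production")
    expect_identical(dn$direction, "degradation")
  }
})

test_that("published SCFA and procyanidin rate constants are recovered to 3 decimals", {
  # acetate production and procyanidin degradation, donor O1
  ace <- fit_fractional_conversion(make_tc(0, 60, 0.131))
  pca <- fit_fractional_conversion(make_tc(0.8, 0.1, 0.211, matrix = "Mno",
                                           analyte = "procyanidins"))
  expect_equal(round(ace$K, 3), 0.131)
  expect_equal(round(pca$K, 3), 0.211)
})

test_that("degenerate series are rejected with informative errors", {
  flat <- timecourse("O1", "Mnc", 1, "acetate", t9, rep(5, 9),
                     corrected = TRUE)
  expect_error(fit_fractional_conversion(flat), "identifiable")
  expect_error(fit_fractional_conversion(c(0, 2, 4), c(1, 2, 3)),
               "at least 4 points")
  expect_warning(
    f <- fit_fractional_conversion(c(0, 0, 2, 4, 6, 8),
                                   c(0.1, 0.3, 1, 2, 2.5, 2.8)),
    "duplicated")
  expect_equal(f$n, 5)  # the two t = 0 points were averaged
})

test_that("fit methods behave like a standard model object", {
  fit <- fit_fractional_conversion(make_tc(0, 60, 0.131))
  expect_named(coef(fit), c("C0", "Cinf", "K"))
  expect_equal(predict(fit, 0), coef(fit)[["C0"]], tolerance = 1e-6)
  expect_equal(unname(predict(fit)), fit$fitted)
  expect_equal(residuals(fit), fit$conc - fit$fitted)
  expect_lt(summary(fit)$rss, 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(9L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
})

test_that("background subtraction is pointwise with zero-clipping", {
  tc <- timecourse("O1", "Mno", 1, "x", c(0, 2), c(0.05, 0.10))
  ctl <- timecourse("O1", "control", 1, "x", c(0, 2), c(0.08, 0.02))
  out <- subtract_background(tc, ctl)
  expect_equal(out$conc, c(0, 0.08))
  expect_equal(out$clipped_points, 1L)
  expect_true(out$corrected)

  # self-subtraction is identically zero
  a <- make_tc(0, 30, 0.2, matrix = "control", corrected = FALSE)
  self <- subtract_background(make_tc(0, 30, 0.2, corrected = FALSE), a)
  expect_equal(self$conc, rep(0, 9))

  # a zero control leaves the series untouched (except the corrected flag)
  zero <- timecourse("O1", "control", 1, "acetate", t9, rep(0, 9))
  tc2 <- make_tc(0, 30, 0.2, corrected = FALSE)
  out2 <- subtract_background(tc2, zero)
  expect_equal(out2$conc, tc2$conc)
  expect_true(out2$corrected)
})

test_that("subtraction without clipping is invertible", {
  set.seed(3)
  ctl <- timecourse("O1", "control", 1, "acetate", t9, runif(9, 0, 2))
  tc <- make_tc(0, 3, 0.1, corrected = FALSE)  # dips below control early on
  out <- subtract_background(tc, ctl, clip_at_zero = FALSE)
  expect_equal(out$conc + ctl$conc, tc$conc)
})

test_that("background pairing and grid alignment are enforced", {
  tc <- make_tc(0, 30, 0.2, corrected = FALSE)
  expect_error(
    subtract_background(tc, timecourse("O2", "control", 1, "acetate", t9,
                                       rep(0, 9))),
    "donor or analyte")
  expect_error(
    subtract_background(tc, timecourse("O1", "Mnc", 1, "acetate", t9,
                                       rep(0, 9))),
    "control arm")
  short <- timecourse("O1", "control", 1, "acetate", c(0, 24, 48),
                      c(0.1, 0.2, 0.3))
  expect_error(subtract_background(tc, short), "interpolate")
  # and the explicit interpolation path agrees with linear interpolation
  out <- subtract_background(tc, short, interpolate = TRUE)
  expect_equal(out$conc,
               pmax(tc$conc - approx(short$times, short$conc, t9)$y, 0))
})

test_that("degradation extent uses observed endpoints and is scale-free", {
  tc <- timecourse("O1", "Mno", 1, "procyanidins",
                   c(0, 24, 48), c(10, 4, 1.6), corrected = TRUE)
  expect_equal(degradation_extent(tc), 84)
  for (s in c(0.01, 3, 1000)) {
    sc <- timecourse("O1", "Mno", 1, "procyanidins",
                     c(0, 24, 48), s * c(10, 4, 1.6), corrected = TRUE)
    expect_equal(degradation_extent(sc), 84)
  }
  full <- timecourse("O1", "Mno", 1, "p", c(0, 48), c(10, 0))
  none <- timecourse("O1", "Mno", 1, "p", c(0, 48), c(10, 10))
  expect_equal(degradation_extent(full), 100)
  expect_equal(degradation_extent(none), 0)
  expect_error(degradation_extent(timecourse("O1", "Mno", 1, "p",
                                             c(0, 48), c(0, 1))),
               "not positive")
  expect_error(degradation_extent(timecourse("O1", "Mno", 1, "p",
                                             c(0, 24), c(1, 0.5))),
               "t = 0 and t = 48")
})

test_that("rate tables have one row per arm and keep non-converged fits", {
  expect_equal(nrow(build_rate_table(list())), 0)

  two <- list(fit_fractional_conversion(make_tc(0, 60, 0.1, donor = "O1")),
              fit_fractional_conversion(make_tc(0, 60, 0.2, donor = "O2")))
  expect_equal(nrow(build_rate_table(two)), 2)

  grid <- expand.grid(donor = paste0("O", 1:4),
                      matrix = c("Mno", "Mnc", "Mcov"),
                      analyte = c("acetate", "propionate", "butyrate",
                                  "procyanidins"),
                      stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i)
    list(donor = grid$donor[i], matrix = grid$matrix[i],
         analyte = grid$analyte[i],
         fit = list(K = 0.1, converged = i %% 7 != 0)))
  tab <- build_rate_table(fits)
  expect_equal(nrow(tab), 48)
  expect_true(any(!tab$converged))  # flagged, not dropped

  expect_error(build_rate_table(c(two, two[1])), "duplicate")
})

test_that("timecourse invariants are enforced at construction", {
  expect_error(timecourse("O1", "Mnc", 1, "a", c(0, 2, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(timecourse("O1", "Mnc", 1, "a", c(0, 2), c(1, 2, 3)),
               "same length")
  expect_error(timecourse("O1", "Mnc", 1, "a", c(0, 2), c(1, NaN)), "finite")
  expect_error(timecourse("O1", "Mnc", 1, "a", c(0, 2), c(-1, 2)),
               "non-negative")
  # negative values are representable once flagged as corrected
  ok <- timecourse("O1", "Mnc", 1, "a", c(0, 2), c(-1, 2), corrected = TRUE)
  expect_equal(ok$conc[1], -1)
})
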