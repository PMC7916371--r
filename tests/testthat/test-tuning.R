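test_that("a synthetic symmetric quadratic is recovered exactly", {
  pts <- synthetic_quadratic_ptc(tip_level = 30, half_low = 278.25,
                                 half_high = 278.25)
  f <- fit_ptc(pts)
  expect_null(f$error)
  expect_equal(f$bw10, 556.5, tolerance = 1e-6)
  expect_equal(f$q10db, 4, tolerance = 1e-4)
  expect_equal(f$tip_level, 30, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("asymmetric noiseless curves match their generators to 4 sig figs", {
  for (hl in c(200, 400)) {
    for (hh in c(300, 600)) {
      pts <- synthetic_quadratic_ptc(tip_level = 25, half_low = hl,
                                     half_high = hh)
      f <- fit_ptc(pts)
      expect_null(f$error)
      expect_equal(f$bw10, hl + hh, tolerance = 1e-6)
      expect_equal(f$q10db, 2226 / (hl + hh), tolerance = 1e-4)
      # fitted coefficients reproduce the generating quadratics
      a_low <- 10 / hl^2
      expect_equal(unname(f$low_side["a"]), a_low, tolerance = 1e-6)
    }
  }
})

test_that("the >10 dB monotonicity rule excludes planted outliers", {
  pts <- synthetic_quadratic_ptc(tip_level = 30)
  clean <- fit_ptc(pts)
  # plant an extra low-side point far below the running maximum
  outlier <- data.frame(fm = 1550, threshold_db_spl = 20)
  f <- fit_ptc(rbind(pts, outlier))
  expect_equal(f$excluded, 8L)   # the planted row
  expect_lt(abs(f$q10db - clean$q10db), 1e-9)

  # a point 15 dB below its inward neighbour's level is excluded
  pts2 <- pts[order(pts$fm), ]
  pts2$threshold_db_spl[2] <-
    pts2$threshold_db_spl[3] - 15      # 1637 falls 15 dB under 1898.5
  excl <- exclude_nonmonotonic(pts2)
  expect_true(2 %in% excl$excluded)

  # a deviation of exactly 10 dB is retained (strict inequality)
  pts3 <- pts[order(pts$fm), ]
  pts3$threshold_db_spl[1] <-
    max(pts3$threshold_db_spl[2:4]) - 10
  excl3 <- exclude_nonmonotonic(pts3)
  expect_length(excl3$excluded, 0)

  # strictly V-shaped curves lose nothing
  expect_length(exclude_nonmonotonic(pts)$excluded, 0)
})

test_that("degenerate curves return an error object, not a bandwidth", {
  flat <- data.frame(fm = masker_frequencies(),
                     threshold_db_spl = rep(50, 7))
  f <- fit_ptc(flat)
  expect_false(is.null(f$error))
  expect_true(is.na(f$bw10))
  expect_error(q10(2226, 0), "positive")
  expect_error(q10(2226, -5), "positive")
  expect_equal(q10(2226, 2226), 1)
  expect_equal(q10(2226, 556.5), 4)
  expect_equal(q10(2226, 278.25), 8)
  # a side with fewer than 3 surviving points is flagged unreliable
  few <- data.frame(fm = c(1898.5, 2226, 2619, 3143),
                    threshold_db_spl = c(40, 25, 38, 55))
  ff <- fit_ptc(few)
  expect_false(ff$reliable)
})

test_that("bundled group-mean curves order Q10dB by spread", {
  g <- example_group_ptc()
  q <- sapply(c("low", "medium", "high"), function(sp) {
    gi <- g[g$spread == sp, ]
    fit_ptc(data.frame(fm = gi$fm,
                       threshold_db_spl = gi$threshold_db_spl))$q10db
  })
  expect_lt(q[["high"]], q[["low"]])
  expect_lte(q[["high"]], q[["medium"]])
  # same magnitudes as the reported group summary: ~8, ~7, ~3
  expect_equal(unname(q[["low"]]), 8, tolerance = 0.15)
  expect_equal(unname(q[["medium"]]), 7, tolerance = 0.15)
  expect_equal(unname(q[["high"]]), 3.8, tolerance = 0.15)
})

test_that("log-frequency fitting is available and consistent", {
  pts <- synthetic_quadratic_ptc(tip_level = 30)
  f <- fit_ptc(pts, log_freq = TRUE)
  expect_null(f$error)
  expect_gt(f$q10db, 2)
  expect_lt(f$q10db, 8)
})
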