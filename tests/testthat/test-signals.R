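test_that("hand-worked tables give the known statistic values", {
  # balanced table: every estimator at its null
  s <- signal_stats(10, 10, 10, 10)
  expect_equal(s$ror, 1.0)
  expect_equal(s$prr, 1.0)
  expect_equal(s$ebgm, 1.0)
  expect_equal(s$ic, 0.0)
  expect_equal(s$chi2, 0.0)
  expect_equal(s$ror_lo, exp(-1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(s$ror_hi, exp(1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(round(c(s$ror_lo, s$ror_hi), 3), c(0.289, 3.454))

  # skewed table, arithmetic done by hand
  s <- signal_stats(3, 7, 97, 9893)
  expect_equal(s$ror, 3 * 9893 / (7 * 97), tolerance = 1e-12)
  expect_equal(round(s$ror, 2), 43.71)
  expect_equal(s$prr, (3 / 10) / (97 / 9990), tolerance = 1e-12)
  expect_equal(round(s$prr, 2), 30.90)
  expect_equal(s$ebgm, 30.0, tolerance = 1e-12)
  expect_equal(round(s$ebgm05, 2), 7.64)

  # Pearson chi-square without correction: N(ad-bc)^2 / product of margins
  expect_equal(chi_square(20, 10, 10, 20, yates = FALSE),
               60 * (400 - 100)^2 / (30 * 30 * 30 * 30), tolerance = 1e-12)
  expect_equal(round(chi_square(20, 10, 10, 20, yates = FALSE), 3), 6.667)
})

test_that("statistics agree with an independent brute-force oracle", {
  set.seed(404)
  n_tab <- 250
  a <- sample(1:50, n_tab, TRUE)
  b <- sample(1:200, n_tab, TRUE)
  c <- sample(1:500, n_tab, TRUE)
  d <- sample(1:20000, n_tab, TRUE)
  got_y <- signal_stats(a, b, c, d, yates = TRUE)
  got_r <- signal_stats(a, b, c, d, yates = FALSE)
  for (i in seq_len(n_tab)) {
    o <- oracle_stats(a[i], b[i], c[i], d[i])
    for (f in c("ror", "ror_lo", "ror_hi", "prr", "prr_lo", "prr_hi",
                "ic", "ic_minus_2sd", "ebgm", "ebgm05")) {
      expect_equal(got_y[[f]][i], o[[f]], tolerance = 1e-12)
    }
    expect_equal(got_y$chi2[i], o$chi2_yates, tolerance = 1e-12)
    expect_equal(got_r$chi2[i], o$chi2, tolerance = 1e-12)
  }
})

test_that("chi-square cross-checks stats::chisq.test on both variants", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1:30, 1); b <- sample(1:100, 1)
    c <- sample(1:100, 1); d <- sample(1:5000, 1)
    m <- matrix(c(a, b, c, d), 2)
    expect_equal(chi_square(a, b, c, d, yates = FALSE),
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-10)
    expect_equal(chi_square(a, b, c, d, yates = TRUE),
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("algebraic invariants hold over random tables", {
  set.seed(2024)
  a <- sample(1:60, 400, TRUE); b <- sample(1:300, 400, TRUE)
  c <- sample(1:300, 400, TRUE); d <- sample(1:30000, 400, TRUE)
  s <- signal_stats(a, b, c, d)

  # identity: IC is exactly log2 of the observed/expected ratio
  expect_equal(s$ic, log2(s$ebgm), tolerance = 1e-14)
  # sign concordance across all four estimators (away from exact ties,
  # where floating-point rounding makes the sign of zero ill-defined)
  m <- abs(s$ror - 1) > 1e-9
  expect_gt(sum(m), 350)
  expect_equal(sign(s$ror - 1)[m], sign(s$prr - 1)[m])
  expect_equal(sign(s$ror - 1)[m], sign(s$ebgm - 1)[m])
  expect_equal(sign(s$ror - 1)[m], sign(s$ic)[m])
  # log-symmetry: the point is the geometric mean of its bounds
  expect_equal(sqrt(s$ror_lo * s$ror_hi), s$ror, tolerance = 1e-12)
  expect_equal(sqrt(s$prr_lo * s$prr_hi), s$prr, tolerance = 1e-12)
  expect_equal(implied_point_from_ci(s$ror_lo, s$ror_hi), s$ror,
               tolerance = 1e-12)
  # label swap (a<->b, c<->d) inverts the odds ratio
  sw <- signal_stats(b, a, d, c)
  expect_equal(sw$ror, 1 / s$ror, tolerance = 1e-12)
  # Yates correction never increases the statistic
  expect_true(all(chi_square(a, b, c, d, TRUE) <=
                    chi_square(a, b, c, d, FALSE) + 1e-12))
})

test_that("ror and ebgm increase strictly in a; ebgm/prr has limit c/(a+c)", {
  base <- signal_stats(5:10, 40, 60, 8000)
  expect_true(all(diff(base$ror) > 0))
  expect_true(all(diff(base$ebgm) > 0))
  # as d grows with a, b, c fixed, ebgm/prr converges to c/(a+c),
  # i.e. the two estimators coincide when the target event is a
  # vanishing share of the target drug's reports
  ratio <- sapply(10^(3:7), function(d) {
    s <- signal_stats(5, 40, 60, d)
    s$ebgm / s$prr
  })
  expect_true(all(diff(abs(ratio - 60 / 65)) < 0))
  expect_equal(ratio[5], 60 / 65, tolerance = 1e-4)
  s <- signal_stats(5, 40, 5000, 1e7)
  expect_equal(s$ebgm / s$prr, 1, tolerance = 1e-2)
})

test_that("zero cells follow the chosen policy and are flagged", {
  strict <- signal_stats(5, 0, 60, 8000, zero_policy = "strict")
  expect_true(is.na(strict$ror))
  expect_false(strict$continuity_corrected)
  corr <- signal_stats(5, 0, 60, 8000, zero_policy = "correct")
  expect_true(corr$continuity_corrected)
  expect_equal(corr$ror, (5.5 * 8000.5) / (0.5 * 60.5), tolerance = 1e-12)
  expect_equal(corr$a, 5)  # original counts are preserved in the output
  expect_equal(corr$b, 0)
  # tables without zeros are never altered
  both <- signal_stats(c(5, 5), c(0, 7), c(60, 60), c(8000, 8000))
  expect_false(both$continuity_corrected[2])
  expect_equal(both$ror[2], 5 * 8000 / (7 * 60), tolerance = 1e-12)
})

test_that("threshold rules and BCPNN bands classify as specified", {
  mk <- function(a, ror_lo, prr_lo, ic2sd, ebgm05) {
    data.table::data.table(a = a, ror = 2, ror_lo = ror_lo, ror_hi = 9,
                           prr = 2, prr_lo = prr_lo, prr_hi = 9, chi2 = 5,
                           ic = 1, ic_minus_2sd = ic2sd, ebgm = 2,
                           ebgm05 = ebgm05, continuity_corrected = FALSE)
  }
  # all four pass
  r <- classify_signal(mk(3, 1.01, 1.01, 0.1, 2.01))
  expect_true(r$consensus)
  expect_equal(r$band, "+")
  # a >= 3 gate blocks ROR/PRR regardless of the interval
  r <- classify_signal(mk(2, 50, 50, 0.1, 2.01))
  expect_false(r$ror_signal)
  expect_false(r$prr_signal)
  expect_false(r$consensus)
  # band boundaries: (0,1.5] weak, (1.5,3] medium, >3 strong, <=0 none
  expect_equal(classify_signal(mk(3, 2, 2, 1.5, 3))$band, "+")
  expect_equal(classify_signal(mk(3, 2, 2, 1.6, 3))$band, "++")
  expect_equal(classify_signal(mk(3, 2, 2, 3.0, 3))$band, "++")
  expect_equal(classify_signal(mk(3, 2, 2, 3.1, 3))$band, "+++")
  r0 <- classify_signal(mk(3, 2, 2, 0, 3))
  expect_equal(r0$band, "-")
  expect_false(r0$bcpnn_signal)
  # EBGM05 threshold is strict
  expect_false(classify_signal(mk(3, 2, 2, 1, 2))$ebgm_signal)
  # undefined statistics classify as no signal
  na_row <- mk(3, NA, NA, NA, NA)
  rna <- classify_signal(na_row)
  expect_false(any(rna$ror_signal, rna$prr_signal, rna$bcpnn_signal,
                   rna$ebgm_signal, rna$consensus))
  expect_equal(rna$band, "-")
})

test_that("bate variance variant gives a finite, more conservative bound at small a", {
  delta <- information_component(3, 7, 97, 9893, variance = "delta")
  bate <- information_component(3, 7, 97, 9893, variance = "bate")
  expect_equal(delta$ic, bate$ic)  # the point estimate is shared
  expect_true(is.finite(bate$ic_minus_2sd))
  expect_lt(bate$ic_minus_2sd, delta$ic)
})

test_that("implied point recovers published-style interval midpoints", {
  expect_equal(implied_point_from_ci(4, 4), 4)
  expect_equal(round(implied_point_from_ci(6.56, 7.47), 2), 7.00)
  expect_equal(round(implied_point_from_ci(3.05, 3.54), 2), 3.29)
  expect_error(implied_point_from_ci(-1, 2), "positive")
  expect_error(implied_point_from_ci(3, 2), "lower bound exceeds")
})
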