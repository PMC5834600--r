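test_that("positivity rule is inclusive and takes either population", {
  expect_true(classify_positive(13.8, 2.0))   # CD31-like pair
  expect_false(classify_positive(0, 0))
  expect_false(classify_positive(5.4999, 5.4999))
  expect_true(classify_positive(5.5, 0))
  expect_true(classify_positive(0, 5.5))
  expect_error(classify_positive(120, 0))
})

test_that("fold increase floors the denominator and flags it", {
  f <- fold_increase(30, 10)
  expect_equal(as.numeric(f), 3)
  expect_false(attr(f, "floored"))
  expect_equal(as.numeric(fold_increase(42.7, 42.7)), 1)
  expect_equal(as.numeric(fold_increase(13.8, 2.0)), 6.9)
  f0 <- fold_increase(5, 0, floor = 0.5)
  expect_equal(as.numeric(f0), 10)
  expect_true(attr(f0, "floored"))
})

test_that("two-group ANOVA matches the textbook F-statistic", {
  expect_equal(test_marker(c(10, 12, 14), c(10, 12, 14)),
               1)  # identical groups -> F = 0 -> p = 1... but var > 0
  g1 <- c(10, 12, 14); g2 <- c(20, 22, 24)
  # independent oracle: F = SSB/dfB / (SSW/dfW) computed from sums of squares
  gm <- mean(c(g1, g2))
  ssb <- 3 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_stat <- (ssb / 1) / (ssw / 4)
  p_oracle <- stats::pf(f_stat, 1, 4, lower.tail = FALSE)
  expect_equal(test_marker(g1, g2), p_oracle)
  # degenerate zero-variance conventions
  expect_equal(test_marker(c(5, 5), c(5, 5)), 1)
  expect_equal(test_marker(c(5, 5), c(9, 9)), 0)
  expect_error(test_marker(1, c(2, 3)), "test error")
})

test_that("ANOVA p is close to the exhaustive permutation p at n = 3 + 3", {
  # The exact permutation p over the 20 assignments is granular (multiples
  # of 0.05, floor 0.1), so agreement within 0.02 is assessable only where
  # the F-test lands inside that resolvable range; fixtures span p ~ 0.1-0.3.
  fixtures <- list(
    list(g1 = c(16.1, 8.9, 19.6), g2 = c(27.7, 20.8, 21.7)),
    list(g1 = c(5, 16, 11.5), g2 = c(16.3, 24.6, 13.5)),
    list(g1 = c(15.9, 17.9, 21.6), g2 = c(17.6, 22, 26.5)))
  for (fx in fixtures) {
    y <- c(fx$g1, fx$g2)
    obs <- abs(mean(fx$g1) - mean(fx$g2))
    combos <- utils::combn(6, 3)
    perm_stats <- apply(combos, 2, function(ix)
      abs(mean(y[ix]) - mean(y[-ix])))
    p_perm <- mean(perm_stats >= obs - 1e-12)
    p_anova <- test_marker(fx$g1, fx$g2)
    expect_lt(abs(p_anova - p_perm), 0.02)
  }
})

test_that("paired t mode respects pairing", {
  g1 <- c(10, 20, 30); g2 <- c(12, 22, 32)  # constant shift
  cfg <- screen_config(test = "paired-t")
  expect_equal(test_marker(g1, g2, cfg), 0)  # zero-variance differences
  g2b <- c(12, 21, 33)
  expect_equal(test_marker(g1, g2b, cfg),
               stats::t.test(g1, g2b, paired = TRUE)$p.value)
  expect_error(test_marker(g1, c(1, 2), cfg), "equal group lengths")
})

test_that("enrichment filter uses inclusive fold and strict alpha", {
  expect_true(flag_enriched(1.6, 0.01))
  expect_true(flag_enriched(1.5, 0.049))
  expect_false(flag_enriched(1.5, 0.05))
  expect_false(flag_enriched(1.49, 0.001))
  expect_false(flag_enriched(NA_real_, 0.001))
})

test_that("stain index matches hand-computed values on constructed samples", {
  ctrl <- 100 + (10 / 1.4826) * c(-2, -1, 0, 1, 2)
  expect_equal(stats::mad(ctrl), 10)                 # rSD construction
  expect_equal(stain_index(ctrl, ctrl), 0)           # identity
  expect_equal(stain_index(ctrl + 200, ctrl), 10)    # (300-100)/(2*10)
  expect_true(is.na(stain_index(rep(5, 10) + 3, rep(5, 10))))  # zero spread
  expect_true(is.na(stain_index(numeric(0), ctrl)))
})

test_that("stain index is shift-invariant and scales inversely with spread", {
  set.seed(14)
  ctrl <- stats::rlnorm(5000, 4, 0.5)
  stn <- stats::rlnorm(5000, 5.5, 0.5)
  si <- stain_index(stn, ctrl)
  expect_equal(stain_index(stn + 1000, ctrl + 1000), si)
  for (c_ in c(2, 5)) {
    med_c <- stats::median(ctrl)
    scaled_ctrl <- med_c + c_ * (ctrl - med_c)  # spread x c, median fixed
    expect_equal(stain_index(stn, scaled_ctrl), si / c_, tolerance = 1e-12)
  }
})

test_that("stain-index fold handles non-positive reference separation", {
  expect_equal(si_fold(10, 10), 1)
  expect_equal(si_fold(20.8, 2.0), 10.4)
  expect_true(is.na(si_fold(5, 0)))
  expect_true(is.na(si_fold(5, -1)))
  expect_true(is.na(si_fold(NA_real_, 3)))
})

test_that("background statistics recover a planted population ratio", {
  set.seed(15)
  ctrl <- list(FCS = stats::rlnorm(40000, log(390), 0.5),
               PLT = stats::rlnorm(40000, log(30), 0.5))
  bg <- background_stats(ctrl)
  expect_equal(attr(bg, "ratio"), 13, tolerance = 0.1)
  same <- list(FCS = ctrl$PLT, PLT = ctrl$PLT)
  expect_equal(attr(background_stats(same), "ratio"), 1)
  tiny <- list(FCS = c(1, 2, 3), PLT = c(1, 2, 3))
  bg_tiny <- background_stats(tiny)
  expect_true(all(bg_tiny$low_n))
  expect_error(background_stats(list()), "no control wells")
})

test_that("delta-delta-Ct follows the 2^-ddCt arithmetic", {
  expect_equal(ddct_fold(20, 18, 21, 19), 1)
  expect_equal(ddct_fold(20, 18, 22, 18), 4)
  expect_equal(ddct_fold(19, 18, 20, 18), 2)  # one fewer target cycle
  expect_equal(ddct_fold(c(20, 20.4), c(18, 18.2), c(22, 22.4), c(18, 18.2)),
               2^-((20.2 - 18.1) - (22.2 - 18.1)))
  expect_error(ddct_fold(numeric(0), 18, 22, 18), "non-empty")
  expect_error(ddct_fold(NaN, 18, 22, 18), "finite")
})
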