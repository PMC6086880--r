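test_that("BAI of a single outer ring is the closed-form annulus area", {
  s <- ring_series("t1", "p1", "black_spruce", dbh_cm = 10,
                   sampling_year = 2005, years = 2005, width_mm = 5)
  tab <- rings_to_bai(s)
  expect_equal(tab$bai, pi * (5^2 - 4.5^2), tolerance = 1e-12)
  # zero-width ring gives a zero BAI
  s0 <- ring_series("t2", "p1", "black_spruce", 10, 2005,
                    years = 2004:2005, width_mm = c(3, 0))
  expect_equal(rings_to_bai(s0)$bai[2], 0)
})

test_that("BAI telescopes to outer disc minus pith disc for random series", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    w <- runif(n, 0, 3)
    dbh <- sum(w) / 10 * 2 + runif(1, 0.5, 10)
    s <- ring_series(paste0("t", i), "p", "balsam_fir", dbh,
                     2005, years = (2006 - n):2005, width_mm = w)
    tab <- rings_to_bai(s)
    r_pith <- dbh / 2 - sum(w) / 10
    expect_equal(sum(tab$bai), pi * (dbh / 2)^2 - pi * r_pith^2,
                 tolerance = 1e-9)
  }
})

test_that("cumulative widths exceeding the radius are rejected with the tree id", {
  expect_error(
    rings_to_bai(ring_series("bad_tree", "p", "aspen", dbh_cm = 4,
                             sampling_year = 2005, years = 2001:2005,
                             width_mm = rep(6, 5))),
    "bad_tree")
})

test_that("ring series validation catches malformed inputs", {
  expect_error(ring_series("t", "p", "aspen", 12, 2005,
                           years = c(2001, 2003), width_mm = c(1, 1)),
               "contiguous")
  expect_error(ring_series("t", "p", "aspen", 12, 2005,
                           years = 2000:2004, width_mm = rep(1, 5)),
               "outermost")
  # outer_lag = 1 permits the year-before convention
  expect_s3_class(ring_series("t", "p", "aspen", 12, 2005,
                              years = 2000:2004, width_mm = rep(1, 5),
                              outer_lag = 1),
                  "ring_series")
})

test_that("Tukey screening matches a brute-force quartile oracle", {
  x <- c(1, 1, 1, 1, 1, 1, 1, 100)
  expect_identical(tukey_screen(x, k = 3), oracle_tukey_flags(x, k = 3))
  expect_true(tukey_screen(x, k = 3)[8])
  # all-equal values: IQR 0, everything on the fence, no flags
  expect_false(any(tukey_screen(rep(2.5, 10))))
  # infinite fences flag nothing
  expect_false(any(tukey_screen(c(1, 2, 3, 1000), k = Inf)))
  set.seed(7)
  for (i in 1:25) {
    v <- rlnorm(sample(4:30, 1), 1, 1)
    expect_identical(tukey_screen(v, k = 3), oracle_tukey_flags(v, k = 3))
  }
  expect_warning(flags <- tukey_screen(c(1, 2, 3)), "fewer than 4")
  expect_false(any(flags))
})

test_that("growth window selects recent years within the study period", {
  # sampled 1997, rings to 1997: 13 years, kept
  w <- growth_window(1960:1997)
  expect_equal(w$years, 1985:1997)
  expect_equal(w$n, 13)
  expect_true(w$kept)
  # rings 2000-2012: only 6 years inside the period, dropped
  w <- growth_window(2000:2012)
  expect_equal(w$years, 2000:2005)
  expect_false(w$kept)
  # long series capped at 15 years
  w <- growth_window(1950:2005)
  expect_equal(w$years, 1991:2005)
  # order-independent and idempotent
  expect_equal(growth_window(sample(1950:2005)), growth_window(1950:2005))
  expect_equal(growth_window(growth_window(1950:2005)$years),
               growth_window(1950:2005))
})

test_that("tree summaries average reconstructed diameter, age and BAI", {
  s <- ring_series("t", "p", "jack_pine", dbh_cm = 20, sampling_year = 2005,
                   years = 1956:2005, width_mm = rep(1.5, 50))
  obs <- summarize_tree(s)
  expect_equal(obs$n_years, 15)
  # monotone reconstruction: mean annual DBH < sampling DBH
  expect_lt(obs$size, 20)
  tab <- rings_to_bai(s)
  win <- tab$year %in% 1991:2005
  expect_equal(obs$size, mean(tab$dbh_cm[win]))
  expect_equal(obs$age, mean(tab$age[win]))
  expect_equal(obs$bai, mean(tab$bai[win]))
  expect_gte(obs$age, obs$n_years)
  # short trees are dropped with a message
  s2 <- ring_series("t2", "p", "jack_pine", 12, 2012,
                    years = 2000:2012, width_mm = rep(1, 13))
  expect_message(res <- summarize_tree(s2), "dropped")
  expect_null(res)
})
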