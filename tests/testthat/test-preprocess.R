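test_that("asinh transform matches its closed forms and preserves order", {
  m <- matrix(c(0, 1, 10, 1e6), 2, 2)
  expect_equal(asinh_transform(m, 5)[1, 1], 0)
  expect_equal(asinh_transform(matrix(1e6), 1)[1, 1], log(2e6),
               tolerance = 1e-9)
  set.seed(2)
  x <- runif(1000, 0, 1e4); y <- x + runif(1000, 1e-6, 10)
  expect_true(all(asinh_transform(matrix(x), 3) <
                    asinh_transform(matrix(y), 3)))
  # commutes with row subsetting
  mm <- matrix(runif(200), 20)
  i <- c(3, 7, 15)
  expect_equal(asinh_transform(mm, 2)[i, ], asinh_transform(mm[i, ], 2),
               ignore_attr = TRUE)
  expect_error(asinh_transform(mm, 0), "positive")
  expect_error(asinh_transform(mm, -1), "positive")
})

test_that("buffer gating separates signal from background", {
  buffer <- simulate_sample(list(), 0, seed = 2,
                            metadata = ev_metadata(role = "buffer",
                                                   acquisition_minutes = 10))
  sample <- two_pop_sample(n = 4000, seed = 3)
  # EV brightness >> background: nearly all EVs retained
  gated <- gate_events(sample, buffer, quantile = 0.99)
  expect_gt(n_events(gated) / n_events(sample), 0.95)
  # self-gating retains about 1 percent
  self <- gate_events(buffer, buffer, quantile = 0.99)
  expect_lt(abs(attr(self, "retained_fraction") - 0.01), 0.01)
  # quantile 1: only strictly brighter than the buffer max passes
  all_gate <- gate_events(buffer, buffer, quantile = 1)
  expect_equal(n_events(all_gate), 0)
  # retention is monotone nonincreasing in the quantile
  fr <- vapply(c(0.5, 0.9, 0.99, 1), function(q)
    attr(gate_events(sample, buffer, q), "retained_fraction"), numeric(1))
  expect_true(all(diff(fr) <= 0))
  tiny <- subset_events(buffer, 1:10)
  expect_error(gate_events(sample, tiny), "fewer than")
})

test_that("dilution QC accepts ideal series and rejects swarm points", {
  pops <- list(pop("A", 1, 800, 0))
  ideal <- simulate_dilution_series(pops, 16000, c(1, 2, 4, 8), seed = 5,
                                    defaults = quiet_defaults())
  qc <- qc_dilution_series(ideal)
  expect_equal(qc$accepted, c(1, 2, 4, 8))
  expect_gt(qc$r_squared, 0.99)
  expect_lte(qc$mfi_cv, 0.20)

  sat <- simulate_dilution_series(pops, 16000, c(1, 2, 4, 8), seed = 5,
                                  defaults = quiet_defaults(swarm_ceiling = 10000),
                                  swarm = TRUE)
  qc2 <- qc_dilution_series(sat)
  expect_false(1 %in% qc2$accepted)
  expect_true(all(c(2, 4, 8) %in% qc2$accepted))
  expect_error(qc_dilution_series(ideal[1:2]), "at least 3")
})

test_that("QC accepted window is maximal (brute-force check)", {
  pops <- list(pop("A", 1, 800, 0))
  series <- simulate_dilution_series(pops, 16000, c(1, 2, 4, 8, 16), seed = 8,
                                     defaults = quiet_defaults(swarm_ceiling = 10000),
                                     swarm = TRUE)
  qc <- qc_dilution_series(series)
  # enumerate every contiguous window of >= 3 points independently
  tab <- qc$table
  ok_len <- integer(0)
  for (s in 1:(nrow(tab) - 2)) for (e in (s + 2):nrow(tab)) {
    x <- 1 / tab$dilution[s:e]; y <- tab$events_per_min[s:e]
    r2 <- summary(lm(y ~ x))$r.squared
    cv <- sd(tab$mfi_611[s:e]) / mean(tab$mfi_611[s:e])
    if (r2 >= qc$r2_min && cv <= qc$mfi_cv_max) ok_len <- c(ok_len, e - s + 1)
  }
  expect_equal(length(qc$accepted), max(c(0L, ok_len)))
})

test_that("lysis check passes on detergent controls and fails on identity", {
  pops <- list(pop("A", 1, 800, 0.1))
  stained <- simulate_sample(pops, 10000, seed = 4,
                             metadata = ev_metadata(acquisition_minutes = 2))
  ctl <- simulate_controls(pops, 10000, seed = 4,
                           metadata = ev_metadata(acquisition_minutes = 2))
  chk <- lysis_check(stained, ctl$lysed)
  expect_lt(chk$ratio, 0.05)
  expect_true(chk$pass)
  same <- lysis_check(stained, stained)
  expect_equal(same$ratio, 1)
  expect_false(same$pass)
  empty <- two_pop_sample(n = 0)
  expect_error(lysis_check(empty, ctl$lysed), "zero events")
})

test_that("dilution-corrected concentration follows the declared formula", {
  expect_equal(dilution_corrected_concentration(0, 1, 3.66, 1), 0)
  expect_equal(dilution_corrected_concentration(50000, 1, 3.66, 1),
               50000 / 3.66 * 1000)
  expect_equal(dilution_corrected_concentration(50000, 1, 3.66, 1) / 1e7,
               1.366, tolerance = 1e-3)
  c1 <- dilution_corrected_concentration(1234, 2, 3.66, 2)
  c2 <- dilution_corrected_concentration(1234, 2, 3.66, 4)
  expect_equal(c2 / c1, 2)
  expect_error(dilution_corrected_concentration(10, 0, 3.66, 1), "positive")
})
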