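mixture_spectrum_for_test <- function(alpha, m) {
  outer(alpha, m$w_lo) + outer(1 - alpha, m$w_ld)
}

test_that("alpha_for_gp inverts the spectral mixture exactly", {
  m <- spectral_model()
  rng <- gp_range(m)
  expect_equal(alpha_for_gp(rng[2], m), 1)
  expect_equal(alpha_for_gp(rng[1], m), 0)
  set.seed(7)
  alpha0 <- runif(100)
  g <- apply(mixture_spectrum_for_test(alpha0, m), 1, gp_of_spectrum)
  expect_equal(alpha_for_gp(g, m), alpha0, tolerance = 1e-9)
  expect_error(alpha_for_gp(rng[2] + 0.05, m), "outside achievable range")
})

test_that("basis spectra satisfy the declared invariants", {
  m <- spectral_model()
  expect_equal(sum(m$w_lo), 1)
  expect_equal(sum(m$w_ld), 1)
  expect_gt(gp_of_spectrum(m$w_lo), 0)
  expect_lt(gp_of_spectrum(m$w_ld), 0)
  expect_equal(which.max(m$w_lo), 3L)  # 611 nm peak (ordered)
  expect_equal(which.max(m$w_ld), 4L)  # 702 nm peak (disordered)
  expect_error(spectral_model(w_lo = c(0.5, 0.2, 0.1, 0.1, 0.1)),
               "peak at 611")
})

test_that("identical seed and spec give identical event tables", {
  a <- two_pop_sample(n = 500, seed = 123)
  b <- two_pop_sample(n = 500, seed = 123)
  expect_identical(a$data, b$data)
  c <- two_pop_sample(n = 500, seed = 124)
  expect_false(identical(a$data, c$data))
})

test_that("degenerate noise reproduces gp_target exactly; n = 0 is empty", {
  m <- spectral_model(channel_cv = 0)
  tab <- simulate_sample(list(pop("only", 1, 800, 0.23, gp_sd = 0)),
                         200, seed = 5, model = m,
                         defaults = quiet_defaults())
  g <- gp_value(tab$data[["Intensity_488-611"]], tab$data[["Intensity_488-702"]])
  expect_equal(g, rep(0.23, 200), tolerance = 1e-9)
  expect_equal(n_events(simulate_sample(list(), 0, 1,
                                        defaults = quiet_defaults())), 0)
  expect_error(simulate_sample(list(pop("a", 0.7, 100, 0),
                                    pop("b", 0.6, 100, 0)), 10, 1),
               "fractions sum")
  expect_error(simulate_sample(list(pop("a", 1, 100, 0.9)), 10, 1),
               "outside achievable")
})

test_that("population GP medians and label marginals match the generator", {
  n <- 20000
  pops <- list(pop("A", 0.4, 400, -0.4), pop("B", 0.3, 800, -0.1),
               pop("C", 0.2, 1600, 0.2), pop("D", 0.1, 3200, 0.4))
  tab <- simulate_sample(pops, n, seed = 31, defaults = quiet_defaults())
  g <- gp_value(tab$data[["Intensity_488-611"]], tab$data[["Intensity_488-702"]])
  targets <- c(A = -0.4, B = -0.1, C = 0.2, D = 0.4)
  fractions <- c(A = 0.4, B = 0.3, C = 0.2, D = 0.1)
  for (p in names(targets)) {
    idx <- tab$data$.population == p
    expect_lt(abs(median(g[idx]) - targets[[p]]), 0.01)
    # binomial 99% CI on the label marginal
    ci <- 2.576 * sqrt(fractions[[p]] * (1 - fractions[[p]]) / n)
    expect_lt(abs(mean(idx) - fractions[[p]]), ci + 1e-9)
  }
})

test_that("control set has the contracted composition", {
  pops <- list(pop("A", 0.9, 600, 0.1, cargo_probs = c(CD63 = 0.4)))
  ctl <- simulate_controls(pops, 5000, seed = 77)
  stained <- simulate_sample(pops, 5000, seed = 77)
  # lysis removes all vesicles: only rate-based events remain
  expect_false(any(ctl$lysed$data$.population %in% c("A")))
  expect_lt(n_events(ctl$lysed) / n_events(stained), 0.05)
  # buffer is background only
  expect_true(all(ctl$buffer$data$.population == "background"))
  # isotype positivity sits at the configured floor: at a threshold well
  # above the noise floor and below the positive mode, almost nothing passes
  iso_pos <- mean(ctl$isotype$data[["Intensity_405-456"]] > 50)
  stained_pos <- mean(stained$data[["Intensity_405-456"]]
                      [stained$data$.population == "A"] > 50)
  expect_lt(iso_pos, 0.02)
  expect_gt(stained_pos, 0.2)
  expect_identical(ctl$buffer$metadata$role, "buffer")
  expect_identical(ctl$lysed$metadata$role, "lysed")
})

test_that("dilution series scales EV counts as 1/dilution", {
  pops <- list(pop("A", 1, 800, 0))
  series <- simulate_dilution_series(pops, 16000, c(1, 2, 4, 8), seed = 3,
                                     defaults = quiet_defaults())
  counts <- vapply(series, n_events, integer(1))
  fit <- lm(counts ~ I(1 / c(1, 2, 4, 8)))
  expect_gt(summary(fit)$r.squared, 0.99)
  # deep dilution approaches the background-only level
  deep <- simulate_dilution_series(pops, 16000, 1e6, seed = 3)[[1]]
  expect_lt(n_events(deep), 1000)  # nuisance events only
  expect_error(simulate_dilution_series(pops, 100, numeric(0), 1),
               "empty dilution factor")
})

test_that("swarm saturation merges coincident events into brighter ones", {
  pops <- list(pop("A", 1, 800, 0))
  d <- quiet_defaults(swarm_ceiling = 4000)  # events/min; 2 min acquisition
  series <- simulate_dilution_series(pops, 16000, c(1, 8), seed = 9,
                                     defaults = d, swarm = TRUE)
  expect_lte(n_events(series[["1"]]), 8000)
  mfi <- vapply(series, function(t) median(t$data[["Intensity_488-611"]]),
                numeric(1))
  expect_gt(mfi[["1"]], mfi[["8"]])
  expect_true(any(startsWith(series[["1"]]$data$.population, "swarm:")))
})
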