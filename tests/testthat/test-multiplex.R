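ab_chans <- c(CD63 = "Intensity_405-456", CD81 = "Intensity_642-702")

test_that("positivity thresholds reproduce the worst-control quantile", {
  floor_sample <- function(seed, n = 5000, meanlog = log(2), sdlog = 0.6) {
    simulate_sample(list(pop("A", 1, 500, 0,
                             cargo_probs = c(CD63 = 0, CD81 = 0))),
                    n, seed, defaults = quiet_defaults(
                      ab_floor_meanlog = meanlog, ab_floor_sdlog = sdlog))
  }
  c1 <- floor_sample(1)
  c2 <- floor_sample(2, meanlog = log(3))  # brighter floor dominates
  thr <- positivity_threshold(list(c1, c2), ab_chans["CD63"])
  # the quantile-oracle: empirical 99th order statistic of the worst control
  q <- function(t) {
    x <- sort(t$data[[ab_chans["CD63"]]])
    x[ceiling(0.99 * length(x))]
  }
  expect_equal(as.numeric(thr), max(q(c1), q(c2)))
  # achieved false-positive rates at most 1 percent in every control
  expect_true(all(attr(thr, "control_fp") <= 0.01))
  # large-sample agreement with the distribution quantile
  expect_equal(as.numeric(thr), qlnorm(0.99, log(3), 0.6), tolerance = 0.05)
  # all-zero control: threshold at the zero boundary, nothing exceeds
  z <- c1
  z$data[[ab_chans["CD63"]]] <- 0
  thr0 <- positivity_threshold(list(z), ab_chans["CD63"])
  expect_equal(as.numeric(thr0), 0)
  expect_equal(unname(attr(thr0, "control_fp")), 0)
  expect_error(positivity_threshold(list(subset_events(c1, 1:10)),
                                    ab_chans["CD63"]), "at least 100")
})

test_that("cargo classification is exhaustive, exclusive and independent", {
  tab <- simulate_sample(
    list(pop("A", 1, 800, 0, cargo_probs = c(CD63 = 0.3, CD81 = 0.2),
             cargo_meanlog = log(500))),
    50000, seed = 41, defaults = quiet_defaults())
  thr <- c(CD63 = 50, CD81 = 50)  # between floor and positive mode
  status <- classify_cargo(tab, thr, ab_chans)
  expect_equal(sum(table(status)), 50000)
  frac <- prop.table(table(status))
  # independence: dual+ close to the product of the marginals (99% CI)
  p_a <- 0.3; p_b <- 0.2; p_dual <- p_a * p_b
  ci <- 2.576 * sqrt(p_dual * (1 - p_dual) / 50000)
  expect_lt(abs(frac[["dual+"]] - p_dual), ci + 0.01)
  expect_equal(frac[["CD63+"]], p_a * (1 - p_b), tolerance = 0.05)
  # manual quadrant logic on a constructed event
  tiny <- tab
  tiny$data <- tab$data[1:3, ]
  tiny$data[[ab_chans["CD63"]]] <- c(100, 100, 1)
  tiny$data[[ab_chans["CD81"]]] <- c(1, 100, 100)
  expect_equal(as.character(classify_cargo(tiny, thr, ab_chans)),
               c("CD63+", "dual+", "CD81+"))
  expect_error(classify_cargo(tiny, thr, c(CD63 = "nope", CD81 = "x")),
               "missing")
  # threshold monotonicity: raising a threshold never adds positives
  n_pos <- function(t63) sum(classify_cargo(tab, c(CD63 = t63, CD81 = 50),
                                            ab_chans) != "negative")
  expect_true(all(diff(vapply(c(10, 50, 200, 1000), n_pos, numeric(1))) <= 0))
})

test_that("per-cluster cargo partitioning conserves counts and proportions", {
  set.seed(5)
  clusters <- sample(0:3, 2000, replace = TRUE)
  status <- factor(sample(c("negative", "CD63+", "CD81+", "dual+"), 2000,
                          replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05)),
                   levels = c("negative", "CD63+", "CD81+", "dual+"))
  part <- cargo_partition_by_cluster(status, clusters)
  expect_equal(sum(part$n), sum(clusters > 0))
  sums <- tapply(part$proportion, part$cluster, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  # all-negative input: every cluster 100 percent negative
  all_neg <- factor(rep("negative", 2000),
                    levels = c("negative", "CD63+", "CD81+", "dual+"))
  pn <- cargo_partition_by_cluster(all_neg, clusters)
  expect_true(all(pn$proportion[pn$status == "negative"] == 1))
})

test_that("status-vs-size regression recovers constructed slopes", {
  size <- c(100, 300, 700, 1500, 2500)
  down <- c(80, 60, 45, 30, 10)   # decreasing in size (CD63-like)
  up <- c(10, 25, 45, 60, 85)     # increasing in size (CD81-like)
  r1 <- status_vs_size_regression(down, size)
  r2 <- status_vs_size_regression(up, size)
  expect_lt(r1$slope, 0)
  expect_gt(r2$slope, 0)
  expect_gt(r2$r_squared, 0.9)
  cst <- status_vs_size_regression(c(40, 40, 40), c(1, 2, 3))
  expect_equal(cst$slope, 0)
  expect_equal(cst$r_squared, 0)  # documented convention
  expect_error(status_vs_size_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("quadrant gating partitions and reports the large/small ratio", {
  tab <- simulate_sample(list(pop("small", 0.9, 300, 0),
                              pop("large", 0.1, 30000, 0)),
                         20000, seed = 13, defaults = quiet_defaults())
  ssc_thr <- median(tab$data$SSC[tab$data$.population == "small"]) * 4
  i_thr <- median(tab$data[["Intensity_488-611"]]
                  [tab$data$.population == "small"]) * 4
  qg <- quadrant_gate(tab, ssc_thr, i_thr)
  expect_equal(sum(qg$counts), 20000)
  ur_frac <- qg$counts[["ur"]] / 20000
  ci <- 2.576 * sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(ur_frac - 0.1), ci + 0.01)
  expect_equal(qg$ratio_large_small,
               qg$counts[["ur"]] / (20000 - qg$counts[["ur"]]))
  # all events below both thresholds; non-finite thresholds rejected
  qg0 <- quadrant_gate(tab, 1e18, 1e18)
  expect_equal(unname(qg0$counts), c(20000, 0, 0, 0))
  expect_error(quadrant_gate(tab, Inf, 10), "is.finite")
})
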