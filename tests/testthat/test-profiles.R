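test_that("GP matches its closed form, bounds and scale invariance", {
  expect_equal(gp_value(5, 5), 0)
  expect_equal(gp_value(7, 0), 1)
  expect_equal(gp_value(0, 3), -1)
  expect_equal(gp_value(3, 1), 0.5)
  expect_true(is.na(gp_value(0, 0)))
  set.seed(1)
  a <- runif(1000, 0, 1e4); b <- runif(1000, 0, 1e4)
  # exact under power-of-two scaling (no rounding), 1e-12 otherwise
  expect_identical(gp_value(8 * a, 8 * b), gp_value(a, b))
  c <- runif(1000, 0.1, 9)
  expect_equal(gp_value(c * a, c * b), gp_value(a, b), tolerance = 1e-12)
  expect_true(all(gp_value(a, b) >= -1 & gp_value(a, b) <= 1))
  expect_error(gp_value(-1, 2), "nonnegative")
})

test_that("total fluorescence is the linear 5-channel intensity sum", {
  tab <- two_pop_sample(n = 50, seed = 6)
  cols <- paste0("Intensity_488-", c(528, 583, 611, 702, 773))
  manual <- rowSums(as.matrix(tab$data[, cols]))
  expect_equal(total_fluorescence(tab), manual)
  tab$data[1, cols] <- as.list(c(10, 20, 40, 25, 5))
  expect_equal(total_fluorescence(tab)[1], 100)
  scaled <- tab
  scaled$data[cols] <- tab$data[cols] * 3
  expect_equal(total_fluorescence(scaled), 3 * total_fluorescence(tab))
  broken <- tab
  broken$data[[cols[2]]] <- NULL
  expect_error(total_fluorescence(broken), "missing")
})

test_that("cluster profiles equal brute-force per-event recomputation", {
  tab1 <- two_pop_sample(n = 600, seed = 11, id = "u")
  tab2 <- two_pop_sample(n = 400, seed = 12, id = "v")
  # assignment from ground truth (independent of any clustering)
  mk_assign <- function(t) tibble::tibble(
    sample_id = t$sample_id, event = seq_len(n_events(t)),
    cluster = as.integer(factor(t$data$.population, c("lo", "hi"))))
  asg <- dplyr::bind_rows(mk_assign(tab1), mk_assign(tab2))
  prof <- profile_clusters(list(tab1, tab2), asg)

  pooled_raw <- rbind(tab1$data, tab2$data)
  for (k in 1:2) {
    p <- c("lo", "hi")[k]
    rows <- pooled_raw$.population == p
    expect_equal(prof$pooled$n_pooled[k], sum(rows))
    expect_equal(prof$pooled$mfi_611[k],
                 median(pooled_raw[["Intensity_488-611"]][rows]))
    g <- (pooled_raw[["Intensity_488-611"]][rows] -
            pooled_raw[["Intensity_488-702"]][rows]) /
         (pooled_raw[["Intensity_488-611"]][rows] +
            pooled_raw[["Intensity_488-702"]][rows])
    expect_equal(prof$pooled$gp_median[k], median(g))
    expect_equal(prof$pooled$tfl[k],
                 median(rowSums(as.matrix(
                   pooled_raw[rows, paste0("Intensity_488-",
                                           c(528, 583, 611, 702, 773))]))))
  }
  # abundance fractions + noise sum to 1 per sample; counts conserved
  for (sid in c("u", "v")) {
    ps <- prof$per_sample[prof$per_sample$sample_id == sid, ]
    expect_equal(sum(ps$abundance), 1)
    expect_equal(sum(ps$n), if (sid == "u") 600L else 400L)
  }
  # size rank follows brightness: hi population has rank 1
  expect_equal(prof$pooled$size_rank[2], 1L)
  # dilution correction: corrected counts use each sample's metadata
  m <- tab1$metadata
  expect_equal(
    prof$per_sample$corrected_count[prof$per_sample$sample_id == "u" &
                                      prof$per_sample$cluster == 1],
    sum(tab1$data$.population == "lo") /
      (m$acquisition_minutes * m$flow_rate_ul_per_min) * m$dilution * 1000)
})

test_that("minor clusters are filtered at the 1 percent default", {
  pooled <- tibble::tibble(cluster = 1:4,
                           abundance = c(0.5, 0.3, 0.15, 0.005),
                           mfi_611 = c(4, 3, 2, 1))
  prof <- structure(list(pooled = pooled,
                         per_sample = tibble::tibble(
                           sample_id = "s", cluster = 0:4, n = 1,
                           abundance = 0.2)),
                    class = "cluster_profiles")
  out <- filter_minor_clusters(prof)
  expect_equal(out$pooled$cluster, 1:3)
  expect_equal(out$minor$cluster, 4L)
  expect_equal(filter_minor_clusters(prof, 0)$pooled$cluster, 1:4)
  expect_false(4L %in% out$per_sample$cluster)
  expect_true(0L %in% out$per_sample$cluster)
})

test_that("S-EV/L-EV classification follows pellet enrichment and MFI", {
  # construct profiles directly: 4 clusters with known shares
  per_sample <- tibble::tibble(
    sample_id = rep(c("p10", "p100"), each = 4),
    cluster = rep(1:4, 2),
    n = c(100, 900, 500, 10, 900, 100, 500, 990),
    condition = rep(c("10K", "100K"), each = 4),
    role = "none",
    corrected_count = c(100, 900, 500, 10, 900, 100, 500, 990) * 10,
    abundance = 0.1)
  pooled <- tibble::tibble(cluster = 1:4, n_pooled = 1000,
                           mfi_611 = c(10, 1000, 600, 20),
                           gp_median = 0, gp_q1 = 0, gp_q3 = 0,
                           gp_undefined = 0, tfl = 1, abundance = 0.25,
                           size_rank = c(4L, 1L, 2L, 3L))
  prof <- structure(list(pooled = pooled, per_sample = per_sample),
                    class = "cluster_profiles")
  out <- classify_sev_lev(prof, "p10", "p100")
  expect_equal(out$share_100k, c(0.9, 0.1, 0.5, 0.99))
  # cluster 1: 100K-enriched + lowest MFI -> S-EV
  # cluster 2: 10K-enriched -> L-EV; cluster 3: 50/50 but high MFI -> uncl.
  # cluster 4: 100K-enriched + low MFI -> S-EV
  expect_equal(out$sev_lev, c("S-EV", "L-EV", "unclassified", "S-EV"))
  expect_error(classify_sev_lev(prof, "p10", "missing"), "present")
})

test_that("percent of control and the change map respond to knockdown", {
  # two samples identical except population lo reduced 10-fold in kd
  pops_ctrl <- list(pop("lo", 0.5, 400, -0.3), pop("hi", 0.5, 3200, 0.3))
  pops_kd <- list(pop("lo", 0.0909, 400, -0.3), pop("hi", 0.9091, 3200, 0.3))
  ctrl <- simulate_sample(pops_ctrl, 20000, 21, "ctrl",
                          defaults = quiet_defaults())
  kd <- simulate_sample(pops_kd, 11000, 22, "kd",
                        defaults = quiet_defaults())
  mk_assign <- function(t) tibble::tibble(
    sample_id = t$sample_id, event = seq_len(n_events(t)),
    cluster = as.integer(factor(t$data$.population, c("lo", "hi"))))
  prof <- profile_clusters(list(ctrl, kd),
                           dplyr::bind_rows(mk_assign(ctrl), mk_assign(kd)))
  pc <- percent_of_control(prof, "ctrl")
  expect_equal(pc$percent_of_control[pc$cluster == 1], 10, tolerance = 0.1)
  expect_equal(pc$percent_of_control[pc$cluster == 2], 100, tolerance = 0.05)
  # control vs itself is 100 percent everywhere
  pc_self <- percent_of_control(prof, "kd")
  expect_true(all(abs(pc_self$percent_of_control /
                        (100 / pc$percent_of_control * 100) - 1) < 0.01))
  som <- size_order_change_map(prof, "ctrl", "kd", covariate = "gp_median")
  reg <- attr(som, "regression")
  expect_gt(reg$slope, 0)  # low-GP population was suppressed
  expect_equal(nrow(som), 2)
})

test_that("ladder mapping brackets cluster statistics", {
  lad <- standard_ladder(paste0("chol_", c(0, 15, 30, 45)),
                         c(-0.45, -0.15, 0.15, 0.42), kind = "gp")
  pooled <- tibble::tibble(cluster = 1:4, n_pooled = 1,
                           mfi_611 = 1, gp_median = c(-0.6, -0.15, 0.0, 0.5),
                           gp_q1 = 0, gp_q3 = 0, gp_undefined = 0, tfl = 1,
                           abundance = 0.25, size_rank = 1:4)
  prof <- structure(list(pooled = pooled, per_sample = NULL),
                    class = "cluster_profiles")
  out <- map_to_ladder(prof, lad)
  expect_equal(out$ladder_interval,
               c("below chol_0", "chol_15", "chol_15..chol_30",
                 "above chol_45"))
  expect_error(standard_ladder(c("a", "b", "c"), c(1, 3, 2)), "monotone")
})
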