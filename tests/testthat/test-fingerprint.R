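test_that("subsampling is uniform, seeded and source-faithful", {
  tabs <- list(two_pop_sample(n = 1000, seed = 1, id = "x"),
               two_pop_sample(n = 500, seed = 2, id = "y"))
  s <- subsample_events(tabs, 0.5, seed = 9)
  expect_equal(sum(s$sample_id == "x"), 500)
  expect_equal(sum(s$sample_id == "y"), 250)
  # all drawn events exist in their source, without replacement
  expect_false(any(duplicated(s[, c("sample_id", "event")])))
  expect_true(all(s$event[s$sample_id == "y"] <= 500))
  # same seed -> identical selection; fraction 1 -> identity
  s2 <- subsample_events(tabs, 0.5, seed = 9)
  expect_identical(s, s2)
  all_ev <- subsample_events(tabs, 1, seed = 1)
  expect_equal(nrow(all_ev), 1500)
  expect_equal(all_ev$event[all_ev$sample_id == "x"], 1:1000)
})

test_that("embedding preserves separability and is reproducible", {
  tab <- two_pop_sample(n = 600, seed = 8)
  feats <- asinh_transform(select_di8_features(tab), 1)
  e1 <- embed_events(feats, seed = 4)
  e2 <- embed_events(feats, seed = 4)
  expect_equal(e1$coords, e2$coords)
  # silhouette of the true labels in 2-D
  lab <- as.integer(factor(tab$data$.population))
  d <- as.matrix(dist(e1$coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(embed_events(feats[1:10, ], n_neighbors = 15),
               "more events than n_neighbors")
})

test_that("clustering the embedding recovers the simulated populations", {
  tabs <- bench_tables(n = 5000, seed = 2)
  sub <- subsample_events(tabs, 1, seed = 3)
  feats <- asinh_transform(as.matrix(sub[, di8_channel_names()]), 1)
  emb <- embed_events(feats, seed = 5)
  lab <- cluster_embedding(emb)
  truth <- sub$.population
  ev <- truth %in% LETTERS[1:4]
  expect_gte(attr(lab, "n_clusters"), 4)
  expect_gt(adjusted_rand_index(truth[ev], as.integer(lab)[ev]), 0.8)
  expect_error(cluster_embedding(matrix(numeric(0), 0, 2)), "empty")
})

test_that("stage-2 reexamination filters full data with high fidelity", {
  tabs <- bench_tables(n = 5000, seed = 4)
  sub <- subsample_events(tabs, 0.4, seed = 5)
  feats <- asinh_transform(as.matrix(sub[, di8_channel_names()]), 1)
  emb <- embed_events(feats, seed = 6)
  lab <- cluster_embedding(emb)
  ids <- setdiff(sort(unique(lab)), 0L)
  expect_identical(nrow(reexamine_clusters(tabs, feats, lab, integer(0))), 0L)
  expect_error(reexamine_clusters(tabs, feats, lab, max(ids) + 5L),
               "absent from the subsample")
  asg <- reexamine_clusters(tabs, feats, lab, ids, seed = 7)
  # selecting all clusters recovers at least the assigned subsample size
  expect_gte(nrow(asg), sum(lab > 0))
  # held-out accuracy vs ground truth through cluster->population matching
  cmap <- match_clusters(sub$.population, as.integer(lab))
  full <- bind_events(tabs)
  got <- dplyr::inner_join(asg, full, by = c("sample_id", "event"))
  ok <- cmap[as.character(got$cluster)] == got$.population
  ev <- got$.population %in% LETTERS[1:4]
  expect_gt(mean(ok[ev]), 0.95)
  # ground-truth membership count changes by < 5 percent per EV cluster
  for (i in ids) {
    p <- cmap[as.character(i)]
    if (!p %in% LETTERS[1:4]) next
    n_true <- sum(full$.population == p)
    expect_lt(abs(sum(got$cluster == i) - n_true) / n_true, 0.05)
  }
})

test_that("buffer-derived clusters are removed by origin fraction", {
  labels <- c(rep(1L, 60), rep(2L, 40), rep(3L, 50))
  sample_ids <- c(rep("s", 60),                 # pure sample cluster
                  rep("buf", 40),               # pure buffer cluster
                  rep(c("s", "buf"), c(40, 10)))  # mixed, 20% buffer
  roles <- c(s = "none", buf = "buffer")
  out <- remove_buffer_clusters(labels, sample_ids, roles)
  expect_equal(attr(out, "removed"), 2L)
  expect_true(all(out[61:100] == 0L))
  expect_true(all(out[1:60] > 0L))
  expect_true(all(out[101:150] > 0L))
  # time normalization: buffer acquired 4x longer counts 4x less
  out2 <- remove_buffer_clusters(
    c(rep(1L, 80)), rep(c("s", "buf"), c(30, 50)), roles,
    minutes = c(s = 1, buf = 4))
  expect_length(attr(out2, "removed"), 0)  # 50/4 = 12.5 vs 30 -> kept
  expect_error(remove_buffer_clusters(labels, sample_ids,
                                      c(s = "none", buf = "none")),
               "no buffer")
})
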