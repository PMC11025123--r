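# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nuisance-free simulator settings for tests that need clean ground truth.
quiet_defaults <- function(...) {
  scenario_defaults(background_rate = 0, free_dye_rate = 0, ...)
}

pop <- function(name, fraction, brightness, gp, ...) {
  population_spec(name, fraction, log_brightness_mean = log(brightness),
                  gp_target = gp, ...)
}

# Two bright, well-separated populations on a quiet background.
two_pop_sample <- function(n = 1500, seed = 42, id = "s", ...) {
  simulate_sample(list(pop("lo", 0.5, 400, -0.3), pop("hi", 0.5, 3200, 0.3)),
                  n, seed, sample_id = id, defaults = quiet_defaults(), ...)
}

# The four-population benchmark at reduced size for unit tests.
bench_tables <- function(n = 6000, seed = 1) {
  simulate_scenario(demo_scenario(n_events = n), seed = seed)
}

adjusted_rand_index <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  comb <- function(x) sum(choose(x, 2))
  exp_idx <- comb(rowSums(ct)) * comb(colSums(ct)) / choose(n, 2)
  max_idx <- 0.5 * (comb(rowSums(ct)) + comb(colSums(ct)))
  (comb(ct) - exp_idx) / (max_idx - exp_idx)
}

# Match each cluster to the ground-truth population contributing most of its
# events; returns a named map cluster id -> population label.
match_clusters <- function(truth, clusters) {
  ids <- setdiff(sort(unique(clusters)), 0L)
  stats::setNames(
    vapply(ids, function(i) names(which.max(table(truth[clusters == i]))),
           character(1)),
    ids)
}
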