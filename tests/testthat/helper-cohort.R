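# One moderately sized simulated cohort, built once and shared across test
# files (simulation dominates test runtime otherwise).
.cohort_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.cohort_cache$c200)) {
    spec <- cohort_spec(n_mss = 200, n_msih = 200)
    sim <- simulate_cohort(spec, seed = 101)
    tagged <- tag_in_repeats(sim$cohort, build_repeat_index(sim$track))
    feats <- extract_features(tagged, sim$capture_mb)
    feats <- set_msi_status(feats,
                            stats::setNames(sim$labels$status, sim$labels$tumor_id))
    .cohort_cache$c200 <- list(spec = spec, sim = sim, tagged = tagged,
                               feats = feats)
  }
  .cohort_cache$c200
}

# Small end-to-end run: simulate, split in half, fit on a compact grid,
# return held-out accuracy.
heldout_accuracy <- function(n_per_class = 60, effect = 1, seed = 1) {
  spec <- cohort_spec(n_mss = n_per_class, n_msih = n_per_class,
                      effect = effect)
  sim <- simulate_cohort(spec, seed = seed)
  tagged <- tag_in_repeats(sim$cohort, build_repeat_index(sim$track))
  feats <- extract_features(tagged, sim$capture_mb)
  labels <- stats::setNames(sim$labels$status, sim$labels$tumor_id)
  plan <- stratified_split(stats::setNames(sim$labels$status,
                                           sim$labels$tumor_id),
                           test_fraction = 0.5, seed = seed)
  tr <- intersect(train_ids(plan), rownames(feats))
  te <- intersect(test_ids(plan), rownames(feats))
  fit <- msi_fit(feats[tr, ], labels[tr], C = c(1, 100), gamma = c(0.01, 0.1),
                 folds = 5, seed = seed)
  mean(predict(fit, feats[te, ]) == labels[te])
}
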