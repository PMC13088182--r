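# Shared fixtures, built in code. Generated data sets are cached per
# (scenario, seed) so test files can reuse them without regeneration.

.payn_cache <- new.env(parent = emptyenv())

cached_scenario <- function(name = "separable", seed = 1L) {
  key <- paste(name, seed, sep = "/")
  if (is.null(.payn_cache[[key]])) {
    gen <- generate_hte_dataset(make_scenario(name, seed = seed))
    feats <- featurize_reaction(gen$table, featurizer_spec(mode = "passthrough"))
    .payn_cache[[key]] <- list(gen = gen, table = gen$table, features = feats)
  }
  .payn_cache[[key]]
}

# Tiny hand-built reaction table: 3 roles are overkill for plumbing
# tests, two suffice.
tiny_table <- function(yields = c(0, 55.3, 100)) {
  reaction_table(
    data.frame(halide = c("c1ccc(Br)cc1", "c1ccc(Cl)cc1", "c1ccc(I)cc1"),
               ligand = c("CCO", "CCO", "CC(C)O"),
               stringsAsFactors = FALSE),
    yield_pct = yields)
}

# Run the spy pipeline on a cached scenario and return every stage.
run_spy_pipeline <- function(scen, pu_ratio = 0.5, spy_rate = 0.1,
                             tolerance = 0.05, seed = 101L, n_spies = NULL) {
  labels <- binarize_yields(scen$table)
  pu <- make_pu_dataset(scen$table, labels,
                        bias_spec(pu_ratio = pu_ratio, seed = seed))
  asg <- inject_spies(pu, spy_rate = spy_rate, seed = seed + 1L,
                      n_spies = n_spies)
  clf <- fit_pu_classifier(scen$features, asg)
  spy_scores <- predict(clf, scen$features, ids = asg$spy_ids)
  thr <- compute_spy_threshold(spy_scores, tolerance)
  rn <- extract_reliable_negatives(pu, asg, clf, scen$features, thr)
  list(labels = labels, pu = pu, assignment = asg, clf = clf,
       spy_scores = spy_scores, thr = thr, rn = rn)
}
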