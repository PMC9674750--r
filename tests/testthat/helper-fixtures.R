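# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no stored data.

rand_space <- function(n, d, seed) {
  withr::with_seed(seed, {
    vector_space(matrix(rnorm(n * d), n, d),
                 labels = sprintf("w%03d", seq_len(n)))
  })
}

# small labeled inventory: `spec` is a named vector label -> n images
toy_inventory <- function(spec, d = 4L, seed = 1L, freq = NULL) {
  withr::with_seed(seed, {
    labels <- rep(names(spec), spec)
    ids <- sprintf("%s_i%02d", labels,
                   unlist(lapply(spec, seq_len), use.names = FALSE))
    image_inventory(matrix(rnorm(length(labels) * d), ncol = d), ids, labels,
                    label_frequency = freq)
  })
}

# brute-force neighbor oracle: full sort of all cosines, lexicographic ties
oracle_neighbors <- function(space, query, k) {
  pool <- setdiff(rownames(space), query)
  sims <- vapply(pool, function(lb) cosine(space[lb, ], space[query, ]),
                 numeric(1))
  ord <- order(-sims, pool, method = "radix")
  data.frame(label = pool[ord][seq_len(k)], similarity = sims[ord][seq_len(k)],
             stringsAsFactors = FALSE)
}

# end-to-end zero-shot retrieval accuracy on held-out grounded labels
heldout_retrieval_accuracy <- function(noise_sd, seed, holdout_n = 25L,
                                       scheme = "exemplar") {
  w <- generate_world(world_config(
    n_words = 200L, lang_dim = 20L, vis_dim = 30L, n_training_labels = 60L,
    images_per_label = 8L, noise_sd = noise_sd, seed = seed))
  hold <- w$training_labels[seq_len(holdout_n)]
  keep <- which(!w$inventory$label %in% hold)
  inv_train <- image_inventory(w$inventory$features[keep, , drop = FALSE],
                               w$inventory$image_id[keep],
                               w$inventory$label[keep],
                               w$inventory$label_frequency)
  bt <- build_training_set(w$lang, inv_train, regime = "prototype",
                           target_dim = 30L)
  model <- fit_mapping(bt$training_set)
  inv_red <- project_features(w$inventory, bt$projection)
  proto_red <- project_features(compute_prototypes(w$inventory),
                                bt$projection)
  hits <- vapply(hold, function(lb) {
    v_hat <- predict(model, w$lang[lb, ])
    id <- retrieve_image(v_hat, inv_red, proto_red, scheme = scheme)
    identical(attr(id, "label"), lb)
  }, logical(1))
  list(accuracy = mean(hits), chance = 1 / length(w$training_labels),
       model = model, world = w, projection = bt$projection)
}

# simulated item covariate table for choice-model tests (standardized scales)
sim_items <- function(n_items, seed) {
  withr::with_seed(seed, {
    data.frame(word = sprintf("item%03d", seq_len(n_items)),
               concreteness = rnorm(n_items),
               mean_training_similarity = rnorm(n_items),
               stringsAsFactors = FALSE)
  })
}
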