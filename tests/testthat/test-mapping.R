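test_that("build_training_set assembles pairs per regime with SVD-reduced targets", {
  lang <- rand_space(10, 6, seed = 1)
  labs <- space_labels(lang)[1:5]
  inv <- withr::with_seed(2, {
    image_inventory(matrix(rnorm(5 * 3 * 4), 15, 4),
                    sprintf("%s_i%d", rep(labs, each = 3), rep(1:3, 5)),
                    rep(labs, each = 3))
  })

  # prototype regime: one pair per label, targets equal the SVD oracle rows
  bt <- build_training_set(lang, inv, regime = "prototype", target_dim = 3)
  expect_equal(nrow(bt$training_set$L), 5L)
  proto <- compute_prototypes(inv)
  oracle <- svd_reduce(unclass(proto$space), 3L)
  expect_equal(bt$training_set$V, oracle$reduced, tolerance = 1e-10)
  expect_equal(bt$training_set$L, unclass(lang)[rownames(oracle$reduced), ],
               tolerance = 1e-12, ignore_attr = TRUE)

  # exemplar regime: k pairs per label
  bt2 <- build_training_set(lang, inv, regime = "exemplar", target_dim = 3,
                            exemplar_k = 2, seed = 5)
  expect_equal(nrow(bt2$training_set$L), 10L)
  expect_true(all(table(bt2$training_set$labels) == 2L))

  # labels absent from the language space are reported
  bad <- image_inventory(inv$features, inv$image_id,
                         sub("w001", "unknown", inv$label))
  expect_error(build_training_set(lang, bad, regime = "prototype",
                                  target_dim = 3), "unknown")
})

test_that("fit_mapping solves the least-squares problem", {
  # identity map
  L <- withr::with_seed(3, matrix(rnorm(36), 6, 6))
  m_id <- fit_mapping(list(L = L, V = L))
  expect_equal(m_id$M, diag(6), tolerance = 1e-8, ignore_attr = TRUE)

  # planted-model recovery and normal-equations oracle, 50x8 -> 6
  withr::with_seed(7, {
    L <- matrix(rnorm(50 * 8), 50, 8)
    M_star <- matrix(rnorm(8 * 6), 8, 6)
  })
  V <- L %*% M_star
  fit <- fit_mapping(list(L = L, V = V))
  expect_equal(fit$M, M_star, tolerance = 1e-8, ignore_attr = TRUE)
  oracle <- solve(crossprod(L), crossprod(L, V))
  expect_equal(fit$M, oracle, tolerance = 1e-8, ignore_attr = TRUE)

  # with noise the solutions still coincide with the normal equations
  V_noisy <- V + withr::with_seed(8, matrix(rnorm(300, sd = 0.3), 50, 6))
  fit_n <- fit_mapping(list(L = L, V = V_noisy))
  expect_equal(fit_n$M, solve(crossprod(L), crossprod(L, V_noisy)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # a 400-dim language side against 300 reduced visual dims gives a 400x300 map
  withr::with_seed(9, {
    L4 <- matrix(rnorm(450 * 400), 450, 400)
    V4 <- matrix(rnorm(450 * 300), 450, 300)
  })
  expect_equal(dim(fit_mapping(list(L = L4, V = V4))$M), c(400L, 300L))

  expect_error(fit_mapping(list(L = matrix(0, 5, 2), V = matrix(1, 5, 2))),
               "degenerate")
  expect_warning(fit_mapping(list(L = L[1:4, ], V = V[1:4, ])),
                 "underdetermined")
})

test_that("predict is the linear map, verified coordinate-wise", {
  withr::with_seed(10, {
    L <- matrix(rnorm(40 * 5), 40, 5)
    M_star <- matrix(rnorm(5 * 4), 5, 4)
  })
  model <- fit_mapping(list(L = L, V = L %*% M_star))

  expect_equal(predict(model, rep(0, 5)), rep(0, 4), ignore_attr = TRUE)

  withr::with_seed(11, {
    l <- rnorm(5); x <- rnorm(5); y <- rnorm(5)
    a <- rnorm(1); b <- rnorm(1)
  })
  # homogeneity and additivity
  expect_equal(predict(model, a * l), a * predict(model, l), tolerance = 1e-10)
  expect_equal(predict(model, a * x + b * y),
               a * predict(model, x) + b * predict(model, y),
               tolerance = 1e-10)

  # per-coordinate loop oracle: v_j = sum_i M_ij l_i
  v <- predict(model, l)
  for (j in 1:4) {
    acc <- 0
    for (i in 1:5) acc <- acc + model$M[i, j] * l[i]
    expect_equal(unname(v[j]), acc, tolerance = 1e-10)
  }

  expect_error(predict(model, rnorm(6)), "expected 5")
})

test_that("retrieve_image matches exhaustive argmax oracles in both schemes", {
  d <- 5L
  labs <- c("A", "B", "C")
  inv <- toy_inventory(c(A = 4, B = 4, C = 4), d = d, seed = 12)
  protos <- compute_prototypes(inv)

  # exemplar self-match
  v_self <- inv$features[7, ]
  got <- retrieve_image(v_self, inv, scheme = "exemplar")
  expect_equal(as.character(got), inv$image_id[7])

  # brute-force two-loop oracle over random queries
  withr::with_seed(13, queries <- replicate(8, rnorm(d), simplify = FALSE))
  for (q in queries) {
    # exemplar: global argmax over images
    sims <- vapply(seq_len(12), function(i) cosine(q, inv$features[i, ]),
                   numeric(1))
    expect_equal(as.character(retrieve_image(q, inv, scheme = "exemplar")),
                 inv$image_id[which.max(sims)])
    # prototype: argmax prototype, then argmax image vs that prototype
    psims <- vapply(labs, function(lb)
      cosine(q, unclass(protos$space)[lb, ]), numeric(1))
    best_lab <- labs[which.max(psims)]
    idx <- which(inv$label == best_lab)
    isims <- vapply(idx, function(i)
      cosine(unclass(protos$space)[best_lab, ], inv$features[i, ]), numeric(1))
    expect_equal(as.character(retrieve_image(q, inv, protos,
                                             scheme = "prototype")),
                 inv$image_id[idx[which.max(isims)]])
  }

  # prototype stage 2: an image identical to the prototype wins
  feats <- rbind(c(1, 0), c(1, 0), c(0.6, 0.8), c(0, 1))
  inv2 <- image_inventory(feats, c("a1", "a2", "a3", "b1"),
                          c("A", "A", "A", "B"))
  pr2 <- compute_prototypes(inv2)
  proto_A <- unclass(pr2$space)["A", ]
  inv3 <- image_inventory(rbind(feats, proto_A),
                          c("a1", "a2", "a3", "b1", "a4"),
                          c("A", "A", "A", "B", "A"))
  pr3 <- compute_prototypes(inv3)
  got <- retrieve_image(unclass(pr3$space)["A", ] + c(0.01, 0), inv3, pr3,
                        scheme = "prototype")
  # the retrieved image must match the winning prototype exactly in cosine
  win <- unclass(pr3$space)[attr(got, "label"), ]
  best_cos <- max(vapply(which(inv3$label == attr(got, "label")),
                         function(i) cosine(win, inv3$features[i, ]),
                         numeric(1)))
  got_cos <- cosine(win, inv3$features[match(as.character(got),
                                             inv3$image_id), ])
  expect_equal(got_cos, best_cos, tolerance = 1e-12)

  empty <- image_inventory(matrix(numeric(0), 0, d), character(0), character(0))
  expect_error(retrieve_image(rnorm(d), empty), "empty")
})

test_that("random control draws are seeded, exclusive, and uniform", {
  expect_equal(pick_random_control(c("x", "y"), exclude = "x", seed = 99), "y")
  expect_equal(pick_random_control(letters, seed = 1),
               pick_random_control(letters, seed = 1))
  expect_error(pick_random_control(c("x"), exclude = "x", seed = 1),
               "no images")

  pool <- sprintf("img%02d", 1:10)
  draws <- vapply(1:1000, function(i) pick_random_control(pool, seed = i),
                  character(1))
  tab <- table(factor(draws, levels = pool))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("mapping models serialize and load losslessly", {
  withr::with_seed(20, {
    L <- matrix(rnorm(30 * 4), 30, 4)
    V <- matrix(rnorm(30 * 3), 30, 3)
  })
  model <- fit_mapping(list(L = L, V = V, regime = "prototype",
                            labels = sprintf("w%02d", 1:30)))
  dir <- withr::local_tempdir()
  write_mapping_model(model, dir)
  back <- read_mapping_model(dir)
  expect_equal(back$M, model$M, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$training_labels, model$training_labels)
  l <- withr::with_seed(21, rnorm(4))
  expect_equal(unname(predict(back, l)), unname(predict(model, l)),
               tolerance = 1e-12)
})
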