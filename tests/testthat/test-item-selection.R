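make_norms <- function(words, conc, freq, noun = TRUE) {
  data.frame(word = words, concreteness = conc, frequency = freq,
             is_noun = noun, stringsAsFactors = FALSE)
}

test_that("candidate_pool applies strict frequency bounds and exclusions", {
  vs <- rand_space(12, 4, seed = 40)
  labs <- space_labels(vs)
  norms <- make_norms(
    c(labs[1:10], "absent1", "absent2"),
    conc = seq(1, 5, length.out = 12),
    freq = c(100, 101, 500, 11999, 12000, 5000, 50, 3000, 800, 200, 400, 900),
    noun = c(rep(TRUE, 11), FALSE))
  training <- labs[c(8, 9)]
  pool <- candidate_pool(norms, vs, training)
  # hand filter: freq strictly in (100, 12000), in space, noun, not training
  expect_setequal(pool$word, labs[c(2, 3, 4, 6, 10)])
  expect_false(any(c(labs[1], labs[5], labs[7]) %in% pool$word))
  expect_false(any(training %in% pool$word))
  expect_error(candidate_pool(norms, vs, labs), "empty")
})

test_that("median_split partitions at the median with ties going abstract", {
  p <- make_norms(paste0("w", 1:4), c(1, 2, 3, 4), 1000)
  sp <- median_split(p)
  expect_setequal(sp$abstract$word, c("w1", "w2"))
  expect_setequal(sp$concrete$word, c("w3", "w4"))

  # degenerate: all equal ratings -> everything abstract
  pe <- make_norms(paste0("w", 1:5), rep(3, 5), 1000)
  expect_equal(nrow(median_split(pe)$abstract), 5L)
  expect_equal(nrow(median_split(pe)$concrete), 0L)

  # sizes match a sort-based oracle on an odd-sized pool
  conc <- withr::with_seed(41, runif(101, 1, 5))
  pr <- make_norms(sprintf("w%03d", 1:101), conc, 1000)
  sp2 <- median_split(pr)
  med <- sort(conc)[51]
  expect_equal(nrow(sp2$abstract), sum(conc <= med))
  expect_equal(nrow(sp2$concrete), sum(conc > med))
  expect_equal(nrow(sp2$abstract) + nrow(sp2$concrete), 101L)
  expect_length(intersect(sp2$abstract$word, sp2$concrete$word), 0L)
})

test_that("the five-condition design has the defining properties", {
  withr::with_seed(42, {
    n_abs <- 120L; n_con <- 120L
    abstract <- make_norms(sprintf("a%03d", 1:n_abs), runif(n_abs, 1, 2.5), 1000)
    concrete <- make_norms(sprintf("c%03d", 1:n_con), runif(n_con, 2.5, 5), 1000)
    counts <- c(
      stats::setNames(c(rep(0L, 60), rpois(60, 6)), abstract$word),
      stats::setNames(c(rep(0L, 40), rpois(80, 12)), concrete$word))
  })
  items <- build_conditions_exp12(abstract, concrete, counts, seed = 7)
  expect_equal(nrow(items), 115L)
  expect_equal(sort(unique(items$condition)),
               c("abstract/far", "abstract/near", "concrete/far",
                 "concrete/maximum", "concrete/near"))
  expect_equal(as.vector(table(items$condition)), rep(23L, 5))
  expect_false(anyDuplicated(items$word) > 0)

  # far conditions have zero visual neighbors by construction
  far <- items$visual_neighbor_count_k[grepl("/far", items$condition)]
  expect_true(all(far == 0L))

  # near/maximum are the count-maximizing choices
  abs_near <- items$word[items$condition == "abstract/near"]
  expect_equal(unname(sort(counts[abs_near], decreasing = TRUE)[1]),
               max(counts[setdiff(abstract$word,
                                  items$word[items$condition == "abstract/far"])]))

  # the near conditions end up with closely matched mean neighbor counts
  con_near <- items$word[items$condition == "concrete/near"]
  expect_lt(abs(mean(counts[con_near]) - mean(counts[abs_near])), 0.5)

  # deterministic under the seed
  again <- build_conditions_exp12(abstract, concrete, counts, seed = 7)
  expect_identical(items$word, again$word)

  expect_error(build_conditions_exp12(abstract[1:10, ], concrete, counts,
                                      seed = 7), "abstract/far")
})

test_that("near-count matching achieves the exhaustively best subset", {
  # exact brute force at small scale: every 5-subset of 12 candidates
  withr::with_seed(48, {
    small <- stats::setNames(rpois(12, 5), sprintf("s%02d", 1:12))
  })
  target <- 19L
  sel <- crossmap:::match_count_subset(small, 5L, target)
  expect_length(sel, 5L)
  expect_false(anyDuplicated(sel) > 0)
  combos <- utils::combn(names(small), 5L)
  best_gap <- min(abs(colSums(matrix(small[combos], nrow = 5L)) - target))
  expect_equal(abs(sum(small[sel]) - target), best_gap, ignore_attr = TRUE)

  # 23-of-30, the experimental configuration, against a set-based sum oracle
  withr::with_seed(43, {
    abs_counts <- rpois(23, 6) + 1L
    cand_counts <- stats::setNames(rpois(30, 6), sprintf("c%02d", 1:30))
  })
  target_sum <- sum(abs_counts)
  sel23 <- crossmap:::match_count_subset(cand_counts, 23L, target_sum)
  reach <- vector("list", 24L) # slot s+1 holds achievable sums using s items
  reach[[1L]] <- 0L
  for (ct in unname(cand_counts)) {
    for (sz in 23:1) {
      if (!is.null(reach[[sz]])) {
        reach[[sz + 1L]] <- unique(c(reach[[sz + 1L]], reach[[sz]] + ct))
      }
    }
  }
  best_gap23 <- min(abs(reach[[24L]] - target_sum))
  expect_equal(abs(sum(cand_counts[sel23]) - target_sum), best_gap23,
               ignore_attr = TRUE)
})

test_that("grid sampling respects cell caps, bin arithmetic, and decorrelates", {
  # undersized cell: both items selected
  pool <- data.frame(word = c("a", "b"), concreteness = c(1, 1.01),
                     mean_training_similarity = c(0.1, 0.1))
  out <- grid_sample_exp3(pool, n_bins = 1, per_cell = 4, seed = 1)
  expect_equal(nrow(out), 2L)

  # fully populated grid: exactly per_cell per cell
  withr::with_seed(44, {
    full <- expand.grid(cb = 1:10, sb = 1:10)
    full <- full[rep(seq_len(nrow(full)), each = 6), ]
    pool2 <- data.frame(
      word = sprintf("w%04d", seq_len(nrow(full))),
      concreteness = full$cb + runif(nrow(full), 0.05, 0.95) - 1,
      mean_training_similarity = full$sb + runif(nrow(full), 0.05, 0.95) - 1)
  })
  out2 <- grid_sample_exp3(pool2, n_bins = 10, per_cell = 4, seed = 2)
  expect_equal(nrow(out2), 400L)
  tab <- table(out2$concreteness_bin, out2$similarity_bin)
  expect_true(all(tab == 4L))

  # bin assignment agrees with floor arithmetic; max value goes to top bin
  x <- c(0, 0.94, 1.0, 2.5, 10)
  poolx <- data.frame(word = letters[1:5], concreteness = x,
                      mean_training_similarity = x)
  outx <- grid_sample_exp3(poolx, n_bins = 10, per_cell = 5, seed = 3)
  width <- (max(x) - min(x)) / 10
  want <- pmin(floor((x - min(x)) / width) + 1L, 10L)
  expect_equal(outx$concreteness_bin[match(letters[1:5], outx$word)], want)

  # Monte-Carlo decorrelation: sampling from a central rectangle window of
  # a pool at the experimental density (~30 items/cell) leaves the selected
  # |r| below the pooled |r| in >= 90% of seeded runs
  win <- list(concreteness_bins = 3:8, similarity_bins = 3:8)
  wins <- 0L
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      z <- matrix(rnorm(3000 * 2), ncol = 2)
      x1 <- z[, 1]
      x2 <- 0.53 * z[, 1] + sqrt(1 - 0.53^2) * z[, 2]
    })
    poolr <- data.frame(word = sprintf("w%04d", 1:3000), concreteness = x1,
                        mean_training_similarity = x2)
    sel <- grid_sample_exp3(poolr, n_bins = 10, per_cell = 4, window = win,
                            seed = s)
    if (abs(attr(sel, "achieved_r")) < abs(attr(sel, "pool_r"))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 90L)
})

test_that("split_lists gives a seeded partition with maximally even sizes", {
  items <- data.frame(word = sprintf("w%03d", 1:371))
  out <- split_lists(items, 3, seed = 9)
  expect_equal(sort(as.vector(table(out$list_id)), decreasing = TRUE),
               c(124L, 124L, 123L))
  # partition law: union equals input, lists disjoint
  expect_setequal(out$word, items$word)
  expect_false(anyDuplicated(out$word) > 0)

  out9 <- split_lists(data.frame(word = letters[1:9]), 3, seed = 1)
  expect_equal(as.vector(table(out9$list_id)), c(3L, 3L, 3L))
  expect_identical(split_lists(items, 3, seed = 9)$list_id, out$list_id)
})
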