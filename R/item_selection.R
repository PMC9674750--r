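#' Candidate word pool for item selection
#'
#' Filters a word-norms table down to the experimental candidate pool: nouns
#' only, word frequency strictly between `freq_min` and `freq_max`
#' (defaults 100 and 12,000 — medium-frequency words participants are likely
#' to know without extreme exposure), present in the language space, and
#' outside the visually grounded training set (zero-shot items only).
#'
#' @param norms Data frame with columns `word`, `concreteness`, `frequency`,
#'   `is_noun` (and optionally `known_proportion`).
#' @param lang A [vector_space()].
#' @param training_labels Character vector of training labels to exclude.
#' @param freq_min,freq_max Exclusive frequency bounds (defaults 100, 12000).
#' @return The filtered norms data frame.
#' @export
candidate_pool <- function(norms, lang, training_labels,
                           freq_min = 100, freq_max = 12000) {
  req <- c("word", "concreteness", "frequency", "is_noun")
  if (!all(req %in% names(norms))) {
    stop("norms table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  keep <- norms$is_noun &
    norms$frequency > freq_min & norms$frequency < freq_max &
    norms$word %in% rownames(lang) &
    !norms$word %in% training_labels
  out <- norms[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("candidate pool is empty", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Median split on concreteness
#'
#' Partitions the pool into abstract and concrete halves at the median
#' concreteness rating. Words exactly at the median go to the abstract side
#' (a fixed, documented tie rule), so the partition is exhaustive and
#' disjoint.
#'
#' @param pool A norms data frame with a `concreteness` column (>= 2 rows).
#' @return A list with data frames `abstract` and `concrete`.
#' @export
median_split <- function(pool) {
  if (nrow(pool) < 2L) stop("need at least 2 words to split", call. = FALSE)
  med <- stats::median(pool$concreteness)
  list(abstract = pool[pool$concreteness <= med, , drop = FALSE],
       concrete = pool[pool$concreteness > med, , drop = FALSE])
}

# deterministic "top n by count" with lexicographic tie-break
top_by_count <- function(words, counts, n) {
  ord <- order(-counts, words, method = "radix")
  words[ord][seq_len(n)]
}

# Exact count matcher: choose n candidates whose summed neighbor count is as
# close as possible to target_sum. 0/1 knapsack dynamic programme over
# (subset size, achievable sum) with parent pointers; candidates are scanned
# in lexicographic order so the selection is deterministic. Counts are small
# non-negative integers, so the state space stays tiny.
match_count_subset <- function(counts, n, target_sum) {
  words <- sort(names(counts))
  ct <- as.integer(round(counts[words]))
  if (any(ct < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(ct) < n) stop("fewer candidates than requested", call. = FALSE)
  max_sum <- sum(sort(ct, decreasing = TRUE)[seq_len(n)])
  reach <- matrix(FALSE, n + 1L, max_sum + 1L)
  parent <- matrix(0L, n + 1L, max_sum + 1L)
  reach[1L, 1L] <- TRUE
  for (ci in seq_along(ct)) {
    for (sz in min(ci, n):1L) {
      cols <- which(reach[sz, ])
      new <- cols + ct[[ci]]
      new <- new[new <= max_sum + 1L]
      fresh <- new[!reach[sz + 1L, new]]
      if (length(fresh) > 0L) {
        reach[sz + 1L, fresh] <- TRUE
        parent[sz + 1L, fresh] <- ci
      }
    }
  }
  sums <- which(reach[n + 1L, ]) - 1L
  best <- sums[order(abs(sums - target_sum), sums)][1L]
  sel <- integer(n)
  s <- best
  for (sz in (n + 1L):2L) {
    ci <- parent[sz, s + 1L]
    sel[[sz - 1L]] <- ci
    s <- s - ct[[ci]]
  }
  sort(words[sel])
}

#' Five-condition item set (factorial design)
#'
#' Builds the 2 x 2 + 1 design crossing concreteness (abstract / concrete)
#' with the position of visual neighbors:
#' \itemize{
#'   \item `abstract/far`, `concrete/far`: seeded random samples of words with
#'     *zero* visual neighbors among their top-k;
#'   \item `abstract/near`: the abstract words with the most visual neighbors;
#'   \item `concrete/maximum`: the concrete words with the most visual
#'     neighbors;
#'   \item `concrete/near`: the subset of remaining concrete words whose
#'     summed neighbor count is as close as possible to the abstract/near
#'     total (exact subset matching via a dynamic programme over achievable
#'     sums), equating the mean count across the two near conditions.
#' }
#'
#' @param abstract,concrete Norms data frames (from [median_split()]).
#' @param counts Named integer vector: visual neighbor count per word (see
#'   [visual_neighbor_count()]), covering both pools.
#' @param n_per_condition Items per condition (default 23, for 115 items in
#'   total).
#' @param seed Integer seed for the far-condition sampling.
#' @return A data frame of class `item_set` with columns `word`, `condition`,
#'   `concreteness`, `visual_neighbor_count_k`; attribute `design = "exp12"`.
#' @export
build_conditions_exp12 <- function(abstract, concrete, counts,
                                   n_per_condition = 23L, seed) {
  n <- n_per_condition
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  pools <- list(abstract = abstract$word, concrete = concrete$word)
  missing <- setdiff(unlist(pools), names(counts))
  if (length(missing) > 0L) {
    stop("counts missing for: ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  far_pools <- lapply(pools, function(w) sort(w[counts[w] == 0]))
  for (side in names(far_pools)) {
    if (length(far_pools[[side]]) < n) {
      stop("condition ", side, "/far: only ", length(far_pools[[side]]),
           " zero-neighbor candidates for ", n, " items", call. = FALSE)
    }
  }
  far <- withr::with_seed(seed, lapply(far_pools, function(w) sample(w, n)))

  abs_rest <- setdiff(pools$abstract, far$abstract)
  if (length(abs_rest) < n) stop("condition abstract/near: pool exhausted", call. = FALSE)
  abs_near <- top_by_count(abs_rest, counts[abs_rest], n)

  con_rest <- setdiff(pools$concrete, far$concrete)
  if (length(con_rest) < 2L * n) {
    stop("concrete pool too small for maximum + near conditions", call. = FALSE)
  }
  con_max <- top_by_count(con_rest, counts[con_rest], n)

  # concrete/near: match the abstract/near total neighbor count exactly as
  # possible over the remaining concrete candidates
  con_cand <- setdiff(con_rest, con_max)
  if (length(con_cand) < n) stop("condition concrete/near: pool exhausted", call. = FALSE)
  con_near <- match_count_subset(counts[con_cand], n, sum(counts[abs_near]))

  sets <- list("abstract/far" = far$abstract, "abstract/near" = abs_near,
               "concrete/far" = far$concrete, "concrete/near" = con_near,
               "concrete/maximum" = con_max)
  norms_all <- rbind(abstract, concrete)
  out <- do.call(rbind, lapply(names(sets), function(cond) {
    w <- sets[[cond]]
    data.frame(word = w, condition = cond,
               concreteness = norms_all$concreteness[match(w, norms_all$word)],
               visual_neighbor_count_k = as.integer(counts[w]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "design") <- "exp12"
  class(out) <- c("item_set", class(out))
  out
}

#' Binned decorrelation sampler (continuous design)
#'
#' Segments the observed ranges of two correlated item covariates —
#' concreteness and mean training-item similarity — into `n_bins` equal-width
#' bins each (default 10 x 10 = 100 cells) and draws up to `per_cell` items
#' uniformly from every cell inside a selection window (default: all cells);
#' undersized cells contribute all their items. Sampling uniformly over the
#' covariate grid rather than over items flattens the joint distribution, so
#' the two variables' effects can be estimated separately.
#'
#' The window matters: over the *full* grid, the sparsely populated extreme
#' cells of two correlated variables lie along their joint major axis (both
#' variables extreme together), so upweighting them can *increase* the
#' correlation. Decorrelation comes from restricting sampling to a central
#' rectangle of cells where off-axis cells are populated — pass e.g.
#' `window = list(concreteness_bins = 3:8, similarity_bins = 3:8)`.
#'
#' Bins are left-closed with the top bin closed on both sides (the maximum
#' value falls in bin `n_bins`).
#'
#' @param pool Data frame with columns `word`, `concreteness`,
#'   `mean_training_similarity`.
#' @param n_bins Bins per variable (default 10).
#' @param per_cell Items drawn per cell (default 4).
#' @param window Optional list with integer vectors `concreteness_bins` and
#'   `similarity_bins` restricting the cell rectangle; default all cells.
#' @param seed Integer seed.
#' @return A data frame of class `item_set` with the pool columns plus
#'   `concreteness_bin` and `similarity_bin`; attributes `design = "exp3"`,
#'   `achieved_r` (Pearson correlation of the two covariates among selected
#'   items) and `pool_r` (the same in the full pool).
#' @export
grid_sample_exp3 <- function(pool, n_bins = 10L, per_cell = 4L,
                             window = NULL, seed) {
  req <- c("word", "concreteness", "mean_training_similarity")
  if (!all(req %in% names(pool))) {
    stop("pool needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(pool) == 0L) stop("empty pool", call. = FALSE)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  bin_of <- function(x) {
    if (max(x) == min(x)) return(rep(1L, length(x)))
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  cb <- bin_of(pool$concreteness)
  sb <- bin_of(pool$mean_training_similarity)
  in_window <- rep(TRUE, nrow(pool))
  if (!is.null(window)) {
    if (!is.null(window$concreteness_bins)) {
      in_window <- in_window & cb %in% window$concreteness_bins
    }
    if (!is.null(window$similarity_bins)) {
      in_window <- in_window & sb %in% window$similarity_bins
    }
  }
  cell <- paste(cb, sb, sep = ":")
  idx_by_cell <- split(which(in_window), cell[in_window])
  sel <- withr::with_seed(seed, {
    unlist(lapply(idx_by_cell, function(idx) {
      if (length(idx) <= per_cell) idx else sort(sample(idx, per_cell))
    }), use.names = FALSE)
  })
  sel <- sort(sel)
  out <- pool[sel, , drop = FALSE]
  out$concreteness_bin <- cb[sel]
  out$similarity_bin <- sb[sel]
  rownames(out) <- NULL
  attr(out, "design") <- "exp3"
  attr(out, "achieved_r") <- if (nrow(out) > 2L) {
    stats::cor(out$concreteness, out$mean_training_similarity)
  } else NA_real_
  attr(out, "pool_r") <- if (nrow(pool) > 2L) {
    stats::cor(pool$concreteness, pool$mean_training_similarity)
  } else NA_real_
  class(out) <- c("item_set", class(out))
  out
}

#' Split an item set into presentation lists
#'
#' Random partition of the items into `n_lists` lists of maximally even sizes
#' (sizes differ by at most 1, larger lists first), e.g. 371 items over 3
#' lists gives 124 / 124 / 123.
#'
#' @param items An `item_set` data frame (or any data frame of items).
#' @param n_lists Number of lists (>= 1).
#' @param seed Integer seed.
#' @return The input data frame with a `list_id` column added.
#' @export
split_lists <- function(items, n_lists, seed) {
  if (n_lists < 1L) stop("n_lists must be >= 1", call. = FALSE)
  n <- nrow(items)
  base <- n %/% n_lists
  extra <- n %% n_lists
  sizes <- rep(base, n_lists) + rep(c(1L, 0L), c(extra, n_lists - extra))
  perm <- withr::with_seed(seed, sample.int(n))
  list_id <- integer(n)
  list_id[perm] <- rep(seq_len(n_lists), sizes)
  items$list_id <- list_id
  items
}
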