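#' Count visually grounded words among a word's nearest neighbors
#'
#' How many of the `k` nearest neighbors (by cosine, default `k = 50`) of a
#' word are training labels, i.e. words for which a visual representation
#' exists. This is the categorical "visual neighbors" measure behind the
#' far / near / maximum conditions: a word in the *far* condition has count 0.
#'
#' @param lang A [vector_space()].
#' @param word A label present in `lang`.
#' @param training_labels Character vector of visually grounded labels.
#' @param k Neighborhood size (default 50).
#' @return Integer count in `[0, k]`.
#' @export
visual_neighbor_count <- function(lang, word, training_labels, k = 50L) {
  nb <- nearest_neighbors(lang, word, k = k)
  sum(nb$label %in% training_labels)
}

#' Neighborhood profile of a word relative to the training set
#'
#' Computes the four relative-position measures of a target word `w` with
#' respect to the visually grounded training items `t_i` (i = 1..n), ranking
#' within the full supplied lexicon (the target itself excluded, ranks
#' 1-based, ties sharing the minimum rank):
#' \describe{
#'   \item{nearest_training_similarity}{`max_i cos(w, t_i)`;}
#'   \item{nearest_training_rank}{rank of that best training item in the full
#'     similarity ordering of the lexicon;}
#'   \item{mean_training_rank}{mean rank of all training items;}
#'   \item{mean_training_similarity}{`(1/n) * sum_i cos(w, t_i)` — the
#'     continuous neighborhood measure used when concreteness and
#'     neighborhood must be treated as continuous variables.}
#' }
#' If the word is itself a training label it is excluded from its own profile
#' with a warning.
#'
#' @param lang A [vector_space()].
#' @param word A label present in `lang`.
#' @param training_labels Character vector of visually grounded labels, all
#'   present in `lang`; must be nonempty (after excluding `word`).
#' @return A one-row data frame of class `neighborhood_profile` with columns
#'   `word`, `nearest_training_rank`, `nearest_training_similarity`,
#'   `mean_training_rank`, `mean_training_similarity`.
#' @export
training_profile <- function(lang, word, training_labels) {
  labs <- rownames(lang)
  if (!word %in% labs) stop("word not in space: ", word, call. = FALSE)
  training_labels <- unique(as.character(training_labels))
  missing <- setdiff(training_labels, labs)
  if (length(missing) > 0L) {
    stop("training label(s) not in space: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (word %in% training_labels) {
    warning("target word '", word, "' is itself a training label; excluded ",
            "from its own profile")
    training_labels <- setdiff(training_labels, word)
  }
  if (length(training_labels) == 0L) {
    stop("empty training set for word: ", word, call. = FALSE)
  }
  others <- setdiff(labs, word)
  sims <- cosine_to_rows(lang[others, , drop = FALSE], lang[word, ])
  names(sims) <- others
  # competition ranking: tied similarities share the minimum rank
  ranks <- rank(-sims, ties.method = "min")
  tsims <- sims[training_labels]
  tranks <- ranks[training_labels]
  out <- data.frame(
    word = word,
    nearest_training_rank = as.integer(min(tranks[tsims == max(tsims)])),
    nearest_training_similarity = max(tsims),
    mean_training_rank = mean(tranks),
    mean_training_similarity = mean(tsims),
    stringsAsFactors = FALSE
  )
  class(out) <- c("neighborhood_profile", class(out))
  out
}

#' Neighborhood profiles for many words
#'
#' Vectorized driver over [training_profile()] plus the top-`k` visual
#' neighbor count, returning one row per word.
#'
#' @param lang A [vector_space()].
#' @param words Character vector of target words.
#' @param training_labels Character vector of visually grounded labels.
#' @param k Neighborhood size for the count column (default 50).
#' @param count Include the `visual_neighbor_count_k` column? Default `TRUE`
#'   (skipping it saves time on large batches where only the four continuous
#'   measures are needed).
#' @return A data frame with one row per word.
#' @export
training_profiles <- function(lang, words, training_labels, k = 50L,
                              count = TRUE) {
  rows <- lapply(words, function(w) {
    p <- training_profile(lang, w, training_labels)
    if (count) {
      p$visual_neighbor_count_k <- visual_neighbor_count(lang, w,
                                                         training_labels, k)
    }
    p
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
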