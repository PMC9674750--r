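#' Visual feature inventory
#'
#' Holds per-image feature vectors (e.g. penultimate-layer CNN activations)
#' tagged with their noun labels, plus an optional label -> corpus-frequency
#' map used to resolve multi-label image sets. Image ids may be shared across
#' labels on input (multi-label sets); [dedupe_multilabel()] resolves them.
#'
#' @param features Numeric matrix, one row per image record.
#' @param image_id Character vector of image identifiers, parallel to rows.
#' @param label Character vector of labels, parallel to rows.
#' @param label_frequency Optional named numeric vector mapping labels to
#'   word-frequency counts.
#' @return An object of class `image_inventory`.
#' @export
image_inventory <- function(features, image_id, label, label_frequency = NULL) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  image_id <- as.character(image_id)
  label <- as.character(label)
  if (length(image_id) != nrow(features) || length(label) != nrow(features)) {
    stop("image_id and label must match the number of feature rows", call. = FALSE)
  }
  if (!all(is.finite(features))) stop("all feature values must be finite", call. = FALSE)
  if (anyDuplicated(paste(image_id, label, sep = "\r"))) {
    stop("duplicate (image_id, label) records", call. = FALSE)
  }
  rownames(features) <- NULL
  structure(list(features = features, image_id = image_id, label = label,
                 label_frequency = label_frequency),
            class = "image_inventory")
}

#' @exportS3Method base::print
print.image_inventory <- function(x, ...) {
  cat("<image_inventory> ", nrow(x$features), " images, ",
      length(unique(x$label)), " labels, ", ncol(x$features), " features\n",
      sep = "")
  invisible(x)
}

#' @rdname image_inventory
#' @param inv An `image_inventory`.
#' @export
n_images <- function(inv) nrow(inv$features)

# subset an inventory by row index, keeping the frequency map
inventory_subset <- function(inv, idx) {
  image_inventory(inv$features[idx, , drop = FALSE], inv$image_id[idx],
                  inv$label[idx], inv$label_frequency)
}

#' Read / write an image inventory as TSV
#'
#' Columns: `image_id`, `label`, then one column per feature. Frequencies, if
#' supplied, travel separately (see `label_frequency` argument).
#'
#' @param path TSV file path.
#' @param label_frequency Optional named numeric vector to attach on read.
#' @return `read_inventory()` an `image_inventory`; `write_inventory()` the
#'   path, invisibly.
#' @export
read_inventory <- function(path, label_frequency = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("image_id", "label") %in% names(df))) {
    stop("inventory TSV must have columns image_id and label", call. = FALSE)
  }
  feat_cols <- setdiff(names(df), c("image_id", "label"))
  if (length(feat_cols) == 0L) stop("no feature columns found", call. = FALSE)
  mat <- as.matrix(df[feat_cols])
  storage.mode(mat) <- "double"
  image_inventory(mat, df$image_id, df$label, label_frequency)
}

#' @rdname read_inventory
#' @param inv An `image_inventory`.
#' @export
write_inventory <- function(inv, path) {
  feat <- as.data.frame(inv$features)
  names(feat) <- sprintf("f%04d", seq_len(ncol(inv$features)))
  df <- cbind(data.frame(image_id = inv$image_id, label = inv$label,
                         stringsAsFactors = FALSE), feat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter labels by image availability
#'
#' Drops labels with fewer than `min_images` images and down-samples labels
#' with more than `cap` images uniformly without replacement to exactly `cap`.
#' The defaults (at least 100 images, capped at 200) are the inventory
#' construction rule used when harvesting labeled image sets for mapping
#' experiments.
#'
#' @param inv An [image_inventory()].
#' @param min_images Minimum images per retained label (default 100).
#' @param cap Maximum images per label after down-sampling (default 200).
#' @param seed Integer seed making the down-sampling reproducible.
#' @return A filtered `image_inventory`. Empty results warn, they do not error.
#' @export
filter_labels <- function(inv, min_images = 100L, cap = 200L, seed) {
  if (min_images > cap) stop("min_images must be <= cap", call. = FALSE)
  counts <- table(inv$label)
  keep_labels <- names(counts)[counts >= min_images]
  if (length(keep_labels) == 0L) {
    warning("no label has >= ", min_images, " images; result is empty")
  }
  idx_by_label <- split(seq_along(inv$label), inv$label)
  keep_idx <- withr::with_seed(seed, {
    unlist(lapply(keep_labels, function(lb) {
      idx <- idx_by_label[[lb]]
      if (length(idx) > cap) sort(sample(idx, cap)) else idx
    }), use.names = FALSE)
  })
  inventory_subset(inv, sort(keep_idx))
}

#' Resolve multi-label image sets to the most frequent label
#'
#' An image annotated with several labels is retained only under the label
#' with the highest word frequency (ties broken lexicographically), so each
#' image id appears exactly once afterwards.
#'
#' @param inv An [image_inventory()] with `label_frequency` populated for any
#'   contested label.
#' @return A deduplicated `image_inventory`.
#' @export
dedupe_multilabel <- function(inv) {
  dup_ids <- unique(inv$image_id[duplicated(inv$image_id)])
  if (length(dup_ids) == 0L) return(inv)
  freq <- inv$label_frequency
  drop <- logical(length(inv$image_id))
  for (id in dup_ids) {
    idx <- which(inv$image_id == id)
    labs <- inv$label[idx]
    missing <- labs[!labs %in% names(freq)]
    if (length(missing) > 0L) {
      stop("no frequency entry for contested label(s): ",
           paste(unique(missing), collapse = ", "), call. = FALSE)
    }
    f <- freq[labs]
    best <- idx[order(-f, labs, method = "radix")][1L]
    drop[setdiff(idx, best)] <- TRUE
  }
  inventory_subset(inv, which(!drop))
}

#' Per-label prototype vectors
#'
#' The prototype of a label is the arithmetic mean of its images' feature
#' vectors — one visual representation per word, the "prototype regime"
#' training target.
#'
#' @param inv An [image_inventory()]; every label must have at least 1 image.
#' @return An object of class `prototype_set`: list with `space` (a
#'   [vector_space()] over labels) and `counts` (images averaged per label).
#' @export
compute_prototypes <- function(inv) {
  if (n_images(inv) == 0L) stop("empty inventory", call. = FALSE)
  sums <- rowsum(inv$features, inv$label)
  counts <- as.vector(table(inv$label)[rownames(sums)])
  proto <- sums / counts
  structure(list(space = vector_space(proto),
                 counts = stats::setNames(as.integer(counts), rownames(sums))),
            class = "prototype_set")
}

#' @exportS3Method base::print
print.prototype_set <- function(x, ...) {
  cat("<prototype_set> ", nrow(x$space), " labels x ", ncol(x$space),
      " dims\n", sep = "")
  invisible(x)
}

#' Sample exemplar images per label
#'
#' Draws exactly `k` images per label uniformly without replacement — the
#' "exemplar regime" training targets, default 20 per label.
#'
#' @param inv An [image_inventory()]; every label must have at least `k`
#'   images.
#' @param k Exemplars per label (default 20).
#' @param seed Integer seed.
#' @return An `image_inventory` with `k` images per label.
#' @export
sample_exemplars <- function(inv, k = 20L, seed) {
  idx_by_label <- split(seq_along(inv$label), inv$label)
  sizes <- lengths(idx_by_label)
  deficient <- names(sizes)[sizes < k]
  if (length(deficient) > 0L) {
    stop("label(s) with fewer than k = ", k, " images: ",
         paste(deficient, collapse = ", "), call. = FALSE)
  }
  keep <- withr::with_seed(seed, {
    unlist(lapply(idx_by_label, function(idx) {
      if (length(idx) == k) idx else sort(sample(idx, k))
    }), use.names = FALSE)
  })
  inventory_subset(inv, sort(keep))
}

#' Project an inventory or prototype set into a reduced space
#'
#' Applies an SVD projection (see [svd_reduce()]) to the feature side so that
#' retrieval operates in the same reduced space the mapping was trained in.
#'
#' @param x An [image_inventory()] or [compute_prototypes()] result.
#' @param projection A `d x target_dim` projection matrix.
#' @return The same kind of object with reduced features.
#' @export
project_features <- function(x, projection) {
  if (inherits(x, "image_inventory")) {
    image_inventory(x$features %*% projection, x$image_id, x$label,
                    x$label_frequency)
  } else if (inherits(x, "prototype_set")) {
    structure(list(space = vector_space(unclass(x$space) %*% projection),
                   counts = x$counts),
              class = "prototype_set")
  } else {
    stop("`x` must be an image_inventory or prototype_set", call. = FALSE)
  }
}
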