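#' Labeled vector space
#'
#' A `vector_space` is a real matrix with one row per labeled entity (words in
#' a distributional semantic space, image labels in a visual feature space).
#' All geometry in the package is cosine-based, so vectors are stored
#' unnormalized and normalization happens inside [cosine()].
#'
#' @param mat Numeric matrix, one row per label. All entries must be finite.
#' @param labels Character vector of unique row labels; defaults to
#'   `rownames(mat)`.
#' @return An object of class `vector_space`: the matrix with labels as
#'   rownames.
#' @examples
#' vs <- vector_space(matrix(rnorm(6), 3, 2), labels = c("a", "b", "c"))
#' space_labels(vs)
#' @export
vector_space <- function(mat, labels = rownames(mat)) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(labels)) stop("labels are required (rownames or `labels`)", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) {
    stop("number of labels (", length(labels), ") != number of rows (",
         nrow(mat), ")", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(mat))) stop("all vector entries must be finite", call. = FALSE)
  if (ncol(mat) < 1L) stop("dimensionality must be >= 1", call. = FALSE)
  rownames(mat) <- labels
  class(mat) <- c("vector_space", class(mat))
  mat
}

#' @rdname vector_space
#' @param x A `vector_space`.
#' @export
space_labels <- function(x) rownames(x)

#' @rdname vector_space
#' @export
space_dim <- function(x) ncol(x)

#' @exportS3Method base::print
print.vector_space <- function(x, ...) {
  cat("<vector_space> ", nrow(x), " labels x ", ncol(x), " dims\n", sep = "")
  invisible(x)
}

#' Read a vector space in word2vec text format
#'
#' The format is a header line `"<count> <dim>"` followed by one
#' whitespace-separated `"label v1 ... vdim"` row per entity. The header is
#' mandatory; a mismatch between the header and the body is an error naming
#' the offending line.
#'
#' @param path Path to a word2vec text file.
#' @return A [vector_space()].
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("line 1: expected header \"<count> <dim>\", got: ", lines[[1L]],
         call. = FALSE)
  }
  n <- as.integer(header[[1L]])
  d <- as.integer(header[[2L]])
  body <- lines[-1L]
  if (length(body) != n) {
    stop("header declares ", n, " rows but file has ", length(body),
         call. = FALSE)
  }
  labels <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[[i]]), "\\s+")[[1L]]
    if (length(parts) != d + 1L) {
      stop("line ", i + 1L, ": expected ", d + 1L, " fields, found ",
           length(parts), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) stop("line ", i + 1L, ": non-numeric vector entry", call. = FALSE)
    labels[[i]] <- parts[[1L]]
    mat[i, ] <- vals
  }
  vector_space(mat, labels)
}

#' Write a vector space in word2vec text format
#'
#' @param space A [vector_space()] (or any labeled numeric matrix).
#' @param path Output file path.
#' @param digits Significant digits written; default 17 round-trips doubles.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(space, path, digits = 17L) {
  labs <- rownames(space)
  if (is.null(labs)) stop("`space` must have row labels", call. = FALSE)
  rows <- vapply(seq_len(nrow(space)), function(i) {
    paste(c(labs[[i]], format(space[i, ], digits = digits, trim = TRUE,
                              scientific = TRUE)), collapse = " ")
  }, character(1L))
  writeLines(c(paste(nrow(space), ncol(space)), rows), path)
  invisible(path)
}

#' Cosine similarity between two vectors
#'
#' Standard cosine: the inner product of the two vectors divided by the
#' product of their Euclidean norms. Symmetric and invariant to positive
#' rescaling of either argument. A zero vector has no direction, so it is an
#' error — never silently 0.
#'
#' @param a,b Numeric vectors of equal length, both nonzero.
#' @return Similarity in `[-1, 1]`.
#' @examples
#' cosine(c(1, 0), c(1, 1)) # 1/sqrt(2)
#' @export
cosine <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine is undefined for a zero vector", call. = FALSE)
  }
  min(1, max(-1, sum(a * b) / (na * nb)))
}

# Cosine of one query vector against every row of a matrix.
# Rows with zero norm yield NA (callers decide whether that is an error).
cosine_to_rows <- function(mat, q) {
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("cosine is undefined for a zero vector", call. = FALSE)
  norms <- sqrt(rowSums(mat^2))
  sims <- as.vector(mat %*% q) / (norms * nq)
  sims[norms == 0] <- NA_real_
  pmin(1, pmax(-1, sims))
}

#' Nearest neighbors by cosine similarity
#'
#' Returns the `k` most similar labels to `query` within the space (or within
#' a candidate subset), the query itself always excluded. Ties in similarity
#' are broken by lexicographic label order so results are deterministic.
#'
#' @param space A [vector_space()].
#' @param query A label present in `space`.
#' @param k Number of neighbors; default 50, the conventional window for
#'   scanning a word's immediate semantic neighborhood.
#' @param candidates Optional character vector restricting the pool.
#' @return A data frame of class `neighbor_list` with columns `label` and
#'   `similarity` (weakly decreasing), and attributes `query` and `k`.
#' @export
nearest_neighbors <- function(space, query, k = 50L, candidates = NULL) {
  labs <- rownames(space)
  if (!query %in% labs) stop("query label not in space: ", query, call. = FALSE)
  pool <- if (is.null(candidates)) labs else intersect(as.character(candidates), labs)
  pool <- setdiff(pool, query)
  if (k > length(pool)) {
    stop("k = ", k, " exceeds available candidates (", length(pool), ")",
         call. = FALSE)
  }
  sims <- cosine_to_rows(space[pool, , drop = FALSE], space[query, ])
  ord <- order(-sims, pool, method = "radix")[seq_len(k)]
  out <- data.frame(label = pool[ord], similarity = sims[ord],
                    stringsAsFactors = FALSE)
  attr(out, "query") <- query
  attr(out, "k") <- as.integer(k)
  class(out) <- c("neighbor_list", class(out))
  out
}

#' Truncated SVD reduction of a feature matrix
#'
#' Reduces an `n x d` matrix to `n x target_dim` via the truncated singular
#' value decomposition: rows of the reduced matrix are `U_k S_k`, and the
#' returned projection (`d x target_dim`, the leading right singular vectors)
#' maps any new `d`-vector into the reduced space. The reduction that takes
#' 4096-dimensional CNN activations down to 300 dimensions before mapping is
#' exactly this operation, hence the default `target_dim = 300`.
#'
#' The sign of each singular vector is fixed so that its largest-magnitude
#' component is positive; geometry is unaffected and serialized reductions
#' become reproducible across platforms.
#'
#' @param mat Numeric matrix, `n x d`.
#' @param target_dim Output dimensionality, at most `min(n, d)`. Exceeding the
#'   rank is allowed (trailing dimensions are numerically zero).
#' @return A list with `reduced` (`n x target_dim`, row labels preserved),
#'   `projection` (`d x target_dim`) and `singular_values` (all
#'   `min(n, d)` of them, descending).
#' @export
svd_reduce <- function(mat, target_dim = 300L) {
  n <- nrow(mat)
  d <- ncol(mat)
  if (target_dim < 1L || target_dim > min(n, d)) {
    stop("target_dim must be in [1, min(n, d)] = [1, ", min(n, d), "]",
         call. = FALSE)
  }
  s <- svd(mat, nu = target_dim, nv = target_dim)
  for (j in seq_len(target_dim)) {
    i_max <- which.max(abs(s$v[, j]))
    if (s$v[i_max, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  reduced <- s$u %*% diag(s$d[seq_len(target_dim)], nrow = target_dim)
  rownames(reduced) <- rownames(mat)
  colnames(reduced) <- paste0("dim", seq_len(target_dim))
  projection <- s$v
  rownames(projection) <- colnames(mat)
  colnames(projection) <- colnames(reduced)
  list(reduced = reduced, projection = projection, singular_values = s$d)
}
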