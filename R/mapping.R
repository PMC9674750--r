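#' Build a language-to-vision training set
#'
#' Pairs language vectors with visual targets under one of two regimes:
#' \describe{
#'   \item{prototype}{one pair per label, the visual target being the mean of
#'     that label's image vectors;}
#'   \item{exemplar}{`exemplar_k` pairs per label (default 20), each an
#'     individual image vector.}
#' }
#' Visual targets are reduced by truncated SVD to `target_dim` dimensions
#' (default 300), separately per regime; language vectors are left untouched.
#'
#' @param lang A [vector_space()] of language vectors covering every visual
#'   label.
#' @param vis An [image_inventory()] (either regime) or a `prototype_set`
#'   (prototype regime only).
#' @param regime `"prototype"` or `"exemplar"`.
#' @param target_dim Reduced visual dimensionality (default 300).
#' @param exemplar_k Images per label in the exemplar regime (default 20).
#' @param seed Seed for exemplar sampling (required for `"exemplar"` when
#'   `vis` has more than `exemplar_k` images for some label).
#' @return A list with `training_set` (class `training_set`: `L`, `V`,
#'   `labels`, `regime`), `projection`, and `singular_values`.
#' @export
build_training_set <- function(lang, vis,
                               regime = c("prototype", "exemplar"),
                               target_dim = 300L, exemplar_k = 20L,
                               seed = NULL) {
  regime <- match.arg(regime)
  if (regime == "prototype") {
    proto <- if (inherits(vis, "prototype_set")) vis else compute_prototypes(vis)
    V_raw <- unclass(proto$space)
    labels <- rownames(V_raw)
  } else {
    if (!inherits(vis, "image_inventory")) {
      stop("exemplar regime requires an image_inventory", call. = FALSE)
    }
    sizes <- table(vis$label)
    inv <- if (all(sizes == exemplar_k)) vis else {
      if (is.null(seed)) stop("`seed` is required for exemplar sampling", call. = FALSE)
      sample_exemplars(vis, exemplar_k, seed)
    }
    V_raw <- inv$features
    labels <- inv$label
  }
  missing <- setdiff(unique(labels), rownames(lang))
  if (length(missing) > 0L) {
    stop("label(s) missing from the language space: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  td <- min(target_dim, nrow(V_raw), ncol(V_raw))
  if (td < target_dim) target_dim <- td
  red <- svd_reduce(V_raw, target_dim)
  L <- unclass(lang)[labels, , drop = FALSE]
  ts <- structure(list(L = L, V = red$reduced, labels = labels,
                       regime = regime),
                  class = "training_set")
  list(training_set = ts, projection = red$projection,
       singular_values = red$singular_values)
}

#' @exportS3Method base::print
print.training_set <- function(x, ...) {
  cat("<training_set> ", nrow(x$L), " pairs (", x$regime, "), ",
      ncol(x$L), " -> ", ncol(x$V), " dims\n", sep = "")
  invisible(x)
}

#' Fit the linear language-to-vision mapping
#'
#' Estimates the matrix `M` of the linear map `v_hat = M . l` (equivalently a
#' multivariate linear regression of each visual dimension on all language
#' dimensions) by the least-squares criterion
#' `argmin_M sum ||v - M.l||^2`, solved through a rank-revealing
#' pseudoinverse of the language matrix with a relative singular-value cutoff.
#' There is no intercept by default — the model is purely `M . l` — and no
#' regularization (`lambda = 0`); ridge shrinkage is available for
#' ill-conditioned inputs.
#'
#' @param ts A `training_set` from [build_training_set()], or a list with
#'   numeric matrices `L` (n x p) and `V` (n x q).
#' @param lambda Ridge penalty (default 0 = plain least squares).
#' @param intercept Add a bias column? Default `FALSE`.
#' @param sv_cutoff Relative singular-value cutoff for the pseudoinverse
#'   (default 1e-10).
#' @return An object of class `mapping_model`: list with `M` (p x q, so that
#'   predictions are `l %*% M`), `intercept` (q-vector or NULL), `regime`,
#'   `training_labels`, `input_dim`, `output_dim`.
#' @export
fit_mapping <- function(ts, lambda = 0, intercept = FALSE, sv_cutoff = 1e-10) {
  L <- ts$L
  V <- ts$V
  if (!is.matrix(L) || !is.matrix(V) || nrow(L) != nrow(V)) {
    stop("`ts` must carry matrices L and V with equal row counts", call. = FALSE)
  }
  if (all(L == 0)) stop("degenerate training set: language matrix is all zero", call. = FALSE)
  X <- if (intercept) cbind(`(intercept)` = 1, L) else L
  if (nrow(X) < ncol(X)) {
    warning("fewer training pairs (", nrow(X), ") than input dimensions (",
            ncol(X), "); the least-squares problem is underdetermined")
  }
  s <- svd(X)
  keep <- s$d > sv_cutoff * s$d[[1L]]
  dinv <- if (lambda > 0) s$d[keep] / (s$d[keep]^2 + lambda) else 1 / s$d[keep]
  # pseudoinverse solution M = V_x D^+ U' V, computed without forming pinv(X)
  coef <- s$v[, keep, drop = FALSE] %*%
    (dinv * crossprod(s$u[, keep, drop = FALSE], V))
  if (intercept) {
    b0 <- coef[1L, ]
    M <- coef[-1L, , drop = FALSE]
  } else {
    b0 <- NULL
    M <- coef
  }
  rownames(M) <- colnames(L)
  colnames(M) <- colnames(V)
  structure(list(M = M, intercept = b0,
                 regime = if (!is.null(ts$regime)) ts$regime else NA_character_,
                 training_labels = unique(ts$labels),
                 input_dim = ncol(L), output_dim = ncol(V),
                 sv_cutoff = sv_cutoff, lambda = lambda),
            class = "mapping_model")
}

#' @exportS3Method base::print
print.mapping_model <- function(x, ...) {
  cat("<mapping_model> ", x$input_dim, " -> ", x$output_dim, " (",
      x$regime, " regime, ", length(x$training_labels),
      " training labels)\n", sep = "")
  invisible(x)
}

#' Predict a visual vector from a language vector
#'
#' Zero-shot prediction: `v_hat_j = sum_i M_ij l_i` for any language vector,
#' including — and especially — words outside the training set.
#'
#' @param object A `mapping_model`.
#' @param l A language vector of length `input_dim`, or a matrix of row
#'   vectors.
#' @param ... Unused.
#' @return The predicted visual vector (or matrix of predictions).
#' @export
predict.mapping_model <- function(object, l, ...) {
  if (is.null(dim(l))) {
    if (length(l) != object$input_dim) {
      stop("input has length ", length(l), ", expected ", object$input_dim,
           call. = FALSE)
    }
    v <- drop(l %*% object$M)
  } else {
    if (ncol(l) != object$input_dim) {
      stop("input has ", ncol(l), " columns, expected ", object$input_dim,
           call. = FALSE)
    }
    v <- l %*% object$M
  }
  if (!is.null(object$intercept)) {
    v <- if (is.null(dim(v))) v + object$intercept else
      sweep(v, 2L, object$intercept, "+")
  }
  v
}

#' Retrieve the predicted image for a predicted visual vector
#'
#' Two retrieval schemes over a reduced-space inventory:
#' \describe{
#'   \item{exemplar}{the image whose (reduced) feature vector is most cosine-
#'     similar to the prediction;}
#'   \item{prototype}{first the prototype most similar to the prediction, then
#'     within that label the image most similar to the *prototype* (not to the
#'     prediction).}
#' }
#' Ties are broken lexicographically on label / image id.
#'
#' @param v_hat Predicted visual vector in the reduced space.
#' @param inv An [image_inventory()] already projected into the reduced space
#'   (see [project_features()]).
#' @param prototypes A reduced-space `prototype_set`; required for the
#'   prototype scheme.
#' @param scheme `"exemplar"` or `"prototype"`.
#' @return The retrieved `image_id` (character scalar), with the winning
#'   label as attribute `label`.
#' @export
retrieve_image <- function(v_hat, inv, prototypes = NULL,
                           scheme = c("exemplar", "prototype")) {
  scheme <- match.arg(scheme)
  if (n_images(inv) == 0L) stop("empty inventory", call. = FALSE)
  if (scheme == "exemplar") {
    sims <- cosine_to_rows(inv$features, v_hat)
    best <- order(-sims, inv$image_id, method = "radix")[1L]
    out <- inv$image_id[[best]]
    attr(out, "label") <- inv$label[[best]]
    return(out)
  }
  if (is.null(prototypes)) {
    stop("prototype scheme requires `prototypes`", call. = FALSE)
  }
  pmat <- unclass(prototypes$space)
  psims <- cosine_to_rows(pmat, v_hat)
  plabs <- rownames(pmat)
  best_label <- plabs[order(-psims, plabs, method = "radix")[1L]]
  idx <- which(inv$label == best_label)
  if (length(idx) == 0L) {
    stop("no images for retrieved label: ", best_label, call. = FALSE)
  }
  # stage 2 compares images to the winning prototype, not to v_hat
  isims <- cosine_to_rows(inv$features[idx, , drop = FALSE],
                          pmat[best_label, ])
  best <- idx[order(-isims, inv$image_id[idx], method = "radix")[1L]]
  out <- inv$image_id[[best]]
  attr(out, "label") <- best_label
  out
}

#' Draw a random control image
#'
#' Uniform seeded draw from the image pool minus an exclusion set — the
#' baseline image paired against the model prediction in a 2AFC trial.
#'
#' @param pool Character vector of image ids, or an [image_inventory()].
#' @param exclude Image ids to exclude.
#' @param seed Integer seed.
#' @return A single image id.
#' @export
pick_random_control <- function(pool, exclude = character(), seed) {
  ids <- if (inherits(pool, "image_inventory")) unique(pool$image_id) else
    as.character(pool)
  avail <- setdiff(ids, exclude)
  if (length(avail) == 0L) stop("no images left after exclusion", call. = FALSE)
  withr::with_seed(seed, avail[sample.int(length(avail), 1L)])
}

#' Serialize / load a mapping model
#'
#' Writes a JSON manifest (dims, regime, solver settings, training labels)
#' plus TSV matrix payloads to a directory, and reads them back.
#'
#' @param model A `mapping_model`.
#' @param dir Directory path (created if needed).
#' @return `write_mapping_model()` returns `dir` invisibly;
#'   `read_mapping_model()` returns the `mapping_model`.
#' @export
write_mapping_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(input_dim = model$input_dim, output_dim = model$output_dim,
                   regime = model$regime, sv_cutoff = model$sv_cutoff,
                   lambda = model$lambda,
                   has_intercept = !is.null(model$intercept),
                   training_labels = model$training_labels)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(model$M, file.path(dir, "M.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(model$intercept)) {
    writeLines(format(model$intercept, digits = 17L),
               file.path(dir, "intercept.txt"))
  }
  invisible(dir)
}

#' @rdname write_mapping_model
#' @export
read_mapping_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  M <- as.matrix(utils::read.delim(file.path(dir, "M.tsv"), row.names = 1L,
                                   check.names = FALSE))
  b0 <- if (isTRUE(manifest$has_intercept)) {
    as.numeric(readLines(file.path(dir, "intercept.txt")))
  } else NULL
  structure(list(M = M, intercept = b0, regime = manifest$regime,
                 training_labels = manifest$training_labels,
                 input_dim = manifest$input_dim,
                 output_dim = manifest$output_dim,
                 sv_cutoff = manifest$sv_cutoff, lambda = manifest$lambda),
            class = "mapping_model")
}
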