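#' Configuration for a synthetic language/vision world
#'
#' Defaults are desk-scale study conditions: a lexicon two orders of magnitude
#' smaller than a full distributional space but with a comparably *sparse*
#' set of visually grounded labels (80 of 2080, ~4%, vs 7801 of 300,000 in a
#' full space — the density drives how often a word has zero visual neighbors
#' among its top 50), a concreteness coupling of `rho = 0.53` (the naturally
#' observed correlation between concreteness and mean training-item
#' similarity that the binned sampler must then undo), and 20 images per
#' grounded label (the exemplar count).
#'
#' @param n_words Target (non-training) words in the lexicon.
#' @param lang_dim Language-vector dimensionality.
#' @param vis_dim Visual-feature dimensionality.
#' @param n_training_labels Visually grounded labels.
#' @param images_per_label Images generated per grounded label.
#' @param noise_sd Per-image Gaussian scatter around the planted mapping.
#' @param rho Target correlation between concreteness and mean training-item
#'   similarity, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_words = 2000L, lang_dim = 24L, vis_dim = 40L,
                         n_training_labels = 80L, images_per_label = 20L,
                         noise_sd = 0.5, rho = 0.53, seed = 1L) {
  stopifnot(lang_dim >= 2L, vis_dim >= 2L, noise_sd >= 0, n_words >= 2L,
            n_training_labels >= 2L, images_per_label >= 1L)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  structure(list(n_words = as.integer(n_words), lang_dim = as.integer(lang_dim),
                 vis_dim = as.integer(vis_dim),
                 n_training_labels = as.integer(n_training_labels),
                 images_per_label = as.integer(images_per_label),
                 noise_sd = noise_sd, rho = rho, seed = as.integer(seed)),
            class = "world_config")
}

#' Generate a coupled synthetic language/vision world
#'
#' Builds every input the mapping pipeline needs, with a controllable
#' concreteness-correlated geometry:
#' \itemize{
#'   \item Language vectors lie on the unit sphere (times a random positive
#'     length): each word's cosine alignment with a hub direction is driven by
#'     a latent Gaussian `z = rho * conc + sqrt(1 - rho^2) * noise`, so more
#'     concrete words sit nearer (in cosine) to the training labels, which
#'     cluster around the hub. The realized correlation between concreteness
#'     ratings and mean training-item similarity lands close to `rho`.
#'   \item A hidden planted matrix `M_star` maps language to vision; each
#'     image of a grounded label is `l %*% M_star + Normal(0, noise_sd)`
#'     scatter. `M_star` is returned for recovery tests.
#'   \item A norms table with concreteness ratings on a 1-5 scale, log-normal
#'     frequencies, and `is_noun = TRUE`.
#' }
#'
#' @param cfg A [world_config()].
#' @return A list with `lang` (a [vector_space()] over target words and
#'   training labels), `inventory` (an [image_inventory()]),
#'   `norms` (data frame), `training_labels` (character), `M_star`, `config`.
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  withr::with_seed(cfg$seed, {
    n_w <- cfg$n_words
    n_t <- cfg$n_training_labels
    d <- cfg$lang_dim
    words <- sprintf("w%05d", seq_len(n_w))
    tlabs <- sprintf("t%05d", seq_len(n_t))

    # hub direction the training labels cluster around
    u <- rnorm(d)
    u <- u / sqrt(sum(u^2))

    unit_perp <- function(n) {
      # random unit vectors orthogonal to u, one per row
      g <- matrix(rnorm(n * d), n, d)
      g <- g - outer(as.vector(g %*% u), u)
      g / sqrt(rowSums(g^2))
    }

    # latent concreteness and the coupled alignment driver
    c_lat <- rnorm(n_w)
    z <- cfg$rho * c_lat + sqrt(1 - cfg$rho^2) * rnorm(n_w)
    align_w <- 0.05 + 0.9 * stats::pnorm(z)
    align_t <- stats::runif(n_t, 0.85, 0.98)

    mk_vectors <- function(a) {
      n <- length(a)
      len <- stats::runif(n, 0.5, 1.5)
      len * (a * matrix(u, n, d, byrow = TRUE) +
               sqrt(1 - a^2) * unit_perp(n))
    }
    lang_mat <- rbind(mk_vectors(align_w), mk_vectors(align_t))
    rownames(lang_mat) <- c(words, tlabs)
    lang <- vector_space(lang_mat)

    # norms: ratings on a 1-5 scale; training labels skew concrete
    conc <- c(1 + 4 * stats::pnorm(c_lat), stats::runif(n_t, 3.5, 5))
    freq <- pmax(1, round(stats::rlnorm(n_w + n_t, meanlog = 6, sdlog = 1.3)))
    norms <- data.frame(word = c(words, tlabs), concreteness = conc,
                        frequency = freq, is_noun = TRUE,
                        stringsAsFactors = FALSE)

    # planted linear map and per-image scatter; language vectors are ~unit
    # norm, so unit-variance entries give O(1) visual features and noise_sd
    # reads as scatter relative to the signal scale
    M_star <- matrix(rnorm(d * cfg$vis_dim), d, cfg$vis_dim)
    k <- cfg$images_per_label
    v_mean <- lang_mat[tlabs, , drop = FALSE] %*% M_star
    feats <- v_mean[rep(seq_len(n_t), each = k), , drop = FALSE] +
      matrix(rnorm(n_t * k * cfg$vis_dim, sd = cfg$noise_sd),
             n_t * k, cfg$vis_dim)
    inv <- image_inventory(
      feats,
      image_id = sprintf("%s_img%03d", rep(tlabs, each = k), rep(seq_len(k), n_t)),
      label = rep(tlabs, each = k),
      label_frequency = stats::setNames(freq, c(words, tlabs))[tlabs]
    )

    list(lang = lang, inventory = inv, norms = norms,
         training_labels = tlabs, M_star = M_star, config = cfg)
  })
}

#' Configuration for the 2AFC choice simulator
#'
#' Parameters of the generative mixed-effects logistic choice model: the
#' probability of choosing the model-predicted image over the random control
#' on each trial is
#' `plogis(beta0 + beta_c * x_c + beta_n * x_n + beta_cn * x_c * x_n + u_p + u_i)`
#' with participant and item random intercepts `u ~ Normal(0, tau^2)`.
#'
#' @param beta0 Intercept on the log-odds scale.
#' @param beta_c Concreteness fixed effect.
#' @param beta_n Neighborhood-measure fixed effect.
#' @param beta_cn Interaction coefficient.
#' @param tau_participant,tau_item Random-intercept standard deviations (>= 0).
#' @param n_participants Number of simulated participants.
#' @param n_catch Catch trials per participant (default 10).
#' @param catch_error_rate Probability a participant misses a catch trial.
#' @param seed Integer seed.
#' @return A list of class `choice_config`.
#' @export
choice_config <- function(beta0 = 0, beta_c = 0, beta_n = 0, beta_cn = 0,
                          tau_participant = 0, tau_item = 0,
                          n_participants = 50L, n_catch = 10L,
                          catch_error_rate = 0.02, seed = 1L) {
  stopifnot(tau_participant >= 0, tau_item >= 0, n_participants >= 1L,
            n_catch >= 0L, catch_error_rate >= 0, catch_error_rate <= 1)
  structure(list(beta0 = beta0, beta_c = beta_c, beta_n = beta_n,
                 beta_cn = beta_cn, tau_participant = tau_participant,
                 tau_item = tau_item, n_participants = as.integer(n_participants),
                 n_catch = as.integer(n_catch),
                 catch_error_rate = catch_error_rate, seed = as.integer(seed)),
            class = "choice_config")
}

#' Simulate 2AFC trials under the mixed-effects choice model
#'
#' One row per participant x item (every participant sees every item, or only
#' their list if `items$list_id` is present and `by_list = TRUE`), plus
#' `n_catch` catch trials per participant answered correctly with probability
#' `1 - catch_error_rate`.
#'
#' @param items An item data frame with columns `word`, `concreteness`, and a
#'   neighborhood covariate (`neighbor_col`, default
#'   `"mean_training_similarity"`; falls back to `visual_neighbor_count_k`).
#'   An optional `condition` column is carried through.
#' @param cfg A [choice_config()].
#' @param neighbor_col Name of the neighborhood covariate column.
#' @param by_list If `TRUE` and `items$list_id` exists, participants are
#'   rotated over lists and each sees one list only.
#' @return A data frame of class `trial_table` with columns `participant_id`,
#'   `word`, `chose_model_image`, `concreteness`, `neighbor` (the covariate),
#'   optionally `condition` and `list_id`, plus `is_catch` and
#'   `catch_correct`.
#' @export
simulate_trials <- function(items, cfg = choice_config(),
                            neighbor_col = "mean_training_similarity",
                            by_list = TRUE) {
  stopifnot(inherits(cfg, "choice_config"))
  if (!neighbor_col %in% names(items)) {
    if ("visual_neighbor_count_k" %in% names(items)) {
      neighbor_col <- "visual_neighbor_count_k"
    } else {
      stop("items lack a neighborhood covariate column ('", neighbor_col, "')",
           call. = FALSE)
    }
  }
  if (!all(c("word", "concreteness") %in% names(items))) {
    stop("items need columns word and concreteness", call. = FALSE)
  }
  withr::with_seed(cfg$seed, {
    n_p <- cfg$n_participants
    u_p <- stats::rnorm(n_p, 0, cfg$tau_participant)
    u_i <- stats::rnorm(nrow(items), 0, cfg$tau_item)
    pids <- sprintf("p%03d", seq_len(n_p))
    has_lists <- by_list && "list_id" %in% names(items)
    plist <- if (has_lists) {
      lists <- sort(unique(items$list_id))
      lists[(seq_len(n_p) - 1L) %% length(lists) + 1L]
    } else rep(NA_integer_, n_p)

    rows <- lapply(seq_len(n_p), function(p) {
      idx <- if (has_lists) which(items$list_id == plist[[p]]) else
        seq_len(nrow(items))
      x_c <- items$concreteness[idx]
      x_n <- items[[neighbor_col]][idx]
      eta <- cfg$beta0 + cfg$beta_c * x_c + cfg$beta_n * x_n +
        cfg$beta_cn * x_c * x_n + u_p[[p]] + u_i[idx]
      resp <- stats::rbinom(length(idx), 1L, stats::plogis(eta))
      df <- data.frame(participant_id = pids[[p]], word = items$word[idx],
                       chose_model_image = resp, concreteness = x_c,
                       neighbor = x_n, is_catch = FALSE, catch_correct = NA,
                       stringsAsFactors = FALSE)
      if ("condition" %in% names(items)) df$condition <- items$condition[idx]
      if (has_lists) df$list_id <- plist[[p]]
      if (cfg$n_catch > 0L) {
        ok <- stats::rbinom(cfg$n_catch, 1L, 1 - cfg$catch_error_rate) == 1L
        catch <- data.frame(participant_id = pids[[p]],
                            word = sprintf("catch%02d", seq_len(cfg$n_catch)),
                            chose_model_image = NA_integer_,
                            concreteness = NA_real_, neighbor = NA_real_,
                            is_catch = TRUE, catch_correct = ok,
                            stringsAsFactors = FALSE)
        if ("condition" %in% names(items)) catch$condition <- NA_character_
        if (has_lists) catch$list_id <- plist[[p]]
        df <- rbind(df, catch)
      }
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("trial_table", class(out))
    out
  })
}
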