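#' Apply participant exclusions by catch-trial performance
#'
#' Drops every trial of any participant who answered fewer than
#' `min_catch_correct` of their catch trials correctly (default 8 of 10),
#' then removes the catch rows themselves from the analysis table.
#'
#' @param trials A `trial_table` (see [simulate_trials()]) with catch rows
#'   flagged by `is_catch`; every participant must have catch trials.
#' @param min_catch_correct Minimum correct catch answers (default 8).
#' @return The filtered trial table; attribute `exclusions` holds a data
#'   frame of participant id, catch-correct count and retention flag.
#' @export
apply_exclusions <- function(trials, min_catch_correct = 8L) {
  stopifnot(all(c("participant_id", "is_catch", "catch_correct") %in%
                  names(trials)))
  catch <- trials[trials$is_catch, , drop = FALSE]
  participants <- unique(trials$participant_id)
  no_catch <- setdiff(participants, unique(catch$participant_id))
  if (length(no_catch) > 0L) {
    stop("participant(s) with no catch trials: ",
         paste(no_catch, collapse = ", "), call. = FALSE)
  }
  correct <- tapply(catch$catch_correct, catch$participant_id, sum)
  log <- data.frame(participant_id = names(correct),
                    catch_correct = as.integer(correct),
                    retained = as.integer(correct) >= min_catch_correct,
                    stringsAsFactors = FALSE)
  keep_p <- log$participant_id[log$retained]
  out <- trials[!trials$is_catch & trials$participant_id %in% keep_p, ,
                drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- log
  out
}

#' Shift covariates so their minimum is zero
#'
#' `x -> x - min(x)` per covariate, so the model intercept is interpretable
#' as the predicted performance at the lowest observed covariate values.
#' Slopes are unaffected (pure reparameterization).
#'
#' @param trials A trial table.
#' @param covariates Character vector of numeric column names.
#' @return The shifted table; attribute `minima` records the subtracted
#'   minima.
#' @export
zero_min_transform <- function(trials, covariates) {
  minima <- numeric(0)
  for (cv in covariates) {
    if (!cv %in% names(trials)) stop("no such covariate: ", cv, call. = FALSE)
    m <- min(trials[[cv]], na.rm = TRUE)
    trials[[cv]] <- trials[[cv]] - m
    minima[[cv]] <- m
  }
  attr(trials, "minima") <- minima
  trials
}

#' Mixed-effects logistic regression with crossed random intercepts
#'
#' Fits a logistic GLMM of the binary 2AFC response on the given fixed-effect
#' terms, with crossed random intercepts for participants and items,
#' estimated by Laplace approximation via [lme4::glmer()]. Random slopes are
#' deliberately out of scope (they routinely fail to converge for this
#' design). Categorical fixed effects use treatment coding, so with the
#' condition factor ordered as abstract/far first, the intercept codes the
#' abstract/far condition.
#'
#' @param trials A trial table (catch rows already removed).
#' @param fixed Character vector of fixed-effect terms (e.g.
#'   `c("concreteness", "neighbor", "concreteness:neighbor")`), or `NULL` /
#'   `character(0)` for an intercept-only model.
#' @param response Response column (default `"chose_model_image"`).
#' @param groups Grouping columns for the random intercepts (default
#'   participants and items).
#' @param nAGQ Integration points passed to `glmer` (1 = Laplace).
#' @return An object of class `glmm_fit`: list with `fixed_effects` (term,
#'   beta, se, z, p), `random_variances`, `log_likelihood`, `df`, `n_obs`,
#'   `sigma2_fixed` (variance of the fixed-effect linear predictor),
#'   `formula`, `converged`, and the underlying `merMod` as `fit`.
#' @export
fit_glmm <- function(trials, fixed = NULL, response = "chose_model_image",
                     groups = c("participant_id", "word"), nAGQ = 1L) {
  stopifnot(response %in% names(trials))
  if (!all(trials[[response]] %in% c(0L, 1L))) {
    stop("response must be binary 0/1", call. = FALSE)
  }
  for (g in groups) {
    if (!g %in% names(trials)) stop("no such grouping column: ", g, call. = FALSE)
    if (length(unique(trials[[g]])) < 2L) {
      stop("grouping factor '", g, "' needs >= 2 levels", call. = FALSE)
    }
  }
  fe <- if (length(fixed) == 0L) "1" else paste(fixed, collapse = " + ")
  re <- paste(sprintf("(1 | %s)", groups), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", fe, "+", re))
  fit <- lme4::glmer(fml, data = trials, family = stats::binomial(),
                     nAGQ = nAGQ)
  sm <- summary(fit)
  co <- sm$coefficients
  fixed_effects <- data.frame(term = rownames(co), beta = co[, "Estimate"],
                              se = co[, "Std. Error"], z = co[, "z value"],
                              p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(fixed_effects) <- NULL
  vc <- lme4::VarCorr(fit)
  random_variances <- vapply(vc, function(v) as.numeric(v[1L, 1L]), numeric(1))
  ll <- stats::logLik(fit)
  eta_fixed <- as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
  msgs <- sm$optinfo$conv$lme4$messages
  # a boundary (singular) fit is a legitimate zero-variance estimate,
  # not a convergence failure
  msgs <- msgs[!grepl("boundary (singular)", msgs, fixed = TRUE)]
  conv <- length(msgs) == 0L && isTRUE(sm$optinfo$conv$opt == 0L)
  if (!conv) warning("GLMM convergence is questionable; inspect `$fit`")
  structure(list(fixed_effects = fixed_effects,
                 random_variances = random_variances,
                 log_likelihood = as.numeric(ll),
                 df = attr(ll, "df"),
                 n_obs = stats::nobs(fit),
                 sigma2_fixed = if (length(eta_fixed) > 1L)
                   stats::var(eta_fixed) else 0,
                 formula = paste(deparse(fml), collapse = " "),
                 converged = conv, fit = fit),
            class = "glmm_fit")
}

#' @exportS3Method base::print
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit> ", x$formula, "\n  n = ", x$n_obs, ", logLik = ",
      format(x$log_likelihood, digits = 6), ", df = ", x$df,
      if (!x$converged) "  [convergence questionable]" else "", "\n", sep = "")
  print(x$fixed_effects, digits = 4)
  cat("random-intercept variances:\n")
  print(x$random_variances, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested model fits
#'
#' `X^2 = 2 * (logLik_full - logLik_reduced)` (clamped at zero), with degrees
#' of freedom equal to the parameter-count difference and a chi-squared
#' upper-tail p value. Both fits must be on the same data.
#'
#' @param full,reduced `glmm_fit` objects, `reduced` nested in `full`.
#' @return A list of class `lrt_result` with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs) {
    stop("models were fitted to different numbers of observations", call. = FALSE)
  }
  df <- full$df - reduced$df
  if (df < 0L) stop("`reduced` has more parameters than `full`", call. = FALSE)
  x2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  p <- if (df == 0L) 1 else stats::pchisq(x2, df, lower.tail = FALSE)
  structure(list(statistic = x2, df = df, p = p), class = "lrt_result")
}

#' @exportS3Method base::print
print.lrt_result <- function(x, ...) {
  cat(sprintf("X^2(%d) = %.2f, p = %.4g\n", x$df, x$statistic, x$p))
  invisible(x)
}

#' Backward elimination of fixed effects by likelihood-ratio tests
#'
#' Starting from the full model (two main effects plus their interaction, by
#' default), removes terms whose removal does not significantly deteriorate
#' model fit, in a fixed order: the interaction first, then each main effect
#' in turn (a main effect is never dropped while the interaction survives).
#' Each candidate removal is tested with [likelihood_ratio_test()] at
#' `alpha`.
#'
#' @param trials A trial table.
#' @param main Character vector of the two main-effect terms.
#' @param interaction Include the two-way interaction in the full model?
#' @param alpha Significance level for retention (default 0.05).
#' @param ... Passed on to [fit_glmm()].
#' @return A list with `final` (the final `glmm_fit`), `retained` (character
#'   vector of surviving fixed terms), and `steps` (data frame of each tested
#'   removal: term, statistic, df, p, dropped).
#' @export
backward_elimination <- function(trials, main = c("concreteness", "neighbor"),
                                 interaction = TRUE, alpha = 0.05, ...) {
  terms <- main
  if (interaction) terms <- c(terms, paste(main, collapse = ":"))
  current <- fit_glmm(trials, fixed = terms, ...)
  steps <- data.frame(term = character(), statistic = numeric(),
                      df = integer(), p = numeric(), dropped = logical(),
                      stringsAsFactors = FALSE)
  repeat {
    is_int <- grepl(":", terms, fixed = TRUE)
    droppable <- if (any(is_int)) terms[is_int] else terms
    if (length(droppable) == 0L) break
    dropped_any <- FALSE
    for (tm in droppable) {
      rest <- setdiff(terms, tm)
      reduced <- fit_glmm(trials, fixed = rest, ...)
      lrt <- likelihood_ratio_test(current, reduced)
      drop_it <- lrt$p >= alpha
      steps <- rbind(steps, data.frame(term = tm, statistic = lrt$statistic,
                                       df = lrt$df, p = lrt$p,
                                       dropped = drop_it,
                                       stringsAsFactors = FALSE))
      if (drop_it) {
        terms <- rest
        current <- reduced
        dropped_any <- TRUE
        break
      }
    }
    if (!dropped_any) break
  }
  list(final = current, retained = terms, steps = steps)
}

#' Marginal and conditional R-squared for a logistic GLMM
#'
#' The variance-partition R-squared for mixed models with a logistic link:
#' with `s2f` the variance of the fixed-effect linear predictor, `t2` the
#' summed random-intercept variances, and `pi^2/3` the logistic residual
#' variance,
#' \deqn{R^2_{marginal} = s2f / (s2f + t2 + \pi^2/3), \quad
#'       R^2_{conditional} = (s2f + t2) / (s2f + t2 + \pi^2/3).}
#'
#' @param fit A `glmm_fit`, or any list with numeric `sigma2_fixed` and
#'   `random_variances`.
#' @return Named numeric vector with `marginal` and `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  s2f <- fit$sigma2_fixed
  t2 <- sum(fit$random_variances)
  if (is.null(s2f) || is.null(t2)) {
    stop("fit must carry sigma2_fixed and random_variances", call. = FALSE)
  }
  denom <- s2f + t2 + pi^2 / 3
  c(marginal = s2f / denom, conditional = (s2f + t2) / denom)
}

#' Per-condition mapping performance with 0.95 confidence intervals
#'
#' Mapping performance is the proportion of trials on which the
#' model-predicted image was chosen over the random control; chance is 0.5.
#' Intervals are normal-approximation (Wald) over trials.
#'
#' @param trials A trial table with a condition column.
#' @param condition_col Name of the condition column (default `"condition"`).
#' @param response Response column (default `"chose_model_image"`).
#' @param level Confidence level (default 0.95).
#' @return Data frame with `condition`, `n`, `mean`, `ci_lower`, `ci_upper`;
#'   attribute `chance = 0.5`.
#' @export
condition_summary <- function(trials, condition_col = "condition",
                              response = "chose_model_image", level = 0.95) {
  if (!condition_col %in% names(trials)) {
    stop("no such condition column: ", condition_col, call. = FALSE)
  }
  conds <- split(trials[[response]], trials[[condition_col]])
  if (any(lengths(conds) == 0L)) stop("empty condition", call. = FALSE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(names(conds), function(cd) {
    y <- conds[[cd]]
    p <- mean(y)
    se <- sqrt(p * (1 - p) / length(y))
    data.frame(condition = cd, n = length(y), mean = p,
               ci_lower = p - zq * se, ci_upper = p + zq * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "chance") <- 0.5
  out
}
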