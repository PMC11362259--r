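#' Fit a naive Bayes classifier with one categorical predictor
#'
#' With a single categorical feature the classifier reduces to
#' `argmax_y P(y) * P(x | y)` with Laplace-smoothed conditionals
#' `(count + alpha) / (n_y + alpha * n_levels)`. Optional upsampling
#' resamples training rows (with replacement, seeded) so every target
#' category matches the largest category's count before estimation.
#'
#' @param x Character vector of predictor levels (gesture action or
#'   morph).
#' @param y Character vector of target labels (goal or community).
#' @param alpha Laplace smoothing constant (default 1; 0 = maximum
#'   likelihood).
#' @param upsample Balance target categories by resampling (default
#'   `FALSE`).
#' @param seed Seed used when `upsample = TRUE`.
#' @return An object of class `nb_model`: `prior` (named), `cond`
#'   (targets x levels conditional matrix), `levels`, `targets`,
#'   `alpha`.
#' @export
fit_naive_bayes <- function(x, y, alpha = 1, upsample = FALSE, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2) {
    stop("training data must contain at least two target categories")
  }
  if (upsample) {
    set.seed(seed)
    target_n <- max(table(y))
    idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
      c(ii, ii[sample.int(length(ii), target_n - length(ii),
                          replace = TRUE)])
    }), use.names = FALSE)
    x <- x[idx]
    y <- y[idx]
  }
  targets <- sort(unique(y))
  levs <- sort(unique(x))
  tab <- table(factor(y, levels = targets), factor(x, levels = levs))
  prior <- as.vector(table(factor(y, levels = targets))) / length(y)
  names(prior) <- targets
  cond <- (tab + alpha) / (rowSums(tab) + alpha * length(levs))
  structure(list(prior = prior, cond = as.matrix(cond), levels = levs,
                 targets = targets, alpha = alpha),
            class = "nb_model")
}

#' @export
#' @rdname fit_naive_bayes
#' @param object An `nb_model`.
#' @param newdata Character vector of predictor levels.
#' @param ... Unused.
predict.nb_model <- function(object, newdata, ...) {
  out <- character(length(newdata))
  prior_win <- object$targets[which.max(object$prior)]
  seen <- newdata %in% object$levels
  out[!seen] <- prior_win  # unseen level: prior-only prediction
  if (any(seen)) {
    scores <- log(object$cond[, newdata[seen], drop = FALSE]) +
      log(object$prior)
    out[seen] <- object$targets[apply(scores, 2, which.max)]
  }
  out
}

#' Cross-validate a single-predictor naive Bayes classifier
#'
#' Folds are stratified by target (seeded): within every target category
#' the shuffled tokens are dealt round-robin across folds, so each fold
#' sees close to the global target composition. Token-level accuracy is
#' the share of correct held-out predictions (pooled over folds, which
#' makes it exactly the support-weighted mean of per-category recalls);
#' goal-level accuracy is the unweighted mean of per-category recalls.
#'
#' @param x Predictor levels (one per token).
#' @param y Target labels, all known.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed driving fold allocation (and upsampling).
#' @param alpha Laplace smoothing constant.
#' @param upsample Balance target categories within each training fold.
#' @return An object of class `cv_result`: `fold_accuracy`,
#'   `token_accuracy`, `recall` (named per target), `category_accuracy`
#'   (unweighted mean recall), `chance` (1 / number of target
#'   categories), `predictions` (data frame with `y`, `yhat`, `fold`).
#' @export
cross_validate_predictor <- function(x, y, folds = 10, seed = 1L,
                                     alpha = 1, upsample = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (n < folds) stop("need at least as many tokens as folds")
  set.seed(seed)
  fold_id <- integer(n)
  for (cat_ in unique(y)) {
    ii <- which(y == cat_)
    ii <- ii[sample.int(length(ii))]
    fold_id[ii] <- rep_len(sample.int(folds), length(ii))
  }
  yhat <- character(n)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (!any(test)) {
      fold_acc[f] <- NA_real_
      next
    }
    model <- fit_naive_bayes(x[!test], y[!test], alpha = alpha,
                             upsample = upsample,
                             seed = .restart_seed(seed, f, 0L))
    yhat[test] <- predict(model, x[test])
    fold_acc[f] <- mean(yhat[test] == y[test])
  }
  recall <- vapply(sort(unique(y)), function(cat_) {
    mean(yhat[y == cat_] == cat_)
  }, numeric(1))
  structure(list(
    fold_accuracy = fold_acc,
    token_accuracy = mean(yhat == y),
    recall = recall,
    category_accuracy = mean(recall),
    chance = 1 / length(unique(y)),
    predictions = data.frame(y = y, yhat = yhat, fold = fold_id,
                             stringsAsFactors = FALSE)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("CV result: token accuracy", round(x$token_accuracy, 3),
      "| category-mean accuracy", round(x$category_accuracy, 3),
      "| chance", round(x$chance, 3), "\n")
  invisible(x)
}

#' Compare gesture action vs morph as predictors of goal or community
#'
#' Runs [cross_validate_predictor()] for both predictors on the identical
#' token set, folds and seed, and reports token-level accuracies,
#' per-category recalls, category-level mean accuracies, and the
#' categories predicted correctly (recall > 0) only under morphs.
#'
#' @param tokens Data frame with `action`, `morph` and the target column;
#'   tokens with unknown target or no morph assignment are dropped.
#' @param target `"goal"` or `"community"`.
#' @param folds,seed,alpha Passed through.
#' @param upsample Balance target categories in training folds (default
#'   `TRUE`, mirroring the goal analysis).
#' @return An object of class `predictor_comparison`: `action`, `morph`
#'   (both `cv_result`), `per_category` (data frame with recalls under
#'   both predictors), `morph_only_categories`, `n`.
#' @export
compare_predictors <- function(tokens, target = c("goal", "community"),
                               folds = 10, seed = 1L, alpha = 1,
                               upsample = TRUE) {
  target <- match.arg(target)
  tok <- tokens[!is.na(tokens$morph) &
                  tokens[[target]] != .RES[["unknown"]], , drop = FALSE]
  y <- tok[[target]]
  cv_a <- cross_validate_predictor(tok$action, y, folds = folds,
                                   seed = seed, alpha = alpha,
                                   upsample = upsample)
  cv_m <- cross_validate_predictor(tok$morph, y, folds = folds,
                                   seed = seed, alpha = alpha,
                                   upsample = upsample)
  per_cat <- data.frame(category = names(cv_a$recall),
                        recall_action = unname(cv_a$recall),
                        recall_morph = unname(cv_m$recall),
                        stringsAsFactors = FALSE)
  structure(list(
    action = cv_a, morph = cv_m, per_category = per_cat,
    morph_only_categories = per_cat$category[
      per_cat$recall_morph > 0 & per_cat$recall_action == 0],
    target = target, n = nrow(tok)),
    class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  cat("Predictor comparison (", x$target, ", n = ", x$n, "):\n", sep = "")
  cat("  token accuracy   action", round(x$action$token_accuracy, 3),
      "| morph", round(x$morph$token_accuracy, 3), "\n")
  cat("  category accuracy action", round(x$action$category_accuracy, 3),
      "| morph", round(x$morph$category_accuracy, 3), "\n")
  cat("  categories predicted only under morphs:",
      length(x$morph_only_categories), "\n")
  invisible(x)
}
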