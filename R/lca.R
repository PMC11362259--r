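#' Fit a latent class model to a one-hot indicator matrix by EM
#'
#' The classical latent class model for categorical data: tokens belong
#' to one of `K` unobserved classes, and conditional on the class every
#' modifier is independent with a class-specific distribution over its
#' levels. When `X` carries a `blocks` attribute (as produced by
#' [one_hot_encode()]) each multi-column block is treated as one
#' multinomial modifier -- the class-conditional probability of a pattern
#' multiplies one `theta` entry per block. Columns without a block (or
#' singleton blocks) are treated as independent Bernoulli indicators.
#'
#' Fitting runs EM to a MAP estimate under weak symmetric smoothing --
#' Dirichlet(1.01) within every modifier block (Beta(1.01, 1.01) for
#' Bernoulli columns) and Dirichlet(1.01) on the class weights -- which
#' keeps parameters off the boundary while iterating; after convergence a
#' short unsmoothed EM phase polishes the solution towards the
#' maximum-likelihood optimum, and the reported `loglik` is the
#' observed-data log-likelihood at the final parameters.
#'
#' Rows with identical indicator patterns are collapsed to weighted
#' patterns internally, so cost scales with the number of distinct
#' modifier combinations, not tokens.
#'
#' @param X Binary matrix (tokens x indicator columns), optionally with a
#'   `blocks` attribute naming the modifier of every column.
#' @param K Number of latent classes (>= 1).
#' @param seed Integer seed for the random start.
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Absolute log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param alpha Dirichlet/Beta smoothing parameter used while iterating
#'   (default 1.01).
#' @return An object of class `lca_fit`: `K`, `pi` (class weights),
#'   `theta` (K x columns level probabilities), `loglik`, `n_iter`,
#'   `seed`, `converged`, `trace` (log-likelihood per iteration), `n`,
#'   and `D` (free parameters per class: levels minus one per multinomial
#'   block, one per Bernoulli column).
#' @export
fit_lca_em <- function(X, K, seed = 1L, max_iter = 1000L, tol = 1e-6,
                       alpha = 1.01) {
  blocks <- attr(X, "blocks")
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("X is empty")
  if (!all(X %in% c(0, 1))) stop("X must be binary (0/1)")
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(X)) stop("K exceeds the number of rows")
  n <- nrow(X)
  D <- ncol(X)
  if (is.null(blocks)) blocks <- paste0(".col", seq_len(D))
  multi <- names(which(table(blocks) >= 2))
  is_mn <- blocks %in% multi          # multinomial columns
  block_list <- lapply(multi, function(b) which(blocks == b))
  D_free <- sum(!is_mn) + sum(vapply(block_list, length, 1L) - 1L)

  key <- apply(X, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  P <- X[uniq, , drop = FALSE]            # distinct patterns
  w <- as.vector(table(key)[key[uniq]])   # pattern multiplicities
  m <- nrow(P)
  has_bn <- any(!is_mn)
  Pb1 <- if (has_bn) 1 - P[, !is_mn, drop = FALSE] else NULL
  rows_m <- seq_len(m)

  set.seed(seed)
  theta <- matrix(stats::runif(K * D, 0.1, 0.9), nrow = K)
  for (j in block_list) {
    theta[, j] <- theta[, j, drop = FALSE] /
      rowSums(theta[, j, drop = FALSE])
  }
  pi_k <- rep(1 / K, K)

  em_pass <- function(theta, pi_k, a, iters, ll_prev) {
    trace <- numeric(iters)
    converged <- FALSE
    used <- 0L
    for (it in seq_len(iters)) {
      lth <- log(pmax(theta, 1e-300))
      L <- tcrossprod(P, lth)                        # m x K
      if (has_bn) {
        lth1 <- log(pmax(1 - theta[, !is_mn, drop = FALSE], 1e-300))
        L <- L + tcrossprod(Pb1, lth1)
      }
      L <- L + rep(log(pmax(pi_k, 1e-300)), each = m)
      mx <- L[cbind(rows_m, max.col(L, ties.method = "first"))]
      lse <- mx + log(rowSums(exp(L - mx)))
      ll <- sum(w * lse)
      trace[it] <- ll
      used <- it
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
        converged <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
      wR <- exp(L - lse) * w                         # responsibilities
      Nk <- colSums(wR)
      pi_k <- (Nk + (a - 1)) / (sum(Nk) + K * (a - 1))
      S <- crossprod(wR, P)
      if (has_bn) {
        theta[, !is_mn] <- (S[, !is_mn, drop = FALSE] + (a - 1)) /
          (Nk + 2 * (a - 1))
      }
      for (j in block_list) {
        theta[, j] <- (S[, j, drop = FALSE] + (a - 1)) /
          (Nk + length(j) * (a - 1))
      }
    }
    list(theta = theta, pi_k = pi_k, trace = trace[seq_len(used)],
         loglik = ll_prev, converged = converged, n_iter = used)
  }

  p1 <- em_pass(theta, pi_k, alpha, max_iter, -Inf)
  # unsmoothed polish towards the ML optimum (skipped for runs stopped at
  # the iteration cap: their likelihood is only used to rank restarts)
  p2 <- if (p1$converged) {
    em_pass(p1$theta, p1$pi_k, 1, min(200L, max_iter), -Inf)
  } else {
    list(theta = p1$theta, pi_k = p1$pi_k, trace = numeric(0),
         loglik = p1$loglik, converged = FALSE, n_iter = 0L)
  }

  theta <- p2$theta
  dimnames(theta) <- list(NULL, colnames(X))
  structure(
    list(K = K, pi = as.numeric(p2$pi_k), theta = theta,
         loglik = p2$loglik,
         n_iter = p1$n_iter + p2$n_iter, seed = seed,
         converged = p1$converged || p2$converged,
         trace = c(p1$trace, p2$trace), n = n, D = D_free,
         n_cols = D, is_mn = is_mn),
    class = "lca_fit"
  )
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("LCA fit: K =", x$K, " loglik =", format(x$loglik, digits = 8),
      " BIC =", format(compute_bic(x), digits = 8),
      " iters =", x$n_iter, " converged =", x$converged, "\n")
  invisible(x)
}

#' Bayesian information criterion of a latent class fit
#'
#' `BIC = -2 loglik + p log(n)` with `p = (K - 1) + K * D` free
#' parameters: `K - 1` class weights plus `D` class-conditional level
#' parameters per class (one per Bernoulli indicator; levels minus one
#' per multinomial modifier block). Lower is better.
#'
#' @param fit An `lca_fit`.
#' @param n Token count (defaults to the fit's).
#' @param D Free parameters per class (defaults to the fit's).
#' @return The BIC score.
#' @export
compute_bic <- function(fit, n = fit$n, D = fit$D) {
  if (is.null(n) || n <= 0) stop("n must be positive")
  p <- (fit$K - 1) + fit$K * D
  -2 * fit$loglik + p * log(n)
}

#' Modal class assignment under a latent class fit
#'
#' Each row goes to the class with the largest posterior probability;
#' exact ties break to the lowest class index (tied rows are recorded in
#' the `ties` attribute).
#'
#' @param fit An `lca_fit`.
#' @param X Binary matrix over the same columns the fit used.
#' @return Integer vector of class indices with attribute `ties`.
#' @export
assign_classes <- function(fit, X) {
  X <- as.matrix(X)
  post <- posterior_classes(fit, X)
  z <- max.col(post, ties.method = "first")
  mx <- post[cbind(seq_len(nrow(post)), z)]
  ties <- which(rowSums(abs(post - mx) < 1e-12) > 1)
  attr(z, "ties") <- ties
  z
}

#' Posterior class membership probabilities
#'
#' @param fit An `lca_fit`.
#' @param X Binary matrix over the fit's columns.
#' @return Matrix (rows x K) of posterior probabilities.
#' @export
posterior_classes <- function(fit, X) {
  X <- as.matrix(X)
  is_mn <- fit$is_mn
  if (is.null(is_mn)) is_mn <- rep(FALSE, ncol(X))
  lth <- log(pmax(fit$theta, 1e-300))
  L <- X %*% t(lth)
  if (any(!is_mn)) {
    lth1 <- log(pmax(1 - fit$theta[, !is_mn, drop = FALSE], 1e-300))
    L <- L + (1 - X[, !is_mn, drop = FALSE]) %*% t(lth1)
  }
  L <- sweep(L, 2, log(pmax(fit$pi, 1e-300)), "+")
  mx <- apply(L, 1, max)
  exp(L - (mx + log(rowSums(exp(L - mx)))))
}

# deterministic seed per (K, restart) derived from a master seed
.restart_seed <- function(master, K, r) {
  as.integer((as.numeric(master) + 100003 * K + 613 * r) %% 2147483629)
}

#' Select the morph solution for one gesture action
#'
#' Fits latent class models for every class count between 1 and the
#' number of distinct observed modifier-level combinations, `restarts`
#' random starts per class count, keeping the best-likelihood restart.
#' A candidate solution is eligible when (a) its modal assignment is
#' deterministic -- every observed modifier-level combination maps to
#' exactly one class -- and (b) every class holds at least
#' `min_cluster_n` tokens. Among eligible candidates the lowest-BIC one
#' wins; the one-class solution is always eligible, so a result is
#' guaranteed.
#'
#' @param dataset An `action_dataset`.
#' @param restarts Random starts per class count (default 10).
#' @param min_cluster_n Minimum tokens per class (default 5).
#' @param seed Master seed; restart seeds derive from it via a fixed
#'   counter scheme.
#' @param max_iter,tol Passed to [fit_lca_em()].
#' @return An object of class `solution_choice`: `action`, `K`, `fit`
#'   (`NULL` for actions with no retained modifiers), `assignments`
#'   (integer class per token, named by token id), `candidate_log`
#'   (per-(K, restart) audit data frame), `accepted`.
#' @export
select_morph_solution <- function(dataset, restarts = 10, min_cluster_n = 5,
                                  seed = 1L, max_iter = 1000L, tol = 1e-6) {
  stopifnot(inherits(dataset, "action_dataset"))
  n <- nrow(dataset$tokens)
  ids <- dataset$tokens$token_id
  if (length(dataset$retained_modifiers) == 0) {
    # no modifier variation: the action is one morph by construction
    z <- stats::setNames(rep(1L, n), ids)
    return(structure(list(action = dataset$action, K = 1L, fit = NULL,
                          assignments = z,
                          candidate_log = .empty_candidate_log(),
                          accepted = TRUE),
                     class = "solution_choice"))
  }
  X <- one_hot_encode(dataset)
  combos <- apply(dataset$tokens[, dataset$retained_modifiers,
                                 drop = FALSE], 1, paste, collapse = "\r")
  # class counts beyond this bound can never satisfy the minimum cluster
  # size: classes are unions of whole combinations, so at most every
  # combination with >= min_cluster_n tokens plus groups of the small
  # ones summing to min_cluster_n can form a class of their own
  cc <- table(combos)
  k_bound <- sum(cc >= min_cluster_n) +
    floor(sum(cc[cc < min_cluster_n]) / min_cluster_n)
  k_max <- max(1L, min(dataset$n_combinations, k_bound))
  log_rows <- list()
  best_by_k <- vector("list", k_max)
  screen_iter <- min(max_iter, 250L)
  for (K in seq_len(k_max)) {
    # short-run screening of the random starts, full refinement of the
    # best one (emEM strategy)
    fits <- vector("list", restarts)
    for (r in seq_len(restarts)) {
      s <- .restart_seed(seed, K, r)
      fits[[r]] <- fit_lca_em(X, K, seed = s, max_iter = screen_iter,
                              tol = tol)
    }
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    best_r <- which.max(lls)
    fit <- fits[[best_r]]
    if (!fit$converged) {
      fit <- fit_lca_em(X, K, seed = .restart_seed(seed, K, best_r),
                        max_iter = max_iter, tol = tol)
      lls[best_r] <- fit$loglik
    }
    z <- assign_classes(fit, X)
    sizes <- tabulate(z, nbins = K)
    deterministic <- .is_deterministic(z, combos)
    reason <- ""
    if (!deterministic) reason <- "non-deterministic"
    if (any(sizes < min_cluster_n)) {
      reason <- paste0(reason, if (nzchar(reason)) ";",
                       "min_cluster_n")
    }
    eligible <- K == 1 || !nzchar(reason)
    bic <- compute_bic(fit)
    for (r in seq_len(restarts)) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        K = K, restart = r, seed = .restart_seed(seed, K, r),
        loglik = lls[r], best_restart = r == best_r,
        bic = if (r == best_r) bic else NA_real_,
        n_iter = fits[[r]]$n_iter, converged = fits[[r]]$converged,
        eligible = if (r == best_r) eligible else NA,
        rejection_reason = if (r == best_r) reason else "",
        stringsAsFactors = FALSE)
    }
    best_by_k[[K]] <- list(fit = fit, z = z, bic = bic,
                           eligible = eligible)
  }
  cand <- do.call(rbind, log_rows)
  bics <- vapply(best_by_k, function(b) {
    if (b$eligible) b$bic else Inf
  }, numeric(1))
  K_star <- which.min(bics)
  chosen <- best_by_k[[K_star]]
  structure(list(action = dataset$action, K = K_star, fit = chosen$fit,
                 assignments = stats::setNames(chosen$z, ids),
                 candidate_log = cand, accepted = TRUE),
            class = "solution_choice")
}

.empty_candidate_log <- function() {
  data.frame(K = integer(0), restart = integer(0), seed = integer(0),
             loglik = numeric(0), best_restart = logical(0),
             bic = numeric(0), n_iter = integer(0), converged = logical(0),
             eligible = logical(0), rejection_reason = character(0),
             stringsAsFactors = FALSE)
}

# TRUE when every observed combination maps to exactly one class
.is_deterministic <- function(z, combos) {
  all(tapply(z, combos, function(v) length(unique(v))) == 1L)
}

#' @export
print.solution_choice <- function(x, ...) {
  cat("Morph solution for '", x$action, "': K = ", x$K,
      " (", length(x$assignments), " tokens)\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expected value under random
#' labeling.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
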