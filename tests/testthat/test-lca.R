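# small blocked one-hot matrix builder: levels given as integer codes
block_matrix <- function(...) {
  cols <- list(...)
  X <- do.call(cbind, lapply(cols, function(v) {
    stats::model.matrix(~ factor(v) - 1)
  }))
  X <- unname(X)
  attr(X, "blocks") <- rep(paste0("m", seq_along(cols)),
                           vapply(cols, function(v) length(unique(v)), 1L))
  X
}

test_that("one-class fit recovers level frequencies in closed form", {
  v1 <- c(1, 1, 1, 2, 2)
  v2 <- c(1, 2, 1, 2, 1)
  X <- block_matrix(v1, v2)
  fit <- fit_lca_em(X, K = 1, seed = 3)
  expect_equal(as.vector(fit$theta), colMeans(X), tolerance = 1e-6)
  # closed-form product-multinomial log-likelihood
  ll <- sum(table(v1) * log(table(v1) / 5)) +
    sum(table(v2) * log(table(v2) / 5))
  expect_equal(fit$loglik, as.numeric(ll), tolerance = 1e-6)
  expect_equal(fit$D, 2)  # one free level per two-level block
})

test_that("two disjoint identical-combination groups separate exactly", {
  v1 <- rep(c(1, 2), each = 10)
  v2 <- rep(c(1, 2), each = 10)
  X <- block_matrix(v1, v2)
  fits <- lapply(1:5, function(r) fit_lca_em(X, K = 2, seed = r))
  fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  z <- assign_classes(fit, X)
  expect_equal(length(unique(z[1:10])), 1)
  expect_equal(length(unique(z[11:20])), 1)
  expect_true(z[1] != z[11])
  # and the achieved likelihood equals the two-combination oracle
  expect_equal(fit$loglik, 20 * log(0.5), tolerance = 1e-6)
})

test_that("log-likelihood trace is non-decreasing for every run", {
  set.seed(10)
  for (r in 1:5) {
    X <- matrix(rbinom(80, 1, 0.4), nrow = 20)
    fit <- fit_lca_em(X, K = 3, seed = r)
    expect_true(all(diff(fit$trace) >= -1e-6))
  }
})

test_that("fit_lca_em validates its inputs", {
  X <- matrix(c(0, 1, 1, 0), 2)
  expect_error(fit_lca_em(X, K = 0), "K")
  expect_error(fit_lca_em(X, K = 3), "exceeds")
  expect_error(fit_lca_em(matrix(c(0.5, 1, 0, 1), 2), K = 1), "binary")
  expect_error(fit_lca_em(X[0, , drop = FALSE], K = 1), "empty")
})

test_that("BIC follows -2 loglik + p log n with p = (K-1) + K D", {
  fit <- structure(list(K = 2, loglik = -100, n = 50, D = 4),
                   class = "lca_fit")
  expect_equal(compute_bic(fit), 200 + 9 * log(50))
  fit1 <- structure(list(K = 1, loglik = -100, n = 50, D = 4),
                    class = "lca_fit")
  expect_equal(compute_bic(fit1), 200 + 4 * log(50))
  # for fixed loglik the penalty is strictly increasing in K
  bics <- vapply(1:5, function(K) {
    compute_bic(structure(list(K = K, loglik = -100, n = 50, D = 4),
                          class = "lca_fit"))
  }, numeric(1))
  expect_true(all(diff(bics) > 0))
  expect_error(compute_bic(fit, n = 0), "positive")
})

test_that("modal assignment matches a direct Bayes-rule oracle", {
  set.seed(21)
  X <- matrix(rbinom(15, 1, 0.5), nrow = 5)
  fit <- fit_lca_em(X, K = 2, seed = 2)
  post <- posterior_classes(fit, X)
  oracle <- oracle_posterior(fit$pi, fit$theta, X)
  expect_equal(post, oracle, tolerance = 1e-8)
  z <- assign_classes(fit, X)
  expect_equal(as.vector(z), apply(oracle, 1, which.max))
  # an exact tie breaks to the lowest class index and is logged
  tie_fit <- structure(list(K = 2, pi = c(0.5, 0.5),
                            theta = matrix(0.5, 2, 3),
                            is_mn = rep(FALSE, 3)),
                       class = "lca_fit")
  zt <- assign_classes(tie_fit, X[1:2, , drop = FALSE])
  expect_equal(as.vector(zt), c(1, 1))
  expect_equal(attr(zt, "ties"), c(1L, 2L))
})

test_that("best-restart likelihood matches brute-force maximisation", {
  # <= 3 distinct combinations, K <= 3: multinomial-block instance
  v1 <- rep(c(1, 1, 2), times = c(8, 4, 5))
  v2 <- rep(c(1, 2, 2), times = c(8, 4, 5))
  X <- block_matrix(v1, v2)
  for (K in 1:3) {
    lls <- vapply(1:20, function(r) {
      fit_lca_em(X, K, seed = r)$loglik
    }, numeric(1))
    oracle <- oracle_max_loglik(X, K, starts = 40)
    expect_equal(max(lls), oracle, tolerance = 1e-4)
  }
  # blockless Bernoulli instance
  Xb <- matrix(rep(c(1, 1, 0, 0, 1, 0), times = c(6, 6, 5, 5, 4, 4)),
               ncol = 2)
  for (K in 1:2) {
    lls <- vapply(1:20, function(r) {
      fit_lca_em(Xb, K, seed = r)$loglik
    }, numeric(1))
    expect_equal(max(lls), oracle_max_loglik(Xb, K, starts = 40),
                 tolerance = 1e-4)
  }
})

test_that("solution selection recovers planted noiseless partitions", {
  spec <- planted_action_spec(4, 120, theta_def = 1, seed = 31)
  gen <- generate_tokens(spec)
  prep <- preprocess_tokens(gen$table)
  sol <- select_morph_solution(prep$datasets[["synthact"]], seed = 8)
  expect_true(sol$accepted)
  expect_equal(sol$K, 4)
  truth <- gen$truth$morph[match(names(sol$assignments),
                                 gen$truth$token_id)]
  expect_equal(adjusted_rand_index(sol$assignments, truth), 1)
  # candidate log covers every fitted (K, restart) pair
  expect_equal(sum(sol$candidate_log$best_restart),
               max(sol$candidate_log$K))
})

test_that("the minimum-cluster constraint forces lumping of thin splits", {
  # two combinations, one with only 4 tokens: no eligible K > 1 exists
  df <- make_tokens("A", repetition = c(rep("Yes", 30), rep("No", 4)),
                    laterality = "Both")
  ds <- drop_incomplete_tokens(df, "repetition")
  sol <- select_morph_solution(ds, seed = 2)
  expect_equal(sol$K, 1)
  expect_true(all(sol$assignments == 1L))
})

test_that("actions without modifier variation yield one morph without LCA", {
  df <- make_tokens("A", repetition = "Yes", n = 15)
  ds <- drop_incomplete_tokens(df, character(0))
  sol <- select_morph_solution(ds, seed = 1)
  expect_equal(sol$K, 1)
  expect_null(sol$fit)
  expect_true(sol$accepted)
})

test_that("identical seeds give bit-identical solutions", {
  spec <- planted_action_spec(3, 150, seed = 77)
  gen <- generate_tokens(spec)
  prep <- preprocess_tokens(gen$table)
  s1 <- select_morph_solution(prep$datasets[["synthact"]], seed = 5)
  s2 <- select_morph_solution(prep$datasets[["synthact"]], seed = 5)
  expect_identical(s1$assignments, s2$assignments)
  expect_identical(s1$candidate_log, s2$candidate_log)
  expect_identical(s1$fit$theta, s2$fit$theta)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(33)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
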