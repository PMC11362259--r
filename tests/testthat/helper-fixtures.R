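# Shared fixtures: tiny schemas, token tables and independent oracles.

tiny_schema <- function() {
  modifier_schema(
    modifiers = list(
      body_part_signaller = c("Hand", "Foot", "Head", "Arm"),
      repetition = c("Yes", "No"),
      laterality = c("Unimanual", "Both", "Alternating")
    ),
    lump_actions = list(
      hitting_other = list(action = "hit_other",
                           modifiers = list(repetition = "Yes")),
      hit_other_raw = list(action = "hit_other",
                           modifiers = list(repetition = "No"))
    )
  )
}

# build a token data frame from per-column vectors, recycling scalars
make_tokens <- function(action, ..., goal = "Play", community = "Sonso",
                        n = NULL) {
  mods <- list(...)
  if (is.null(n)) {
    n <- max(c(length(action), lengths(mods), length(goal),
               length(community)))
  }
  df <- data.frame(action = rep_len(action, n),
                   goal = rep_len(goal, n),
                   community = rep_len(community, n),
                   stringsAsFactors = FALSE)
  for (m in names(mods)) df[[m]] <- rep_len(mods[[m]], n)
  df
}

tiny_table <- function(df, schema = tiny_schema()) {
  for (m in names(schema$modifiers)) {
    if (is.null(df[[m]])) df[[m]] <- schema$modifiers[[m]][1]
  }
  token_table(df, schema)
}

# independent posterior oracle: direct Bayes rule, no log-space tricks
oracle_posterior <- function(pi_k, theta, X) {
  K <- length(pi_k)
  out <- matrix(0, nrow(X), K)
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(K)) {
      out[i, k] <- pi_k[k] *
        prod(theta[k, ]^X[i, ] * (1 - theta[k, ])^(1 - X[i, ]))
    }
    out[i, ] <- out[i, ] / sum(out[i, ])
  }
  out
}

# independent maximum-likelihood oracle for tiny instances: direct
# multi-start optimisation of the mixture likelihood over free
# parameters. Honors the block structure of one-hot matrices (softmax
# per modifier block); blockless columns are independent Bernoullis.
oracle_max_loglik <- function(X, K, starts = 40, seed = 99) {
  blocks <- attr(X, "blocks")
  X <- as.matrix(X)
  D <- ncol(X)
  if (is.null(blocks)) blocks <- paste0(".col", seq_len(D))
  tabb <- table(blocks)
  multi <- names(tabb)[tabb >= 2]
  is_mn <- blocks %in% multi
  block_cols <- lapply(multi, function(b) which(blocks == b))
  n_par <- (K - 1) + K * D
  row_prob <- function(x, th, k) {
    p <- 1
    for (j in which(!is_mn)) {
      p <- p * th[k, j]^x[j] * (1 - th[k, j])^(1 - x[j])
    }
    for (cols in block_cols) p <- p * sum(th[k, cols] * x[cols])
    p
  }
  loglik_at <- function(par) {
    pi_k <- if (K == 1) 1 else {
      raw <- c(1, exp(par[seq_len(K - 1)]))
      raw / sum(raw)
    }
    th <- matrix(stats::plogis(par[K:(K - 1 + K * D)]), nrow = K)
    for (cols in block_cols) {
      th[, cols] <- th[, cols, drop = FALSE] /
        rowSums(th[, cols, drop = FALSE])
    }
    ll <- 0
    for (i in seq_len(nrow(X))) {
      li <- 0
      for (k in seq_len(K)) li <- li + pi_k[k] * row_prob(X[i, ], th, k)
      ll <- ll + log(li)
    }
    ll
  }
  set.seed(seed)
  best <- -Inf
  for (s in seq_len(starts)) {
    par0 <- stats::rnorm(n_par, 0, 2)
    opt <- try(stats::optim(par0, loglik_at,
                            control = list(fnscale = -1, maxit = 2000),
                            method = "BFGS"), silent = TRUE)
    if (!inherits(opt, "try-error")) best <- max(best, opt$value)
  }
  best
}

# random explained-ruleset generator for round-trip property tests
random_ruleset <- function(schema, n_actions = 3, seed = 1) {
  set.seed(seed)
  morphs <- list()
  for (a in seq_len(n_actions)) {
    action <- paste0("act", a)
    k <- sample(1:4, 1)
    for (i in seq_len(k)) {
      rule <- list()
      for (m in names(schema$modifiers)) {
        if (stats::runif(1) < 0.5) next
        lv <- schema$modifiers[[m]]
        pickable <- c(lv, "NOT_VALID", "OTHER")
        rule[[m]] <- sort(sample(pickable, sample(1:2, 1)))
      }
      morphs[[length(morphs) + 1]] <- list(
        name = paste0(action, ".", i), action = action,
        support = sample(5:100, 1), explained = TRUE, rule = rule,
        combinations = NULL)
    }
  }
  morph_ruleset(morphs, schema)
}
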