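test_that("pre-split actions are lumped with induced modifier values", {
  df <- rbind(
    make_tokens("hit_other_raw", body_part_signaller = "Hand",
                repetition = "MISSING", laterality = "Unimanual", n = 4),
    make_tokens("hitting_other", body_part_signaller = "Hand",
                repetition = "MISSING", laterality = "Unimanual", n = 6))
  tt <- tiny_table(df)
  out <- lump_presplit_actions(tt)
  expect_equal(unique(out$tokens$action), "hit_other")
  expect_equal(sum(out$tokens$repetition == "No"), 4)
  expect_equal(sum(out$tokens$repetition == "Yes"), 6)
  expect_match(tail(out$provenance, 1), "lump")
})

test_that("lumping refuses contradictory explicit codings, keeps identity", {
  df <- make_tokens("hitting_other", body_part_signaller = "Hand",
                    repetition = "No", laterality = "Unimanual", n = 3)
  tt <- tiny_table(df)
  expect_error(lump_presplit_actions(tt), "conflict")
  # identity map leaves the table unchanged
  df2 <- make_tokens("slap", body_part_signaller = "Hand",
                     repetition = "Yes", laterality = "Both", n = 5)
  tt2 <- tiny_table(df2)
  out2 <- lump_presplit_actions(tt2, lump_map = list())
  expect_equal(out2$tokens, tt2$tokens)
})

test_that("actions below the token threshold are removed", {
  df <- rbind(make_tokens("A", n = 12), make_tokens("B", n = 9),
              make_tokens("C", n = 10))
  tt <- tiny_table(df)
  out <- filter_actions_by_count(tt, min_n = 10)
  expect_setequal(unique(out$tokens$action), c("A", "C"))
  expect_match(tail(out$provenance, 1), "removed 1: B")
  # all below threshold: empty table, provenance still written
  out2 <- filter_actions_by_count(tt, min_n = 100)
  expect_equal(nrow(out2$tokens), 0)
  expect_match(tail(out2$provenance, 1), "filter_actions_by_count")
})

test_that("rare levels consolidate to OTHER, thin OTHER to MISSING", {
  df <- make_tokens("A", body_part_signaller =
                      c(rep("Hand", 20), rep("Head", 3), rep("Foot", 2)))
  out <- consolidate_rare_levels(df, "body_part_signaller", min_n = 5)
  expect_equal(sum(out$body_part_signaller == "OTHER"), 5)
  expect_equal(sum(out$body_part_signaller == "Hand"), 20)

  df2 <- make_tokens("A", body_part_signaller =
                       c(rep("Hand", 20), rep("Head", 3)))
  out2 <- consolidate_rare_levels(df2, "body_part_signaller", min_n = 5)
  expect_equal(sum(out2$body_part_signaller == "MISSING"), 3)

  df3 <- make_tokens("A", repetition = c(rep("UNKNOWN", 4), rep("Yes", 6)))
  out3 <- consolidate_rare_levels(df3, "repetition", min_n = 5)
  expect_equal(sum(out3$repetition == "MISSING"), 4)
})

test_that("informative modifiers need two well-supported levels", {
  df <- make_tokens("A",
                    repetition = c(rep("Yes", 6), rep("No", 5)),
                    laterality = c(rep("Unimanual", 7), rep("MISSING", 4)),
                    body_part_signaller = "Hand", n = 11)
  keep <- select_informative_modifiers(
    df, c("body_part_signaller", "repetition", "laterality"), min_n = 5)
  expect_equal(keep, "repetition")
  # NOT_VALID counts as a level, MISSING never does
  df2 <- make_tokens("A",
                     laterality = c(rep("NOT_VALID", 6), rep("Both", 5)),
                     n = 11)
  expect_equal(select_informative_modifiers(df2, "laterality"),
               "laterality")
  # no variation anywhere: single-morph action
  df3 <- make_tokens("A", repetition = "Yes", n = 12)
  expect_length(select_informative_modifiers(df3, "repetition"), 0)
})

test_that("tokens missing a retained modifier are dropped, others kept", {
  df <- make_tokens("A",
                    repetition = c(rep("Yes", 5), rep("No", 3), "MISSING",
                                   "MISSING"),
                    laterality = c(rep("MISSING", 9), "Unimanual"))
  ds <- drop_incomplete_tokens(df, "repetition")
  expect_s3_class(ds, "action_dataset")
  expect_equal(nrow(ds$tokens), 8)
  expect_equal(as.vector(ds$level_counts$repetition[c("Yes", "No")]),
               c(5, 3))
  expect_equal(ds$n_combinations, 2)
  # removing on a non-retained modifier does not happen
  expect_equal(sum(ds$tokens$laterality == "MISSING"), 8)
  # all tokens incomplete: degenerate action errors
  df2 <- make_tokens("A", repetition = "MISSING", n = 4)
  expect_error(drop_incomplete_tokens(df2, "repetition"), "degenerate")
})

test_that("one-hot encoding has one indicator block per modifier", {
  df <- make_tokens("A",
                    repetition = c("Yes", "No", "Yes"),
                    laterality = c("Both", "Unimanual", "NOT_VALID"))
  ds <- drop_incomplete_tokens(df, c("repetition", "laterality"))
  X <- one_hot_encode(ds)
  expect_equal(dim(X), c(3, 5))
  expect_true(all(rowSums(X) == 2))
  expect_true("NOT_VALID" %in% attr(X, "levels"))
  blocks <- attr(X, "blocks")
  for (b in unique(blocks)) {
    expect_true(all(rowSums(X[, blocks == b, drop = FALSE]) == 1))
  }
  # single retained modifier
  ds1 <- drop_incomplete_tokens(df, "laterality")
  X1 <- one_hot_encode(ds1)
  expect_equal(ncol(X1), 3)
  expect_true(all(rowSums(X1) == 1))
  # zero retained modifiers is the caller's single-morph case
  ds0 <- drop_incomplete_tokens(df, character(0))
  expect_error(one_hot_encode(ds0), "single-morph")
})

test_that("preprocessing pipeline enforces its invariants end to end", {
  spec <- corpus_like_spec(scale = 0.08, seed = 5)
  gen <- generate_tokens(spec)
  n0 <- nrow(gen$table$tokens)
  prep <- preprocess_tokens(gen$table)
  n_kept <- sum(vapply(prep$datasets, function(d) nrow(d$tokens),
                       numeric(1)))
  expect_lte(n_kept, n0)
  for (ds in prep$datasets) {
    for (m in ds$retained_modifiers) {
      counts <- table(ds$tokens[[m]])
      # after preprocessing every modelled level is well supported
      expect_true(all(counts[setdiff(names(counts), "MISSING")] >= 5))
      expect_false("UNKNOWN" %in% names(counts))
      expect_false("MISSING" %in% names(counts))
    }
    expect_gte(ds$n_combinations, 1)
  }
  # goal/community columns are never altered by preprocessing
  merged <- do.call(rbind, lapply(prep$datasets, `[[`, "tokens"))
  orig <- gen$table$tokens[match(merged$token_id,
                                 gen$table$tokens$token_id), ]
  expect_equal(merged$goal, orig$goal)
  expect_equal(merged$community, orig$community)
  # provenance proves the fixed order
  expect_match(prep$table$provenance[2], "lump")
  expect_match(prep$table$provenance[3], "filter_actions_by_count")
})
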