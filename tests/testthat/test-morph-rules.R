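# craft an action_dataset plus class assignment without running EM
manual_dataset <- function(df, mods) {
  drop_incomplete_tokens(df, mods)
}
manual_solution <- function(ds, z) {
  structure(list(action = ds$action, K = max(z), fit = NULL,
                 assignments = stats::setNames(as.integer(z),
                                               ds$tokens$token_id),
                 candidate_log = NULL, accepted = TRUE),
            class = "solution_choice")
}

test_that("combination probability and specificity follow their definitions", {
  df <- make_tokens("A",
                    repetition = rep(c("Yes", "No", "No"), each = 10),
                    laterality = rep(c("Both", "Both", "Unimanual"),
                                     each = 10))
  ds <- manual_dataset(df, c("repetition", "laterality"))
  # class 1 = exactly the Yes/Both tokens; classes split the No tokens
  z <- rep(c(1, 2, 3), each = 10)
  cs <- combination_support(z, ds)
  one <- cs[cs$combination == "Yes / Both" & cs$class == 1, ]
  expect_equal(one$probability, 1)
  expect_equal(one$specificity, 1)
  absent <- cs[cs$combination == "Yes / Both" & cs$class == 2, ]
  expect_equal(absent$probability, 0)
  # a combination split 50/50 across two classes has specificity 0.5
  z2 <- c(rep(1, 10), rep(2, 5), rep(3, 5), rep(2, 10))
  cs2 <- combination_support(z2, ds)
  half <- cs2[cs2$combination == "No / Both" & cs2$class %in% c(2, 3), ]
  expect_equal(half$specificity, c(0.5, 0.5))
})

test_that("single-combination classes get plain conjunctive rules", {
  df <- make_tokens("A",
                    body_part_signaller = rep(c("Foot", "Hand"), c(18, 20)),
                    repetition = rep(c("Yes", "No"), c(18, 20)))
  ds <- manual_dataset(df, c("body_part_signaller", "repetition"))
  sol <- manual_solution(ds, rep(c(2, 1), c(18, 20)))
  rs <- extract_ruleset(sol, ds)
  expect_equal(n_morphs(rs), 2)
  # support-ordered naming: the 20-token class is A.1
  expect_equal(rs$morphs[[1]]$support, 20)
  m2 <- rs$morphs[[2]]
  expect_true(m2$explained)
  # minimisation keeps only one discriminating modifier
  expect_length(m2$rule, 1)
})

test_that("multi-combination exclusive classes get disjunctive rules", {
  bp <- rep(c("Face", "Hand", "Leg", "Head"), each = 10)
  df <- make_tokens("A", body_part_signaller = bp,
                    repetition = "Yes")
  ds <- manual_dataset(df, "body_part_signaller")
  z <- rep(c(1, 1, 1, 2), each = 10)
  rs <- extract_ruleset(manual_solution(ds, z), ds)
  m1 <- rs$morphs[[1]]
  expect_true(m1$explained)
  expect_setequal(m1$rule$body_part_signaller,
                  c("Face", "Hand", "Leg"))
})

test_that("classes whose level sets swallow other combos are unexplained", {
  # class 1 holds (Hand,Yes) and (Foot,No); its level-set product
  # contains (Hand,No), which belongs to class 2
  df <- make_tokens("A",
                    body_part_signaller = rep(c("Hand", "Foot", "Hand"),
                                              each = 10),
                    repetition = rep(c("Yes", "No", "No"), each = 10))
  ds <- manual_dataset(df, c("body_part_signaller", "repetition"))
  z <- rep(c(1, 1, 2), each = 10)
  rs <- extract_ruleset(manual_solution(ds, z), ds)
  un <- rs$morphs[[1]]  # the 20-token class
  expect_false(un$explained)
  expect_length(un$combinations, 2)
  # the explained class still assigns its own tokens
  assigned <- assign_morph(rs, ds$tokens)
  expect_true(all(assigned[21:30] == "A.2"))
  expect_true(all(is.na(assigned[1:20])))
})

test_that("training tokens of explained morphs replay to their morph", {
  for (s in 1:3) {
    spec <- planted_action_spec(3, 200, theta_def = 1, seed = 40 + s)
    gen <- generate_tokens(spec)
    prep <- preprocess_tokens(gen$table)
    ds <- prep$datasets[["synthact"]]
    sol <- select_morph_solution(ds, seed = s)
    rs <- extract_ruleset(sol, ds)
    assigned <- assign_morph(rs, ds$tokens)
    sizes <- tabulate(sol$assignments, nbins = sol$K)
    ord <- order(-sizes, seq_len(sol$K))
    training <- paste0("synthact.", match(sol$assignments, ord))
    explained <- vapply(rs$morphs, `[[`, logical(1), "explained")
    names(explained) <- vapply(rs$morphs, `[[`, character(1), "name")
    in_expl <- explained[training]
    expect_true(all(assigned[in_expl] == training[in_expl]))
  }
})

test_that("tokens with unseen levels are unassigned; overlaps error", {
  sch <- tiny_schema()
  rs <- morph_ruleset(list(
    list(name = "A.1", action = "A", support = 10, explained = TRUE,
         rule = list(repetition = "Yes"), combinations = NULL),
    list(name = "A.2", action = "A", support = 8, explained = TRUE,
         rule = list(repetition = "No"), combinations = NULL)), sch)
  tok <- make_tokens("A", repetition = c("Yes", "No", "UNKNOWN"),
                     laterality = "Both")
  tok$token_id <- paste0("t", 1:3)
  expect_equal(assign_morph(rs, tok), c("A.1", "A.2", NA))
  # overlapping explained predicates violate the ruleset invariant
  rs_bad <- morph_ruleset(list(
    list(name = "A.1", action = "A", support = 10, explained = TRUE,
         rule = list(repetition = "Yes"), combinations = NULL),
    list(name = "A.2", action = "A", support = 8, explained = TRUE,
         rule = list(laterality = "Both"), combinations = NULL)), sch)
  expect_error(assign_morph(rs_bad, tok[1, ]), "more than one")
})

test_that("rule minimisation never changes the induced partition", {
  for (s in 1:3) {
    spec <- planted_action_spec(4, 240, theta_def = 1, seed = 50 + s)
    gen <- generate_tokens(spec)
    prep <- preprocess_tokens(gen$table)
    ds <- prep$datasets[["synthact"]]
    sol <- select_morph_solution(ds, seed = s)
    rs <- extract_ruleset(sol, ds)
    # replay: every token of an explained morph maps back to it
    assigned <- assign_morph(rs, ds$tokens)
    sizes <- tabulate(sol$assignments, nbins = sol$K)
    ord <- order(-sizes, seq_len(sol$K))
    training <- paste0("synthact.", match(sol$assignments, ord))
    expl_names <- vapply(Filter(function(m) m$explained, rs$morphs),
                         `[[`, character(1), "name")
    idx <- training %in% expl_names
    expect_equal(assigned[idx], training[idx])
  }
})

test_that("repertoire summaries add up", {
  sch <- tiny_schema()
  for (s in 1:4) {
    rs <- random_ruleset(sch, n_actions = 4, seed = 60 + s)
    sm <- ruleset_summary(rs)
    expect_equal(sm$n_morphs, n_morphs(rs))
    expect_equal(sum(sm$histogram$frequency), sm$n_actions)
    expect_equal(sum(sm$histogram$morphs_per_action *
                       sm$histogram$frequency), sm$n_morphs)
    expect_true(all(sm$modifier_usage$share_of_morphs >= 0 &
                      sm$modifier_usage$share_of_morphs <= 1))
  }
  # empty input: all-zero summary
  sm0 <- ruleset_summary(morph_ruleset(list(), sch))
  expect_equal(sm0$n_morphs, 0)
  expect_equal(sm0$n_actions, 0)
  expect_equal(nrow(sm0$histogram), 0)
})
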