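#' Probability and specificity of modifier combinations within classes
#'
#' For every (observed modifier-level combination, class) pair:
#' *probability* is the share of the class's tokens carrying the
#' combination, and *specificity* is the share of the combination's tokens
#' falling in the class. A combination that occurs in all of a class's
#' tokens and nowhere else scores 1 on both and can define the morph.
#'
#' @param assignments Integer class vector (one per token).
#' @param dataset The `action_dataset` the assignment was made on.
#' @return Data frame with columns `combination` (modifier levels joined
#'   by `" / "`), `class`, `n`, `probability`, `specificity`.
#' @export
combination_support <- function(assignments, dataset) {
  stopifnot(inherits(dataset, "action_dataset"))
  mods <- dataset$retained_modifiers
  combos <- if (length(mods)) {
    apply(dataset$tokens[, mods, drop = FALSE], 1, paste, collapse = " / ")
  } else rep("(no modifiers)", nrow(dataset$tokens))
  K <- max(assignments)
  levels_c <- sort(unique(combos))
  tab <- table(factor(combos, levels = levels_c),
               factor(assignments, levels = seq_len(K)))
  class_n <- colSums(tab)
  combo_n <- rowSums(tab)
  out <- expand.grid(combination = levels_c, class = seq_len(K),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- as.vector(tab)
  out$probability <- as.vector(sweep(tab, 2, pmax(class_n, 1), "/"))
  out$specificity <- as.vector(sweep(tab, 1, pmax(combo_n, 1), "/"))
  out
}

#' Extract a morph ruleset from an accepted class solution
#'
#' Classes become morphs named `<action>.<index>` with indices ordered by
#' descending support. A class whose observed combinations, taken as a
#' conjunction of per-modifier level sets, occur in no other class becomes
#' an *explained* morph with that conjunction as its defining rule
#' (a single combination gives a plain rule, several give a disjunctive
#' one); rules are then minimised by dropping, in schema order, any
#' modifier whose constraint is not needed to keep the predicates mutually
#' exclusive over the observed combinations. A class whose level-set
#' conjunction would swallow combinations of other classes (an "all other
#' cases" residue) is kept but flagged *unexplained*; new tokens cannot be
#' assigned to it.
#'
#' @param solution A `solution_choice` from [select_morph_solution()].
#' @param dataset The matching `action_dataset`.
#' @return A [morph_ruleset()] for the action.
#' @export
extract_ruleset <- function(solution, dataset) {
  stopifnot(inherits(solution, "solution_choice"),
            inherits(dataset, "action_dataset"))
  mods <- dataset$retained_modifiers
  tok <- dataset$tokens
  z <- as.integer(solution$assignments)
  action <- dataset$action
  K <- solution$K
  sizes <- tabulate(z, nbins = K)
  ord <- order(-sizes, seq_len(K))  # descending support, stable

  if (length(mods) == 0) {
    m <- list(name = paste0(action, ".1"), action = action,
              support = nrow(tok), explained = TRUE, rule = list(),
              combinations = NULL)
    return(morph_ruleset(list(m), dataset_schema(dataset)))
  }

  combo_df <- unique(tok[, mods, drop = FALSE])
  combo_key <- function(df) apply(df, 1, paste, collapse = "\r")
  tok_key <- combo_key(tok[, mods, drop = FALSE])
  combo_df <- combo_df[order(combo_key(combo_df)), , drop = FALSE]
  keys <- combo_key(combo_df)
  # deterministic solution: each combination lives in exactly one class
  combo_class <- vapply(keys, function(k) z[tok_key == k][1], integer(1))

  # per class: observed level sets per modifier
  level_sets <- lapply(seq_len(K), function(k) {
    ck <- combo_df[combo_class == k, , drop = FALSE]
    stats::setNames(lapply(mods, function(m) sort(unique(ck[[m]]))), mods)
  })
  matches <- function(rule, df) {
    ok <- rep(TRUE, nrow(df))
    for (m in names(rule)) ok <- ok & df[[m]] %in% rule[[m]]
    ok
  }
  # explained iff the level-set conjunction captures no other class's combos
  explained <- vapply(seq_len(K), function(k) {
    hit <- matches(level_sets[[k]], combo_df)
    all(combo_class[hit] == k)
  }, logical(1))

  rules <- level_sets
  # minimise rules of explained classes, in morph (support) order
  for (k in ord[explained[ord]]) {
    rule <- rules[[k]]
    for (m in mods) {
      trial <- rule[setdiff(names(rule), m)]
      hit <- matches(trial, combo_df)
      if (all(combo_class[hit] == k)) rule <- trial
    }
    rules[[k]] <- rule
  }

  morphs <- vector("list", K)
  for (i in seq_len(K)) {
    k <- ord[i]
    ck <- combo_df[combo_class == k, , drop = FALSE]
    morphs[[i]] <- list(
      name = paste0(action, ".", i), action = action,
      support = sizes[k],
      explained = explained[k],
      rule = if (explained[k]) rules[[k]] else list(),
      combinations = if (explained[k]) NULL else {
        apply(ck, 1, paste, collapse = " / ")
      })
  }
  morph_ruleset(morphs, dataset_schema(dataset))
}

# the schema travels with the tokens at pipeline level; an action_dataset
# keeps only the columns, so rebuild a minimal schema view for the ruleset
dataset_schema <- function(dataset) {
  sch <- attr(dataset, "schema")
  if (!is.null(sch)) return(sch)
  mods <- names(dataset$level_counts)
  all_mods <- intersect(colnames(dataset$tokens),
                        c("body_part_signaller", "body_part_contact",
                          "repetition", "laterality"))
  if (length(all_mods) == 0) all_mods <- mods
  lv <- lapply(all_mods, function(m) {
    v <- setdiff(unique(dataset$tokens[[m]]), .RES)
    if (length(v)) v else "none_observed"
  })
  modifier_schema(stats::setNames(lv, all_mods))
}

#' Assign tokens to morphs under a ruleset
#'
#' A token is assigned to the unique explained morph of its action whose
#' rule it satisfies. Tokens matching no rule (rare levels, combinations
#' belonging to an unexplained morph, or actions absent from the ruleset)
#' return `NA` (unassigned). A token satisfying two or more explained
#' rules violates the ruleset's mutual-exclusivity invariant and raises an
#' error.
#'
#' @param ruleset A `morph_ruleset`.
#' @param tokens A `token_table` or a token data frame.
#' @return Character vector of morph names (`NA` = unassigned).
#' @export
assign_morph <- function(ruleset, tokens) {
  stopifnot(inherits(ruleset, "morph_ruleset"))
  tok <- if (inherits(tokens, "token_table")) tokens$tokens else tokens
  n <- nrow(tok)
  out <- rep(NA_character_, n)
  hits <- integer(n)
  for (m in ruleset$morphs) {
    if (!m$explained) next
    sel <- tok$action == m$action
    if (!any(sel)) next
    for (mod in names(m$rule)) {
      sel <- sel & tok[[mod]] %in% m$rule[[mod]]
    }
    if (any(sel)) {
      out[sel] <- m$name
      hits[sel] <- hits[sel] + 1L
    }
  }
  if (any(hits > 1)) {
    bad <- utils::head(which(hits > 1), 5)
    stop("ruleset inconsistency: token(s) ",
         paste(tok$token_id[bad], collapse = ", "),
         " satisfy more than one explained morph rule")
  }
  out
}

#' Summarise a morph repertoire
#'
#' Per action: morph count and number of distinct modifiers referenced
#' across its rules. Repertoire totals: total morphs, unexplained morphs,
#' single-morph actions, a morphs-per-action histogram, and the share of
#' morphs whose rule constrains each modifier.
#'
#' @param ruleset A `morph_ruleset` (combine per-action rulesets with
#'   [combine_rulesets()] first).
#' @return An object of class `ruleset_summary`.
#' @export
ruleset_summary <- function(ruleset) {
  stopifnot(inherits(ruleset, "morph_ruleset"))
  ms <- ruleset$morphs
  mods <- names(ruleset$schema$modifiers)
  if (length(ms) == 0) {
    return(structure(list(
      per_action = data.frame(action = character(0), n_morphs = integer(0),
                              n_modifiers = integer(0)),
      n_morphs = 0L, n_actions = 0L, n_unexplained = 0L,
      n_single_morph_actions = 0L,
      histogram = data.frame(morphs_per_action = integer(0),
                             frequency = integer(0)),
      modifier_usage = data.frame(modifier = mods,
                                  share_of_morphs = rep(0, length(mods)))),
      class = "ruleset_summary"))
  }
  acts <- vapply(ms, `[[`, character(1), "action")
  per_action <- do.call(rbind, lapply(unique(acts), function(a) {
    mm <- ms[acts == a]
    used <- unique(unlist(lapply(mm, function(m) names(m$rule))))
    data.frame(action = a, n_morphs = length(mm),
               n_modifiers = length(used), stringsAsFactors = FALSE)
  }))
  hist_tab <- table(per_action$n_morphs)
  usage <- vapply(mods, function(m) {
    mean(vapply(ms, function(x) m %in% names(x$rule), logical(1)))
  }, numeric(1))
  structure(list(
    per_action = per_action,
    n_morphs = length(ms),
    n_actions = nrow(per_action),
    n_unexplained = sum(!vapply(ms, `[[`, logical(1), "explained")),
    n_single_morph_actions = sum(per_action$n_morphs == 1),
    histogram = data.frame(morphs_per_action = as.integer(names(hist_tab)),
                           frequency = as.integer(hist_tab)),
    modifier_usage = data.frame(modifier = mods,
                                share_of_morphs = unname(usage),
                                stringsAsFactors = FALSE)),
    class = "ruleset_summary")
}

#' @export
print.ruleset_summary <- function(x, ...) {
  cat("Morph repertoire:", x$n_morphs, "morphs across", x$n_actions,
      "gesture actions\n")
  cat("  single-morph actions:", x$n_single_morph_actions,
      "; unexplained morphs:", x$n_unexplained, "\n")
  cat("  morphs per action: ",
      paste(x$histogram$morphs_per_action, "x", x$histogram$frequency,
            collapse = ", "), "\n")
  invisible(x)
}
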