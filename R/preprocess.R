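#' Lump pre-split gesture actions
#'
#' Some corpora split gesture actions in the raw coding on a modifier of
#' interest (e.g. "hit other" = one hit vs "hitting other" = repeated
#' hits). To bring all actions to the same level of splitting before morph
#' detection, such actions are renamed to their lumped form and the
#' modifier value the raw name implied is written into the modifier column.
#' An induced value only overwrites an unknown/missing cell or a cell that
#' already agrees; a contradictory explicit coding is an error.
#'
#' @param x A [token_table()].
#' @param lump_map Named list raw action -> list(action=, modifiers=);
#'   defaults to the map declared in the schema.
#' @return The lumped `token_table` (provenance updated).
#' @export
lump_presplit_actions <- function(x, lump_map = x$schema$lump_actions) {
  stopifnot(inherits(x, "token_table"))
  tok <- x$tokens
  for (raw in names(lump_map)) {
    la <- lump_map[[raw]]
    hit <- tok$action == raw
    if (!any(hit)) next
    for (m in names(la$modifiers)) {
      induced <- la$modifiers[[m]]
      cur <- tok[[m]][hit]
      overwritable <- cur %in% c(.RES[["missing"]], .RES[["unknown"]]) |
        cur == induced
      if (!all(overwritable)) {
        stop("lumping '", raw, "' -> '", la$action, "': induced ", m, " = ",
             induced, " conflicts with coded value(s) in token(s) ",
             paste(tok$token_id[hit][!overwritable], collapse = ", "))
      }
      tok[[m]][hit] <- induced
    }
    tok$action[hit] <- la$action
  }
  x$tokens <- tok
  .log_step(x, "lump_presplit_actions")
}

#' Drop gesture actions with too few tokens
#'
#' Rare actions carry too little variation for latent class analysis to
#' say anything about them; only actions observed at least `min_n` times
#' are kept.
#'
#' @param x A [token_table()].
#' @param min_n Minimum token count per action (default 10).
#' @return Filtered `token_table`; removed actions recorded in provenance.
#' @export
filter_actions_by_count <- function(x, min_n = 10) {
  stopifnot(inherits(x, "token_table"), min_n >= 1)
  counts <- table(x$tokens$action)
  keep <- names(counts)[counts >= min_n]
  dropped <- setdiff(names(counts), keep)
  x$tokens <- x$tokens[x$tokens$action %in% keep, , drop = FALSE]
  rownames(x$tokens) <- NULL
  .log_step(x, paste0("filter_actions_by_count(min_n=", min_n, "; removed ",
                      length(dropped), ": ",
                      paste(dropped, collapse = ","), ")"))
}

#' Consolidate rare modifier levels within one gesture action
#'
#' Within a single action's tokens: levels of `modifier` seen fewer than
#' `min_n` times are recoded to the `OTHER` category; if the pooled
#' `OTHER` category itself then has fewer than `min_n` cases those cases
#' become `MISSING`. `UNKNOWN` cells always become `MISSING`. `NOT_VALID`
#' is treated as a regular level throughout (it can define a morph).
#'
#' @param action_tokens Data frame of one action's tokens.
#' @param modifier Modifier column name.
#' @param min_n Minimum level support (default 5).
#' @return The data frame with the modifier column recoded.
#' @export
consolidate_rare_levels <- function(action_tokens, modifier, min_n = 5) {
  v <- action_tokens[[modifier]]
  v[v == .RES[["unknown"]]] <- .RES[["missing"]]
  substantive <- !(v %in% c(.RES[["missing"]], .RES[["other"]]))
  counts <- table(v[substantive])
  # NOT_VALID behaves as a regular level: it can define a morph, and it is
  # subject to the same rarity rule as any other level
  rare <- names(counts)[counts < min_n]
  v[v %in% rare] <- .RES[["other"]]
  if (sum(v == .RES[["other"]]) < min_n) {
    v[v == .RES[["other"]]] <- .RES[["missing"]]
  }
  action_tokens[[modifier]] <- v
  action_tokens
}

#' Retain modifiers that vary within a gesture action
#'
#' A modifier is informative for an action when at least two of its levels
#' each occur at least `min_n` times among the action's tokens after rare-
#' level consolidation. `MISSING` never counts as a level; `NOT_VALID` and
#' `OTHER` do.
#'
#' @param action_tokens Data frame of one action's tokens (already passed
#'   through [consolidate_rare_levels()]).
#' @param modifiers Candidate modifier names.
#' @param min_n Minimum level support (default 5).
#' @return Character vector of retained modifier names (possibly empty:
#'   a single-morph action).
#' @export
select_informative_modifiers <- function(action_tokens, modifiers,
                                         min_n = 5) {
  keep <- character(0)
  for (m in modifiers) {
    v <- action_tokens[[m]]
    v <- v[v != .RES[["missing"]] & v != .RES[["unknown"]]]
    counts <- table(v)
    if (sum(counts >= min_n) >= 2) keep <- c(keep, m)
  }
  keep
}

#' Drop tokens with missing values in retained modifiers
#'
#' Tokens that lack a value in a modifier that otherwise shows sufficient
#' variation within the action cannot be clustered and are removed; a
#' missing value in a non-retained modifier is harmless.
#'
#' @param action_tokens Data frame of one action's tokens.
#' @param retained_modifiers From [select_informative_modifiers()].
#' @param action Action label (defaults to the tokens' action).
#' @return An `action_dataset`: list with `action`, `tokens`,
#'   `retained_modifiers`, `level_counts` (per retained modifier), and
#'   `n_combinations` (unique retained-modifier level combinations).
#' @export
drop_incomplete_tokens <- function(action_tokens, retained_modifiers,
                                   action = unique(action_tokens$action)) {
  stopifnot(length(action) == 1)
  keep <- rep(TRUE, nrow(action_tokens))
  for (m in retained_modifiers) {
    keep <- keep & !(action_tokens[[m]] %in%
                       c(.RES[["missing"]], .RES[["unknown"]]))
  }
  tok <- action_tokens[keep, , drop = FALSE]
  rownames(tok) <- NULL
  if (nrow(tok) == 0) {
    stop("degenerate action '", action,
         "': all tokens removed by missing-value filtering")
  }
  level_counts <- lapply(retained_modifiers, function(m) table(tok[[m]]))
  names(level_counts) <- retained_modifiers
  n_comb <- if (length(retained_modifiers)) {
    nrow(unique(tok[, retained_modifiers, drop = FALSE]))
  } else 1L
  structure(list(action = action, tokens = tok,
                 retained_modifiers = retained_modifiers,
                 level_counts = level_counts,
                 n_combinations = n_comb),
            class = "action_dataset")
}

#' @export
print.action_dataset <- function(x, ...) {
  cat("Action dataset '", x$action, "': ", nrow(x$tokens), " tokens, ",
      length(x$retained_modifiers), " retained modifier(s), ",
      x$n_combinations, " observed combination(s)\n", sep = "")
  invisible(x)
}

#' One-hot encode an action dataset
#'
#' Each retained-modifier level present after consolidation (including
#' `OTHER` and `NOT_VALID`) becomes a 0/1 indicator column; within each
#' modifier's block every row has exactly one 1.
#'
#' @param dataset An `action_dataset` with at least one retained modifier.
#' @return Integer matrix (tokens x indicator columns) with attributes
#'   `blocks` (modifier of each column) and `levels` (level of each
#'   column).
#' @export
one_hot_encode <- function(dataset) {
  stopifnot(inherits(dataset, "action_dataset"))
  mods <- dataset$retained_modifiers
  if (length(mods) == 0) {
    stop("action '", dataset$action, "' has no retained modifiers; ",
         "treat it as a single-morph action without LCA")
  }
  tok <- dataset$tokens
  cols <- list()
  blocks <- character(0)
  levels_ <- character(0)
  for (m in mods) {
    lv <- sort(unique(tok[[m]]))
    for (l in lv) {
      cols[[paste0(m, "=", l)]] <- as.integer(tok[[m]] == l)
      blocks <- c(blocks, m)
      levels_ <- c(levels_, l)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- tok$token_id
  attr(X, "blocks") <- blocks
  attr(X, "levels") <- levels_
  X
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: lump pre-split actions, drop rare actions, consolidate
#' rare modifier levels per action, select informative modifiers, drop
#' incomplete tokens. Actions are not re-filtered after token removal even
#' if they fall below `min_action_n` (set `refilter = TRUE` for the strict
#' variant).
#'
#' @param x A [token_table()].
#' @param min_action_n Minimum tokens per action (default 10).
#' @param min_level_n Minimum level support (default 5).
#' @param refilter Re-apply the action-count filter after token removal.
#' @return List with `datasets` (named list of `action_dataset`),
#'   `table` (the filtered `token_table` before per-action steps), and
#'   `excluded` (named character vector of excluded actions and reasons).
#' @export
preprocess_tokens <- function(x, min_action_n = 10, min_level_n = 5,
                              refilter = FALSE) {
  stopifnot(inherits(x, "token_table"))
  x <- lump_presplit_actions(x)
  x <- filter_actions_by_count(x, min_action_n)
  sch <- x$schema
  datasets <- list()
  excluded <- character(0)
  for (a in sort(unique(x$tokens$action))) {
    tok <- x$tokens[x$tokens$action == a, , drop = FALSE]
    for (m in names(sch$modifiers)) {
      tok <- consolidate_rare_levels(tok, m, min_level_n)
    }
    retained <- select_informative_modifiers(tok, names(sch$modifiers),
                                             min_level_n)
    ds <- tryCatch(drop_incomplete_tokens(tok, retained, action = a),
                   error = function(e) NULL)
    if (is.null(ds)) {
      excluded[a] <- "all tokens incomplete"
      next
    }
    if (refilter && nrow(ds$tokens) < min_action_n) {
      excluded[a] <- "below min_action_n after token removal"
      next
    }
    attr(ds, "schema") <- sch
    datasets[[a]] <- ds
  }
  x <- .log_step(x, paste0("per_action_preprocessing(min_level_n=",
                           min_level_n, ")"))
  list(datasets = datasets, table = x, excluded = excluded)
}
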