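#!/usr/bin/env Rscript

# Optional external validation against the deposited field dataset.
#
# The corpus-dependent results (7879 tokens, 61 -> 42 actions after the
# 10-token filter, 527 observed action/modifier combinations, 115 morphs
# with 99 explained by a single rule, 7560 of 7749 cases assignable,
# naive Bayes accuracies, entropy-test counts, play-exclusive morphs)
# can only be recomputed from the deposited data, which is not shipped
# with the package. Clone the data repository locally, export the token
# table as CSV with the column layout documented in ?read_tokens, and
# point this script at it:
#
#   Rscript scripts/external_validation.R <tokens.csv> <out_dir>
#
# The script runs the full pipeline at the published thresholds and
# prints the corpus-level counts for comparison.

suppressPackageStartupMessages(library(gesturemorphs))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) {
  stop("usage: external_validation.R <tokens.csv> <out_dir>",
       call. = FALSE)
}

cfg <- run_config(input = args[[1]], schema = chimp_schema(),
                  out_dir = args[[2]], min_action_n = 10,
                  min_level_n = 5, min_cluster_n = 5, restarts = 10,
                  n_perm = 1000, folds = 10, seed = 1L)
res <- run_pipeline(cfg)

m <- res$manifest
cat("tokens read:                 ", m$counts$tokens_read, "\n")
cat("tokens after preprocessing:  ", m$counts$tokens_post_preprocessing,
    "\n")
cat("actions analysed:            ", m$counts$actions_analysed, "\n")
cat("morphs:                      ", m$counts$morphs, "\n")
cat("  unexplained:               ", m$counts$unexplained_morphs, "\n")
cat("tokens assignable by rule:   ", m$counts$tokens_assignable_by_rule,
    "\n")
cat("NB token accuracy (action):  ",
    round(m$classifier$token_accuracy_action, 3), "\n")
cat("NB token accuracy (morph):   ",
    round(m$classifier$token_accuracy_morph, 3), "\n")
cat("NB category accuracy (action):",
    round(m$classifier$category_accuracy_action, 3), "\n")
cat("NB category accuracy (morph): ",
    round(m$classifier$category_accuracy_morph, 3), "\n")
cat("actions with goal-informative morphs:     ",
    res$value$n_actions_goal_significant, "of",
    res$value$n_actions_tested, "\n")
cat("actions with community-informative morphs:",
    res$value$n_actions_community_significant, "of",
    res$value$n_actions_tested, "\n")
cat("play-exclusive morphs:       ", length(res$value$play_exclusive),
    "\n")
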