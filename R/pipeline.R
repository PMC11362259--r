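#' Assemble a pipeline run configuration
#'
#' @param input Path to a token CSV/TSV, or `NULL` when `spec` is given.
#' @param spec A [synthetic_spec()] to generate input from, or `NULL`.
#' @param schema A [modifier_schema()] (ignored when `spec` carries one).
#' @param out_dir Output directory (created if absent).
#' @param min_action_n,min_level_n,min_cluster_n Sampling thresholds.
#' @param restarts,max_iter,tol Latent-class fitting settings.
#' @param n_perm Permutations for the entropy tests.
#' @param folds Cross-validation folds.
#' @param upsample Balance goal categories in classifier training folds.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, spec = NULL, schema = chimp_schema(),
                       out_dir = tempfile("morphrun"),
                       min_action_n = 10, min_level_n = 5,
                       min_cluster_n = 5, restarts = 10,
                       max_iter = 1000, tol = 1e-6, n_perm = 1000,
                       folds = 10, upsample = TRUE, seed = 1L) {
  if (is.null(input) && is.null(spec)) {
    stop("provide either an input path or a synthetic spec")
  }
  stopifnot(min_action_n >= 1, min_level_n >= 1, min_cluster_n >= 1)
  structure(list(input = input, spec = spec, schema = schema,
                 out_dir = out_dir, min_action_n = min_action_n,
                 min_level_n = min_level_n,
                 min_cluster_n = min_cluster_n, restarts = restarts,
                 max_iter = max_iter, tol = tol, n_perm = n_perm,
                 folds = folds, upsample = upsample,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full morph pipeline
#'
#' Preprocess, split every action by constrained latent class analysis,
#' extract morph rules, test the information value of morphs, and compare
#' action vs morph as goal predictors. Writes six artefacts to the
#' configured output directory: `morph_table.csv`, `ruleset_summary.csv`,
#' `morph_value_report.csv`, `classifier_comparison.csv`,
#' `candidate_log.csv`, and `manifest.json`. Reruns with an identical
#' configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `token_table`, per-action datasets,
#'   solutions, the combined `ruleset`, its `summary`, assigned tokens,
#'   the `value` report, the classifier `comparison`, and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$spec)) {
    gen <- generate_tokens(config$spec)
    tt <- gen$table
    truth <- gen$truth
  } else {
    tt <- read_tokens(config$input, config$schema)
  }
  n_read <- nrow(tt$tokens)

  prep <- preprocess_tokens(tt, min_action_n = config$min_action_n,
                            min_level_n = config$min_level_n)
  if (length(prep$datasets) == 0) {
    stop("no gesture action survives preprocessing; nothing to analyse ",
         "(", n_read, " tokens read)")
  }

  acts <- names(prep$datasets)  # already sorted
  solutions <- list()
  rulesets <- list()
  cand_logs <- list()
  failures <- character(0)
  for (i in seq_along(acts)) {
    a <- acts[i]
    res <- tryCatch({
      sol <- select_morph_solution(
        prep$datasets[[a]], restarts = config$restarts,
        min_cluster_n = config$min_cluster_n,
        seed = .restart_seed(config$seed, i, 0L),
        max_iter = config$max_iter, tol = config$tol)
      list(sol = sol, rs = extract_ruleset(sol, prep$datasets[[a]]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[a] <- conditionMessage(res)
      next
    }
    solutions[[a]] <- res$sol
    rulesets[[a]] <- res$rs
    cl <- res$sol$candidate_log
    if (nrow(cl)) cl$action <- a
    cand_logs[[a]] <- cl
  }
  if (length(failures)) {
    warning("per-action failures (run continued): ",
            paste(names(failures), collapse = ", "))
  }
  ruleset <- combine_rulesets(rulesets)
  summ <- ruleset_summary(ruleset)

  # analysis token set: per-action preprocessed tokens with their
  # training-time morph labels (unexplained morphs included)
  assigned <- do.call(rbind, lapply(names(solutions), function(a) {
    ds <- prep$datasets[[a]]
    sol <- solutions[[a]]
    sizes <- tabulate(sol$assignments, nbins = sol$K)
    ord <- order(-sizes, seq_len(sol$K))
    morph_index <- match(sol$assignments, ord)
    tok <- ds$tokens
    tok$morph <- paste0(a, ".", morph_index)
    tok
  }))
  rownames(assigned) <- NULL
  rule_morph <- assign_morph(ruleset, assigned)
  assigned$morph_by_rule <- rule_morph

  value <- morph_value_report(assigned, n_perm = config$n_perm,
                              seed = config$seed)
  comparison <- compare_predictors(assigned, target = "goal",
                                   folds = config$folds,
                                   seed = config$seed,
                                   upsample = config$upsample)

  paths <- c(
    morph_table = file.path(config$out_dir, "morph_table.csv"),
    ruleset_summary = file.path(config$out_dir, "ruleset_summary.csv"),
    value_report = file.path(config$out_dir, "morph_value_report.csv"),
    classifier = file.path(config$out_dir, "classifier_comparison.csv"),
    candidate_log = file.path(config$out_dir, "candidate_log.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))

  write_morph_table(ruleset, paths[["morph_table"]])
  utils::write.csv(summ$per_action, paths[["ruleset_summary"]],
                   row.names = FALSE)
  utils::write.csv(value$entropy, paths[["value_report"]],
                   row.names = FALSE)
  utils::write.csv(comparison$per_category, paths[["classifier"]],
                   row.names = FALSE)
  cand <- do.call(rbind, cand_logs)
  if (is.null(cand)) cand <- .empty_candidate_log()
  utils::write.csv(cand, paths[["candidate_log"]], row.names = FALSE)

  manifest <- list(
    package = "gesturemorphs",
    version = as.character(utils::packageVersion("gesturemorphs")),
    seed = config$seed,
    thresholds = list(min_action_n = config$min_action_n,
                      min_level_n = config$min_level_n,
                      min_cluster_n = config$min_cluster_n),
    lca = list(restarts = config$restarts, max_iter = config$max_iter,
               tol = config$tol),
    n_perm = config$n_perm, folds = config$folds,
    upsample = config$upsample,
    input = if (is.null(config$input)) "synthetic" else config$input,
    synthetic_seed = if (is.null(config$spec)) NULL else config$spec$seed,
    counts = list(
      tokens_read = n_read,
      tokens_post_preprocessing = sum(vapply(prep$datasets, function(d) {
        nrow(d$tokens)
      }, numeric(1))),
      tokens_assignable_by_rule = sum(!is.na(rule_morph)),
      actions_analysed = length(solutions),
      morphs = summ$n_morphs,
      unexplained_morphs = summ$n_unexplained),
    classifier = list(
      token_accuracy_action = comparison$action$token_accuracy,
      token_accuracy_morph = comparison$morph$token_accuracy,
      category_accuracy_action = comparison$action$category_accuracy,
      category_accuracy_morph = comparison$morph$category_accuracy),
    excluded_actions = as.list(prep$excluded),
    per_action_failures = as.list(failures))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(table = tt, truth = truth, datasets = prep$datasets,
                 solutions = solutions, ruleset = ruleset,
                 summary = summ, assigned = assigned, value = value,
                 comparison = comparison, manifest = manifest,
                 paths = paths))
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; a `synthetic`
#' block (`scale`, `seed`, `theta_def`) builds the input via
#' [corpus_like_spec()] instead of reading a file.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(y$synthetic)) {
    spec <- corpus_like_spec(
      scale = if (is.null(y$synthetic$scale)) 1 else y$synthetic$scale,
      seed = if (is.null(y$synthetic$seed)) y$seed else y$synthetic$seed,
      theta_def = if (is.null(y$synthetic$theta_def)) 0.95 else
        y$synthetic$theta_def)
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  args$spec <- spec
  do.call(run_config, args)
}
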