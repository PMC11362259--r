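#' Construct a token table
#'
#' A token table couples a data frame of gesture tokens (one row per
#' observed gesture) with the schema under which it is interpreted and a
#' provenance log recording, in order, every transformation applied.
#'
#' @param tokens Data frame with columns `token_id`, `community`,
#'   `signaller_id`, `action`, one column per schema modifier, `goal`.
#'   Missing `token_id`/`signaller_id`/`community` columns are auto-filled.
#' @param schema A [modifier_schema()].
#' @param provenance Character vector of processing-step labels.
#' @param validate Check levels against the schema (default `TRUE`).
#' @return An object of class `token_table`.
#' @export
token_table <- function(tokens, schema, provenance = "constructed",
                        validate = TRUE) {
  stopifnot(inherits(schema, "modifier_schema"), is.data.frame(tokens))
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  if (is.null(tokens$token_id)) {
    tokens$token_id <- sprintf("tok%05d", seq_len(nrow(tokens)))
  }
  if (is.null(tokens$signaller_id)) tokens$signaller_id <- "unknown_signaller"
  if (is.null(tokens$community)) tokens$community <- "unknown_community"
  need <- c("action", names(schema$modifiers), "goal")
  miss <- setdiff(need, names(tokens))
  if (length(miss)) {
    stop("token table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("token_id", "community", "signaller_id", "action",
                names(schema$modifiers), "goal")) {
    tokens[[col]] <- as.character(tokens[[col]])
  }
  if (anyDuplicated(tokens$token_id)) stop("token_ids must be unique")
  tokens$is_play <- tokens$goal == schema$play_goal
  ord <- c("token_id", "community", "signaller_id", "action",
           names(schema$modifiers), "goal", "is_play")
  tokens <- tokens[, c(ord, setdiff(names(tokens), ord)), drop = FALSE]
  rownames(tokens) <- NULL
  x <- structure(list(tokens = tokens, schema = schema,
                      provenance = provenance),
                 class = "token_table")
  if (validate) validate_token_table(x)
  x
}

#' Validate a token table against its schema
#'
#' Checks that every modifier cell holds a declared level or a reserved
#' code, and that goal/community labels fall in the schema's closed sets
#' (when declared).
#'
#' @param x A `token_table`.
#' @return `x`, invisibly; errors list the offending rows.
#' @export
validate_token_table <- function(x) {
  stopifnot(inherits(x, "token_table"))
  tok <- x$tokens
  sch <- x$schema
  for (m in names(sch$modifiers)) {
    ok <- tok[[m]] %in% c(sch$modifiers[[m]], .RES)
    if (!all(ok)) {
      stop("modifier '", m, "' holds level(s) not in schema: ",
           paste(unique(tok[[m]][!ok]), collapse = ", "),
           " (rows ", paste(utils::head(which(!ok), 10), collapse = ", "),
           ")")
    }
  }
  if (!is.null(sch$goals)) {
    ok <- tok$goal %in% c(sch$goals, .RES[["unknown"]])
    if (!all(ok)) {
      stop("goal label(s) not in schema: ",
           paste(unique(tok$goal[!ok]), collapse = ", "),
           " (rows ", paste(utils::head(which(!ok), 10), collapse = ", "),
           ")")
    }
  }
  if (!is.null(sch$communities)) {
    ok <- tok$community %in% sch$communities
    if (!all(ok)) {
      stop("community label(s) not in schema: ",
           paste(unique(tok$community[!ok]), collapse = ", "),
           " (rows ", paste(utils::head(which(!ok), 10), collapse = ", "),
           ")")
    }
  }
  invisible(x)
}

#' @export
print.token_table <- function(x, ...) {
  cat("Token table:", nrow(x$tokens), "tokens,",
      length(unique(x$tokens$action)), "gesture actions\n")
  cat("Provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# append a provenance entry
.log_step <- function(x, step) {
  x$provenance <- c(x$provenance, step)
  x
}
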