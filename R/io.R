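#' Read a gesture-token table from a delimited file
#'
#' Reads a CSV/TSV export of gesture tokens (one row per observed gesture).
#' The delimiter is sniffed from the header line (tab wins over comma when
#' both occur). Cells spelled as the schema's unknown/not-valid/missing/
#' other spellings, and empty cells, are mapped to the reserved codes;
#' raw-level lump maps declared in the schema (e.g. Left/Right ->
#' Unimanual) are applied before validation.
#'
#' @param path Path to a delimited text file with a header row holding at
#'   minimum `gesture_action` (or `action`), one column per schema
#'   modifier, `goal`, and `community`.
#' @param schema A [modifier_schema()].
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return A [token_table()] with provenance `read`.
#' @export
read_tokens <- function(path, schema, delim = NULL) {
  stopifnot(inherits(schema, "modifier_schema"))
  if (is.null(delim)) delim <- .sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!is.null(raw$gesture_action) && is.null(raw$action)) {
    names(raw)[names(raw) == "gesture_action"] <- "action"
  }
  need <- c("action", names(schema$modifiers), "goal", "community")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("input file lacks required column(s): ",
         paste(sub("^action$", "gesture_action", miss), collapse = ", "))
  }
  for (m in names(schema$modifiers)) {
    v <- .decode_reserved(raw[[m]], schema$spellings)
    map <- schema$lump_levels[[m]]
    if (!is.null(map)) {
      hit <- v %in% names(map)
      v[hit] <- unname(map[v[hit]])
    }
    raw[[m]] <- v
  }
  raw$goal <- .decode_reserved(raw$goal, schema$spellings)
  token_table(raw, schema, provenance = "read")
}

#' Write a token table to CSV
#'
#' @param x A `token_table`.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [read_tokens()].
#' @export
write_tokens <- function(x, path) {
  stopifnot(inherits(x, "token_table"))
  tok <- x$tokens
  names(tok)[names(tok) == "action"] <- "gesture_action"
  tok$is_play <- NULL
  utils::write.csv(tok, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.sniff_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
}

# ---- morph rulesets ---------------------------------------------------------

#' Construct a morph ruleset
#'
#' A ruleset holds named morphs, each belonging to a gesture action and
#' defined either by a predicate -- a conjunction of per-modifier
#' membership constraints, with unconstrained modifiers absent -- or, for
#' unexplained morphs, by nothing (their tokens are "all other cases" of
#' the action and new tokens cannot be assigned to them).
#'
#' @param morphs List of morph entries, each a list with elements `name`
#'   (`"<action>.<index>"`), `action`, `support` (token count), `explained`
#'   (flag), `rule` (named list: modifier -> character vector of allowed
#'   levels; may include the `NOT_VALID`/`OTHER` codes), and optionally
#'   `combinations` (the raw observed combination list, kept for
#'   unexplained morphs).
#' @param schema A [modifier_schema()].
#' @return An object of class `morph_ruleset`.
#' @export
morph_ruleset <- function(morphs, schema) {
  stopifnot(inherits(schema, "modifier_schema"))
  nms <- vapply(morphs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate morph name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  for (m in morphs) {
    extra <- setdiff(names(m$rule), names(schema$modifiers))
    if (length(extra)) {
      stop("morph ", m$name, " constrains undeclared modifier(s): ",
           paste(extra, collapse = ", "))
    }
    for (mod in names(m$rule)) {
      lv <- m$rule[[mod]]
      ok <- lv %in% c(schema$modifiers[[mod]],
                      .RES[["not_valid"]], .RES[["other"]])
      if (!all(ok)) {
        stop("morph ", m$name, ", modifier '", mod,
             "': level(s) not in schema: ",
             paste(lv[!ok], collapse = ", "))
      }
    }
  }
  structure(list(morphs = morphs, schema = schema), class = "morph_ruleset")
}

#' @export
print.morph_ruleset <- function(x, ...) {
  acts <- vapply(x$morphs, `[[`, character(1), "action")
  cat("Morph ruleset:", length(x$morphs), "morphs across",
      length(unique(acts)), "gesture actions\n")
  invisible(x)
}

#' Number of morphs in a ruleset
#' @param x A `morph_ruleset`.
#' @export
n_morphs <- function(x) length(x$morphs)

#' Combine per-action rulesets
#' @param ... `morph_ruleset` objects sharing one schema.
#' @return A single `morph_ruleset`.
#' @export
combine_rulesets <- function(...) {
  rs <- list(...)
  if (length(rs) == 1 && is.list(rs[[1]]) &&
      !inherits(rs[[1]], "morph_ruleset")) {
    rs <- rs[[1]]
  }
  stopifnot(length(rs) >= 1)
  morph_ruleset(do.call(c, lapply(rs, `[[`, "morphs")), rs[[1]]$schema)
}

.UNEXPLAINED_CELL <- "All other cases"

#' Parse a morph table (published-repertoire layout) into a ruleset
#'
#' The file is a delimited table with columns `morph_name`, `count`, then
#' one column per modifier; further columns (notes, accuracies) are
#' ignored. Cell conventions: a named level constrains the modifier to
#' that level; `"a|b"` to membership of the set; an empty cell leaves the
#' modifier unconstrained; `NV` denotes the not-valid code; `Other` the
#' consolidated rare-level code; a cell reading `"All other cases"` marks
#' the morph as unexplained.
#'
#' @param path Path to the delimited file (delimiter sniffed).
#' @param schema A [modifier_schema()].
#' @return A [morph_ruleset()].
#' @export
parse_rule_table <- function(path, schema) {
  stopifnot(inherits(schema, "modifier_schema"))
  delim <- .sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!all(c("morph_name", "count") %in% names(raw))) {
    stop("morph table lacks required column(s): morph_name, count")
  }
  mods <- intersect(names(schema$modifiers), names(raw))
  if (anyDuplicated(raw$morph_name)) {
    stop("duplicate morph name(s): ",
         paste(unique(raw$morph_name[duplicated(raw$morph_name)]),
               collapse = ", "))
  }
  morphs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    name <- raw$morph_name[i]
    action <- sub("\\.[0-9]+$", "", name)
    cells <- vapply(mods, function(m) raw[[m]][i], character(1))
    explained <- !any(cells == .UNEXPLAINED_CELL)
    rule <- list()
    if (explained) {
      for (m in mods) {
        cell <- trimws(cells[[m]])
        if (!nzchar(cell)) next
        lv <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
        lv <- .decode_rule_levels(lv, schema, m)
        rule[[m]] <- lv
      }
    }
    morphs[[i]] <- list(name = name, action = action,
                        support = as.numeric(raw$count[i]),
                        explained = explained, rule = rule,
                        combinations = NULL)
  }
  morph_ruleset(morphs, schema)
}

# normalise rule-cell levels: NV spellings -> NOT_VALID, other -> OTHER,
# case-tolerant match against schema levels
.decode_rule_levels <- function(lv, schema, modifier) {
  sp <- schema$spellings
  out <- character(length(lv))
  legal <- schema$modifiers[[modifier]]
  for (j in seq_along(lv)) {
    v <- lv[j]
    if (v %in% c(sp$not_valid, .RES[["not_valid"]])) {
      out[j] <- .RES[["not_valid"]]
    } else if (tolower(v) %in% c(tolower(sp$other), "other") ||
               v == .RES[["other"]]) {
      out[j] <- .RES[["other"]]
    } else {
      hit <- legal[tolower(legal) == tolower(v)]
      out[j] <- if (length(hit)) hit[1] else v  # ruleset ctor validates
    }
  }
  out
}

#' Write a morph ruleset in the published-repertoire layout
#'
#' One row per morph: `morph_name`, `count`, then one cell per modifier
#' (`"|"`-joined level sets, blank when unconstrained, `NV` for the
#' not-valid code, `Other` for the consolidated-rare code, and
#' `"All other cases"` in the first modifier cell of unexplained morphs).
#' Round-trips through [parse_rule_table()].
#'
#' @param ruleset A `morph_ruleset`.
#' @param path Output path.
#' @param counts Optional named vector of per-morph token counts; defaults
#'   to the supports stored in the ruleset. Every morph must have a count.
#' @return `path`, invisibly.
#' @export
write_morph_table <- function(ruleset, path, counts = NULL) {
  stopifnot(inherits(ruleset, "morph_ruleset"))
  sch <- ruleset$schema
  mods <- names(sch$modifiers)
  nms <- vapply(ruleset$morphs, `[[`, character(1), "name")
  if (is.null(counts)) {
    counts <- vapply(ruleset$morphs, function(m) {
      if (is.null(m$support)) NA_real_ else as.numeric(m$support)
    }, numeric(1))
    names(counts) <- nms
  }
  if (any(!nms %in% names(counts)) || anyNA(counts[nms])) {
    stop("every morph must have a count")
  }
  rows <- lapply(ruleset$morphs, function(m) {
    cells <- stats::setNames(rep("", length(mods)), mods)
    if (!m$explained) {
      cells[[1]] <- .UNEXPLAINED_CELL
    } else {
      for (mod in names(m$rule)) {
        lv <- m$rule[[mod]]
        lv[lv == .RES[["not_valid"]]] <- "NV"
        lv[lv == .RES[["other"]]] <- "Other"
        cells[[mod]] <- paste(lv, collapse = "|")
      }
    }
    c(morph_name = m$name, count = as.character(counts[[m$name]]), cells)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 2 + length(mods)),
      c("morph_name", "count", mods)
    ))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Path to the bundled transcription of the published chimpanzee morph table
#'
#' A hand-transcribed copy of the published 115-morph table (42 gesture
#' actions) used as a test fixture. The printed typography runs cells
#' together, so a `note` column flags rows whose count or body-part column
#' is an editorial reading; analyses should not lean on flagged cells.
#'
#' @return File path within the installed package.
#' @export
chimp_morph_table <- function() {
  system.file("extdata", "chimp_morph_table.csv", package = "gesturemorphs",
              mustWork = TRUE)
}
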