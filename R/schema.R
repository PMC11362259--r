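#' Reserved modifier codes
#'
#' Modifier cells that do not hold a substantive level carry one of four
#' reserved codes: `UNKNOWN` (coded but not identifiable from video),
#' `NOT_VALID` (the level of another modifier makes this one inapplicable,
#' e.g. laterality of a head gesture), `MISSING` (removed from analysis),
#' and `OTHER` (consolidated rare levels). `NOT_VALID` and `OTHER` are
#' modelled as ordinary levels downstream; `UNKNOWN` and `MISSING` never are.
#'
#' @return Named character vector of the four reserved codes.
#' @export
reserved_codes <- function() {
  c(unknown = "UNKNOWN", not_valid = "NOT_VALID",
    missing = "MISSING", other = "OTHER")
}

.RES <- c(unknown = "UNKNOWN", not_valid = "NOT_VALID",
          missing = "MISSING", other = "OTHER")

#' Declare a modifier schema
#'
#' A schema names the categorical modifiers of a gesture corpus, their legal
#' level sets, the closed goal/community label sets, the raw-file spellings
#' of the reserved codes, and optional lumping maps: level lumps (e.g.
#' left/right -> Unimanual) and action lumps for gesture actions that were
#' pre-split in the original coding on a modifier of interest (e.g.
#' "hitting other" -> "hit other" with repetition = Yes).
#'
#' @param modifiers Named list; each element a character vector of legal
#'   levels for that modifier. Order is kept and used throughout.
#' @param goals Character vector of legal goal labels, or `NULL` for an open
#'   set. The `UNKNOWN` code is always legal for goals.
#' @param communities Character vector of legal community labels, or `NULL`.
#' @param play_goal Goal label treated as play (drives the `is_play` flag).
#' @param spellings Named list mapping each reserved-code slot (`unknown`,
#'   `not_valid`, `missing`, `other`) to the raw spellings that denote it in
#'   input files. Empty cells always read as missing.
#' @param lump_levels Named list: modifier -> named character vector mapping
#'   raw levels to analysis levels.
#' @param lump_actions Named list: raw action name -> list(action = lumped
#'   name, modifiers = named list of induced modifier levels).
#' @return An object of class `modifier_schema`.
#' @examples
#' sch <- modifier_schema(list(repetition = c("Yes", "No")))
#' @export
modifier_schema <- function(modifiers,
                            goals = NULL,
                            communities = NULL,
                            play_goal = "Play",
                            spellings = NULL,
                            lump_levels = list(),
                            lump_actions = list()) {
  if (!is.list(modifiers) || is.null(names(modifiers)) ||
      any(!nzchar(names(modifiers)))) {
    stop("`modifiers` must be a named list of level vectors")
  }
  modifiers <- lapply(modifiers, as.character)
  bad <- vapply(modifiers, function(l) any(l %in% .RES), logical(1))
  if (any(bad)) {
    stop("modifier level sets must be disjoint from the reserved codes: ",
         paste(names(modifiers)[bad], collapse = ", "))
  }
  sp <- list(unknown = "unknown", not_valid = c("not_valid", "NV"),
             missing = "", other = "other")
  if (!is.null(spellings)) sp[names(spellings)] <- spellings
  for (m in names(lump_levels)) {
    if (!m %in% names(modifiers)) {
      stop("lump_levels refers to undeclared modifier: ", m)
    }
    map <- lump_levels[[m]]
    if (is.null(names(map)) || any(!nzchar(names(map)))) {
      stop("lump_levels[['", m, "']] must be a named raw -> analysis map")
    }
    if (any(!map %in% modifiers[[m]])) {
      stop("lump_levels[['", m, "']] maps onto levels absent from schema")
    }
  }
  for (a in names(lump_actions)) {
    la <- lump_actions[[a]]
    if (!is.list(la) || is.null(la$action)) {
      stop("lump_actions[['", a, "']] must be list(action=, modifiers=)")
    }
    ind <- la$modifiers
    if (length(ind) && any(!names(ind) %in% names(modifiers))) {
      stop("lump_actions[['", a, "']] induces undeclared modifiers")
    }
  }
  structure(
    list(modifiers = modifiers, goals = goals, communities = communities,
         play_goal = play_goal, spellings = sp,
         lump_levels = lump_levels, lump_actions = lump_actions),
    class = "modifier_schema"
  )
}

#' Default chimpanzee gesture schema
#'
#' The four modifiers routinely coded across chimpanzee gesture corpora:
#' the signaller's body part (11 levels), the body part contacted on the
#' recipient or the signaller's own body (9 levels), rhythmic repetition
#' (2 levels), and laterality (3 levels after lumping left/right-handed
#' unimanual gestures as "Unimanual").
#'
#' @return A `modifier_schema`.
#' @export
chimp_schema <- function() {
  modifier_schema(
    modifiers = list(
      body_part_signaller = c("Arm", "Hand", "Fingers", "Foot", "Leg",
                              "Head", "Body", "Back", "Face", "Bottom",
                              "Genitals"),
      body_part_contact = c("Arm", "Back", "Body", "Face", "Genitals",
                            "Hand", "Head", "Leg", "None"),
      repetition = c("Yes", "No"),
      laterality = c("Unimanual", "Both", "Alternating")
    ),
    play_goal = "Play",
    lump_levels = list(
      laterality = c(Left = "Unimanual", Right = "Unimanual",
                     Unimanual = "Unimanual", Both = "Both",
                     Alternating = "Alternating")
    )
  )
}

#' @export
print.modifier_schema <- function(x, ...) {
  cat("Modifier schema:", length(x$modifiers), "modifiers\n")
  for (m in names(x$modifiers)) {
    cat("  ", m, ": ", paste(x$modifiers[[m]], collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$goals)) cat("  goals:", length(x$goals), "labels\n")
  if (!is.null(x$communities)) {
    cat("  communities:", length(x$communities), "labels\n")
  }
  invisible(x)
}

# map raw cell spellings to reserved codes; leaves substantive levels alone
.decode_reserved <- function(x, spellings) {
  x <- as.character(x)
  x[is.na(x)] <- .RES[["missing"]]
  for (slot in names(.RES)) {
    sp <- spellings[[slot]]
    if (length(sp)) x[x %in% sp] <- .RES[[slot]]
  }
  x
}
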