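#' Declare a synthetic gesture corpus with planted morph structure
#'
#' Each action plants a number of morphs, every morph defined by one
#' combination of modifier levels. A generated token draws its morph from
#' the mixing weights, then expresses the morph's defining level on each
#' modifier with probability `theta_def` (level fidelity) and a uniformly
#' chosen other level of that modifier otherwise -- exactly the
#' class-conditional independence the latent class model assumes. Goal
#' and community are drawn from per-morph distributions, so planted
#' morphs can carry goal/community information (or not).
#'
#' @param actions Named list. Per action: `n` (token count), `modifiers`
#'   (named list modifier -> character level set used by this action),
#'   `morphs` (list; per morph: `combination` -- named list giving the
#'   defining level of every action modifier --, `weight`, `goals` and
#'   `communities` -- named probability vectors), `theta_def` in (0.5, 1].
#' @param missing_rate Probability a modifier cell is recorded as
#'   unknown (default 0).
#' @param unknown_goal_rate Probability the goal is unrecorded (default
#'   0).
#' @param schema The [modifier_schema()] the corpus uses (default
#'   [chimp_schema()]).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(actions, missing_rate = 0,
                           unknown_goal_rate = 0,
                           schema = chimp_schema(), seed = 1L) {
  stopifnot(is.list(actions), !is.null(names(actions)))
  for (a in names(actions)) {
    act <- actions[[a]]
    if (is.null(act$theta_def)) actions[[a]]$theta_def <- act$theta_def <- 1
    if (act$theta_def <= 0.5 || act$theta_def > 1) {
      stop("action '", a, "': theta_def must lie in (0.5, 1]")
    }
    w <- vapply(act$morphs, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-8) {
      stop("action '", a, "': morph weights must sum to 1")
    }
    for (m in act$morphs) {
      if (!setequal(names(m$combination), names(act$modifiers))) {
        stop("action '", a, "': every morph combination must cover ",
             "exactly the action's modifiers")
      }
      for (dist in list(m$goals, m$communities)) {
        if (abs(sum(dist) - 1) > 1e-8) {
          stop("action '", a,
               "': goal/community distributions must sum to 1")
        }
      }
    }
  }
  structure(list(actions = actions, missing_rate = missing_rate,
                 unknown_goal_rate = unknown_goal_rate, schema = schema,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  n <- sum(vapply(x$actions, `[[`, numeric(1), "n"))
  cat("Synthetic spec:", length(x$actions), "actions,", n,
      "tokens, seed", x$seed, "\n")
  invisible(x)
}

#' Generate a token table from a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [token_table()]) and `truth` (class
#'   `planted_truth`: data frame `token_id`, `action`, `morph` -- the
#'   planted morph index --, plus attributes `true_k` and the spec).
#' @export
generate_tokens <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sch <- spec$schema
  all_mods <- names(sch$modifiers)
  rows <- list()
  truth_rows <- list()
  communities_seen <- character(0)
  tid <- 0L
  for (a in names(spec$actions)) {
    act <- spec$actions[[a]]
    w <- vapply(act$morphs, `[[`, numeric(1), "weight")
    morph_idx <- sample.int(length(w), act$n, replace = TRUE, prob = w)
    for (i in seq_len(act$n)) {
      tid <- tid + 1L
      m <- act$morphs[[morph_idx[i]]]
      cells <- stats::setNames(rep(.RES[["not_valid"]], length(all_mods)),
                               all_mods)
      for (mod in names(act$modifiers)) {
        levs <- act$modifiers[[mod]]
        def <- m$combination[[mod]]
        if (length(levs) == 1 || stats::runif(1) <= act$theta_def) {
          cells[[mod]] <- def
        } else {
          others <- setdiff(levs, def)
          cells[[mod]] <- others[sample.int(length(others), 1)]
        }
        if (spec$missing_rate > 0 &&
            stats::runif(1) < spec$missing_rate) {
          cells[[mod]] <- .RES[["unknown"]]
        }
      }
      goal <- names(m$goals)[sample.int(length(m$goals), 1,
                                        prob = m$goals)]
      if (spec$unknown_goal_rate > 0 &&
          stats::runif(1) < spec$unknown_goal_rate) {
        goal <- .RES[["unknown"]]
      }
      comm <- names(m$communities)[sample.int(length(m$communities), 1,
                                              prob = m$communities)]
      rows[[tid]] <- c(token_id = sprintf("syn%06d", tid),
                       community = comm,
                       signaller_id = sprintf("chimp%02d",
                                              sample.int(40, 1)),
                       action = a, cells, goal = goal)
      truth_rows[[tid]] <- data.frame(
        token_id = sprintf("syn%06d", tid), action = a,
        morph = morph_idx[i], stringsAsFactors = FALSE)
    }
  }
  tok <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  tt <- token_table(tok, sch, provenance = "generated", validate = FALSE)
  truth <- do.call(rbind, truth_rows)
  attr(truth, "true_k") <- vapply(spec$actions, function(a) {
    length(a$morphs)
  }, numeric(1))
  attr(truth, "spec") <- spec
  class(truth) <- c("planted_truth", class(truth))
  list(table = tt, truth = truth)
}

#' One-action planted spec for recovery experiments
#'
#' A convenience builder: one gesture action over all four modifiers,
#' `k` planted morphs on well-separated defining combinations. For
#' `k <= 4` the combinations form a code of pairwise Hamming distance at
#' least three, so a token that slips on a single modifier still sits
#' strictly closer to its own morph's combination than to any other --
#' slips decode uniquely and never pool into coherent off-morph pockets.
#' Mixing weights are uniform; each morph carries one dominant goal over
#' a four-goal set and a home community over three.
#'
#' @param k Number of planted morphs (1..9).
#' @param n Token count.
#' @param theta_def Level fidelity (default 0.95).
#' @param seed Seed stored in the spec.
#' @param goal_point_mass Give each morph a single fixed goal instead of
#'   a mixture (default `FALSE`).
#' @return A [synthetic_spec()] with one action named `"synthact"`.
#' @export
planted_action_spec <- function(k, n, theta_def = 0.95, seed = 1L,
                                goal_point_mass = FALSE) {
  stopifnot(k >= 1, k <= 9)
  bp <- c("Hand", "Foot", "Head", "Arm")
  ct <- c("Back", "Leg", "Face", "None")
  lat <- c("Unimanual", "Both", "Alternating")
  rep_ <- c("Yes", "No")
  cmb <- function(b, c_, l, r) {
    list(body_part_signaller = b, body_part_contact = c_,
         laterality = l, repetition = r)
  }
  combos <- list(
    cmb("Hand", "Back", "Unimanual", "Yes"),
    cmb("Foot", "Leg", "Both", "No"),
    cmb("Head", "Face", "Alternating", "Yes"),
    cmb("Arm", "None", "Unimanual", "No"),
    cmb("Foot", "Face", "Unimanual", "Yes"),
    cmb("Head", "Back", "Both", "No"),
    cmb("Arm", "Leg", "Alternating", "Yes"),
    cmb("Hand", "None", "Both", "No"),
    cmb("Foot", "Back", "Alternating", "No"))
  goals <- c("Play", "Travel", "Groom", "Feed")
  comms <- c("Sonso", "Waibira", "Issa")
  # the action's level sets are the levels the planted morphs actually
  # use, so a level slip lands on another legal level of the repertoire;
  # modifiers the planted morphs never vary carry no signal and are left
  # out of the action
  used <- lapply(c(body_part_signaller = "body_part_signaller",
                   body_part_contact = "body_part_contact",
                   laterality = "laterality", repetition = "repetition"),
                 function(m) {
    unique(vapply(combos[seq_len(k)], function(cb) cb[[m]], character(1)))
  })
  modifiers <- used[lengths(used) >= 2]
  if (length(modifiers) == 0) {
    modifiers <- list(repetition = rep_)  # k = 1: one inert modifier
  }
  w <- rep(1 / k, k)
  morphs <- lapply(seq_len(k), function(i) {
    g <- stats::setNames(rep(0.1 / 3, 4), goals)
    g[[goals[(i - 1) %% 4 + 1]]] <- 0.9
    if (goal_point_mass) {
      g <- stats::setNames(rep(0, 4), goals)
      g[[goals[(i - 1) %% 4 + 1]]] <- 1
    }
    cm <- stats::setNames(rep(0.15, 3), comms)
    cm[[comms[(i - 1) %% 3 + 1]]] <- 0.7
    combination <- combos[[i]][names(modifiers)]
    if (length(combination) == 0) {
      combination <- list(repetition = combos[[i]][["repetition"]])
    }
    list(combination = combination,
         weight = w[i], goals = g, communities = cm)
  })
  synthetic_spec(
    actions = list(synthact = list(
      n = n, modifiers = modifiers,
      morphs = morphs, theta_def = theta_def)),
    seed = seed)
}

#' Corpus-shaped synthetic spec
#'
#' Emulates the shape of a large multi-community chimpanzee gesture
#' corpus: 61 gesture actions of which 19 are too rare to analyse
#' (fewer than 10 tokens), heavy-tailed token counts over the remaining
#' 42 (clipped to 10-871, median near 68, total near 7879 at scale 1),
#' one to seven planted morphs per action, 25 goal categories with a
#' dominant play-like goal near 31% of tokens, and five communities with
#' skewed representation. At smaller scales every planted morph keeps an
#' expected support of at least five tokens or is dropped (its weight
#' folded into the first morph).
#'
#' @param scale Fraction of the full corpus size, in (0, 1].
#' @param seed Integer seed (drives both spec construction and, by
#'   default, generation).
#' @param theta_def Level fidelity planted for every action (default
#'   0.95).
#' @return A [synthetic_spec()].
#' @export
corpus_like_spec <- function(scale = 1, seed = 1L, theta_def = 0.95) {
  stopifnot(scale > 0, scale <= 1)
  set.seed(seed)
  sch <- chimp_schema()
  goals <- c("Play", sprintf("Goal%02d", 1:24))
  goal_pool <- c(0.31, 0.69 * (0.85 ^ (1:24)) / sum(0.85 ^ (1:24)))
  names(goal_pool) <- goals
  comms <- c("Sonso", "Waibira", "Issa", "Kanyawara", "Kalinzu")
  comm_pool <- c(0.62, 0.19, 0.08, 0.06, 0.05)
  names(comm_pool) <- comms

  n_major <- 42
  raw <- exp(stats::rnorm(n_major, log(60), 1.05))
  raw <- pmin(pmax(raw, 10), 871)
  small <- sample(1:9, 19, replace = TRUE)
  target_major <- 7879 - sum(small)
  counts <- round(raw * target_major / sum(raw))
  counts <- pmin(pmax(counts, 10), 871)
  counts <- c(counts, small)
  counts <- pmax(1L, as.integer(round(counts * scale)))
  names(counts) <- sprintf("action%02d", seq_along(counts))

  actions <- list()
  for (i in seq_along(counts)) {
    a <- names(counts)[i]
    n_a <- counts[[i]]
    n_mods <- sample(1:4, 1, prob = c(0.3, 0.4, 0.2, 0.1))
    mods_a <- sample(names(sch$modifiers), n_mods)
    level_sets <- lapply(mods_a, function(m) {
      lv <- sch$modifiers[[m]]
      sample(lv, min(length(lv), sample(2:3, 1)))
    })
    names(level_sets) <- mods_a
    grid <- expand.grid(level_sets, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    k_wanted <- sample(1:7, 1, prob = c(2, 3, 2, 1.5, 1, 0.5, 0.5))
    k <- min(k_wanted, nrow(grid), max(1L, floor(n_a / 12)))
    # plant identifiable morphs: defining combinations pairwise two or
    # more modifiers apart, so no pair is representable by one class
    cand <- sample.int(nrow(grid))
    pick <- cand[1]
    for (j in cand[-1]) {
      if (length(pick) >= k) break
      dmin <- min(vapply(pick, function(p) {
        sum(grid[j, ] != grid[p, ])
      }, numeric(1)))
      if (dmin >= 2) pick <- c(pick, j)
    }
    k <- length(pick)
    w <- stats::rexp(k) + 0.3
    w <- w / sum(w)
    # planted morphs must keep expected support >= 5 (or be dropped)
    repeat {
      ok <- n_a * w >= 5 | seq_len(k) == 1
      if (all(ok) || k == 1) break
      drop <- which(!ok)[1]
      w[1] <- w[1] + w[drop]
      w <- w[-drop]
      pick <- pick[-drop]
      k <- k - 1
    }
    if (k > 1 && n_a * w[1] < 5) {   # fold everything into one morph
      k <- 1
      w <- 1
      pick <- pick[1]
    }
    morphs <- lapply(seq_len(k), function(j) {
      g <- 0.4 * goal_pool
      primary <- sample(goals, 1, prob = goal_pool)
      g[primary] <- g[primary] + 0.6
      cm <- 0.7 * comm_pool
      home <- sample(comms, 1, prob = comm_pool)
      cm[home] <- cm[home] + 0.3
      list(combination = as.list(grid[pick[j], , drop = FALSE]),
           weight = w[j], goals = g, communities = cm)
    })
    actions[[a]] <- list(n = n_a, modifiers = level_sets,
                         morphs = morphs, theta_def = theta_def)
  }
  synthetic_spec(actions, missing_rate = 0.01, unknown_goal_rate = 0.2,
                 schema = sch, seed = seed)
}
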