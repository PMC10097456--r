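# Model-checking semantics.  State sets are logical vectors indexed by
# state id + 1; least fixpoints are computed by Knaster-Tarski iteration
# from the empty set, which on a finite LTS converges in at most
# n_states + 1 rounds.

.rf_eval <- function(f, lts, env, defs) {
  n <- lts$n_states
  switch(f$kind,
    tt = rep(TRUE, n),
    ff = rep(FALSE, n),
    var = {
      v <- env[[f$name]]
      if (is.null(v)) .rf_stop("bad_input", "unbound variable '%s'", f$name)
      v
    },
    ref = {
      v <- defs[[f$name]]
      if (is.null(v)) .rf_stop("bad_input", "undefined property '%s'", f$name)
      v
    },
    dia = {
      body <- .rf_eval(f$body, lts, env, defs)
      res <- rep(FALSE, n)
      sel <- (lts$action %in% f$actions) & body[lts$to + 1L]
      res[lts$from[sel] + 1L] <- TRUE
      res
    },
    codia = {
      body <- .rf_eval(f$body, lts, env, defs)
      res <- rep(FALSE, n)
      sel <- !(lts$action %in% f$excluded) & body[lts$to + 1L]
      res[lts$from[sel] + 1L] <- TRUE
      res
    },
    boxall = {
      # deadlocked states satisfy [-]phi vacuously
      body <- .rf_eval(f$body, lts, env, defs)
      res <- rep(TRUE, n)
      res[lts$from[!body[lts$to + 1L]] + 1L] <- FALSE
      res
    },
    or = .rf_eval(f$left, lts, env, defs) | .rf_eval(f$right, lts, env, defs),
    min = {
      x <- rep(FALSE, n)
      repeat {
        env[[f$var]] <- x
        nx <- .rf_eval(f$body, lts, env, defs)
        if (identical(nx, x)) break
        x <- nx
      }
      x
    },
    .rf_stop("bad_input", "unknown formula kind '%s'", f$kind))
}

# Iterates of a least fixpoint (used by monotonicity diagnostics/tests).
.rf_lfp_iterates <- function(f, lts, env = list(), defs = list()) {
  stopifnot(f$kind == "min")
  n <- lts$n_states
  x <- rep(FALSE, n)
  iters <- list(x)
  repeat {
    env[[f$var]] <- x
    nx <- .rf_eval(f$body, lts, env, defs)
    iters[[length(iters) + 1L]] <- nx
    if (identical(nx, x)) break
    x <- nx
  }
  iters
}

# Satisfying sets of every named property, in dependency order.
.rf_compute_defs <- function(lts, props) {
  defs <- list()
  for (nm in props$order)
    defs[[nm]] <- .rf_eval(props$defs[[nm]], lts, list(), defs)
  defs
}

#' States of an LTS satisfying a formula
#'
#' Standard modal mu-calculus semantics: `tt` holds everywhere, `<A>phi` at
#' states with a successor via an action in `A` satisfying `phi`, `<-E>phi`
#' at states with a successor via any action outside `E`, `[-]phi` where
#' all successors satisfy `phi` (deadlocks vacuously), and `min X = phi` is
#' the least fixpoint.
#'
#' @param lts A [chain_lts()] / [to_lts()] transition system.
#' @param formula A formula object, or the name of a property in `props`.
#' @param props Optional `radformal_props` set supplying named references.
#' @return Sorted integer vector of satisfying state ids (0-based).
#' @export
satisfying_states <- function(lts, formula, props = NULL) {
  stopifnot(inherits(lts, "radformal_lts"))
  defs <- if (is.null(props)) list() else .rf_compute_defs(lts, props)
  if (is.character(formula)) {
    if (is.null(defs[[formula]]))
      .rf_stop("bad_input", "unknown property '%s'", formula)
    return(which(defs[[formula]]) - 1L)
  }
  stopifnot(inherits(formula, "radformal_formula"))
  which(.rf_eval(formula, lts, list(), defs)) - 1L
}

# Witness reconstruction on acyclic chains: walk the satisfied diamond
# obligations forward, expanding macros and fixpoint variables.  A depth
# guard covers pathological unguarded fixpoints.
.rf_witness <- function(lts, props, defs, entry) {
  env_sets <- new.env(parent = emptyenv())
  eval_at <- function(f, binds) .rf_eval(f, lts, binds, defs)
  limit <- (lts$n_states + 2L) * 50L
  steps <- 0L
  walk <- function(f, s, binds, fixf) {
    steps <<- steps + 1L
    if (steps > limit) return(NULL)
    switch(f$kind,
      tt = character(0),
      boxall = character(0),
      ref = walk(props$defs[[f$name]], s, list(), fixf),
      var = walk(fixf[[f$name]], s, binds, fixf),
      min = {
        binds[[f$var]] <- eval_at(f, binds)
        fixf[[f$var]] <- f
        walk(f$body, s, binds, fixf)
      },
      or = {
        lsat <- eval_at(f$left, binds)
        if (lsat[s + 1L]) walk(f$left, s, binds, fixf)
        else walk(f$right, s, binds, fixf)
      },
      dia = ,
      codia = {
        ok <- if (f$kind == "dia") lts$action %in% f$actions
              else !(lts$action %in% f$excluded)
        body_sat <- eval_at(f$body, binds)
        cand <- which(lts$from == s & ok & body_sat[lts$to + 1L])
        if (length(cand) == 0L) return(NULL)
        i <- cand[1L]
        rest <- walk(f$body, lts$to[i], binds, fixf)
        if (is.null(rest)) return(NULL)
        c(lts$action[i], rest)
      },
      NULL)
  }
  walk(props$defs[[entry]], 0L, list(), list())
}

#' Model-check a patient and report verdict, witness and failure note
#'
#' Evaluates the entry property of `props` at the initial state. When the
#' verdict is true, a witness action path consistent with the satisfied
#' diamond obligations is reconstructed; when false, the failure note names
#' the sub-property whose obligations advanced furthest along the chain and
#' the slice where progress stopped.
#'
#' @param lts A `radformal_lts`.
#' @param props A `radformal_props` set.
#' @param entry Entry property name (default: the set's entry point).
#' @return Object of class `radformal_check`: `verdict` (logical), `entry`,
#'   `states` (satisfying state sets per named property), `witness`
#'   (character vector of actions or `NULL`), `failure` (string or `NULL`).
#' @export
check_patient <- function(lts, props, entry = props$entry) {
  stopifnot(inherits(lts, "radformal_lts"), inherits(props, "radformal_props"))
  if (!entry %in% names(props$defs))
    .rf_stop("bad_input", "entry property '%s' is not defined", entry)
  defs <- .rf_compute_defs(lts, props)
  verdict <- defs[[entry]][1L]
  states <- lapply(defs, function(v) which(v) - 1L)
  witness <- NULL
  failure <- NULL
  if (verdict) {
    witness <- .rf_witness(lts, props, defs, entry)
  } else {
    failure <- .rf_failure_note(lts, props, defs, entry)
  }
  structure(list(verdict = verdict, entry = entry, states = states,
                 witness = witness, failure = failure,
                 slice_of_state = lts$slice_of_state),
            class = "radformal_check")
}

# Depth of each named property below the entry in the macro-reference
# graph; used to pick the "furthest progress" sub-property for the note.
.rf_ref_depths <- function(props, entry) {
  depth <- stats::setNames(rep(NA_integer_, length(props$defs)),
                           names(props$defs))
  depth[[entry]] <- 0L
  queue <- entry
  while (length(queue)) {
    nm <- queue[1L]; queue <- queue[-1L]
    for (r in unique(.rf_formula_refs(props$defs[[nm]]))) {
      if (is.na(depth[[r]]) || depth[[r]] < depth[[nm]] + 1L) {
        depth[[r]] <- depth[[nm]] + 1L
        queue <- c(queue, r)
      }
    }
  }
  depth
}

.rf_failure_note <- function(lts, props, defs, entry) {
  depth <- .rf_ref_depths(props, entry)
  cand <- names(defs)[vapply(defs, any, logical(1)) & !is.na(depth)]
  if (length(cand) == 0L)
    return(sprintf("%s fails: no sub-property is satisfied at any state",
                   entry))
  d <- depth[cand]
  cand <- cand[d == max(d)]
  furthest <- vapply(cand, function(nm) max(which(defs[[nm]])) - 1L, numeric(1))
  best <- cand[which.max(furthest)]
  stop_state <- furthest[which.max(furthest)]
  sprintf(paste0("%s fails: obligations advanced furthest in sub-property ",
                 "%s, last satisfied at slice %d"),
          entry, best, lts$slice_of_state[stop_state + 1L])
}

#' Slice-level localization of satisfied properties
#'
#' Maps each named property's satisfying states back to image slices: a
#' slice is reported when it owns at least one satisfying state.
#'
#' @param lts A `radformal_lts`.
#' @param props A `radformal_props` set.
#' @param names Property names to localize (default: all).
#' @return Named list of sorted integer slice-index vectors.
#' @export
localize <- function(lts, props, names = base::names(props$defs)) {
  stopifnot(inherits(lts, "radformal_lts"), inherits(props, "radformal_props"))
  unknown <- setdiff(names, base::names(props$defs))
  if (length(unknown))
    .rf_stop("bad_input", "unknown property name(s): %s",
             paste(unknown, collapse = ", "))
  defs <- .rf_compute_defs(lts, props)
  out <- lapply(names, function(nm)
    sort(unique(lts$slice_of_state[which(defs[[nm]])])))
  stats::setNames(out, names)
}

#' @export
print.radformal_check <- function(x, ...) {
  cat(sprintf("<radformal_check: %s is %s>\n", x$entry,
              if (x$verdict) "TRUE" else "FALSE"))
  if (!is.null(x$witness))
    cat("  witness:", paste(x$witness, collapse = " . "), "\n")
  if (!is.null(x$failure))
    cat(" ", x$failure, "\n")
  invisible(x)
}
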