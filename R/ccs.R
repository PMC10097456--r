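# CCS chain processes.  Each exam becomes a single sequential process built
# with the action-prefix ("." combination) operator and nil termination;
# choice, parallel composition and restriction are deliberately outside the
# supported fragment.

.rf_action_regex <- "^b[1-3]of3(sphericity|kurtosis|skewness|elongation|meshsurface)$"

.rf_check_actions <- function(actions, where = "process") {
  bad <- actions[!grepl(.rf_action_regex, actions)]
  if (length(bad))
    .rf_stop("parse_error", "invalid action label(s) in %s: %s", where,
             paste(unique(bad), collapse = ", "))
  invisible(actions)
}

#' Build a CCS chain process from an action sequence
#'
#' @param seq A `radformal_actionseq` (see [to_action_sequence()]).
#' @return An object of class `radformal_ccs`: `name`, `actions`,
#'   `slice_ids` (slice attribution of each action).
#' @export
build_process <- function(seq) {
  stopifnot(inherits(seq, "radformal_actionseq"))
  if (length(seq$actions) == 0L)
    .rf_stop("bad_input", "cannot build a process from an empty sequence")
  name <- gsub("[^A-Za-z0-9_]", "_", as.character(seq$patient_id))
  if (!grepl("^[A-Za-z]", name)) name <- paste0("P", name)
  structure(list(name = name, actions = seq$actions,
                 slice_ids = seq$slice_ids),
            class = "radformal_ccs")
}

#' Serialize CCS processes
#'
#' Concrete syntax: one `proc NAME = a1.a2.....nil` definition per line,
#' `#` starts a comment. [parse_ccs()] inverts [write_ccs()] exactly on the
#' supported fragment.
#'
#' @param procs A `radformal_ccs` or list of them.
#' @return Character scalar of `.ccs` text.
#' @export
write_ccs <- function(procs) {
  if (inherits(procs, "radformal_ccs")) procs <- list(procs)
  lines <- vapply(procs, function(p) {
    sprintf("proc %s = %s.nil", p$name, paste(p$actions, collapse = "."))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname write_ccs
#' @param text `.ccs` text.
#' @return `parse_ccs()`: named list of `radformal_ccs` processes.
#' @export
parse_ccs <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  out <- list()
  pending <- ""      # definitions may wrap across lines until ".nil"
  pending_line <- 0L
  for (ln in seq_along(lines)) {
    stripped <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(stripped))) next
    if (pending == "") pending_line <- ln
    pending <- paste(pending, stripped)
    if (!grepl("\\bnil\\b", pending)) next
    p <- .rf_parse_proc(pending, pending_line)
    if (p$name %in% names(out))
      .rf_stop("parse_error", "line %d: duplicate process name '%s'",
               pending_line, p$name)
    out[[p$name]] <- p
    pending <- ""
  }
  if (nzchar(trimws(pending)))
    .rf_stop("parse_error", "line %d: unterminated process (missing 'nil')",
             pending_line)
  if (length(out) == 0L)
    .rf_stop("parse_error", "no process definitions found")
  out
}

.rf_parse_proc <- function(txt, line) {
  m <- regmatches(txt, regexec(
    "^\\s*proc\\s+([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*$", txt))[[1]]
  if (length(m) == 0L)
    .rf_stop("parse_error", "line %d: expected 'proc NAME = ...'", line)
  name <- m[2]
  body <- m[3]
  parts <- trimws(strsplit(body, ".", fixed = TRUE)[[1]])
  if (length(parts) == 0L || parts[length(parts)] != "nil")
    .rf_stop("parse_error", "line %d: process body must end in 'nil'", line)
  actions <- parts[-length(parts)]
  if (any(!nzchar(actions)))
    .rf_stop("parse_error", "line %d: empty action in prefix chain", line)
  if (any(actions == "nil"))
    .rf_stop("parse_error", "line %d: 'nil' may only terminate the chain",
             line)
  tryCatch(.rf_check_actions(actions, sprintf("line %d", line)),
           radformal_parse_error = function(e)
             .rf_stop("parse_error", "line %d: column %d: %s", line,
                      regexpr(sub(".*: ", "", conditionMessage(e)), txt)[1],
                      conditionMessage(e)))
  structure(list(name = name, actions = actions,
                 slice_ids = (seq_along(actions) - 1L) %/% 5L + 1L),
            class = "radformal_ccs")
}

#' Build a chain labelled transition system
#'
#' States are 0..k for k actions; state i steps to i+1 via the (i+1)-th
#' action and the final state is deadlocked. Each state is attributed to
#' the slice of the action it is about to consume; the final state belongs
#' to the last slice.
#'
#' @param actions Character vector of transition labels.
#' @param slice_ids Optional per-action slice indices (default: consecutive
#'   groups of five actions form one slice).
#' @return An object of class `radformal_lts` with fields `n_states`,
#'   `from`, `action`, `to` and `slice_of_state`.
#' @export
chain_lts <- function(actions, slice_ids = NULL) {
  k <- length(actions)
  if (is.null(slice_ids)) slice_ids <- (seq_len(k) - 1L) %/% 5L + 1L
  if (k > 0L && length(slice_ids) != k)
    .rf_stop("bad_input", "need one slice id per action")
  slice_of_state <- if (k == 0L) 1L else c(slice_ids, slice_ids[k])
  structure(list(n_states = k + 1L,
                 from = if (k) 0:(k - 1L) else integer(0),
                 action = as.character(actions),
                 to = if (k) 1:k else integer(0),
                 slice_of_state = as.integer(slice_of_state)),
            class = "radformal_lts")
}

#' Unfold a CCS chain process into its labelled transition system
#'
#' @param p A `radformal_ccs` process.
#' @return A `radformal_lts` (see [chain_lts()]).
#' @export
to_lts <- function(p) {
  stopifnot(inherits(p, "radformal_ccs"))
  chain_lts(p$actions, p$slice_ids)
}

#' @export
print.radformal_lts <- function(x, ...) {
  cat(sprintf("<radformal_lts: %d states, %d transitions, %d slice(s)>\n",
              x$n_states, length(x$from), length(unique(x$slice_of_state))))
  invisible(x)
}

#' @export
print.radformal_ccs <- function(x, ...) {
  cat(write_ccs(x))
  invisible(x)
}
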