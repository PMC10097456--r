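# Modal mu-calculus dialect used for the disease properties.
#
# Supported connectives: tt, ff, disjunction, existential step over a
# listed action set <a, b>, existential step over the complement of a set
# <- a, b> (with <-> the "some action" case), the universal step [-] over
# all actions (so [-]ff characterizes deadlock), and least fixpoints
# min X = phi.  Named properties (F0, F1, ...) are acyclic macros, distinct
# from fixpoint variables.  Conjunction, negation and greatest fixpoints are
# not part of the dialect and are rejected with clear errors.

.rf_mc <- function(kind, ...) structure(list(kind = kind, ...),
                                        class = "radformal_formula")
.rf_tt <- function() .rf_mc("tt")
.rf_ff <- function() .rf_mc("ff")
.rf_var <- function(name) .rf_mc("var", name = toupper(name))
.rf_ref <- function(name) .rf_mc("ref", name = name)
.rf_dia <- function(actions, body) .rf_mc("dia", actions = actions, body = body)
.rf_codia <- function(excluded, body) .rf_mc("codia", excluded = excluded,
                                             body = body)
.rf_boxall <- function(body) .rf_mc("boxall", body = body)
.rf_or <- function(left, right) .rf_mc("or", left = left, right = right)
.rf_min <- function(var, body) .rf_mc("min", var = toupper(var), body = body)

# --- tokenizer ---------------------------------------------------------

.rf_mc_tokenize <- function(text) {
  text <- paste(text, collapse = "\n")
  # accept the typeset variants: U+2228 OR, U+2212 minus, U+2013 dash
  text <- gsub("∨", "\\\\/", text)
  text <- gsub("[−–]", "-", text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- "\\\\/|[A-Za-z][A-Za-z0-9_]*|[<>\\[\\]()=,-]|\\S"
  toks <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    for (m in regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]) {
      toks[[length(toks) + 1L]] <- list(tok = m, line = ln)
    }
    # recompute columns
  }
  if (length(toks)) {
    cols <- integer(length(toks))
    i <- 1L
    for (ln in seq_along(lines)) {
      line <- sub("#.*$", "", lines[ln])
      mm <- gregexpr(pat, line, perl = TRUE)[[1]]
      if (mm[1] != -1L) for (p in as.vector(mm)) { cols[i] <- p; i <- i + 1L }
    }
    for (j in seq_along(toks)) toks[[j]]$col <- cols[j]
  }
  toks
}

.rf_mc_state <- function(toks) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks; e$i <- 1L; e$bound <- character(0)
  e
}

.rf_mc_peek <- function(st) {
  if (st$i > length(st$toks)) return(NULL)
  st$toks[[st$i]]
}

.rf_mc_next <- function(st) {
  t <- .rf_mc_peek(st)
  if (is.null(t)) .rf_stop("parse_error", "unexpected end of property text")
  st$i <- st$i + 1L
  t
}

.rf_mc_expect <- function(st, tok) {
  t <- .rf_mc_next(st)
  if (t$tok != tok)
    .rf_stop("parse_error", "line %d, column %d: expected '%s', found '%s'",
             t$line, t$col, tok, t$tok)
  t
}

.rf_is_name <- function(tok) grepl("^[A-Za-z][A-Za-z0-9_]*$", tok)

# --- grammar -----------------------------------------------------------

.rf_parse_disj <- function(st) {
  left <- .rf_parse_prefix(st)
  repeat {
    t <- .rf_mc_peek(st)
    if (is.null(t) || t$tok != "\\/") return(left)
    .rf_mc_next(st)
    left <- .rf_or(left, .rf_parse_prefix(st))
  }
}

.rf_parse_actlist <- function(st) {
  out <- character(0)
  repeat {
    t <- .rf_mc_next(st)
    if (!.rf_is_name(t$tok))
      .rf_stop("parse_error", "line %d, column %d: expected an action name",
               t$line, t$col)
    out <- c(out, t$tok)
    t <- .rf_mc_peek(st)
    if (is.null(t) || t$tok != ",") return(out)
    .rf_mc_next(st)
  }
}

.rf_parse_prefix <- function(st) {
  t <- .rf_mc_peek(st)
  if (is.null(t)) .rf_stop("parse_error", "unexpected end of property text")
  if (t$tok == "<") {
    .rf_mc_next(st)
    t2 <- .rf_mc_peek(st)
    if (!is.null(t2) && t2$tok == "-") {
      .rf_mc_next(st)
      t3 <- .rf_mc_peek(st)
      excl <- if (!is.null(t3) && t3$tok == ">") character(0)
              else .rf_parse_actlist(st)
      .rf_mc_expect(st, ">")
      return(.rf_codia(excl, .rf_parse_prefix(st)))
    }
    acts <- .rf_parse_actlist(st)
    .rf_mc_expect(st, ">")
    return(.rf_dia(acts, .rf_parse_prefix(st)))
  }
  if (t$tok == "[") {
    .rf_mc_next(st)
    .rf_mc_expect(st, "-")
    .rf_mc_expect(st, "]")
    return(.rf_boxall(.rf_parse_prefix(st)))
  }
  .rf_parse_atom(st)
}

.rf_parse_atom <- function(st) {
  t <- .rf_mc_next(st)
  if (t$tok == "(") {
    f <- .rf_parse_disj(st)
    .rf_mc_expect(st, ")")
    return(f)
  }
  if (tolower(t$tok) == "min") {
    v <- .rf_mc_next(st)
    if (!.rf_is_name(v$tok))
      .rf_stop("parse_error", "line %d, column %d: expected a variable after 'min'",
               v$line, v$col)
    .rf_mc_expect(st, "=")
    st$bound <- c(st$bound, toupper(v$tok))
    body <- .rf_parse_disj(st)
    st$bound <- st$bound[-length(st$bound)]
    return(.rf_min(v$tok, body))
  }
  if (tolower(t$tok) == "max")
    .rf_stop("parse_error",
             "line %d: greatest fixpoints ('max') are not supported", t$line)
  if (t$tok == "tt") return(.rf_tt())
  if (t$tok == "ff") return(.rf_ff())
  if (.rf_is_name(t$tok)) {
    if (toupper(t$tok) %in% st$bound) return(.rf_var(t$tok))
    return(.rf_ref(t$tok))
  }
  .rf_stop("parse_error", "line %d, column %d: unexpected token '%s'",
           t$line, t$col, t$tok)
}

.rf_formula_refs <- function(f) {
  switch(f$kind,
         ref = f$name,
         or = c(.rf_formula_refs(f$left), .rf_formula_refs(f$right)),
         dia = , codia = , boxall = , min = .rf_formula_refs(f$body),
         character(0))
}

# --- property sets -----------------------------------------------------

#' Parse a property file into a set of named mu-calculus formulas
#'
#' The concrete syntax is one `prop NAME = formula` definition per
#' (logical) line, `#` comments, with both the ASCII (`\/`, `<->`) and the
#' typeset (`∨`, `< − >`) operator spellings accepted. Named
#' properties are macros: references between them must be defined and
#' acyclic, and every fixpoint variable must be bound by an enclosing
#' `min`.
#'
#' @param text Property text (character, possibly multi-line).
#' @param entry Entry-point name; defaults to `"F0"` when defined, else the
#'   first definition.
#' @return An object of class `radformal_props`: list with `defs` (named
#'   formulas), `entry` and `order` (dependency order, leaves first).
#' @export
parse_properties <- function(text, entry = NULL) {
  st <- .rf_mc_state(.rf_mc_tokenize(text))
  defs <- list()
  repeat {
    t <- .rf_mc_peek(st)
    if (is.null(t)) break
    if (tolower(t$tok) != "prop")
      .rf_stop("parse_error", "line %d, column %d: expected 'prop', found '%s'",
               t$line, t$col, t$tok)
    .rf_mc_next(st)
    nm <- .rf_mc_next(st)
    if (!.rf_is_name(nm$tok))
      .rf_stop("parse_error", "line %d: expected a property name", nm$line)
    if (nm$tok %in% names(defs))
      .rf_stop("parse_error", "line %d: property '%s' defined twice",
               nm$line, nm$tok)
    .rf_mc_expect(st, "=")
    defs[[nm$tok]] <- .rf_parse_disj(st)
  }
  if (length(defs) == 0L)
    .rf_stop("parse_error", "no property definitions found")
  # resolve and order references; reject cycles and unknown names
  order <- character(0)
  state <- stats::setNames(rep(0L, length(defs)), names(defs))  # 0 new, 1 open, 2 done
  visit <- function(name, via) {
    if (!name %in% names(defs))
      .rf_stop("parse_error",
               "undefined name '%s' referenced from '%s' (an unbound variable or missing property)",
               name, via)
    if (state[[name]] == 1L)
      .rf_stop("parse_error", "cyclic property reference through '%s'", name)
    if (state[[name]] == 2L) return(invisible())
    state[[name]] <<- 1L
    for (r in unique(.rf_formula_refs(defs[[name]]))) visit(r, name)
    state[[name]] <<- 2L
    order <<- c(order, name)
  }
  for (nm in names(defs)) visit(nm, nm)
  if (is.null(entry)) entry <- if ("F0" %in% names(defs)) "F0" else names(defs)[1]
  if (!entry %in% names(defs))
    .rf_stop("bad_input", "entry property '%s' is not defined", entry)
  structure(list(defs = defs, entry = entry, order = order),
            class = "radformal_props")
}

.rf_format_formula <- function(f, top = FALSE) {
  wrap_or <- function(g) {
    s <- .rf_format_formula(g)
    if (g$kind == "or") paste0("(", s, ")") else s
  }
  switch(f$kind,
         tt = "tt",
         ff = "ff",
         var = f$name,
         ref = f$name,
         or = paste(.rf_format_formula(f$left), "\\/",
                    .rf_format_formula(f$right)),
         dia = paste0("<", paste(f$actions, collapse = ", "), "> ",
                      wrap_or(f$body)),
         codia = if (length(f$excluded) == 0L)
                   paste0("<-> ", wrap_or(f$body))
                 else
                   paste0("<- ", paste(f$excluded, collapse = ", "), "> ",
                          wrap_or(f$body)),
         boxall = paste0("[-] ", wrap_or(f$body)),
         min = paste0("(min ", f$var, " = ", .rf_format_formula(f$body), ")"))
}

#' Serialize a property set back to its concrete syntax
#'
#' `parse_properties(write_properties(p))` is structurally the identity.
#'
#' @param props A `radformal_props` set.
#' @return Character scalar of property text (ASCII operator spellings).
#' @export
write_properties <- function(props) {
  stopifnot(inherits(props, "radformal_props"))
  lines <- vapply(names(props$defs), function(nm)
    paste0("prop ", nm, " = ", .rf_format_formula(props$defs[[nm]], TRUE)),
    character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.radformal_formula <- function(x, ...) {
  cat(.rf_format_formula(x), "\n")
  invisible(x)
}

#' @export
print.radformal_props <- function(x, ...) {
  cat(write_properties(x))
  cat(sprintf("# entry: %s\n", x$entry))
  invisible(x)
}

#' The bundled soft-tissue sarcoma recurrence/metastasis property set
#'
#' Returns the disease property used for classification: entry point
#' `F0 = F1 \/ F10`, where the F1--F4 chain demands four occurrences of a
#' high-sphericity action immediately followed by a low-kurtosis action
#' (the last two with recursion restricted to steps over other actions),
#' and the F10--F14 chain describes repeated high-sphericity /
#' low-or-medium-kurtosis / high-meshsurface-or-elongation triples ending
#' in a slice whose meshsurface or elongation action at the basal level
#' leads to termination (`[-]ff`).
#'
#' @return A `radformal_props` set with 10 definitions, entry `F0`.
#' @export
sts_property_set <- function() {
  path <- system.file("extdata", "sts_recurrence.mcf", package = "radformal",
                      mustWork = TRUE)
  parse_properties(readChar(path, file.size(path), useBytes = TRUE))
}
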