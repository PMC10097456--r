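# Independent oracles used across the suite.
#
# ora_eval: brute-force mu-calculus semantics over explicit integer state
# sets with per-state loops and least fixpoints enumerated by repeated full
# re-evaluation (named references are re-expanded from the AST on every
# use, never memoized).  Deliberately shares no code with the package's
# vectorized fixpoint evaluator beyond the AST data structure.

ora_eval <- function(f, lts, env = list(), defs_ast = list()) {
  states <- 0:(lts$n_states - 1L)
  succ_ok <- function(s, body, keep) {
    for (i in seq_along(lts$from)) {
      if (lts$from[i] == s && keep(lts$action[i]) && (lts$to[i] %in% body))
        return(TRUE)
    }
    FALSE
  }
  switch(f$kind,
    tt = states,
    ff = integer(0),
    var = {
      v <- env[[f$name]]
      if (is.null(v)) stop("oracle: unbound var ", f$name)
      v
    },
    ref = ora_eval(defs_ast[[f$name]], lts, list(), defs_ast),
    dia = {
      body <- ora_eval(f$body, lts, env, defs_ast)
      Filter(function(s) succ_ok(s, body, function(a) a %in% f$actions),
             states)
    },
    codia = {
      body <- ora_eval(f$body, lts, env, defs_ast)
      Filter(function(s) succ_ok(s, body, function(a) !(a %in% f$excluded)),
             states)
    },
    boxall = {
      body <- ora_eval(f$body, lts, env, defs_ast)
      Filter(function(s) {
        for (i in seq_along(lts$from))
          if (lts$from[i] == s && !(lts$to[i] %in% body)) return(FALSE)
        TRUE
      }, states)
    },
    or = sort(union(ora_eval(f$left, lts, env, defs_ast),
                    ora_eval(f$right, lts, env, defs_ast))),
    min = {
      x <- integer(0)
      repeat {
        env[[f$var]] <- x
        nx <- sort(as.integer(ora_eval(f$body, lts, env, defs_ast)))
        if (identical(nx, x)) break
        x <- nx
      }
      x
    },
    stop("oracle: unknown kind ", f$kind))
}

# Random closed formulas over a small action alphabet.  `depth` bounds the
# nesting of modalities/fixpoints.
gen_formula <- function(depth, actions, bound = character(0)) {
  leaf <- function() {
    opts <- c("tt", "ff")
    if (length(bound)) opts <- c(opts, "var", "var")
    k <- sample(opts, 1L)
    switch(k,
           tt = radformal:::.rf_tt(),
           ff = radformal:::.rf_ff(),
           var = radformal:::.rf_var(sample(bound, 1L)))
  }
  if (depth == 0L) return(leaf())
  kind <- sample(c("dia", "codia", "boxall", "or", "min", "leaf"),
                 1L, prob = c(0.25, 0.2, 0.1, 0.2, 0.15, 0.1))
  switch(kind,
    leaf = leaf(),
    dia = radformal:::.rf_dia(sample(actions, sample(1:2, 1L)),
                              gen_formula(depth - 1L, actions, bound)),
    codia = radformal:::.rf_codia(
      if (stats::runif(1) < 0.3) character(0)
      else sample(actions, sample(1:2, 1L)),
      gen_formula(depth - 1L, actions, bound)),
    boxall = radformal:::.rf_boxall(gen_formula(depth - 1L, actions, bound)),
    or = radformal:::.rf_or(gen_formula(depth - 1L, actions, bound),
                            gen_formula(depth - 1L, actions, bound)),
    min = {
      v <- paste0("X", length(bound) + 1L)
      radformal:::.rf_min(v, gen_formula(depth - 1L, actions, c(bound, v)))
    })
}

gen_chain <- function(max_states, actions = c("a", "b", "c", "d")) {
  k <- sample(0:(max_states - 1L), 1L)
  chain_lts(sample(actions, k, replace = TRUE))
}

# Hand-derived suffix-scan oracle for the bundled disease property on a
# chain of actions: each sub-property is computed by backward recursion
# over suffix states (no fixpoint iteration).  State t's next action is
# actions[t + 1].
oracle_sts_f0 <- function(actions) {
  k <- length(actions)
  a <- c(actions, rep("", 3L))  # sentinel padding
  s3 <- "b3of3sphericity"; k1 <- "b1of3kurtosis"; k2 <- "b2of3kurtosis"
  m3 <- "b3of3meshsurface"; m2 <- "b2of3meshsurface"
  e3 <- "b3of3elongation"; e2 <- "b2of3elongation"
  pair <- function(t) a[t + 1L] == s3 && a[t + 2L] == k1
  triple <- function(t, third) a[t + 1L] == s3 && a[t + 2L] %in% c(k1, k2) &&
    a[t + 3L] %in% third
  F4 <- F3 <- F2 <- F1 <- logical(k + 1L)
  F14 <- F13 <- F12 <- F11 <- F10 <- logical(k + 1L)
  at <- function(v, t) if (t <= k) v[t + 1L] else FALSE
  for (t in k:0) {
    free_step <- t < k
    F4[t + 1L] <- pair(t) ||
      (free_step && !(a[t + 1L] %in% c(s3, k1)) && at(F4, t + 1L))
    F3[t + 1L] <- (pair(t) && at(F4, t + 2L)) ||
      (free_step && !(a[t + 1L] %in% c(s3, k1)) && at(F3, t + 1L))
    F2[t + 1L] <- (pair(t) && at(F3, t + 2L)) || (free_step && at(F2, t + 1L))
    F1[t + 1L] <- (pair(t) && at(F2, t + 2L)) || (free_step && at(F1, t + 1L))
    F14[t + 1L] <- (a[t + 1L] %in% c(m2, e2) && t + 1L == k) ||
      (free_step && at(F14, t + 1L))
    F13[t + 1L] <- (triple(t, c(e3, m3)) && at(F14, t + 3L)) ||
      (free_step && at(F13, t + 1L))
    F12[t + 1L] <- (triple(t, c(m3, e3)) && at(F13, t + 3L)) ||
      (free_step && at(F12, t + 1L))
    F11[t + 1L] <- (triple(t, c(m3, m2)) && at(F12, t + 3L)) ||
      (free_step && at(F11, t + 1L))
    F10[t + 1L] <- (triple(t, c(m3, e3)) && at(F11, t + 3L)) ||
      (free_step && at(F10, t + 1L))
  }
  list(verdict = F1[1L] || F10[1L], F1 = F1, F10 = F10)
}

# Rasterized disk mask (pixel-centre test), radius in pixels.
disk_mask <- function(radius_px, spacing = c(0.6, 0.6), margin = 3L) {
  n <- 2L * (radius_px + margin) + 1L
  cc <- radius_px + margin + 1L
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  mk <- matrix(as.integer((idx$r - cc)^2 + (idx$c - cc)^2 <= radius_px^2),
               n, n)
  slice_mask(mk, spacing)
}

# Small feature table with known values, two patients.
toy_feature_table <- function() {
  data.frame(
    patient_id = rep(c("p1", "p2"), each = 3L),
    slice_index = rep(1:3, 2L),
    kurtosis = c(0, 4.5, 9, 1, 5, 8),
    skewness = c(-1, 0, 1, -0.5, 0.2, 0.9),
    elongation = c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8),
    sphericity = c(0.3, 0.6, 0.9, 0.4, 0.5, 0.85),
    mesh_surface = c(10, 55, 100, 20, 60, 90),
    stringsAsFactors = FALSE)
}

# Uniform random well-formed level matrix -> action chain.
random_levels <- function(n_slices) {
  matrix(sample(1:3, 5L * n_slices, replace = TRUE), nrow = 5L)
}
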