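# Property parsing and model-checking semantics.

test_that("the bundled disease property parses into its ten definitions", {
  props <- sts_property_set()
  expect_s3_class(props, "radformal_props")
  expect_length(props$defs, 10L)
  expect_setequal(names(props$defs),
                  c("F0", paste0("F", c(1:4, 10:14))))
  expect_equal(props$entry, "F0")
  # F3's restricted recursion excludes exactly the two pattern actions
  f3 <- props$defs$F3
  expect_equal(f3$kind, "min")
  right <- f3$body$right
  expect_equal(right$kind, "codia")
  expect_setequal(right$excluded, c("b3of3sphericity", "b1of3kurtosis"))
  # F14 terminates in a deadlock obligation after a basal mesh/elongation step
  f14 <- props$defs$F14
  dia <- f14$body$left
  expect_setequal(dia$actions, c("b2of3meshsurface", "b2of3elongation"))
  expect_equal(dia$body$kind, "boxall")
  expect_equal(dia$body$body$kind, "ff")
})

test_that("the grammar accepts both ASCII and typeset operator spellings", {
  a <- parse_properties("prop P = (min X = <a> tt \\/ <->X)")
  b <- parse_properties("prop P = (min x = <a> tt ∨ < − > X)")
  expect_equal(a$defs, b$defs)
  f <- a$defs$P
  expect_equal(f$kind, "min")
  expect_equal(f$body$left$kind, "dia")
  expect_equal(f$body$right$kind, "codia")
  expect_length(f$body$right$excluded, 0L)
  expect_equal(f$body$right$body$kind, "var")

  c_ <- parse_properties("prop P = (min X = <a, b> tt \\/ <- a , b > X)")
  expect_setequal(c_$defs$P$body$right$excluded, c("a", "b"))
})

test_that("cyclic or undefined references and unsupported operators are rejected", {
  expect_error(parse_properties("prop A = B\nprop B = A"),
               class = "radformal_parse_error")
  expect_error(parse_properties("prop A = <a> Q"),
               class = "radformal_parse_error")
  # a variable used outside its binder is an unresolved name
  expect_error(parse_properties("prop A = <a> X"),
               class = "radformal_parse_error")
  expect_error(parse_properties("prop A = (max X = <a> tt \\/ <->X)"),
               class = "radformal_parse_error")
  expect_error(parse_properties("prop A = <> tt"),
               class = "radformal_parse_error")
})

test_that("property sets round-trip through their concrete syntax", {
  props <- sts_property_set()
  expect_equal(parse_properties(write_properties(props))$defs, props$defs)
})

test_that("box over all actions characterizes deadlock", {
  lts <- chain_lts(c("a", "b"))
  dead <- satisfying_states(lts, parse_properties("prop D = [-] ff",
                                                  entry = "D")$defs$D)
  expect_equal(dead, 2L)  # only the final state
})

test_that("a two-step eventually pattern resolves by hand-checkable fixpoint", {
  lts <- chain_lts(c("x", "a", "b", "y"))
  p <- parse_properties("prop P = (min X = <a><b> tt \\/ <-> X)")
  states <- satisfying_states(lts, "P", p)
  # <a><b>tt holds at state 1 only; the recursion closes states 0..1
  expect_equal(states, c(0L, 1L))
  expect_true(0L %in% satisfying_states(chain_lts(c("a", "b")), "P", p))
  expect_length(satisfying_states(chain_lts(c("b", "a")), "P", p), 0L)
})

test_that("the checker agrees with the brute-force oracle on random instances", {
  set.seed(31)
  acts <- c("a", "b", "c", "d")
  for (i in 1:200) {
    lts <- gen_chain(8L, acts)
    f <- gen_formula(sample(0:4, 1L), acts)
    mine <- satisfying_states(lts, f)
    ora <- sort(as.integer(ora_eval(f, lts)))
    expect_identical(mine, ora)
  }
})

test_that("fixpoint iteration is monotone and converges within the state count", {
  set.seed(32)
  acts <- c("a", "b", "c")
  for (i in 1:50) {
    lts <- gen_chain(10L, acts)
    v <- paste0("X", 1L)
    f <- radformal:::.rf_min(v, radformal:::.rf_or(
      gen_formula(2L, acts), radformal:::.rf_codia(character(0),
                                                   radformal:::.rf_var(v))))
    iters <- radformal:::.rf_lfp_iterates(f, lts)
    for (j in seq_len(length(iters) - 1L))
      expect_true(all(iters[[j + 1L]] | !iters[[j]]))  # iterate j subset j+1
    # strict growth steps are bounded by the number of states
    expect_lte(length(iters), lts$n_states + 2L)
  }
})

test_that("on chains, unrestricted recursion means 'some suffix state satisfies the body'", {
  set.seed(33)
  acts <- c("a", "b", "c")
  for (i in 1:50) {
    lts <- gen_chain(12L, acts)
    phi <- radformal:::.rf_dia(sample(acts, sample(1:2, 1)), radformal:::.rf_tt())
    ef <- radformal:::.rf_min("X", radformal:::.rf_or(
      phi, radformal:::.rf_codia(character(0), radformal:::.rf_var("X"))))
    mine <- satisfying_states(lts, ef)
    # direct suffix scan oracle
    phi_states <- satisfying_states(lts, phi)
    suffix <- Filter(function(s) any(phi_states >= s), 0:(lts$n_states - 1L))
    expect_identical(mine, as.integer(suffix))
  }
})

test_that("verdicts carry witnesses when true and progress notes when false", {
  props <- sts_property_set()
  # four consecutive pattern slices -> true through the F1 branch
  lev <- random_levels(6L)
  lev[1, 2:5] <- 3L; lev[2, 2:5] <- 1L
  lev[1, c(1, 6)] <- 1L; lev[2, c(1, 6)] <- 2L  # no stray pattern actions
  seqc <- action_sequence_from_levels("w", lev)
  chk <- check_patient(chain_lts(seqc$actions, seqc$slice_ids), props)
  expect_true(chk$verdict)
  expect_true(0L %in% chk$states$F1)
  # the witness is a genuine path: a prefix of the chain's actions
  expect_false(is.null(chk$witness))
  expect_identical(chk$witness, seqc$actions[seq_along(chk$witness)])

  # no high-sphericity action anywhere and last meshsurface not basal -> false
  lev2 <- random_levels(4L)
  lev2[1, ] <- 1L            # sphericity never level 3
  lev2[4, 4] <- 1L           # last elongation low
  lev2[5, 4] <- 3L           # last meshsurface high
  seq2 <- action_sequence_from_levels("f", lev2)
  chk2 <- check_patient(chain_lts(seq2$actions, seq2$slice_ids), props)
  expect_false(chk2$verdict)
  expect_null(chk2$witness)
  expect_match(chk2$failure, "fails")

  # nil-only model: entry false, deadlock property true
  nil <- chain_lts(character(0))
  expect_false(check_patient(nil, props)$verdict)
  expect_equal(satisfying_states(nil, radformal:::.rf_boxall(radformal:::.rf_ff())),
               0L)
})

test_that("localization maps satisfying states to their slices", {
  props <- sts_property_set()
  lev <- matrix(2L, 5, 3)
  lev[1, 3] <- 3L; lev[2, 3] <- 1L  # the F4 pattern sits in slice 3 only
  seqc <- action_sequence_from_levels("l", lev)
  lts <- chain_lts(seqc$actions, seqc$slice_ids)
  loc <- localize(lts, props, c("F0", "F4", "F14"))
  # F4 is reachable under its restricted recursion from every earlier slice
  expect_true(3L %in% loc$F4)
  expect_length(localize(lts, props, "F10")$F10, 0L)
  expect_error(localize(lts, props, "nope"), class = "radformal_bad_input")

  # a property satisfied only at one state localizes to that state's slice
  p <- parse_properties("prop P = <b1of3kurtosis> tt")
  states <- satisfying_states(lts, "P", p)
  expect_equal(states, 11L)  # state before slice 3's kurtosis action
  expect_equal(localize(lts, p, "P")$P, 3L)
})

test_that("padding with actions a property never names cannot break it", {
  set.seed(34)
  props <- sts_property_set()
  irrelevant <- c("b1of3sphericity", "b2of3sphericity", "b3of3kurtosis",
                  "b1of3skewness", "b2of3skewness", "b3of3skewness",
                  "b1of3elongation", "b1of3meshsurface")
  for (i in 1:20) {
    lev <- radformal:::.rf_implant_pattern(random_levels(sample(4:8, 1)))
    actions <- action_sequence_from_levels("p", lev)$actions
    stopifnot(check_patient(chain_lts(actions), props)$verdict)
    # insert irrelevant actions between obligations (at slice boundaries,
    # never splitting a two-step diamond obligation)
    boundaries <- seq(0L, length(actions), by = 5L)
    picks <- sort(sample(boundaries, sample(1:4, 1)), decreasing = TRUE)
    for (pos in picks)  # descending so earlier insertions don't shift later ones
      actions <- append(actions, sample(irrelevant, 1L), after = pos)
    expect_true(check_patient(chain_lts(actions), props)$verdict)
  }
})

test_that("the F10 chain is unsatisfiable on well-formed five-feature sequences", {
  set.seed(35)
  props <- sts_property_set()
  for (i in 1:30) {
    seqc <- action_sequence_from_levels("p", random_levels(sample(1:8, 1)))
    lts <- chain_lts(seqc$actions, seqc$slice_ids)
    expect_length(satisfying_states(lts, "F10", props), 0L)
    # cross-checked against the independent suffix-scan oracle
    expect_false(any(oracle_sts_f0(seqc$actions)$F10))
  }
})
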