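# Grammar core: builtins, consistency, structural checks, derivation counts.

test_that("builtin grammars load with the documented shape", {
  g <- gsto()
  expect_equal(length(g$rules), 54)
  expect_equal(length(g$nonterminals), 26)
  expect_identical(g$axiom, "S'")
  expect_identical(as.character(weight_of(g, premise = "E", conclusion = "S")),
                   "137/6476")
  gs <- load_builtin("Gs")
  expect_equal(length(gs$rules), 7)
  expect_setequal(gs$nonterminals, c("S", "A", "B", "C"))
  expect_equal(length(star_rat()$rules), 105)
  expect_equal(length(star_int()$rules), 105)
  expect_error(load_builtin("nope"), "unknown builtin")
})

test_that("loads are referentially transparent", {
  a <- load_builtin("Gsto_hat")
  b <- load_builtin("Gsto_hat")
  for (i in seq_along(a$rules)) {
    expect_identical(a$rules[[i]]$id, b$rules[[i]]$id)
    expect_identical(a$rules[[i]]$conclusion, b$rules[[i]]$conclusion)
    expect_true(rnaunrank:::rq_eq(a$rules[[i]]$weight, b$rules[[i]]$weight))
  }
})

test_that("consistency check sums weights exactly", {
  expect_true(check_consistency(gsto())$pass)
  bad <- wcfg(c("S", "A"), "S",
              list(rnaunrank:::r_("S", "( A )", rq(1, 2)),
                   rnaunrank:::r_("S", "| S |", rq(1, 3)),
                   rnaunrank:::r_("A", "| | |", rq(1))))
  rep <- check_consistency(bad)
  expect_false(rep$pass)
  expect_identical(rep$sum[rep$premise == "S"], "5/6")
  # RNF weights are not probabilities: premise V sums to 1.3243
  repv <- check_consistency(star_rat())
  expect_false(repv$pass)
  expect_identical(repv$sum[repv$premise == "V"], "13243/10000")
})

test_that("epsilon- and loop-freeness are detected", {
  chk <- check_epsilon_loop_free(gsto())
  expect_true(chk$epsilon_free)
  expect_true(chk$loop_free)
  gs <- load_builtin("Gs")  # C -> epsilon
  expect_false(check_epsilon_loop_free(gs)$epsilon_free)
  loopy <- wcfg(c("S", "A", "B"), "S",
                list(rnaunrank:::r_("S", "( A )", rq(1)),
                     rnaunrank:::r_("A", "B", rq(1, 2)),
                     rnaunrank:::r_("A", "| | |", rq(1, 2)),
                     rnaunrank:::r_("B", "A", rq(1))))
  expect_false(check_epsilon_loop_free(loopy)$loop_free)
})

test_that("derivation counts match exhaustive enumeration (unambiguity)", {
  d <- count_derivations_by_length(gsto(), 14)
  expect_equal(d[4], 0)  # shortest structure has size 5
  expect_equal(d[5], 1)
  for (n in 1:14) expect_equal(d[n], length(lang(n)), info = paste("n =", n))
})

test_that("the simple and the detailed grammar count derivations identically", {
  expect_equal(count_derivations_by_length(load_builtin("Gs"), 14),
               count_derivations_by_length(gsto(), 14))
})

test_that("generating-function identity holds for the counts and only them", {
  d <- count_derivations_by_length(gsto(), 20)
  expect_true(all(verify_generating_function(d) == 0))
  d2 <- d; d2[6] <- d2[6] + 1
  expect_true(any(verify_generating_function(d2) != 0))
  res0 <- verify_generating_function(rep(0, 20))
  expect_equal(res0[5], -1)  # the bare -z^5 term survives
})

test_that("grammar JSON serialization round-trips with exact weights", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_grammar_json(star_int(), f)
  g2 <- read_grammar_json(f)
  expect_equal(length(g2$rules), 105)
  for (i in seq_along(g2$rules)) {
    expect_true(rnaunrank:::rq_eq(g2$rules[[i]]$weight,
                                  star_int()$rules[[i]]$weight))
    expect_identical(g2$rules[[i]]$conclusion, star_int()$rules[[i]]$conclusion)
  }
  expect_identical(grammar_fingerprint(g2), grammar_fingerprint(star_int()))
})
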