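# Normal-form transformation: chain gathering, substitution, census,
# word-equivalence.

test_that("chain gathering on the detailed grammar", {
  ch <- collect_chains(gsto())
  expect_equal(length(ch), 32)
  # T => C => |  collapses with weight p7 * p8 via C
  t_bar <- Filter(function(x) x$source == "T" && x$target == "|", ch)
  expect_equal(length(t_bar), 1)
  expect_identical(t_bar[[1]]$via, "C")
  p7 <- weight_of(gsto(), id = 7); p8 <- weight_of(gsto(), id = 8)
  expect_true(rnaunrank:::rq_eq(t_bar[[1]]$weight, rnaunrank:::rq_mul(p7, p8)))
  # chain weight is always the product of the traversed unit-rule weights
  y_a <- Filter(function(x) x$source == "Y" && x$target == "A", ch)[[1]]
  expect_identical(y_a$via, c("Z", "X"))
  expect_identical(y_a$symbol, "Y{A,ZX}")
})

test_that("chain gathering on the five-rule example grammar", {
  ch <- collect_chains(load_builtin("Gd"))
  expect_equal(length(ch), 3)
  keys <- vapply(ch, function(x)
    paste0(x$source, ">", x$target, "/", paste(x$via, collapse = "")), "")
  expect_setequal(keys, c("B>C/", "B>|/C", "C>|/"))
})

test_that("grammars whose only unit rules sit at the axiom have no chains", {
  g <- wcfg(c("S", "A"), "S",
            list(rnaunrank:::r_("S", "A", rq(1)),
                 rnaunrank:::r_("A", "( A )", rq(1, 2)),
                 rnaunrank:::r_("A", "| | |", rq(1, 2))))
  expect_equal(length(collect_chains(g)), 0)
})

test_that("preconditions are enforced", {
  expect_error(collect_chains(load_builtin("Gs")), "epsilon")
  loopy <- wcfg(c("S", "A", "B"), "S",
                list(rnaunrank:::r_("S", "( A )", rq(1)),
                     rnaunrank:::r_("A", "B", rq(1, 2)),
                     rnaunrank:::r_("A", "| | |", rq(1, 2)),
                     rnaunrank:::r_("B", "A", rq(1))))
  expect_error(collect_chains(loopy), "loop")
})

test_that("the transformation census on the detailed grammar", {
  rep <- to_rnf(gsto())
  expect_equal(length(rep$removed_unit_rules), 22)
  expect_equal(length(rep$chains), 32)
  expect_equal(length(rep$chain_rules), 32)
  expect_equal(length(rep$substituted_rules), 79)
  expect_setequal(rep$dead_symbols, c("T", "L", "N", "Y"))
  expect_equal(length(rep$dead_rules), 6)
  expect_equal(rep$main_rule_count, 73)
  expect_equal(length(rep$result$rules), 105)
  expect_equal(length(rep$axiom_fixes), 0)
})

test_that("the transformed grammar carries the published 4-decimal weights", {
  rep <- to_rnf(gsto())
  key <- function(r) paste(r$premise, paste(r$conclusion, collapse = " "),
                           sep = " -> ")
  mine <- stats::setNames(lapply(rep$result$rules, function(r) r$weight),
                          vapply(rep$result$rules, key, ""))
  for (r in star_rat()$rules[1:73]) {
    k <- key(r)
    expect_false(is.null(mine[[k]]), info = k)
    expect_true(rnaunrank:::rq_eq(rnaunrank:::rq_round(mine[[k]], 4), r$weight),
                info = k)
  }
  expect_setequal(vapply(rep$result$rules[74:105], key, ""),
                  vapply(star_rat()$rules[74:105], key, ""))
})

test_that("the five-rule example produces the expected 11-rule grammar", {
  rep <- to_rnf(load_builtin("Gd"))
  g2 <- rep$result
  expect_equal(length(g2$rules), 11)
  expect_equal(rep$main_rule_count, 8)
  expect_equal(length(rep$chain_rules), 3)
  expect_equal(length(rep$dead_symbols), 0)
  # S -> B{|,C} gets weight w1 * w3 * w4 = 1 * 1/2 * 1/3
  expect_identical(as.character(weight_of(g2, premise = "S",
                                          conclusion = "B{|,C}")), "1/6")
  expect_identical(as.character(weight_of(g2, premise = "C",
                                          conclusion = c("|", "C{|,}"))),
                   "2/9")  # w5 * w4 = 2/3 * 1/3
})

test_that("an RNF grammar without non-axiom unit rules is a fixpoint", {
  g <- wcfg(c("S", "A", "F"), "S",
            list(rnaunrank:::r_("S", "A", rq(1)),
                 rnaunrank:::r_("A", "( F )", rq(2, 3)),
                 rnaunrank:::r_("A", "( A )", rq(1, 3)),
                 rnaunrank:::r_("F", "| | |", rq(1))))
  rep <- to_rnf(g)
  expect_equal(length(rep$chains), 0)
  expect_equal(length(rep$dead_rules), 0)
  expect_equal(length(rep$result$rules), length(g$rules))
  for (i in seq_along(g$rules)) {
    expect_identical(rep$result$rules[[i]]$conclusion, g$rules[[i]]$conclusion)
    expect_true(rnaunrank:::rq_eq(rep$result$rules[[i]]$weight,
                                  g$rules[[i]]$weight))
  }
})

test_that("axiom rules with long conclusions are split in step 5", {
  g <- wcfg(c("S", "A"), "S",
            list(rnaunrank:::r_("S", "A A", rq(1)),
                 rnaunrank:::r_("A", "( A )", rq(1, 2)),
                 rnaunrank:::r_("A", "( | | | )", rq(1, 2))))
  rep <- to_rnf(g)
  expect_equal(length(rep$axiom_fixes), 1)
  for (r in rep$result$rules) {
    if (r$premise == "S") expect_lte(length(r$conclusion), 1)
  }
  # word-equivalence spot check
  w <- "(|||)(|||)"
  expect_true(rnaunrank:::rq_eq(word_weight(g, w), word_weight(rep$result, w)))
})

test_that("the transformation is word-equivalent on the structure language", {
  rep <- to_rnf(gsto())
  for (n in 5:8) {
    tot_a <- rq(0); tot_b <- rq(0)
    for (w in lang(n)) {
      wa <- word_weight(gsto(), w)
      wb <- word_weight(rep$result, w)
      expect_true(rnaunrank:::rq_eq(wa, wb), info = w)
      tot_a <- tot_a + wa; tot_b <- tot_b + wb
    }
    expect_true(rnaunrank:::rq_eq(tot_a, tot_b))
  }
})

test_that("chain symbols appear only where substitution placed them", {
  rep <- to_rnf(gsto())
  chain_syms <- vapply(rep$chain_rules, `[[`, "", "premise")
  placed <- unlist(lapply(rep$result$rules[1:73], `[[`, "conclusion"))
  for (r in rep$result$rules[74:105]) {
    expect_false(any(r$conclusion %in% chain_syms))  # chains map to originals
  }
  expect_true(all(setdiff(placed, c("(", ")", "|")) %in%
                    c(rep$result$nonterminals)))
})
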