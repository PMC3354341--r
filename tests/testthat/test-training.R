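# Derivation counting, relative-frequency training, stability, recovery.

test_that("rule counts of the unique derivation match hand-derived examples", {
  g <- gsto()
  cnt <- derive_rule_counts(g, "(|||)")
  used <- which(cnt > 0)
  expect_setequal(used, c(1, 2, 4, 10, 16, 25))
  expect_true(all(cnt[used] == 1))
  cnt2 <- derive_rule_counts(g, "|(|||)")
  expect_setequal(which(cnt2 > 0), c(1, 2, 5, 7, 8, 10, 16, 25))
  cnt3 <- derive_rule_counts(g, "((|||))")
  expect_equal(unname(cnt3[10]), 2)
  expect_equal(unname(cnt3[c(11, 16, 25, 1, 2, 4)]), rep(1, 6))
})

test_that("the linear decomposer agrees with the chart parser", {
  g <- gsto()
  # exhaustive over the language up to size 11
  for (n in 5:11) {
    for (w in lang(n)) {
      s <- parse_dotbracket(w)
      expect_identical(unname(derive_rule_counts(g, s, method = "decomposer")),
                       unname(derive_rule_counts(g, s, method = "parser")),
                       info = w)
    }
  }
  # seeded spot checks at sizes 12-14
  set.seed(31)
  for (n in 12:14) {
    for (w in sample(lang(n), 15)) {
      s <- parse_dotbracket(w)
      expect_identical(unname(derive_rule_counts(g, s, method = "decomposer")),
                       unname(derive_rule_counts(g, s, method = "parser")),
                       info = w)
    }
  }
})

test_that("the decomposer agrees with the sampler's derivation bookkeeping", {
  g <- gsto()
  fx <- sample_grammar(g, 150, seed = 99)
  m <- rnaunrank:::rule_count_matrix(g, lapply(fx$words, parse_dotbracket))
  expect_equal(unname(m), unname(fx$counts))
})

test_that("training computes exact relative frequencies", {
  g <- gsto()
  suppressWarnings(tr <- train(g, list("(|||)", "((|||))")))
  expect_identical(as.character(weight_of(tr, id = 11)), "1/3")
  expect_identical(as.character(weight_of(tr, id = 16)), "2/3")
  expect_true(check_consistency(tr)$pass)
  expect_warning(tr1 <- train(g, list("(|||)")), "uniform")
  expect_identical(as.character(weight_of(tr1, id = 25)), "1")
  # unseen premise G got the uniform distribution over its 4 rules
  expect_identical(as.character(weight_of(tr1, id = 18)), "1/4")
  expect_error(train(g, list()), "empty")
})

test_that("pseudocounts smooth the estimate", {
  g <- gsto()
  tr <- train(g, list("(|||)"), pseudocount = 1)
  # premise F: counts (1,0,0), 3 rules -> (1+1)/(1+3)
  expect_identical(as.character(weight_of(tr, id = 25)), "1/2")
  expect_identical(as.character(weight_of(tr, id = 26)), "1/4")
  expect_true(check_consistency(tr)$pass)
})

test_that("training any fixture database yields an exactly consistent SCFG", {
  g <- gsto()
  for (seed in 1:3) {
    fx <- sample_grammar(g, 80, seed = seed)
    suppressWarnings(tr <- train(g, lapply(fx$words, parse_dotbracket)))
    expect_true(check_consistency(tr)$pass)
  }
})

test_that("subsample stability behaves as the sampling variance predicts", {
  g <- gsto()
  fx <- sample_grammar(g, 5000, seed = 11)
  db <- lapply(fx$words, parse_dotbracket)
  v <- subsample_stability(g, db, fraction = 0.9, reps = 40, seed = 3)
  expect_true(all(v < 1e-3, na.rm = TRUE))
  # premises with a single production are exactly constant
  singles <- c("1", "10", "22", "38", "39", "40", "45", "48")
  expect_true(all(v[singles] == 0))
  expect_error(subsample_stability(g, db, 0.9, reps = 1), "reps")
  expect_error(subsample_stability(g, db[1:3], 0.1, reps = 5), "empty")
})

test_that("parameter recovery from a seeded fixture converges", {
  g <- gsto()
  fx <- sample_grammar(g, 3000, seed = 17)
  suppressWarnings(tr <- train(g, lapply(fx$words, parse_dotbracket)))
  true_p <- vapply(g$rules, function(r) as.double(r$weight), 0)
  est_p <- vapply(tr$rules, function(r) as.double(r$weight), 0)
  usage <- colSums(fx$counts)
  sel <- usage >= 50
  expect_gt(sum(sel), 40)
  expect_true(all(abs(true_p - est_p)[sel] <= 0.02))
})
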