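# Dot-bracket parsing, enumeration oracle, motif decomposition.

test_that("parsing validates and canonicalises", {
  s <- parse_dotbracket("(|||)")
  expect_equal(s$length, 5)
  expect_equal(unname(s$pairs[1, ]), c(0, 4))
  expect_identical(parse_dotbracket("..((...))", dialect = "dot")$word,
                   "||((|||))")
  expect_identical(parse_dotbracket("..((...))")$word, "||((|||))")  # auto
  expect_error(parse_dotbracket("(||)"), "hairpin")
  expect_error(parse_dotbracket("(|||"), "unmatched")
  expect_error(parse_dotbracket("|||)("), "unmatched")
  expect_error(parse_dotbracket("(xxx)"), "alphabet")
  expect_error(parse_dotbracket("|||||"), "unpaired")
  expect_error(parse_dotbracket("  "), "empty")
  expect_error(parse_dotbracket(".|.|"), "mixes")
})

test_that("error messages carry the first offending position", {
  err <- tryCatch(parse_dotbracket("(|||)(||)"), error = conditionMessage)
  expect_match(err, "position 9")
})

test_that("parse and render are inverse; dialect conversion is an involution", {
  for (w in lang(8)) {
    s <- parse_dotbracket(w)
    expect_identical(render_structure(s), w)
    dotted <- render_structure(s, "dot")
    expect_identical(parse_dotbracket(dotted, dialect = "dot")$word, w)
  }
})

test_that("language enumeration matches the membership definition", {
  expect_identical(enumerate_language(4), character(0))
  expect_identical(enumerate_language(5), "(|||)")
  expect_setequal(enumerate_language(6), c("(||||)", "|(|||)", "(|||)|"))
  expect_equal(length(lang(7)), 7)
  # duplicate-free, sorted, all valid
  w9 <- lang(9)
  expect_false(any(duplicated(w9)))
  expect_identical(w9, sort(w9, method = "radix"))
  for (w in w9) expect_silent(parse_dotbracket(w))
  expect_error(enumerate_language(17), "oracle bound")
})

test_that("motif decomposition matches hand-checked structures", {
  p <- decompose_motifs("(|||)")
  expect_equal(p$num_h, 1); expect_equal(p$num_bps, 1)
  expect_equal(p$num_unp, 3); expect_equal(p$num_hel, 1)
  expect_equal(p$num_s, 0); expect_equal(p$num_e, 1)
  expect_equal(p$unp_h, 3)
  p2 <- decompose_motifs("((|||))")
  expect_equal(p2$num_s, 1); expect_equal(p2$num_h, 1)
  expect_equal(p2$num_hel, 1); expect_equal(p2$num_bps, 2)
  # bulges left/right, interior loops, unpaired runs
  p3 <- decompose_motifs("(||(|||)|)")
  expect_equal(p3$num_i, 1)
  expect_equal(p3$interior_sizes, 3)
  p4 <- decompose_motifs("(||(|||))")
  expect_equal(p4$num_b, 1)
  expect_equal(p4$bulge_sizes, 2)
  expect_equal(p4$num_urs, 2)
})

test_that("the worked multiloop example decomposes as labelled", {
  pm <- decompose_motifs(example_multiloop_word())
  expect_equal(pm$num_m, 2)   # degree-3 and degree-2 multiloops
  expect_equal(pm$num_h, 4)
  expect_equal(pm$num_i, 4)
  expect_equal(pm$num_b, 2)
  expect_equal(pm$multi_branches, c(3, 2))
})

test_that("conservation laws hold across the whole language up to n = 14", {
  for (n in 5:14) {
    for (w in lang(n)) {
      p <- decompose_motifs(w)
      expect_equal(p$num_e, 1)
      expect_equal(p$num_unp, p$unp_e + p$unp_h + p$unp_b + p$unp_i + p$unp_m)
      expect_equal(p$num_bps, p$num_s + p$num_h + p$num_b + p$num_i + p$num_m)
      expect_equal(p$num_bps, sum(p$helix_lengths))
      expect_equal(p$num_hel, length(p$helix_lengths))
    }
  }
})
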