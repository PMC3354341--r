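# Admissible specification and exact size tables.

test_that("grammar translation collapses chains and shares duplicates", {
  spec <- star_spec()
  root <- spec$classes[["S'"]]
  expect_identical(root$kind, "union")
  # chain collapse: S' = mu1*E + mu2*S + mu3*A
  expect_identical(vapply(root$parts, `[[`, "", "part"), c("E", "S", "A"))
  expect_equal(vapply(root$parts, function(p) as.double(rnaunrank:::new_bignat(p$w)), 0),
               c(10000, 212, 3))
  # the bar-pair product class is shared by every premise that uses it
  barbar <- "(atom:|.atom:|)"
  expect_false(is.null(spec$classes[[barbar]]))
  users <- Filter(function(nm) {
    cl <- spec$classes[[nm]]
    cl$kind == "union" && barbar %in% vapply(cl$parts, `[[`, "", "part")
  }, names(spec$classes))
  expect_true(all(c("C", "D", "B", "H", "J", "K", "U") %in% users))
  # right association of multi-factor conclusions
  f1 <- "(atom:|.(atom:|.atom:|))"
  expect_false(is.null(spec$classes[[f1]]))
  expect_error(grammar_to_spec(star_rat()), "integer")
})

test_that("base cases of the size recursion", {
  tbl <- star_tables(12)
  spec <- star_spec()
  expect_equal(as.double(class_size(spec, "(atom:|.atom:|)", 2, tbl)), 1)
  expect_equal(as.double(class_size(spec, "(atom:|.atom:|)", 3, tbl)), 0)
  expect_equal(as.double(class_size(spec, "atom:|", 1, tbl)), 1)
  expect_equal(as.double(class_size(spec, n = 4, table = tbl)), 0)
  expect_error(class_size(spec, "no-such-class", 2, tbl), "unknown class")
})

test_that("with unit weights the sizes equal the language counts", {
  tbl <- uni_tables(12)
  spec <- uni_spec()
  expect_equal(vapply(5:7, function(n) as.double(class_size(spec, n = n, table = tbl)), 0),
               c(1, 3, 7))
  for (n in 1:12) {
    expect_equal(as.double(class_size(spec, n = n, table = tbl)),
                 length(lang(n)), info = paste("n =", n))
  }
})

test_that("weighted sizes equal the brute-force sum of word weights", {
  tbl <- star_tables(12)
  spec <- star_spec()
  for (n in 5:9) {
    tot <- rq(0)
    for (w in lang(n)) tot <- tot + star_word_weight(w)
    expect_true(rnaunrank:::rq_is_integer(tot))
    expect_identical(as.character(tot$num),
                     as.character(class_size(spec, n = n, table = tbl)))
  }
})

test_that("ratio law: word-weight ratios equal conditional probability ratios", {
  # mu(w)/mu(w') must equal P(w | n)/P(w' | n) under the rounded SCFG, i.e.
  # mu(w) * lambda(w') == mu(w') * lambda(w) exactly
  for (n in c(6, 7)) {
    ws <- lang(n)
    lam <- lapply(ws, function(w) word_weight(star_rat(), w))
    mu <- lapply(ws, star_word_weight)
    for (i in seq_along(ws)[-1]) {
      lhs <- rnaunrank:::rq_mul(mu[[i]], lam[[1]])
      rhs <- rnaunrank:::rq_mul(mu[[1]], lam[[i]])
      expect_true(rnaunrank:::rq_eq(lhs, rhs), info = ws[i])
    }
  }
})

test_that("convolution totals are invariant under the accumulation order", {
  spec <- star_spec()
  tbl <- star_tables(12)
  cl <- spec$classes[["(S.C)"]]
  expect_identical(cl$kind, "product")
  for (n in c(8, 10, 12)) {
    js <- 1:(n - 1)
    seqsum <- rnaunrank:::bn_dot(tbl$values[[cl$left]][js + 1],
                                 tbl$values[[cl$right]][n - js + 1])
    jb <- rnaunrank:::split_order(n, "boustrophedon")
    jb <- jb[jb >= 1 & jb <= n - 1]
    bousum <- rnaunrank:::bn_dot(tbl$values[[cl$left]][jb + 1],
                                 tbl$values[[cl$right]][n - jb + 1])
    expect_identical(as.character(rnaunrank:::new_bignat(seqsum)),
                     as.character(rnaunrank:::new_bignat(bousum)))
  }
})

test_that("tables persist and stale fingerprints are refused", {
  spec <- star_spec()
  tbl <- star_tables(12)
  f <- tempfile(fileext = ".jsonl")
  on.exit(unlink(f))
  save_size_table(tbl, f, meta = list(s = "10000", c = "10000", digits = 4))
  t2 <- load_size_table(f, spec)
  for (n in 0:12) {
    expect_identical(as.character(class_size(spec, n = n, table = t2)),
                     as.character(class_size(spec, n = n, table = tbl)))
  }
  expect_error(load_size_table(f, uni_spec()), "stale")
})

test_that("every size from the minimum upward is positive (long range)", {
  spec <- uni_spec()
  tbl <- cached("uni_tbl_400", function() build_tables(uni_spec(), 400))
  sizes <- vapply(5:400, function(n)
    rnaunrank:::bn_is_zero(class_size(spec, n = n, table = tbl)), TRUE)
  expect_false(any(sizes))
  # positive rule weights make the weighted sizes positive wherever the
  # uniform ones are; spot-check on the integer grammar
  tblw <- cached("star_tbl_60", function() build_tables(star_spec(), 60))
  for (n in c(5, 20, 40, 60)) {
    expect_false(rnaunrank:::bn_is_zero(class_size(star_spec(), n = n, table = tblw)))
  }
})
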