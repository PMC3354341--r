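# Weighted unranking: bijectivity, orders, ranking, sampling.

test_that("singletons and range errors", {
  spec <- star_spec(); tbl <- star_tables(12)
  tot5 <- class_size(spec, n = 5, table = tbl)
  for (i in list(0, as.character(rnaunrank:::bn_sub(tot5, bn(1))))) {
    expect_identical(unrank_class(spec, tbl, n = 5, i = i), "(|||)")
    expect_identical(unrank_class(spec, tbl, n = 5, i = i, order = "sequential"),
                     "(|||)")
  }
  expect_error(unrank_class(spec, tbl, n = 5, i = tot5), "out of range")
  expect_error(sample_structures(spec, tbl, n = 4, m = 1), "no structures")
  expect_identical(sample_structures(spec, tbl, n = 5, m = 3, seed = 1),
                   rep("(|||)", 3))
})

test_that("uniform full-range unranking is a bijection onto the language", {
  spec <- uni_spec(); tbl <- uni_tables(12)
  for (n in 6:8) {
    total <- as.double(class_size(spec, n = n, table = tbl))
    for (ord in c("boustrophedon", "sequential")) {
      ws <- vapply(0:(total - 1), function(i)
        unrank_class(spec, tbl, n = n, i = i, order = ord), "")
      expect_identical(sort(ws, method = "radix"), lang(n))
      expect_false(any(duplicated(ws)))
    }
  }
})

test_that("weighted full-range unranking hits each word weight-many times", {
  g <- small_weight_grammar()
  spec <- grammar_to_spec(g)
  tbl <- build_tables(spec, 7)
  for (n in 6:7) {
    total <- as.double(class_size(spec, n = n, table = tbl))
    maps <- list()
    for (ord in c("boustrophedon", "sequential")) {
      ws <- vapply(0:(total - 1), function(i)
        unrank_class(spec, tbl, n = n, i = i, order = ord), "")
      tab <- table(ws)
      expect_setequal(names(tab), lang(n))
      for (w in names(tab)) {
        ww <- word_weight(g, w)
        expect_true(rnaunrank:::rq_is_integer(ww))
        expect_equal(as.double(ww), unname(tab[[w]]), info = w)
      }
      maps[[ord]] <- ws
    }
    # identical multisets under both orders
    expect_setequal(maps[[1]], maps[[2]])
  }
  # the rank -> structure maps themselves generally differ (they coincide at
  # very small sizes where few split blocks exist; n = 8 separates them)
  spec_u <- uni_spec(); tbl_u <- uni_tables(12)
  tot8 <- as.double(class_size(spec_u, n = 8, table = tbl_u))
  a <- vapply(0:(tot8 - 1), function(i)
    unrank_class(spec_u, tbl_u, n = 8, i = i, order = "boustrophedon"), "")
  b <- vapply(0:(tot8 - 1), function(i)
    unrank_class(spec_u, tbl_u, n = 8, i = i, order = "sequential"), "")
  expect_setequal(a, b)
  expect_false(identical(a, b))
})

test_that("ranking is the inverse of unranking up to weight copies", {
  spec <- uni_spec(); tbl <- uni_tables(12)
  expect_equal(as.double(rank_structure(spec, tbl, "(|||)")), 0)
  expect_error(rank_structure(spec, tbl, "(||)"), "hairpin")
  n <- 7
  total <- as.double(class_size(spec, n = n, table = tbl))
  for (ord in c("boustrophedon", "sequential")) {
    for (i in 0:(total - 1)) {
      w <- unrank_class(spec, tbl, n = n, i = i, order = ord)
      r <- rank_structure(spec, tbl, w, order = ord)
      expect_lte(as.double(r), i)
      expect_identical(unrank_class(spec, tbl, n = n, i = r, order = ord), w)
    }
  }
  # weighted copies: rank returns the first copy
  g <- small_weight_grammar()
  specw <- grammar_to_spec(g); tblw <- build_tables(specw, 6)
  for (i in 0:(as.double(class_size(specw, n = 6, table = tblw)) - 1)) {
    w <- unrank_class(specw, tblw, n = 6, i = i)
    r <- rank_structure(specw, tblw, w)
    expect_lte(as.double(r), i)
    expect_identical(unrank_class(specw, tblw, n = 6, i = r), w)
  }
})

test_that("sampling is deterministic under a seed and seed-sensitive", {
  spec <- star_spec(); tbl <- star_tables(12)
  a <- sample_structures(spec, tbl, n = 10, m = 25, seed = 5)
  b <- sample_structures(spec, tbl, n = 10, m = 25, seed = 5)
  expect_identical(a, b)
  d <- sample_structures(spec, tbl, n = 10, m = 25, seed = 6)
  expect_false(identical(a, d))
  for (w in a) expect_silent(parse_dotbracket(w))
})

test_that("sampled frequencies follow the exact weighted distribution", {
  spec <- star_spec(); tbl <- star_tables(12)
  words <- lang(10)
  tot <- as.double(class_size(spec, n = 10, table = tbl))
  p <- vapply(words, function(w) as.double(star_word_weight(w)$num) / tot, 0)
  m <- 6000
  samp <- sample_structures(spec, tbl, n = 10, m = m, seed = 2024)
  obs <- table(factor(samp, levels = words))
  chi <- sum((obs - m * p)^2 / (m * p))
  pval <- stats::pchisq(chi, df = length(words) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("boustrophedon probes scale near-linearly, sequential quadratically", {
  spec <- uni_spec()
  tbl <- cached("uni_tbl_256", function() build_tables(uni_spec(), 256))
  res <- data.frame()
  for (n in c(64, 128, 256)) {
    # adversarial exterior chain: many outer helices, so sequential scans of
    # the split sizes pay ~n per level
    w <- strrep("(|||)", n / 5 - 1)
    w <- paste0(w, "(", strrep("|", n - nchar(w) - 2), ")")
    pb <- new.env(); pb$count <- 0
    ps <- new.env(); ps$count <- 0
    rb <- rank_structure(spec, tbl, w, order = "boustrophedon")
    expect_identical(unrank_class(spec, tbl, n = n, i = rb,
                                  order = "boustrophedon", probes = pb), w)
    rs <- rank_structure(spec, tbl, w, order = "sequential")
    expect_identical(unrank_class(spec, tbl, n = n, i = rs,
                                  order = "sequential", probes = ps), w)
    expect_lte(pb$count, n * log2(n))
    expect_gte(ps$count, n^2 / 16)
    res <- rbind(res, data.frame(n = n, bou = pb$count, seq = ps$count))
  }
  # doubling n roughly doubles boustrophedon probes but quadruples sequential
  expect_lt(res$bou[3] / res$bou[1], 8)
  expect_gt(res$seq[3] / res$seq[1], 12)
})
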