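# Motif-parameter summaries and size-matched comparison samples.

test_that("single-structure summaries", {
  st <- summarize_motifs(list(parse_dotbracket("(|||)")))
  g <- function(p, col) st[st$parameter == p, col]
  expect_equal(g("num_h", "mean"), 1)
  expect_equal(g("num_h", "variance"), 0)
  expect_equal(g("unp_h", "mean"), 3)
  expect_equal(g("num_e", "mean"), 1)
  expect_equal(g("num_e", "variance"), 0)
  expect_true(is.na(g("unp_s", "mean")))     # the "--" cells
  expect_true(is.na(g("bps_h", "mean")))
  expect_error(summarize_motifs(list()), "empty")
})

test_that("structurally constant parameters", {
  set.seed(4)
  samp <- sample_structures(star_spec(), star_tables(12), n = 12, m = 40,
                            as_structures = TRUE)
  st <- summarize_motifs(samp)
  g <- function(p, col) st[st$parameter == p, col]
  expect_equal(g("num_e", "mean"), 1); expect_equal(g("num_e", "variance"), 0)
  if (g("bps_s", "n_obs") > 0) {
    expect_equal(g("bps_s", "mean"), 1)
    expect_equal(g("bps_s", "variance"), 0)
  }
  # pooled per-motif means: unp_h totals / hairpin count
  profs <- lapply(samp, decompose_motifs)
  expect_equal(g("unp_h", "mean"),
               sum(vapply(profs, `[[`, 0, "unp_h")) /
                 sum(vapply(profs, `[[`, 0L, "num_h")))
})

test_that("per-structure-mean pooling is available behind the flag", {
  samp <- list(parse_dotbracket("(|||)(|||||)"))
  pooled <- summarize_motifs(samp, pool_instances = TRUE)
  expect_equal(pooled[pooled$parameter == "unp_h", "mean"], 4)
  per <- summarize_motifs(samp, pool_instances = FALSE)
  expect_equal(per[per$parameter == "unp_h", "mean"], 4)  # one structure
})

test_that("size matching reproduces the native size multiset", {
  spec <- star_spec(); tbl <- star_tables(12)
  db <- lapply(c("(|||)", "(|||)", "|(|||)"), parse_dotbracket)
  rnd <- size_matched_sample(db, spec, tbl, seed = 8)
  expect_identical(vapply(rnd, function(s) s$length, 0L), c(5L, 5L, 6L))
  db5 <- lapply(rep("(|||)", 4), parse_dotbracket)
  rnd5 <- size_matched_sample(db5, spec, tbl, seed = 8)
  expect_true(all(vapply(rnd5, function(s) s$word, "") == "(|||)"))
})

test_that("a fixture database and its size-matched sample agree statistically", {
  # the native fixture is itself drawn from the same grammar, so motif means
  # must agree within pooled standard errors
  g <- gsto()
  pl <- cached("pipeline_g120", function() build_pipeline(g, N = 120))
  set.seed(21)
  native_words <- sample_structures(pl$spec, pl$table, n = 100, m = 60)
  native <- lapply(native_words, parse_dotbracket)
  rnd <- size_matched_sample(native, pl$spec, pl$table, seed = 22)
  sn <- summarize_motifs(native); sr <- summarize_motifs(rnd)
  m_n <- sn[sn$parameter == "num_h", ]
  m_r <- sr[sr$parameter == "num_h", ]
  se <- sqrt(m_n$variance / length(native) + m_r$variance / length(rnd))
  expect_lte(abs(m_n$mean - m_r$mean), 3 * se + 1e-9)
})

test_that("comparison tables serialize as TSV", {
  a <- lapply(c("(|||)", "((|||))"), parse_dotbracket)
  cmp <- compare_samples(a, a)
  expect_identical(cmp$mean_random, cmp$mean_native)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_summary_tsv(cmp, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(cmp))
})
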