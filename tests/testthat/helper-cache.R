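# Shared, lazily built objects; the heavier artifacts (grammars, class
# specifications, size tables) are reused across test files.

.tc <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.tc[[key]])) .tc[[key]] <- builder()
  .tc[[key]]
}

gsto <- function() cached("gsto", function() load_builtin("Gsto_hat"))
star_rat <- function() cached("star_rat", function() load_builtin("Gsto_hat_star_rational"))
star_int <- function() cached("star_int", function() load_builtin("Gsto_hat_star_integer"))

star_spec <- function() cached("star_spec", function() grammar_to_spec(star_int()))
star_tables <- function(N = 12) {
  key <- paste0("star_tbl_", N)
  cached(key, function() build_tables(star_spec(), N))
}

uni_spec <- function() cached("uni_spec", function()
  grammar_to_spec(uniform_weights(star_int())))
uni_tables <- function(N = 12) {
  key <- paste0("uni_tbl_", N)
  cached(key, function() build_tables(uni_spec(), N))
}

# variant of the integer grammar with small weights (mu mod 3 + 1): exercises
# weighted copies with full rank ranges that stay enumerable
small_weight_grammar <- function() cached("small_wcfg", function() {
  g <- star_int()
  for (i in seq_along(g$rules)) {
    mu <- g$rules[[i]]$weight$num
    g$rules[[i]]$weight <- rq((as.double(mu) %% 3) + 1)
  }
  g
})

lang <- function(n) {
  key <- paste0("lang_", n)
  cached(key, function() enumerate_language(n))
}

# exact integer word weight under the bundled integer-weighted grammar
star_word_weight <- function(w) {
  key <- paste0("ww_", w)
  cached(key, function() word_weight(star_int(), w))
}

# the worked multiloop example: exterior loop, a degree-3 multiloop, four
# hairpins, four interior loops, two bulges spread over three helices
example_multiloop_word <- function() {
  hel1 <- paste0("((((", "||||", "(((", "||||||", ")))", "))))")
  hel21 <- "((|(||||)))"
  hel22 <- "(|((|||||))|)"
  hel2 <- paste0("(((", "||", "((((", "|", hel21, "|||||||", "))))",
                 "|||||", hel22, ")))")
  hel3 <- paste0("((", "||", "(", "||", "((((", "|||", "))))",
                 "|||||||", ")", "||", "))")
  paste0("||||", "((((", "|||", hel1, "|||", hel2, "||", hel3, "|",
         "))))", "||")
}
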