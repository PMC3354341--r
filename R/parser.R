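# Generic chart parser over a weighted grammar.
#
# Used as the independent oracle: exact word weights (sum over all
# derivations of the product of rule weights), derivation counts, and
# explicit derivation enumeration for small words.  The motif-directed
# linear-time decomposer in src/structure.cpp is cross-validated against
# this parser.
#
# The chart is filled bottom-up by span length; within one span the
# nonterminals are processed in same-length dependency order (A after B
# whenever a rule A -> alpha lets B absorb the whole span because every
# other symbol of alpha can derive epsilon), which unit chains are a special
# case of.  Loop-freeness makes that order exist.

# nonterminals that can derive the empty word
eps_capable_set <- function(g) {
  eps <- stats::setNames(logical(length(g$nonterminals)), g$nonterminals)
  repeat {
    changed <- FALSE
    for (r in g$rules) {
      if (eps[[r$premise]]) next
      ok <- all(vapply(r$conclusion, function(s)
        !is_terminal(g, s) && eps[[s]], TRUE))
      if (length(r$conclusion) == 0) ok <- TRUE
      if (ok) { eps[[r$premise]] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  eps
}

# order nonterminals so that same-length dependencies come first
same_length_order <- function(g, eps = eps_capable_set(g)) {
  nts <- g$nonterminals
  adj <- stats::setNames(vector("list", length(nts)), nts)
  for (r in g$rules) {
    syms <- r$conclusion
    if (any(vapply(syms, is_terminal, TRUE, g = g))) next
    for (k in seq_along(syms)) {
      if (all(vapply(syms[-k], function(s) eps[[s]], TRUE)))
        adj[[r$premise]] <- unique(c(adj[[r$premise]], syms[[k]]))
    }
  }
  done <- character(0); remaining <- nts; out <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(a)
      all(setdiff(adj[[a]], a) %in% done), TRUE)]
    if (!length(ready)) stop("grammar is not loop-free (same-length cycle)")
    done <- c(done, ready); out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

# semiring-style value operations for the two chart modes
chart_ops <- function(mode) {
  if (mode == "weight") {
    list(zero = rq(0),
         one = rq(1),
         is_zero = function(v) bn_is_zero(v$num),
         add = rq_add,
         mul = rq_mul,
         lift = function(rule, v) rq_mul(rule$weight, v))
  } else {
    list(zero = list(),
         one = list(integer(0)),
         is_zero = function(v) length(v) == 0,
         add = c,
         mul = function(a, b) {
           out <- list()
           for (x in a) for (y in b) out[[length(out) + 1]] <- sort(c(x, y))
           out
         },
         lift = function(rule, v) lapply(v, function(d) sort(c(rule$id, d))))
  }
}

chart_parse <- function(g, word, mode = c("weight", "derivations")) {
  mode <- match.arg(mode)
  ops <- chart_ops(mode)
  chars <- if (nchar(word)) strsplit(word, "")[[1]] else character(0)
  n <- length(chars)
  nts <- g$nonterminals
  eps <- eps_capable_set(g)
  order <- same_length_order(g, eps)

  # epsilon values per nonterminal (fixpoint; loop-free => stabilises)
  epsv <- stats::setNames(rep(list(ops$zero), length(nts)), nts)
  seq_value_eps <- function(syms, cur) {
    v <- ops$one
    for (s in syms) {
      if (is_terminal(g, s)) return(ops$zero)
      v <- ops$mul(v, cur[[s]])
      if (ops$is_zero(v)) return(v)
    }
    v
  }
  for (it in seq_len(length(nts) + 1)) {
    nxt <- stats::setNames(rep(list(ops$zero), length(nts)), nts)
    for (r in g$rules) {
      v <- seq_value_eps(r$conclusion, epsv)
      if (!ops$is_zero(v))
        nxt[[r$premise]] <- ops$add(nxt[[r$premise]], ops$lift(r, v))
    }
    same <- all(vapply(nts, function(a) {
      az <- ops$is_zero(epsv[[a]]); bz <- ops$is_zero(nxt[[a]])
      if (az != bz) return(FALSE)
      if (az) return(TRUE)
      if (mode == "weight") rq_eq(epsv[[a]], nxt[[a]])
      else length(epsv[[a]]) == length(nxt[[a]])
    }, TRUE))
    epsv <- nxt
    if (same) break
  }

  W <- new.env(parent = emptyenv())  # key "A;i;j" for spans of length >= 1
  get_nt <- function(a, i, j) {
    if (j < i) return(epsv[[a]])
    v <- W[[paste0(a, ";", i, ";", j)]]
    if (is.null(v)) ops$zero else v
  }
  # value of a symbol sequence over span (i..j); reads only finalized chart
  # entries (an unfinalized full-span entry is only reachable behind a
  # zero-valued rest, which is skipped before the read), so memoized suffix
  # values stay valid for the rest of the parse
  SM <- new.env(parent = emptyenv())
  seq_value <- function(syms, i, j) {
    if (length(syms) == 0) return(if (j < i) ops$one else ops$zero)
    key <- paste0(paste(syms, collapse = "\1"), ";", i, ";", j)
    hit <- SM[[key]]
    if (!is.null(hit)) return(hit)
    s <- syms[[1]]
    rest <- syms[-1]
    acc <- ops$zero
    if (is_terminal(g, s)) {
      if (i <= j && chars[i] == s) acc <- seq_value(rest, i + 1, j)
    } else {
      # evaluate the head symbol first and skip on zero: a suffix is then
      # only ever expanded at the full current span when the prefix really
      # derived epsilon, in which case the same-length order has already
      # finalized every entry a nonzero term can touch
      for (k in (i - 1):j) {
        w1 <- get_nt(s, i, k)
        if (ops$is_zero(w1)) next
        w2 <- seq_value(rest, k + 1, j)
        if (ops$is_zero(w2)) next
        acc <- ops$add(acc, ops$mul(w1, w2))
      }
    }
    SM[[key]] <- acc
    acc
  }
  if (n > 0) {
    for (l in 1:n) {
      for (i in 1:(n - l + 1)) {
        j <- i + l - 1
        for (a in order) {
          acc <- ops$zero
          for (r in rules_of(g, a)) {
            v <- seq_value(r$conclusion, i, j)
            if (!ops$is_zero(v)) acc <- ops$add(acc, ops$lift(r, v))
          }
          if (!ops$is_zero(acc)) W[[paste0(a, ";", i, ";", j)]] <- acc
        }
      }
    }
  }
  get_nt(g$axiom, 1, n)
}

#' Exact weight of a word under a weighted grammar
#'
#' Sums the product of rule weights over all derivations of the word (for an
#' unambiguous grammar: the weight of its unique derivation). Brute-force
#' oracle; intended for short words.
#'
#' @param g a \code{wcfg}.
#' @param word a bar-bracket string.
#' @return an \code{\link{rq}} exact rational (0 if the word is not in the
#'   language).
#' @export
word_weight <- function(g, word) chart_parse(g, word, "weight")

#' Number of derivation trees of a single word
#' @param g a \code{wcfg}.
#' @param word a string over the grammar's terminals.
#' @return numeric count.
#' @export
count_word_derivations <- function(g, word) {
  length(chart_parse(g, word, "derivations"))
}

#' Enumerate all derivations of a word
#'
#' @param g a \code{wcfg}.
#' @param word a string over the grammar's terminals.
#' @return list of derivations, each a sorted vector of the rule ids used
#'   (with multiplicity). Length 1 certifies the word parses unambiguously.
#' @export
enumerate_derivations <- function(g, word) chart_parse(g, word, "derivations")
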