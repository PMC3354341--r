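# Weighted / stochastic context-free grammars over the bar-bracket alphabet.
#
# A grammar is an immutable list with ordered nonterminals, the terminal set,
# an axiom, and an ordered rule list.  Every rule weight is an exact rational
# (class "rq"); integer-weighted grammars simply have denominator 1.  Rule
# ids are the positions in the defining listing and fix every tie-breaking
# order downstream (chain gathering, substitution, union order, unranking).

TERMINALS <- c("(", ")", "|")

new_rule <- function(id, premise, conclusion, weight) {
  list(id = as.integer(id), premise = premise,
       conclusion = as.character(conclusion), weight = rq(weight))
}

#' Construct a weighted context-free grammar
#'
#' @param nonterminals character vector (ordered, unique).
#' @param axiom one of the nonterminals.
#' @param rules list of rules; each rule is a list with elements
#'   \code{premise}, \code{conclusion} (character vector of symbols, possibly
#'   empty for explicitly epsilon-marked grammars) and \code{weight}
#'   (anything \code{\link{rq}} accepts). Ids are assigned by position unless
#'   supplied.
#' @param terminals terminal alphabet; defaults to the bar-bracket alphabet.
#' @param stochastic if TRUE the per-premise weights must sum to exactly 1.
#' @param allow_epsilon permit empty conclusions (default FALSE).
#' @param allow_zero permit zero rule weights (trained grammars may assign
#'   relative frequency 0 to a rule whose premise was observed; such rules
#'   cannot enter the reweighting pipeline but the grammar is a valid SCFG).
#' @param weight_mode "rational" or "integer" (bookkeeping flag; integer
#'   grammars hold rationals with denominator 1).
#' @return an object of class \code{wcfg}.
#' @export
wcfg <- function(nonterminals, axiom, rules, terminals = TERMINALS,
                 stochastic = FALSE, allow_epsilon = FALSE,
                 allow_zero = FALSE,
                 weight_mode = c("rational", "integer")) {
  weight_mode <- match.arg(weight_mode)
  nonterminals <- as.character(nonterminals)
  if (anyDuplicated(nonterminals)) stop("nonterminal names must be unique")
  if (!axiom %in% nonterminals) stop("axiom must be a declared nonterminal")
  bad_t <- setdiff(terminals, TERMINALS)
  if (length(bad_t)) stop("terminals restricted to '(', ')', '|'")
  rules <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    id <- if (!is.null(r$id)) r$id else i
    rule <- new_rule(id, r$premise, r$conclusion, r$weight)
    if (!rule$premise %in% nonterminals)
      stop("rule ", id, ": premise not declared")
    if (length(rule$conclusion) == 0 && !allow_epsilon)
      stop("rule ", id, ": empty conclusion in a non-epsilon grammar")
    undecl <- setdiff(rule$conclusion, c(nonterminals, terminals))
    if (length(undecl))
      stop("rule ", id, ": undeclared symbol(s) ", paste(undecl, collapse = ", "))
    if (!allow_zero && bn_is_zero(rule$weight$num))
      stop("rule ", id, ": weight must be > 0")
    rule
  })
  premises <- vapply(rules, `[[`, "", "premise")
  missing_premise <- setdiff(nonterminals, premises)
  if (length(missing_premise))
    stop("every nonterminal needs at least one rule; missing: ",
         paste(missing_premise, collapse = ", "))
  g <- structure(list(nonterminals = nonterminals, terminals = terminals,
                      axiom = axiom, rules = rules,
                      weight_mode = weight_mode, stochastic = stochastic),
                 class = "wcfg")
  if (stochastic) {
    cons <- check_consistency(g)
    if (!cons$pass)
      stop("stochastic grammar: weights of premise(s) ",
           paste(cons$premise[!cons$ok], collapse = ", "),
           " do not sum to exactly 1")
  }
  g
}

#' @export
print.wcfg <- function(x, ...) {
  cat(sprintf("<wcfg> %d nonterminals, %d rules, axiom %s, %s weights%s\n",
              length(x$nonterminals), length(x$rules), x$axiom,
              x$weight_mode, if (x$stochastic) " (stochastic)" else ""))
  invisible(x)
}

rules_of <- function(g, premise) {
  Filter(function(r) r$premise == premise, g$rules)
}

is_terminal <- function(g, sym) sym %in% g$terminals

#' Look up the exact weight of a production
#'
#' @param g a \code{wcfg}.
#' @param id rule id; alternatively give \code{premise} and
#'   \code{conclusion} (single string, symbols concatenated, or character
#'   vector).
#' @param premise,conclusion alternative lookup key.
#' @return the weight as an \code{\link{rq}} exact rational.
#' @export
weight_of <- function(g, id = NULL, premise = NULL, conclusion = NULL) {
  if (!is.null(id)) {
    for (r in g$rules) if (r$id == id) return(r$weight)
    stop("no rule with id ", id)
  }
  if (length(conclusion) == 1 && nchar(conclusion[[1]]) > 1 &&
      !conclusion[[1]] %in% c(TERMINALS))
    conclusion <- conclusion  # caller may pass a vector already
  for (r in g$rules) {
    if (r$premise == premise && identical(r$conclusion, as.character(conclusion)))
      return(r$weight)
  }
  stop("no rule ", premise, " -> ", paste(conclusion, collapse = ""))
}

#' Check stochastic consistency of the rule weights
#'
#' For every premise the exact-rational weights of its rules are summed; the
#' grammar passes iff every sum equals 1 exactly. No tolerance is involved.
#'
#' @param g a \code{wcfg} with rational weights.
#' @return a data.frame with one row per premise: the exact sum (as a
#'   string), its double approximation, and an \code{ok} flag; attribute-free
#'   scalar \code{pass} is attached as a column-independent field via
#'   \code{attr(, "pass")} and also returned in \code{$pass} when printed.
#' @export
check_consistency <- function(g) {
  premises <- unique(vapply(g$rules, `[[`, "", "premise"))
  sums <- lapply(premises, function(p) {
    s <- rq(0)
    for (r in rules_of(g, p)) s <- rq_add(s, r$weight)
    s
  })
  ok <- vapply(sums, rq_is_one, TRUE)
  out <- list(premise = premises,
              sum = vapply(sums, as.character, ""),
              sum_num = vapply(sums, rq_to_double, 0),
              ok = ok,
              pass = all(ok))
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("stochastic consistency:", if (x$pass) "PASS" else "FAIL", "\n")
  bad <- which(!x$ok)
  for (i in bad) cat("  ", x$premise[i], "sums to", x$sum[i], "\n")
  invisible(x)
}

# unit-derivation graph: edge A -> B for rules whose conclusion is exactly
# one nonterminal
unit_edges <- function(g) {
  e <- list()
  for (r in g$rules) {
    if (length(r$conclusion) == 1 && !is_terminal(g, r$conclusion)) {
      e[[length(e) + 1]] <- c(r$premise, r$conclusion)
    }
  }
  e
}

# topological order of nonterminals such that unit-rule targets come first;
# NULL if the unit graph has a cycle
unit_topo_order <- function(g, edges = unit_edges(g)) {
  nts <- g$nonterminals
  adj <- stats::setNames(vector("list", length(nts)), nts)   # A -> targets
  indeg <- stats::setNames(integer(length(nts)), nts)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    indeg[[e[1]]] <- indeg[[e[1]]] + 1L  # count outgoing as "unresolved deps"
  }
  # Kahn on reversed edges: process symbols whose unit targets are all done
  done <- character(0)
  remaining <- nts
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(a) {
      all(adj[[a]] %in% done)
    }, TRUE)]
    if (!length(ready)) return(NULL)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  done
}

#' Check epsilon-freeness and loop-freeness
#'
#' Epsilon-free: no rule has an empty conclusion and the axiom never appears
#' in a conclusion. Loop-free: the unit-derivation graph (edges A -> B for
#' rules A -> B with a single-nonterminal conclusion) is acyclic, so no
#' nonempty derivation A =>+ A exists.
#'
#' @param g a \code{wcfg}.
#' @return list with flags \code{epsilon_free}, \code{loop_free}, offending
#'   \code{epsilon_rules} (ids), \code{axiom_occurrences} (ids) and
#'   \code{cycle_symbols}.
#' @export
check_epsilon_loop_free <- function(g) {
  eps_rules <- vapply(Filter(function(r) length(r$conclusion) == 0, g$rules),
                      `[[`, 0L, "id")
  ax_occ <- vapply(Filter(function(r) g$axiom %in% r$conclusion, g$rules),
                   `[[`, 0L, "id")
  topo <- unit_topo_order(g)
  cycle_symbols <- if (is.null(topo)) {
    src <- unique(vapply(unit_edges(g), `[`, "", 1))
    src  # conservative report: symbols involved in unit rules
  } else character(0)
  list(epsilon_free = length(eps_rules) == 0 && length(ax_occ) == 0,
       loop_free = !is.null(topo),
       epsilon_rules = eps_rules,
       axiom_occurrences = ax_occ,
       cycle_symbols = cycle_symbols)
}

#' Count derivation trees by word length
#'
#' Computes d_n, the total number of derivation trees the grammar offers over
#' all words of length n (all weights treated as 1), by dynamic programming
#' over lengths. Used as the empirical unambiguity check: for an unambiguous
#' grammar generating the secondary-structure language, d_n equals the number
#' of structures of size n.
#'
#' @param g a \code{wcfg}; epsilon rules are allowed provided no nonterminal
#'   has infinitely many epsilon-derivations.
#' @param N maximum word length.
#' @return numeric vector d_1..d_N. Counts are exact as long as every
#'   intermediate stays below 2^52; the function stops otherwise.
#' @export
count_derivations_by_length <- function(g, N) {
  nts <- g$nonterminals
  GUARD <- 2^52
  # epsilon-derivation counts by fixpoint iteration (finite if loop-free)
  d0 <- stats::setNames(numeric(length(nts)), nts)
  for (it in seq_len(length(nts) + 1)) {
    nxt <- stats::setNames(numeric(length(nts)), nts)
    for (r in g$rules) {
      v <- 1
      for (s in r$conclusion) {
        v <- v * (if (is_terminal(g, s)) 0 else d0[[s]])
        if (v == 0) break
      }
      if (length(r$conclusion) == 0) v <- 1
      nxt[[r$premise]] <- nxt[[r$premise]] + v
    }
    if (identical(nxt, d0) && it > 1) break
    if (it == length(nts) + 1 && !identical(nxt, d0))
      stop("epsilon-derivation counts do not stabilise (grammar not loop-free)")
    d0 <- nxt
  }
  # same-length dependency order: rule A -> alpha creates an edge A -> B when
  # B could absorb the full length (all other symbols epsilon-capable,
  # no terminals)
  eps_cap <- d0 > 0
  adj <- stats::setNames(vector("list", length(nts)), nts)
  for (r in g$rules) {
    syms <- r$conclusion
    if (any(vapply(syms, is_terminal, TRUE, g = g))) next
    for (k in seq_along(syms)) {
      others <- syms[-k]
      if (all(vapply(others, function(s) eps_cap[[s]], TRUE)))
        adj[[r$premise]] <- unique(c(adj[[r$premise]], syms[[k]]))
    }
  }
  done <- character(0); remaining <- nts
  order <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(a)
      all(setdiff(adj[[a]], a) %in% done), TRUE)]
    if (!length(ready)) stop("length-preserving derivation cycle; grammar not loop-free")
    done <- c(done, ready); order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  d <- matrix(0, nrow = length(nts), ncol = N + 1,
              dimnames = list(nts, NULL))  # column j = length j-1
  d[, 1] <- d0
  for (n in seq_len(N)) {
    for (a in order) {
      total <- 0
      for (r in rules_of(g, a)) {
        # ways[j+1] = number of ways the first k symbols derive length j
        ways <- c(1, numeric(n))
        for (s in r$conclusion) {
          if (is_terminal(g, s)) {
            ways <- c(0, ways[seq_len(n)])
          } else {
            nw <- numeric(n + 1)
            for (j in 0:n) {
              if (ways[j + 1] == 0) next
              add <- ways[j + 1] * d[s, seq_len(n - j + 1)]
              nw[(j + 1):(n + 1)] <- nw[(j + 1):(n + 1)] + add
            }
            ways <- nw
          }
        }
        total <- total + ways[n + 1]
      }
      if (total > GUARD) stop("derivation count exceeds exact double range; reduce N")
      d[a, n + 1] <- total
    }
  }
  d[g$axiom, -1]
}

#' Residuals of the structure generating function identity
#'
#' Substitutes the truncated power series S(z) = sum d_n z^n into the
#' polynomial identity satisfied by the generating function of
#' secondary-structure derivation counts,
#' -z^5 + S(z)(z-1)(-1 + z(2 - S(z)(z-1)z + z^4)) = 0,
#' and returns the coefficients of z^1..z^N of the left-hand side. All must
#' vanish for counts of a grammar word-equivalent to the structure language.
#'
#' @param counts numeric vector d_1..d_N.
#' @param N truncation order (defaults to length(counts)).
#' @return numeric vector of residual coefficients for z^1..z^N.
#' @export
verify_generating_function <- function(counts, N = length(counts)) {
  stopifnot(N <= length(counts))
  # polynomial coefficient vectors indexed 1 = z^0, truncated at z^N
  trunc_mul <- function(p, q) {
    r <- numeric(N + 1)
    for (i in seq_along(p)) {
      if (p[i] == 0) next
      jmax <- min(length(q), N + 2 - i)
      if (jmax < 1) break
      idx <- i + seq_len(jmax) - 1
      r[idx] <- r[idx] + p[i] * q[seq_len(jmax)]
    }
    if (any(abs(r) > 2^52)) stop("residual coefficients exceed exact double range")
    r
  }
  pad <- function(p) { length(p) <- N + 1; p[is.na(p)] <- 0; p }
  S <- pad(c(0, counts[seq_len(N)]))
  zm1 <- pad(c(-1, 1))
  T <- trunc_mul(S, zm1)                       # S(z)(z-1)
  inner <- pad(c(2, numeric(0)))               # 2
  inner <- inner - trunc_mul(T, pad(c(0, 1)))  # - T*z
  inner[5] <- inner[5] + 1                     # + z^4
  bracket <- trunc_mul(pad(c(0, 1)), inner)    # z * inner
  bracket[1] <- bracket[1] - 1                 # -1 + ...
  lhs <- trunc_mul(T, bracket)
  lhs[6] <- lhs[6] - 1                         # - z^5
  lhs[2:(N + 1)]
}

#' Replace all rule weights by 1
#'
#' Handy for uniform counting: with unit weights the weighted class sizes of
#' the derived specification equal plain derivation counts.
#'
#' @param g a \code{wcfg}.
#' @return a new grammar with every weight equal to 1 (not stochastic).
#' @export
uniform_weights <- function(g) {
  rules <- lapply(g$rules, function(r) { r$weight <- rq(1); r })
  g$rules <- rules
  g$stochastic <- FALSE
  g$weight_mode <- "integer"
  g
}

# --- serialization ----------------------------------------------------------

#' Serialize a grammar to JSON (exact weights)
#'
#' Weights are written as exact \code{\{num, den\}} decimal strings, never as
#' floats.
#'
#' @param g a \code{wcfg}.
#' @param path file path; if NULL the JSON string is returned.
#' @export
write_grammar_json <- function(g, path = NULL) {
  obj <- list(
    axiom = g$axiom,
    nonterminals = g$nonterminals,
    terminals = g$terminals,
    weight_mode = g$weight_mode,
    stochastic = g$stochastic,
    rules = lapply(g$rules, function(r) list(
      id = r$id, premise = r$premise, conclusion = as.list(r$conclusion),
      weight = list(num = as.character(r$weight$num),
                    den = as.character(r$weight$den)))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a grammar from its JSON serialization
#' @param path file path or JSON string.
#' @return a \code{wcfg}.
#' @export
read_grammar_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) list(
    id = r$id, premise = r$premise,
    conclusion = unlist(r$conclusion) %||% character(0),
    weight = rq(bn(r$weight$num), bn(r$weight$den))))
  wcfg(unlist(obj$nonterminals), obj$axiom, rules,
       terminals = unlist(obj$terminals),
       stochastic = isTRUE(obj$stochastic),
       allow_epsilon = TRUE,
       weight_mode = obj$weight_mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fingerprint of a grammar's rules and weights
#'
#' Used to tag persisted size tables so stale tables are refused.
#'
#' @param g a \code{wcfg}.
#' @return a character scalar.
#' @export
grammar_fingerprint <- function(g) {
  txt <- paste(vapply(g$rules, function(r) {
    paste(r$id, r$premise, paste(r$conclusion, collapse = " "),
          as.character(r$weight), sep = "|")
  }, ""), collapse = ";")
  # small stable polynomial hash; no external digest dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%d-%d", h, length(g$rules))
}
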