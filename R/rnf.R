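# Reweighting normal form.
#
# A loop-free, epsilon-free weighted grammar is transformed so that every
# non-axiom rule either lengthens the sentential form (|conclusion| > 1) or
# carries an integral weight; afterwards rational weights can be scaled to
# integers without changing relative word weights.  Five steps:
#   1. gather all non-lengthening derivation chains A => A1 => ... => X
#      (A not the axiom, |X| = 1) and remove the non-axiom unit rules;
#   2. introduce one fresh symbol A{X,via} and weight-1 rule A{X,via} -> X
#      per chain;
#   3. for every surviving rule and every chain starting at a nonterminal
#      occurring in its conclusion, add the substituted variant with weight
#      rule weight x chain weight (full cross-product over occurrences;
#      leftmost occurrence varies slowest);
#   4. delete nonterminals that no longer occur as a premise together with
#      every rule mentioning them;
#   5. split axiom rules with |conclusion| > 1 through a fresh symbol.

chain_symbol <- function(source, target, via) {
  paste0(source, "{", target, ",", paste(via, collapse = ""), "}")
}

#' Gather the non-lengthening derivation chains of a grammar
#'
#' All derivations A => A1 => ... => X built from unit rules (conclusions of
#' length one), starting at any non-axiom nonterminal; every prefix is a
#' chain, the final target may be a terminal or a nonterminal. The chain
#' weight is the exact product of the traversed rule weights; the via field
#' spells the intermediate nonterminals.
#'
#' @param g an epsilon-free, loop-free \code{wcfg}.
#' @return an object of class \code{chain_table}: a list of chains (source,
#'   target, via, weight, symbol) in breadth-first order grouped by source
#'   (sources in declaration order).
#' @export
collect_chains <- function(g) {
  chk <- check_epsilon_loop_free(g)
  if (!chk$epsilon_free)
    stop("grammar is not epsilon-free (rules ",
         paste(c(chk$epsilon_rules, chk$axiom_occurrences), collapse = ", "), ")")
  if (!chk$loop_free)
    stop("grammar is not loop-free (unit cycle through ",
         paste(chk$cycle_symbols, collapse = ", "), ")")
  unit <- Filter(function(r) length(r$conclusion) == 1 && r$premise != g$axiom,
                 g$rules)
  chains <- list()
  for (src in setdiff(g$nonterminals, g$axiom)) {
    # breadth-first over unit rules, prefixes included
    frontier <- list(list(target = src, via = character(0), weight = rq(1)))
    repeat {
      nxt <- list()
      for (node in frontier) {
        if (node$target %in% g$terminals) next
        for (r in unit) {
          if (r$premise != node$target) next
          via <- c(node$via, if (identical(node$target, src)) character(0)
                             else node$target)
          ch <- list(source = src, target = r$conclusion,
                     via = via, weight = rq_mul(node$weight, r$weight))
          ch$symbol <- chain_symbol(src, ch$target, ch$via)
          chains[[length(chains) + 1]] <- ch
          nxt[[length(nxt) + 1]] <- ch
        }
      }
      if (!length(nxt)) break
      frontier <- nxt
    }
  }
  structure(chains, class = "chain_table")
}

#' @export
print.chain_table <- function(x, ...) {
  cat("<chain_table>", length(x), "chains\n")
  for (ch in x) {
    cat(sprintf("  %s => %s  (via %s, weight %s)\n", ch$source, ch$target,
                if (length(ch$via)) paste(ch$via, collapse = "") else "-",
                as.character(ch$weight)))
  }
  invisible(x)
}

# substitution combinations for one rule: positions pos (occurrence indices
# into the conclusion), options per position = list(NULL, chain, chain, ...);
# leftmost occurrence varies slowest, listed original-first
sub_combos <- function(rule, chains_by_source) {
  conc <- rule$conclusion
  pos <- which(vapply(seq_along(conc), function(k) {
    !is.null(chains_by_source[[conc[[k]]]])
  }, TRUE))
  combos <- list(list(conclusion = conc, weight = rule$weight,
                      substituted = FALSE))
  for (p in pos) {
    sym <- conc[[p]]
    # leftmost-slowest order: within each block of earlier-position choices,
    # list the unsubstituted variant first, then this position's chains
    out <- list()
    for (base in combos) {
      out[[length(out) + 1]] <- base
      for (ch in chains_by_source[[sym]]) {
        v <- base
        v$conclusion[[p]] <- ch$symbol
        v$weight <- rq_mul(v$weight, ch$weight)
        v$substituted <- TRUE
        out[[length(out) + 1]] <- v
      }
    }
    combos <- out
  }
  combos
}

#' Transform a grammar into reweighting normal form
#'
#' @param g an epsilon-free, loop-free \code{wcfg} with every nonterminal
#'   productive.
#' @return an object of class \code{rnf_report} with fields
#'   \code{removed_unit_rules}, \code{chains}, \code{chain_rules},
#'   \code{substituted_rules} (the full step-3 listing),
#'   \code{dead_symbols}, \code{dead_rules}, \code{axiom_fixes} and
#'   \code{result} (the new grammar, word-equivalent to \code{g}).
#' @export
to_rnf <- function(g) {
  chains <- collect_chains(g)   # also validates the preconditions
  check_productive(g)
  unit_removed <- Filter(function(r)
    length(r$conclusion) == 1 && r$premise != g$axiom, g$rules)
  removed_ids <- vapply(unit_removed, `[[`, 0L, "id")
  survivors <- Filter(function(r) !(r$id %in% removed_ids), g$rules)

  chains_by_source <- list()
  for (ch in chains) {
    chains_by_source[[ch$source]] <- c(chains_by_source[[ch$source]], list(ch))
  }

  # step 2: one weight-1 rule per chain
  chain_rules <- lapply(chains, function(ch)
    list(premise = ch$symbol, conclusion = ch$target, weight = rq(1)))

  # step 3: substitution cross-product over occurrences of chain sources
  step3 <- list()
  for (r in survivors) {
    for (v in sub_combos(r, chains_by_source)) {
      step3[[length(step3) + 1]] <- list(premise = r$premise,
                                         conclusion = v$conclusion,
                                         weight = v$weight,
                                         from_rule = r$id,
                                         substituted = v$substituted)
    }
  }

  # step 4: drop nonterminals that are no longer premises, and all rules
  # mentioning them (iterated to a fixpoint in case a removal orphans
  # another symbol; a single pass suffices for the bundled grammars)
  step4 <- step3
  dead <- character(0)
  dead_rules <- list()
  repeat {
    alive_premises <- unique(c(vapply(step4, `[[`, "", "premise"),
                               vapply(chain_rules, `[[`, "", "premise")))
    new_dead <- setdiff(setdiff(g$nonterminals, dead), alive_premises)
    if (!length(new_dead)) break
    dead <- c(dead, new_dead)
    mentions_dead <- function(rl) any(rl$conclusion %in% dead)
    dead_rules <- c(dead_rules, Filter(mentions_dead, step4))
    step4 <- Filter(function(rl) !mentions_dead(rl), step4)
  }

  # step 5: axiom rules with |conclusion| > 1 are split via a fresh symbol
  axiom_fixes <- list()
  extra_rules <- list()
  step5 <- list()
  fresh_i <- 0
  for (rl in step4) {
    if (rl$premise == g$axiom && length(rl$conclusion) > 1) {
      fresh_i <- fresh_i + 1
      fresh <- paste0(g$axiom, "@", fresh_i)
      axiom_fixes[[length(axiom_fixes) + 1]] <-
        list(original = rl, symbol = fresh)
      step5[[length(step5) + 1]] <- list(premise = g$axiom,
                                         conclusion = fresh,
                                         weight = rl$weight)
      extra_rules[[length(extra_rules) + 1]] <-
        list(premise = fresh, conclusion = rl$conclusion, weight = rq(1))
    } else {
      step5[[length(step5) + 1]] <- rl
    }
  }

  all_rules <- c(step5, chain_rules, extra_rules)
  all_rules <- lapply(seq_along(all_rules), function(i) {
    r <- all_rules[[i]]
    list(id = i, premise = r$premise, conclusion = r$conclusion,
         weight = r$weight)
  })
  nts <- c(setdiff(g$nonterminals, dead),
           vapply(chain_rules, `[[`, "", "premise"),
           vapply(extra_rules, `[[`, "", "premise"))
  result <- wcfg(nts, g$axiom, all_rules, terminals = g$terminals,
                 weight_mode = "rational")
  structure(list(removed_unit_rules = unit_removed,
                 chains = chains,
                 chain_rules = chain_rules,
                 substituted_rules = step3,
                 dead_symbols = dead,
                 dead_rules = dead_rules,
                 axiom_fixes = axiom_fixes,
                 main_rule_count = length(step5),
                 result = result),
            class = "rnf_report")
}

#' @export
print.rnf_report <- function(x, ...) {
  cat("<rnf_report>\n",
      " unit rules removed:", length(x$removed_unit_rules), "\n",
      " chains gathered:   ", length(x$chains), "\n",
      " chain rules added: ", length(x$chain_rules), "\n",
      " step-3 rules:      ", length(x$substituted_rules), "\n",
      " dead symbols:      ", paste(x$dead_symbols, collapse = " "), "\n",
      " dead rules removed:", length(x$dead_rules), "\n",
      " main rules kept:   ", x$main_rule_count, "\n")
  invisible(x)
}

# every nonterminal must derive some terminal word
check_productive <- function(g) {
  productive <- character(0)
  repeat {
    new_p <- vapply(g$nonterminals, function(a) {
      if (a %in% productive) return(TRUE)
      for (r in rules_of(g, a)) {
        ok <- all(vapply(r$conclusion, function(s)
          is_terminal(g, s) || s %in% productive, TRUE))
        if (ok) return(TRUE)
      }
      FALSE
    }, TRUE)
    np <- g$nonterminals[new_p]
    if (length(np) == length(productive)) break
    productive <- np
  }
  bad <- setdiff(g$nonterminals, productive)
  if (length(bad)) stop("unproductive nonterminal(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Serialize an RNF report to JSON
#'
#' @param report an \code{rnf_report}.
#' @param path optional output file.
#' @export
write_rnf_report_json <- function(report, path = NULL) {
  rl <- function(r) list(premise = r$premise,
                         conclusion = paste(r$conclusion, collapse = " "),
                         weight = as.character(rq(r$weight)))
  obj <- list(
    removed_unit_rules = lapply(report$removed_unit_rules, rl),
    chains = lapply(report$chains, function(ch) list(
      source = ch$source, target = ch$target,
      via = paste(ch$via, collapse = ""),
      weight = as.character(ch$weight), symbol = ch$symbol)),
    chain_rules = lapply(report$chain_rules, rl),
    substituted_rules = lapply(report$substituted_rules, rl),
    dead_symbols = report$dead_symbols,
    dead_rules = lapply(report$dead_rules, rl),
    main_rule_count = report$main_rule_count,
    result = jsonlite::fromJSON(write_grammar_json(report$result),
                                simplifyVector = FALSE))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
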