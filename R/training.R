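# Relative-frequency training.
#
# For the unambiguous detailed grammar every structure has a unique leftmost
# derivation, so training reduces to counting rule usages.  The default path
# is a motif-directed decomposer specialised to the 54-rule grammar's
# nonterminal semantics (linear time; handles rRNA-scale structures); a
# generic chart parser serves as the independent oracle on short words.

# does g have the rule shapes of the detailed 54-rule grammar?
is_gsto_shaped <- function(g) {
  shapes <- gsto_hat_shapes()
  if (length(g$rules) != length(shapes)) return(FALSE)
  for (i in seq_along(shapes)) {
    r <- g$rules[[i]]
    conc <- if (identical(shapes[[i]][[2]], "")) character(0)
            else strsplit(shapes[[i]][[2]], " ", fixed = TRUE)[[1]]
    if (r$premise != shapes[[i]][[1]] || !identical(r$conclusion, conc))
      return(FALSE)
  }
  identical(g$axiom, "S'")
}

#' Rule usage counts of the unique derivation of a structure
#'
#' For the bundled detailed grammar (and trained reweightings of it) a
#' specialised linear-time decomposer keyed to the nonterminal semantics is
#' used; for other grammars the generic chart parser extracts the (unique)
#' derivation, with a length cap because the chart is cubic.
#'
#' @param g a \code{wcfg}.
#' @param s a \code{secstruct} or bar-bracket string.
#' @param method "auto", "decomposer" (requires the detailed grammar's rule
#'   shapes) or "parser" (generic oracle).
#' @param parser_cap refuse the generic parser above this length.
#' @return named numeric vector of usage counts, one entry per rule id.
#' @export
derive_rule_counts <- function(g, s, method = c("auto", "decomposer", "parser"),
                               parser_cap = 40) {
  method <- match.arg(method)
  if (is.character(s)) s <- parse_dotbracket(s)
  if (method == "auto") {
    method <- if (is_gsto_shaped(g)) "decomposer" else "parser"
  }
  if (method == "decomposer") {
    if (!is_gsto_shaped(g))
      stop("specialised decomposer is only registered for the detailed grammar")
    cnt <- gsto_rule_counts_(s$word, s$partner)
    names(cnt) <- as.character(seq_along(cnt))
    return(cnt)
  }
  if (s$length > parser_cap)
    stop("structure too long for the generic chart parser (cap ", parser_cap, ")")
  ders <- enumerate_derivations(g, s$word)
  if (length(ders) == 0) stop("structure is not derivable in this grammar")
  if (length(ders) > 1) stop("structure has ", length(ders),
                             " derivations; grammar is ambiguous here")
  ids <- as.character(vapply(g$rules, `[[`, 0L, "id"))
  cnt <- stats::setNames(numeric(length(ids)), ids)
  tab <- table(ders[[1]])
  cnt[names(tab)] <- as.numeric(tab)
  cnt
}

# per-structure count matrix (rows = structures, cols = rule ids)
rule_count_matrix <- function(g, db, method = "auto") {
  rows <- lapply(db, function(s) derive_rule_counts(g, s, method = method))
  do.call(rbind, rows)
}

#' Aggregate rule usage counts over a structure database
#'
#' @param g a \code{wcfg}.
#' @param db list of structures (or strings).
#' @return an object of class \code{rule_count_table}: per-rule counts and
#'   per-premise totals.
#' @export
rule_counts <- function(g, db) {
  m <- rule_count_matrix(g, db)
  counts <- colSums(m)
  premises <- vapply(g$rules, `[[`, "", "premise")
  totals <- tapply(counts, premises, sum)
  structure(list(counts = counts, premises = premises,
                 premise_totals = totals), class = "rule_count_table")
}

#' @export
print.rule_count_table <- function(x, ...) {
  cat("<rule_count_table>", length(x$counts), "rules,",
      sum(x$counts), "total usages\n")
  invisible(x)
}

#' Train rule probabilities as exact relative frequencies
#'
#' weight(rule) = (count + pseudocount) /
#'                (premise total + pseudocount * rules of premise),
#' computed in exact rational arithmetic. Premises never observed get the
#' uniform distribution (with a warning) so the result is always a valid
#' SCFG.
#'
#' @param g the grammar whose rule shapes define the derivations.
#' @param db nonempty list of structures or bar-bracket strings.
#' @param pseudocount non-negative; a numeric integer or "a/b" string.
#' @return a stochastic \code{wcfg} with exact rational weights.
#' @export
train <- function(g, db, pseudocount = 0) {
  if (length(db) == 0) stop("empty training database")
  pc <- rq(pseudocount)
  rc <- rule_counts(g, db)
  premises <- rc$premises
  k_of <- table(premises)
  rules <- g$rules
  for (i in seq_along(rules)) {
    p <- premises[[i]]
    total <- rc$premise_totals[[p]]
    k <- as.numeric(k_of[[p]])
    if (total == 0 && bn_is_zero(pc$num)) next  # uniform fallback below
    num <- rq_add(rq(rc$counts[[i]]), pc)
    den <- rq_add(rq(total), rq_mul(pc, rq(k)))
    rules[[i]]$weight <- rq_reduce(new_rq(bn_mul(num$num, den$den),
                                          bn_mul(num$den, den$num)))
  }
  unseen <- unique(premises[rc$premise_totals[premises] == 0])
  if (length(unseen) && bn_is_zero(pc$num)) {
    warning("premise(s) never observed, assigned uniform weights: ",
            paste(unseen, collapse = ", "))
    for (i in seq_along(rules)) {
      p <- premises[[i]]
      if (p %in% unseen) rules[[i]]$weight <- rq(1, as.numeric(k_of[[p]]))
    }
  }
  wcfg(g$nonterminals, g$axiom, rules, terminals = g$terminals,
       stochastic = TRUE, allow_epsilon = TRUE, allow_zero = TRUE,
       weight_mode = "rational")
}

#' Stability of trained probabilities under subsampling
#'
#' Draws \code{reps} random subsets of floor(fraction * |db|) structures
#' without replacement, retrains on each, and reports the per-rule sample
#' variance of the recovered probabilities.
#'
#' @param g the grammar.
#' @param db structure database.
#' @param fraction subset fraction in (0, 1].
#' @param reps number of repetitions (>= 2).
#' @param seed RNG seed.
#' @return numeric vector of per-rule variances (names = rule ids).
#' @export
subsample_stability <- function(g, db, fraction, reps, seed = 1) {
  if (reps < 2) stop("variance needs reps >= 2")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  size <- floor(fraction * length(db))
  if (size == 0) stop("fraction yields an empty subset")
  m <- rule_count_matrix(g, db)
  premises <- vapply(g$rules, `[[`, "", "premise")
  set.seed(seed)
  probs <- matrix(NA_real_, nrow = reps, ncol = ncol(m))
  for (rep in seq_len(reps)) {
    idx <- sample.int(length(db), size)
    counts <- colSums(m[idx, , drop = FALSE])
    totals <- tapply(counts, premises, sum)
    denom <- as.numeric(totals[premises])
    probs[rep, ] <- ifelse(denom > 0, counts / denom, NA_real_)
  }
  v <- apply(probs, 2, function(x) stats::var(x[!is.na(x)]))
  # rules whose premise has a single production are exactly constant
  single <- premises %in% names(which(table(premises) == 1))
  v[single] <- 0
  stats::setNames(v, vapply(g$rules, function(r) as.character(r$id), ""))
}

# --- ancestral sampling from a stochastic grammar ----------------------------

encode_grammar <- function(g) {
  nts <- g$nonterminals
  nt_idx <- stats::setNames(seq_along(nts) - 1L, nts)
  term_code <- c("(" = -1L, ")" = -2L, "|" = -3L)
  ord <- order(match(vapply(g$rules, `[[`, "", "premise"), nts),
               vapply(g$rules, `[[`, 0L, "id"))
  rules <- g$rules[ord]
  grp <- integer(length(nts) + 1)
  cum <- numeric(length(rules))
  rhs_off <- integer(length(rules) + 1)
  rhs_flat <- integer(0)
  rid <- integer(length(rules))
  pos <- 0L
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    rid[i] <- r$id
    codes <- vapply(r$conclusion, function(s)
      if (s %in% names(term_code)) term_code[[s]] else nt_idx[[s]], 0L)
    rhs_off[i] <- pos
    rhs_flat <- c(rhs_flat, codes)
    pos <- pos + length(codes)
  }
  rhs_off[length(rules) + 1] <- pos
  premf <- vapply(rules, `[[`, "", "premise")
  for (k in seq_along(nts)) grp[k] <- match(TRUE, premf == nts[k]) - 1L
  grp[length(nts) + 1] <- length(rules)
  # cumulative probabilities per premise group
  for (k in seq_along(nts)) {
    rng <- (grp[k] + 1):(grp[k + 1])
    w <- vapply(rules[rng], function(r) rq_to_double(r$weight), 0)
    cum[rng] <- cumsum(w)
  }
  list(axiom = nt_idx[[g$axiom]], grp = grp, cumprob = cum, rule_id = rid,
       rhs_flat = rhs_flat, rhs_off = rhs_off, nrules = length(rules))
}

#' Draw structures by ancestral (top-down) sampling from an SCFG
#'
#' Expands the leftmost nonterminal according to the rule probabilities until
#' only terminals remain; words come out i.i.d. from the unconditional
#' distribution the grammar induces, with sizes distributed as in the
#' training data. Randomness flows through R's RNG: call \code{set.seed}
#' first (or pass \code{seed}) for reproducibility.
#'
#' @param g a stochastic \code{wcfg}.
#' @param m number of structures.
#' @param seed optional seed applied before sampling.
#' @param max_len abort if a single word exceeds this many symbols.
#' @return list with \code{words} (character vector) and \code{counts}
#'   (m x nrules matrix of rule usages of the sampled derivations, columns
#'   in rule-id order).
#' @export
sample_grammar <- function(g, m, seed = NULL, max_len = 1e7) {
  if (!g$stochastic) stop("ancestral sampling needs a stochastic grammar")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_grammar(g)
  out <- scfg_sample_(as.integer(m), enc$axiom, enc$grp, enc$cumprob,
                      enc$rule_id, enc$rhs_flat, enc$rhs_off, enc$nrules,
                      max_len)
  # columns of counts are in rule_id positions already (1-based ids)
  out
}
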