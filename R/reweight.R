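# Rational-to-integer reweighting.
#
# In reweighting normal form the relative weight of every word is preserved
# when axiom rules are scaled by a common factor s and every other rule
# A -> alpha by c^(|alpha|-1): a word of size n accumulates exactly
# s * c^(n-1) regardless of its derivation, so weight ratios of same-size
# words are unchanged.  s and c are the least common multiples of the
# reduced weight denominators (axiom rules, resp. all other rules).

#' Round all rule weights to a fixed number of decimals
#'
#' Rounding is half away from zero; results are stored as exact rationals
#' with denominator 10^digits. A weight that would round to zero would
#' silently delete words from the weighted language, so the precision is
#' escalated grammar-wide until every weight stays positive.
#'
#' @param g a \code{wcfg} with rational weights.
#' @param digits decimal places (>= 1).
#' @return a new \code{wcfg}; the digits actually used are attached as
#'   attribute \code{"digits"}.
#' @export
round_weights <- function(g, digits = 4) {
  if (digits < 1) stop("digits must be >= 1")
  for (r in g$rules) {
    if (bn_is_zero(r$weight$num))
      stop("rule ", r$id, " has weight exactly 0 (unused in training); ",
           "retrain with a pseudocount before reweighting")
  }
  repeat {
    rounded <- lapply(g$rules, function(r) rq_round(r$weight, digits))
    if (!any(vapply(rounded, function(q) bn_is_zero(q$num), TRUE))) break
    digits <- digits + 1
  }
  rules <- g$rules
  for (i in seq_along(rules)) rules[[i]]$weight <- rounded[[i]]
  out <- wcfg(g$nonterminals, g$axiom, rules, terminals = g$terminals,
              weight_mode = "rational")
  attr(out, "digits") <- digits
  out
}

#' Smallest common denominators of the rule weights
#'
#' @param g a \code{wcfg} with rational weights.
#' @return list with bignats \code{s} (least common multiple of the reduced
#'   denominators of the axiom rules) and \code{c} (same over all other
#'   rules).
#' @export
common_denominators <- function(g) {
  s <- bn(1); cc <- bn(1)
  for (r in g$rules) {
    if (r$premise == g$axiom) s <- bn_lcm(s, r$weight$den)
    else cc <- bn_lcm(cc, r$weight$den)
  }
  list(s = s, c = cc)
}

#' Convert RNF rational weights to integers
#'
#' Axiom rules get weight lambda * s; every other rule A -> alpha gets
#' lambda * c^(|alpha|-1). Requires the grammar to be in reweighting normal
#' form: any non-axiom rule with a conclusion of length 1 must already carry
#' an integral weight (chain rules have weight 1), since c^0 = 1 cannot clear
#' a denominator.
#'
#' @param g a \code{wcfg} in RNF with rational weights (typically the output
#'   of \code{\link{round_weights}}).
#' @return an object of class \code{reweight_report}: \code{s}, \code{c}
#'   (bignats), \code{digits} (attribute carried over if present, else NA)
#'   and \code{result}, the integer-weighted grammar.
#' @export
reweight <- function(g) {
  for (r in g$rules) {
    if (r$premise != g$axiom && length(r$conclusion) == 1 &&
        !rq_is_integer(r$weight))
      stop("RNF violation: non-axiom unit rule ", r$id,
           " has non-integral weight ", as.character(r$weight))
    if (r$premise == g$axiom && length(r$conclusion) > 1)
      stop("RNF violation: axiom rule ", r$id, " has |conclusion| > 1")
  }
  cd <- common_denominators(g)
  rules <- g$rules
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    mu <- if (r$premise == g$axiom) {
      rq_scale_to_bn(r$weight, cd$s, 1)
    } else {
      rq_scale_to_bn(r$weight, cd$c, length(r$conclusion) - 1)
    }
    rules[[i]]$weight <- rq(mu, bn(1))
  }
  result <- wcfg(g$nonterminals, g$axiom, rules, terminals = g$terminals,
                 weight_mode = "integer")
  structure(list(s = cd$s, c = cd$c,
                 digits = attr(g, "digits") %||% NA,
                 result = result),
            class = "reweight_report")
}

#' @export
print.reweight_report <- function(x, ...) {
  cat("<reweight_report> s =", as.character(x$s), " c =", as.character(x$c),
      " digits =", x$digits, "\n")
  invisible(x)
}

#' Integer weight of a rule after reweighting
#'
#' @param rep a \code{reweight_report}.
#' @param id rule id in the reweighted grammar.
#' @return the integer weight as a bignat.
#' @export
integer_weight <- function(rep, id) {
  weight_of(rep$result, id = id)$num
}

#' Serialize a reweight report to JSON
#' @param rep a \code{reweight_report}.
#' @param path optional output file.
#' @export
write_reweight_report_json <- function(rep, path = NULL) {
  obj <- list(s = as.character(rep$s), c = as.character(rep$c),
              digits = rep$digits,
              mu = lapply(rep$result$rules, function(r) list(
                id = r$id, premise = r$premise,
                conclusion = paste(r$conclusion, collapse = " "),
                weight = as.character(r$weight$num))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
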