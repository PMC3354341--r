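# Dot-bracket secondary structures.
#
# Canonical dialect is the bar-bracket alphabet: '|' for an unpaired base,
# '(' ')' for a base pair.  The Vienna dot dialect ('.' for unpaired) is
# converted on input.  A valid structure is balanced, properly nested, every
# hairpin loop holds at least 3 unpaired bases, and at least one pair exists
# (completely unpaired words are excluded from the language).

#' Parse and validate a dot-bracket secondary structure
#'
#' @param text a single line in bar-bracket or dot-bracket notation.
#' @param dialect "bar", "dot", or "auto" (detect from the characters used;
#'   a word may not mix '.' and '|').
#' @return an object of class \code{secstruct}: the canonical bar-dialect
#'   word, its length, and the 0-based pair list.
#' @examples
#' parse_dotbracket("(|||)")
#' parse_dotbracket("..((...))", dialect = "dot")
#' @export
parse_dotbracket <- function(text, dialect = c("auto", "bar", "dot")) {
  dialect <- match.arg(dialect)
  w <- gsub("[[:space:]]", "", text)
  if (nchar(w) == 0) stop("empty structure line")
  has_dot <- grepl(".", w, fixed = TRUE)
  has_bar <- grepl("|", w, fixed = TRUE)
  if (has_dot && has_bar) stop("structure mixes '.' and '|' dialects")
  if (dialect == "auto") dialect <- if (has_dot) "dot" else "bar"
  if (dialect == "dot") {
    if (has_bar) stop("'|' found but dialect is 'dot'")
    w <- gsub(".", "|", w, fixed = TRUE)
  } else if (has_dot) {
    stop("'.' found but dialect is 'bar'")
  }
  pt <- pair_table_(w)
  if (!pt$ok) stop("invalid structure at position ", pt$err_pos, ": ", pt$err_msg)
  new_secstruct(w, pt$partner)
}

new_secstruct <- function(word, partner) {
  op <- which(partner >= 0 & seq_along(partner) - 1L < partner)
  pairs <- cbind(open = op - 1L, close = partner[op])
  structure(list(word = word, length = nchar(word),
                 pairs = pairs, partner = as.integer(partner)),
            class = "secstruct")
}

#' @export
print.secstruct <- function(x, ...) {
  cat("<secstruct> n =", x$length, "pairs =", nrow(x$pairs), "\n ", x$word, "\n")
  invisible(x)
}

#' Render a structure back to text
#' @param s a \code{secstruct}.
#' @param dialect output dialect, "bar" (canonical) or "dot".
#' @return a character scalar.
#' @export
render_structure <- function(s, dialect = c("bar", "dot")) {
  dialect <- match.arg(dialect)
  if (dialect == "dot") gsub("|", ".", s$word, fixed = TRUE) else s$word
}

#' @export
as.character.secstruct <- function(x, ...) x$word

#' Exhaustively enumerate the structure language
#'
#' Brute-force oracle: all valid secondary structures of size n (balanced,
#' minimum hairpin 3, at least one pair), in lexicographic word order under
#' the byte ordering '(' < ')' < '|'. Guarded by an oracle bound because the
#' language grows exponentially.
#'
#' @param n word length.
#' @param oracle_bound refuse n above this (default 16).
#' @return character vector of all members of the language at size n.
#' @examples
#' enumerate_language(5)  # "(|||)"
#' @export
enumerate_language <- function(n, oracle_bound = 16) {
  if (n > oracle_bound)
    stop("n = ", n, " above the enumeration oracle bound (", oracle_bound, ")")
  memo_w <- new.env(parent = emptyenv())
  memo_p <- new.env(parent = emptyenv())
  # W(k): sequences of '|' and '(p)' with p a valid pair content
  W <- function(k) {
    key <- as.character(k)
    if (!is.null(memo_w[[key]])) return(memo_w[[key]])
    out <- if (k == 0) "" else {
      acc <- paste0("|", W(k - 1))
      if (k >= 5) {
        for (inner in 3:(k - 2)) {
          wrapped <- paste0("(", P(inner), ")")
          rest <- W(k - inner - 2)
          acc <- c(acc, as.vector(outer(wrapped, rest, paste0)))
        }
      }
      acc
    }
    memo_w[[key]] <- out
    out
  }
  # P(k): valid contents of a pair: contains a pair itself, or >= 3 bars
  P <- function(k) {
    key <- as.character(k)
    if (!is.null(memo_p[[key]])) return(memo_p[[key]])
    cand <- W(k)
    out <- cand[grepl("(", cand, fixed = TRUE)]
    if (k >= 3) out <- c(out, strrep("|", k))
    memo_p[[key]] <- out
    out
  }
  if (n < 5) return(character(0))
  words <- W(n)
  sort(words[grepl("(", words, fixed = TRUE)], method = "radix")
}
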