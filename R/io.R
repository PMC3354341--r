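# Structure-database I/O and fixtures.

#' Read a structure database from a plain-text file
#'
#' One structure per line; lines starting with '>' or '#' (and blank lines)
#' are skipped. Both dialects are accepted and auto-detected per file; a
#' file may not mix '.' and '|'.
#'
#' @param path input file.
#' @param strict if TRUE any invalid line aborts with its line number; if
#'   FALSE invalid lines are dropped and collected in attribute
#'   \code{"errors"}.
#' @return list of \code{secstruct}.
#' @examples
#' f <- system.file("extdata", "example_structures.txt", package = "rnaunrank")
#' length(read_structure_db(f))
#' @export
read_structure_db <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|[>#])", lines)
  idx <- which(keep)
  body <- lines[keep]
  has_dot <- any(grepl(".", body, fixed = TRUE))
  has_bar <- any(grepl("|", body, fixed = TRUE))
  if (has_dot && has_bar) stop("file mixes '.' and '|' dialects: ", path)
  dialect <- if (has_dot) "dot" else "bar"
  out <- list()
  errors <- character(0)
  for (k in seq_along(body)) {
    s <- tryCatch(parse_dotbracket(body[[k]], dialect = dialect),
                  error = function(e) e)
    if (inherits(s, "error")) {
      msg <- paste0(path, ":", idx[k], ": ", conditionMessage(s))
      if (strict) stop(msg)
      errors <- c(errors, msg)
    } else {
      out[[length(out) + 1]] <- s
    }
  }
  attr(out, "errors") <- errors
  out
}

#' Write structures to a plain-text file
#' @param db list of \code{secstruct} (or character words).
#' @param path output file.
#' @param dialect "bar" or "dot".
#' @export
write_structure_db <- function(db, path, dialect = c("bar", "dot")) {
  dialect <- match.arg(dialect)
  words <- vapply(db, function(s) if (is.character(s)) s else s$word, "")
  if (dialect == "dot") words <- gsub("|", ".", words, fixed = TRUE)
  writeLines(words, path)
  invisible(path)
}

#' Specification of a synthetic fixture database
#'
#' @param grammar a stochastic \code{wcfg} (defaults to the bundled detailed
#'   grammar) whose distribution the fixture emulates.
#' @param sizes two-column matrix or list of c(size, count) pairs; all sizes
#'   must be >= 5 and counts >= 1. NULL requests ancestral sampling with the
#'   grammar's own size distribution.
#' @param count number of structures when \code{sizes} is NULL.
#' @param seed RNG seed.
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(grammar = load_builtin("Gsto_hat"), sizes = NULL,
                         count = 1000, seed = 1) {
  if (!is.null(sizes)) {
    sizes <- do.call(rbind, lapply(sizes, function(x) c(x[[1]], x[[2]])))
    if (any(sizes[, 1] < 5)) stop("all fixture sizes must be >= 5")
    if (any(sizes[, 2] < 1)) stop("all fixture counts must be >= 1")
  }
  structure(list(grammar = grammar, sizes = sizes, count = count, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic structure database from a known grammar
#'
#' The fixture stands in for a real training database so that training and
#' parameter recovery are testable offline. With \code{sizes = NULL} the
#' structures are drawn by ancestral sampling (mixed sizes, the grammar's
#' own unconditional distribution); with fixed sizes they are drawn by
#' weighted unranking through the full pipeline (normal form, reweighting,
#' class sizes). Deterministic given the seed.
#'
#' @param fx a \code{fixture_spec}.
#' @param path optional output file (plain text, canonical dialect).
#' @param pipeline optional prebuilt list(spec, table) to reuse across calls.
#' @return character vector of words (invisibly also written to path).
#' @export
generate_fixture_db <- function(fx, path = NULL, pipeline = NULL) {
  set.seed(fx$seed)
  if (is.null(fx$sizes)) {
    words <- sample_grammar(fx$grammar, fx$count)$words
  } else {
    if (is.null(pipeline)) pipeline <- build_pipeline(fx$grammar,
                                                      N = max(fx$sizes[, 1]))
    words <- character(0)
    for (r in seq_len(nrow(fx$sizes))) {
      words <- c(words, sample_structures(pipeline$spec, pipeline$table,
                                          n = fx$sizes[r, 1],
                                          m = fx$sizes[r, 2]))
    }
  }
  if (!is.null(path)) writeLines(words, path)
  invisible(words)
}

#' Run the full preprocessing pipeline of the sampler
#'
#' Normal form, 4-decimal rounding, integer reweighting, translation into
#' weighted classes, and exact size tables up to N. Logged at each stage
#' boundary with the quantities needed to reproduce any sample.
#'
#' @param g a stochastic grammar (rational weights).
#' @param N maximum structure size for the tables.
#' @param digits rounding precision for the normal-form weights.
#' @param verbose log stage boundaries via \code{message}.
#' @return list with \code{rnf} (report), \code{reweighted} (report),
#'   \code{spec} and \code{table}.
#' @export
build_pipeline <- function(g, N, digits = 4, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  rep_rnf <- to_rnf(g)
  say("rnf: ", length(rep_rnf$chains), " chains, ",
      rep_rnf$main_rule_count, " main rules, fingerprint ",
      grammar_fingerprint(rep_rnf$result))
  rounded <- round_weights(rep_rnf$result, digits)
  rep_rw <- reweight(rounded)
  say("reweight: s = ", as.character(rep_rw$s), ", c = ",
      as.character(rep_rw$c), ", digits = ", rep_rw$digits)
  spec <- grammar_to_spec(rep_rw$result)
  table <- build_tables(spec, N)
  say("tables: N = ", N, ", fingerprint ", spec$fingerprint)
  list(rnf = rep_rnf, reweighted = rep_rw, spec = spec, table = table)
}
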