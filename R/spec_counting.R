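# Weighted combinatorial classes.
#
# An integer-weighted RNF grammar translates into an admissible
# specification: one atomic class per terminal, one binary-product chain per
# multi-symbol conclusion (right-associated), and one weighted disjoint
# union per nonterminal whose summands are the rule classes with the integer
# rule weights as multiplicities.  Chain nonterminals (single weight-1 unit
# rule) are collapsed onto their targets, which reproduces the simplified
# specification: duplicated product classes are shared.
#
# size(class, n) follows the standard recursion -- atomic classes contribute
# at size 1, unions sum weight * size(part), products convolve over the
# split sizes -- in exact big-natural arithmetic.

atom_class <- function(sym) paste0("atom:", sym)

#' Translate an integer-weighted RNF grammar into an admissible specification
#'
#' @param g an integer-weighted \code{wcfg} in RNF.
#' @return an object of class \code{adm_spec}: named classes (atoms, binary
#'   products, weighted unions), the root class (the axiom), the same-size
#'   evaluation order, and the grammar fingerprint.
#' @export
grammar_to_spec <- function(g) {
  for (r in g$rules) {
    if (!rq_is_integer(r$weight))
      stop("grammar_to_spec needs integer weights (rule ", r$id, ")")
  }
  # chain collapse: nonterminal with a single weight-1 unit rule is an alias
  # for its target
  alias <- list()
  for (a in g$nonterminals) {
    rs <- rules_of(g, a)
    if (length(rs) == 1 && length(rs[[1]]$conclusion) == 1 &&
        rq_is_one(rs[[1]]$weight) && a != g$axiom) {
      alias[[a]] <- rs[[1]]$conclusion
    }
  }
  resolve <- function(sym) {
    seen <- character(0)
    while (!is.null(alias[[sym]])) {
      if (sym %in% seen) stop("alias cycle through ", sym)
      seen <- c(seen, sym)
      sym <- alias[[sym]]
    }
    sym
  }
  classes <- list()
  class_of_symbol <- function(sym) {
    sym <- resolve(sym)
    if (is_terminal(g, sym)) {
      nm <- atom_class(sym)
      if (is.null(classes[[nm]]))
        classes[[nm]] <<- list(kind = "atom", sym = sym)
      nm
    } else sym
  }
  product_class <- function(left, right) {
    nm <- paste0("(", left, ".", right, ")")
    if (is.null(classes[[nm]]))
      classes[[nm]] <<- list(kind = "product", left = left, right = right)
    nm
  }
  conclusion_class <- function(conc) {
    parts <- vapply(conc, class_of_symbol, "")
    out <- parts[[length(parts)]]
    if (length(parts) >= 2) {
      for (k in (length(parts) - 1):1) out <- product_class(parts[[k]], out)
    }
    out
  }
  for (a in g$nonterminals) {
    if (!is.null(alias[[a]])) next
    parts <- list()
    for (r in rules_of(g, a)) {
      parts[[length(parts) + 1]] <- list(w = r$weight$num,
                                         part = conclusion_class(r$conclusion))
    }
    classes[[a]] <- list(kind = "union", parts = parts)
  }
  spec <- structure(list(classes = classes, root = resolve(g$axiom),
                         order = NULL, fingerprint = grammar_fingerprint(g)),
                    class = "adm_spec")
  spec$order <- spec_topo_order(spec)
  spec
}

# evaluation order at a fixed size: products and atoms first (they only read
# strictly smaller sizes), then unions so that same-size references (unions
# pointing at unions through length-1 summands) are resolved first
spec_topo_order <- function(spec) {
  names_all <- names(spec$classes)
  unions <- names_all[vapply(names_all, function(nm)
    spec$classes[[nm]]$kind == "union", TRUE)]
  non_unions <- setdiff(names_all, unions)
  # same-size dependency among unions: a union depends on any part that is
  # itself a union (a product part only reads smaller sizes... but a
  # length-1 summand pointing at a product still reads size n: products are
  # computed before unions, so only union->union edges need ordering)
  done <- character(0); remaining <- unions; order <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      deps <- vapply(spec$classes[[nm]]$parts, `[[`, "", "part")
      deps <- deps[deps %in% unions]
      all(deps %in% done)
    }, TRUE)]
    if (!length(ready)) stop("cyclic same-size dependency among unions")
    done <- c(done, ready); order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  c(non_unions, order)
}

#' @export
print.adm_spec <- function(x, ...) {
  kinds <- vapply(x$classes, `[[`, "", "kind")
  cat("<adm_spec>", sum(kinds == "union"), "unions,",
      sum(kinds == "product"), "products,", sum(kinds == "atom"),
      "atoms; root", x$root, "\n")
  invisible(x)
}

#' Build the exact size tables of all classes up to size N
#'
#' The preprocessing step of the unranking method: size(class, n) for every
#' class and every n in 0..N, as exact big naturals. Work is quadratic in N
#' for a fixed specification (one convolution per product class and size).
#'
#' @param spec an \code{adm_spec}.
#' @param N maximum size.
#' @return an object of class \code{size_table}.
#' @export
build_tables <- function(spec, N) {
  tbl <- new.env(parent = emptyenv())
  zero <- bn_zero(); one <- bn_one()
  for (nm in names(spec$classes)) {
    v <- vector("list", N + 1)
    for (i in seq_len(N + 1)) v[[i]] <- zero
    tbl[[nm]] <- v
  }
  for (n in 0:N) {
    for (nm in spec$order) {
      cl <- spec$classes[[nm]]
      val <- switch(cl$kind,
        atom = if (n == 1) one else zero,
        product = {
          lv <- tbl[[cl$left]]; rv <- tbl[[cl$right]]
          if (spec$classes[[cl$left]]$kind == "atom") {
            if (n >= 1) rv[[n]] else zero   # rv[[n]] = size(right, n-1)
          } else if (spec$classes[[cl$right]]$kind == "atom") {
            if (n >= 1) lv[[n]] else zero
          } else if (n >= 2) {
            js <- 1:(n - 1)
            bn_dot(lv[js + 1], rv[n - js + 1])
          } else zero
        },
        union = {
          ws <- lapply(cl$parts, `[[`, "w")
          ss <- lapply(cl$parts, function(p) tbl[[p$part]][[n + 1]])
          bn_dot(ws, ss)
        })
      v <- tbl[[nm]]
      v[[n + 1]] <- val
      tbl[[nm]] <- v
    }
  }
  structure(list(values = as.list(tbl), N = N,
                 fingerprint = spec$fingerprint),
            class = "size_table")
}

#' Exact weighted class size
#'
#' @param spec an \code{adm_spec}.
#' @param class class name (a nonterminal, product class, or atom class);
#'   defaults to the root.
#' @param n object size.
#' @param table a prebuilt \code{size_table} (built on demand otherwise).
#' @return the exact count as a bignat.
#' @export
class_size <- function(spec, class = spec$root, n, table = NULL) {
  if (is.null(table)) table <- build_tables(spec, n)
  if (table$fingerprint != spec$fingerprint)
    stop("size table was built for a different grammar (stale fingerprint)")
  if (n > table$N) stop("size table only covers sizes up to ", table$N)
  v <- table$values[[class]]
  if (is.null(v)) stop("unknown class: ", class)
  v[[n + 1]]
}

#' @export
print.size_table <- function(x, ...) {
  cat("<size_table>", length(x$values), "classes, N =", x$N,
      ", fingerprint", x$fingerprint, "\n")
  invisible(x)
}

#' Persist a size table as JSON lines
#'
#' Header line: fingerprint and N (plus any extra metadata supplied); then
#' one line per nonzero entry with the exact decimal value.
#'
#' @param table a \code{size_table}.
#' @param path output file.
#' @param meta optional named list stored in the header (s, c, digits, ...).
#' @export
save_size_table <- function(table, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(list(fingerprint = table$fingerprint, N = table$N), meta)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE), con)
  for (nm in names(table$values)) {
    v <- table$values[[nm]]
    for (n in 0:table$N) {
      if (!bn_is_zero(v[[n + 1]])) {
        writeLines(jsonlite::toJSON(list(class = nm, n = n,
                                         value = as.character(v[[n + 1]])),
                                    auto_unbox = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Load a persisted size table
#'
#' @param path file written by \code{\link{save_size_table}}.
#' @param spec if supplied, the fingerprint is checked and a mismatch is an
#'   error (stale tables are refused).
#' @return a \code{size_table}.
#' @export
load_size_table <- function(path, spec = NULL) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE)
  if (!is.null(spec) && header$fingerprint != spec$fingerprint)
    stop("size table was built for a different grammar (stale fingerprint)")
  values <- list()
  N <- header$N
  zero <- bn_zero()
  blank <- { v <- vector("list", N + 1); for (i in seq_len(N + 1)) v[[i]] <- zero; v }
  for (ln in lines[-1]) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (is.null(values[[rec$class]])) values[[rec$class]] <- blank
    values[[rec$class]][[rec$n + 1]] <- bn(rec$value)
  }
  structure(list(values = values, N = N, fingerprint = header$fingerprint,
                 meta = header),
            class = "size_table")
}
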