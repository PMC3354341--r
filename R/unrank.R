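# Weighted unranking.
#
# Ranks are 0-based big naturals below size(class, n).  The order within a
# class is induced by the specification: union summands in listing order
# with the lambda weight copies copy-major (copy index = rank div part size,
# element = rank mod part size); products ordered by the split size j of the
# left component, scanning j either sequentially (0, 1, ..., n) or in
# boustrophedon order (0, n, 1, n-1, ...), left component major inside a
# block.  The boustrophedon scan bounds the probes per unranking by
# O(n log n) because a block at split j costs min(j, n-j) probes.

split_order <- function(n, order) {
  if (order == "sequential") return(0:n)
  out <- as.vector(rbind(0:n, n:0))
  unique(out)[seq_len(n + 1)]
}

# split orders are queried once per product probe; cache per (order, n)
split_cache <- new.env(parent = emptyenv())
split_order_cached <- function(n, order) {
  key <- paste0(order, n)
  v <- split_cache[[key]]
  if (is.null(v)) {
    v <- split_order(n, order)
    split_cache[[key]] <- v
  }
  v
}

#' Unrank one object of a weighted class
#'
#' Returns the object with 0-based rank \code{i} among the size-n objects of
#' the class, under the chosen scan order. Weighted copies of one object
#' occupy distinct ranks.
#'
#' @param spec an \code{adm_spec}.
#' @param table a \code{size_table} built to at least n.
#' @param class class name (default: the root).
#' @param n object size.
#' @param i rank: bignat, numeric, or decimal string; 0 <= i < size(class,n).
#' @param order "boustrophedon" (default) or "sequential".
#' @param probes optional environment; if supplied, \code{probes$count} is
#'   incremented once per convolution block probed (used for the work-bound
#'   experiments).
#' @return the bar-bracket word (character scalar).
#' @export
unrank_class <- function(spec, table, class = spec$root, n, i,
                         order = c("boustrophedon", "sequential"),
                         probes = NULL) {
  order <- match.arg(order)
  i <- bn(i)
  total <- class_size(spec, class, n, table)
  if (!bn_lt(i, total))
    stop("rank out of range: ", as.character(i), " >= ", as.character(total))
  unrank_rec(spec, table, class, n, i, order, probes)
}

# hot path: iterative with an explicit work stack (structures can nest or
# chain n deep, which would blow the C stack through R recursion), working
# on bare limb vectors via the C entry points directly
unrank_rec <- function(spec, table, class, n, i, order, probes) {
  out <- character(0)
  stack <- list(list(class, n, i))
  classes <- spec$classes
  values <- table$values
  while (length(stack)) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cl <- classes[[task[[1]]]]
    n <- task[[2]]
    i <- task[[3]]
    if (cl$kind == "atom") {
      out[length(out) + 1] <- cl$sym
      next
    }
    if (cl$kind == "union") {
      placed <- FALSE
      for (p in cl$parts) {
        sz <- values[[p$part]][[n + 1]]
        if (length(sz) == 0L) next
        block <- bn_mul_(p$w, sz)
        if (bn_cmp_(i, block) < 0L) {
          elem <- bn_divmod_(i, sz)$r  # copy index i div sz is discarded
          stack[[length(stack) + 1]] <- list(p$part, n, elem)
          placed <- TRUE
          break
        }
        i <- bn_sub_(i, block)
      }
      if (!placed) stop("internal: union rank exhausted")
      next
    }
    # product
    lv <- values[[cl$left]]
    rv <- values[[cl$right]]
    placed <- FALSE
    for (j in split_order_cached(n, order)) {
      szl <- lv[[j + 1]]
      if (length(szl) == 0L) next
      szr <- rv[[n - j + 1]]
      if (length(szr) == 0L) next
      if (!is.null(probes)) probes$count <- probes$count + 1
      block <- bn_mul_(szl, szr)
      if (bn_cmp_(i, block) < 0L) {
        dm <- bn_divmod_(i, szr)
        # right below left so the left component is emitted first
        stack[[length(stack) + 1]] <- list(cl$right, n - j, dm$r)
        stack[[length(stack) + 1]] <- list(cl$left, j, dm$q)
        placed <- TRUE
        break
      }
      i <- bn_sub_(i, block)
    }
    if (!placed) stop("internal: product rank exhausted")
  }
  paste(out, collapse = "")
}

#' Uniform random big-natural rank below a bound
#'
#' Rejection sampling on fixed-width random bit blocks: draw bitlen(bound)
#' bits, reject values >= bound (acceptance probability > 1/2). Unbiased for
#' arbitrary-precision bounds; consumes R's RNG stream.
#'
#' @param bound a bignat > 0.
#' @return a bignat uniform on {0, ..., bound - 1}.
#' @export
random_rank <- function(bound) {
  k <- bn_bitlen(bound)
  if (k == 0) stop("empty range")
  repeat {
    bits <- as.integer(stats::runif(k) < 0.5)
    r <- new_bignat(bn_from_bits_(bits))
    if (bn_lt(r, bound)) return(r)
  }
}

#' Sample random structures of a fixed size
#'
#' Draws m i.i.d. structures of size n with probabilities proportional to
#' their integer word weights: a uniform rank below size(root, n) is drawn
#' and unranked. Deterministic given the seed.
#'
#' @param spec an \code{adm_spec} (from \code{\link{grammar_to_spec}}).
#' @param table size table built to at least n.
#' @param n structure size.
#' @param m number of samples.
#' @param order scan order, "boustrophedon" or "sequential".
#' @param seed optional seed applied before drawing.
#' @param as_structures if TRUE return parsed \code{secstruct} objects,
#'   otherwise bare words.
#' @return character vector (or list of \code{secstruct}).
#' @export
sample_structures <- function(spec, table, n, m,
                              order = c("boustrophedon", "sequential"),
                              seed = NULL, as_structures = FALSE) {
  order <- match.arg(order)
  if (!is.null(seed)) set.seed(seed)
  total <- class_size(spec, spec$root, n, table)
  if (bn_is_zero(total))
    stop("no structures of this size (size ", n, " class is empty)")
  words <- character(m)
  for (k in seq_len(m)) {
    words[k] <- unrank_rec(spec, table, spec$root, n, random_rank(total),
                           order, NULL)
  }
  if (as_structures) lapply(words, parse_dotbracket) else words
}

# --- ranking (inverse; used for round-trip validation) -----------------------

# memoized producibility of word fragments by classes
can_produce <- function(spec, env, class, word) {
  key <- paste0(class, ";", word)
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  cl <- spec$classes[[class]]
  out <- switch(cl$kind,
    atom = identical(word, cl$sym),
    union = {
      any(vapply(cl$parts, function(p) can_produce(spec, env, p$part, word), TRUE))
    },
    product = {
      n <- nchar(word)
      ok <- FALSE
      for (j in 1:max(1, n - 1)) {
        if (j >= n) break
        if (can_produce(spec, env, cl$left, substr(word, 1, j)) &&
            can_produce(spec, env, cl$right, substr(word, j + 1, n))) {
          ok <- TRUE
          break
        }
      }
      ok
    })
  env[[key]] <- out
  out
}

#' Rank of the first copy of a structure
#'
#' The minimal 0-based rank i with unrank(i) equal to the given word, under
#' the chosen order; the inverse of \code{\link{unrank_class}} up to weight
#' copies: unrank(rank(w)) == w always.
#'
#' @param spec an \code{adm_spec}.
#' @param table size table built to at least the word's size.
#' @param s a \code{secstruct}, or a bar-bracket word.
#' @param order scan order.
#' @param class class name (default: root).
#' @return the rank as a bignat.
#' @export
rank_structure <- function(spec, table, s,
                           order = c("boustrophedon", "sequential"),
                           class = spec$root) {
  order <- match.arg(order)
  word <- if (is.character(s)) parse_dotbracket(s)$word else s$word
  env <- new.env(parent = emptyenv())
  if (!can_produce(spec, env, class, word))
    stop("structure is not in the weighted language of this class")
  rank_rec(spec, table, env, class, word, order)
}

rank_rec <- function(spec, table, env, class, word, order) {
  cl <- spec$classes[[class]]
  n <- nchar(word)
  if (cl$kind == "atom") return(bn(0))
  if (cl$kind == "union") {
    acc <- bn(0)
    for (p in cl$parts) {
      sz <- table$values[[p$part]][[n + 1]]
      if (!bn_is_zero(sz) && can_produce(spec, env, p$part, word)) {
        # first copy: copy index 0
        return(bn_add(acc, rank_rec(spec, table, env, p$part, word, order)))
      }
      acc <- bn_add(acc, bn_mul(p$w, sz))
    }
    stop("internal: union does not produce the word")
  }
  lv <- table$values[[cl$left]]
  rv <- table$values[[cl$right]]
  acc <- bn(0)
  for (j in split_order(n, order)) {
    szl <- lv[[j + 1]]
    szr <- rv[[n - j + 1]]
    if (bn_is_zero(szl) || bn_is_zero(szr)) next
    wl <- substr(word, 1, j)
    wr <- substr(word, j + 1, n)
    if ((j == 0 || can_produce(spec, env, cl$left, wl)) &&
        (j == n || can_produce(spec, env, cl$right, wr)) && j > 0 && j < n) {
      rl <- rank_rec(spec, table, env, cl$left, wl, order)
      rr <- rank_rec(spec, table, env, cl$right, wr, order)
      return(bn_add(acc, bn_add(bn_mul(rl, szr), rr)))
    }
    acc <- bn_add(acc, bn_mul(szl, szr))
  }
  stop("internal: product does not produce the word")
}
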