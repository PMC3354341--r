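#' @useDynLib rnaunrank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- big naturals -----------------------------------------------------------
# A bignat is an integer vector of base-2^15 limbs (little-endian, class
# "bignat"); the arithmetic lives in src/bignum.cpp.  All counting and
# unranking quantities in this package are non-negative, so no sign is
# carried.

new_bignat <- function(limbs) structure(as.integer(limbs), class = "bignat")

#' Exact arbitrary-precision non-negative integers
#'
#' Construct a big natural from a non-negative integer-valued number or a
#' decimal string. These are the values used for all weighted class sizes
#' and ranks, where counts routinely exceed the range of doubles.
#'
#' @param x a single non-negative integer-valued numeric, a decimal string,
#'   or a bignat (returned unchanged).
#' @return an object of class \code{bignat}.
#' @examples
#' bn("340900000000")
#' bn(2)^10
#' @export
bn <- function(x) {
  if (inherits(x, "bignat")) return(x)
  if (is.character(x)) return(new_bignat(bn_from_string_(x)))
  new_bignat(bn_from_double_(as.numeric(x)))
}

bn_zero <- function() new_bignat(integer(0))
bn_one <- function() new_bignat(1L)
bn_is_zero <- function(x) length(unclass(x)) == 0L || all(unclass(x) == 0L)

bn_add <- function(a, b) new_bignat(bn_add_(a, b))
bn_sub <- function(a, b) new_bignat(bn_sub_(a, b))
bn_mul <- function(a, b) new_bignat(bn_mul_(a, b))
bn_cmp <- function(a, b) bn_cmp_(a, b)
bn_eq <- function(a, b) bn_cmp_(a, b) == 0L
bn_lt <- function(a, b) bn_cmp_(a, b) < 0L
bn_le <- function(a, b) bn_cmp_(a, b) <= 0L

bn_divmod <- function(a, b) {
  z <- bn_divmod_(a, b)
  list(q = new_bignat(z$q), r = new_bignat(z$r))
}
bn_div <- function(a, b) new_bignat(bn_divmod_(a, b)$q)
bn_mod <- function(a, b) new_bignat(bn_divmod_(a, b)$r)
bn_gcd <- function(a, b) new_bignat(bn_gcd_(a, b))
bn_bitlen <- function(a) bn_bitlen_(a)

#' @export
as.character.bignat <- function(x, ...) bn_to_string_(x)

#' @export
as.double.bignat <- function(x, ...) bn_to_double_(x)

#' @export
print.bignat <- function(x, ...) {
  cat("<bignat> ", bn_to_string_(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.bignat` <- function(e1, e2) bn_add(bn(e1), bn(e2))
#' @export
`-.bignat` <- function(e1, e2) bn_sub(bn(e1), bn(e2))
#' @export
`*.bignat` <- function(e1, e2) bn_mul(bn(e1), bn(e2))
#' @export
`^.bignat` <- function(e1, e2) bn_pow(bn(e1), as.numeric(e2))
#' @export
`==.bignat` <- function(e1, e2) bn_eq(bn(e1), bn(e2))
#' @export
`<.bignat` <- function(e1, e2) bn_lt(bn(e1), bn(e2))

bn_pow <- function(a, k) {
  stopifnot(k >= 0, k == floor(k))
  out <- bn_one()
  base <- a
  while (k > 0) {
    if (k %% 2 == 1) out <- bn_mul(out, base)
    base <- bn_mul(base, base)
    k <- k %/% 2
  }
  out
}

bn_lcm <- function(a, b) {
  if (bn_is_zero(a) || bn_is_zero(b)) return(bn_zero())
  bn_mul(bn_div(a, bn_gcd(a, b)), b)
}

# Sum of elementwise products; xs, ys are lists of bignats.
bn_dot <- function(xs, ys) new_bignat(bn_dot_(xs, ys))

# --- exact rationals --------------------------------------------------------
# Non-negative rationals num/den with bignat parts, always reduced, den >= 1.

new_rq <- function(num, den) structure(list(num = num, den = den), class = "rq")

#' Exact non-negative rational numbers
#'
#' Rule probabilities and reweighting-normal-form weights are carried as
#' exact rationals so that stochastic-consistency checks and the
#' rational-to-integer reweighting are free of floating point error.
#'
#' @param num numerator: non-negative integer-valued numeric, decimal
#'   string, bignat, or a string of the form \code{"a/b"}.
#' @param den denominator (positive); ignored when \code{num} is "a/b".
#' @return an object of class \code{rq}.
#' @examples
#' rq("137/6476")
#' rq(1, 3) + rq(2, 3)
#' @export
rq <- function(num, den = 1) {
  if (inherits(num, "rq")) return(num)
  if (is.character(num) && grepl("/", num, fixed = TRUE)) {
    parts <- strsplit(num, "/", fixed = TRUE)[[1]]
    return(rq_reduce(new_rq(bn(parts[[1]]), bn(parts[[2]]))))
  }
  rq_reduce(new_rq(bn(num), bn(den)))
}

rq_reduce <- function(q) {
  if (bn_is_zero(q$den)) stop("rational with zero denominator")
  if (bn_is_zero(q$num)) return(new_rq(bn_zero(), bn_one()))
  g <- bn_gcd(q$num, q$den)
  if (bn_eq(g, bn_one())) return(q)
  new_rq(bn_div(q$num, g), bn_div(q$den, g))
}

rq_mul <- function(a, b) rq_reduce(new_rq(bn_mul(a$num, b$num), bn_mul(a$den, b$den)))
rq_add <- function(a, b) {
  rq_reduce(new_rq(bn_add(bn_mul(a$num, b$den), bn_mul(b$num, a$den)),
                   bn_mul(a$den, b$den)))
}
rq_cmp <- function(a, b) bn_cmp(bn_mul(a$num, b$den), bn_mul(b$num, a$den))
rq_eq <- function(a, b) rq_cmp(a, b) == 0L
rq_is_one <- function(a) bn_eq(a$num, a$den)
rq_is_integer <- function(a) bn_eq(a$den, bn_one())
rq_to_double <- function(a) bn_to_double_(a$num) / bn_to_double_(a$den)

# round half away from zero to `digits` decimals, returned as an exact
# rational with denominator 10^digits (not reduced away, then reduced)
rq_round <- function(a, digits) {
  p <- bn_pow(bn(10), digits)
  # floor((2 * num * 10^d + den) / (2 * den))
  num2 <- bn_add(bn_mul(bn_mul(bn(2), a$num), p), a$den)
  k <- bn_div(num2, bn_mul(bn(2), a$den))
  rq_reduce(new_rq(k, p))
}

# exact product rational * c^k, which must come out integral
rq_scale_to_bn <- function(a, c_base, k) {
  num <- bn_mul(a$num, bn_pow(c_base, k))
  dm <- bn_divmod(num, a$den)
  if (!bn_is_zero(dm$r)) stop("reweighting did not produce an integer weight")
  dm$q
}

#' @export
print.rq <- function(x, ...) {
  cat("<rq> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.rq <- function(x, ...) {
  if (rq_is_integer(x)) bn_to_string_(x$num)
  else paste0(bn_to_string_(x$num), "/", bn_to_string_(x$den))
}

#' @export
as.double.rq <- function(x, ...) rq_to_double(x)

#' @export
`+.rq` <- function(e1, e2) rq_add(rq(e1), rq(e2))
#' @export
`*.rq` <- function(e1, e2) rq_mul(rq(e1), rq(e2))
#' @export
`==.rq` <- function(e1, e2) rq_eq(rq(e1), rq(e2))
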