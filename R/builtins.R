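# Bundled grammars.
#
# Gsto_hat is the detailed 54-rule SCFG over the bar-bracket alphabet whose
# nonterminals mirror the structural motifs of RNA secondary structure
# (exterior strands, helix initiation, hairpins, bulges, the four interior
# loop families, multiloop branching).  Its probabilities are the exact
# relative frequencies trained on the SSU/LSU rRNA database and are bundled
# here as exact rationals; the 3-decimal approximations commonly quoted
# alongside are reproduced by rounding (see tests).
#
# Gsto_hat_star_rational / _integer are the reweighting-normal-form
# companion: 73 main productions (4-decimal weights, respectively the
# integer weights obtained with s = c = 10,000) plus the 32 weight-1 chain
# productions.  Chain nonterminals are written "A{X,via}" for the collapsed
# derivation A => ... => X through the spelled intermediates.
#
# Gs is the small unambiguous structure grammar used for derivation-count
# cross-checks; Gd is the five-rule epsilon-free example grammar used to
# exercise the normal-form transformation.  Neither carries published
# numeric weights; stochastic placeholder weights are attached so that both
# are valid SCFGs.

r_ <- function(premise, conclusion, weight) {
  list(premise = premise,
       conclusion = if (identical(conclusion, "")) character(0)
                    else strsplit(conclusion, " ", fixed = TRUE)[[1]],
       weight = weight)
}

gsto_hat_rules <- function() {
  w <- gsto_hat_probs()
  defs <- gsto_hat_shapes()
  lapply(seq_along(defs), function(i)
    r_(defs[[i]][[1]], defs[[i]][[2]], rq(w[[i]])))
}

gsto_hat_shapes <- function() list(
  list("S'", "E"),       # 1
  list("E", "S"),        # 2
  list("E", "S C"),      # 3
  list("S", "A"),        # 4
  list("S", "T A"),      # 5
  list("T", "E"),        # 6
  list("T", "C"),        # 7
  list("C", "|"),        # 8
  list("C", "C |"),      # 9
  list("A", "( L )"),    # 10
  list("L", "A"),        # 11
  list("L", "M"),        # 12
  list("L", "P"),        # 13
  list("L", "Q"),        # 14
  list("L", "R"),        # 15
  list("L", "F"),        # 16
  list("L", "G"),        # 17
  list("G", "A |"),      # 18
  list("G", "A D"),      # 19
  list("G", "| A"),      # 20
  list("G", "D A"),      # 21
  list("D", "B |"),      # 22
  list("B", "|"),        # 23
  list("B", "B |"),      # 24
  list("F", "| | |"),    # 25
  list("F", "| | | |"),  # 26
  list("F", "| | | | H"),# 27
  list("H", "|"),        # 28
  list("H", "H |"),      # 29
  list("P", "| A |"),    # 30
  list("P", "| A | |"),  # 31
  list("P", "| | A |"),  # 32
  list("P", "| | A | |"),# 33
  list("Q", "| | O | |"),# 34
  list("Q", "| | V |"),  # 35
  list("R", "| O | |"),  # 36
  list("R", "| | W |"),  # 37
  list("V", "J O"),      # 38
  list("W", "J A"),      # 39
  list("O", "A K"),      # 40
  list("J", "|"),        # 41
  list("J", "J |"),      # 42
  list("K", "|"),        # 43
  list("K", "K |"),      # 44
  list("M", "X Y"),      # 45
  list("X", "A"),        # 46
  list("X", "U A"),      # 47
  list("Y", "Z"),        # 48
  list("Z", "X"),        # 49
  list("Z", "X N"),      # 50
  list("N", "Z"),        # 51
  list("N", "U"),        # 52
  list("U", "|"),        # 53
  list("U", "U |"))      # 54

gsto_hat_probs <- function() c(
  "1/1",
  "137/6476", "6339/6476",
  "177/12952", "12775/12952",
  "11086/12775", "1689/12775",
  "14367/148978", "134611/148978",
  "1/1",
  "605069/792975", "31912/792975", "4912/264325", "5821/158595",
  "1893/264325", "2723/31719", "38399/792975",
  "11667/38399", "7235/38399", "11831/38399", "7666/38399",
  "1/1",
  "4967/12748", "7781/12748",
  "3912/68075", "23208/68075", "8191/13615",
  "8191/40700", "32509/40700",
  "533/4912", "1053/4912", "2963/14736", "7015/14736",
  "4986/29105", "24119/29105",
  "2357/5679", "3322/5679",
  "1/1", "1/1", "1/1",
  "27441/84620", "57179/84620",
  "15731/53725", "37994/53725",
  "1/1",
  "6196/87035", "80839/87035",
  "1/1",
  "2812/55123", "52311/55123",
  "7737/17437", "9700/17437",
  "109939/518817", "408878/518817")

GSTO_NONTERMINALS <- c("S'", "E", "S", "T", "C", "A", "L", "G", "D", "B",
                       "F", "H", "P", "Q", "R", "V", "W", "O", "J", "K",
                       "M", "X", "Y", "Z", "N", "U")

# --- reweighting-normal-form companion ---------------------------------------

star_main_shapes <- function() list(
  list("S'", "E"),                  # 1
  list("S'", "E{S,}"),              # 2
  list("S'", "E{A,S}"),             # 3
  list("E", "S C"),                 # 4
  list("E", "S{A,} C"),             # 5
  list("E", "S C{|,}"),             # 6
  list("E", "S{A,} C{|,}"),         # 7
  list("S", "T{E,} A"),             # 8
  list("S", "T{C,} A"),             # 9
  list("S", "T{|,C} A"),            # 10
  list("S", "T{S,E} A"),            # 11
  list("S", "T{A,ES} A"),           # 12
  list("C", "C |"),                 # 13
  list("C", "C{|,} |"),             # 14
  list("A", "( L{A,} )"),           # 15
  list("A", "( L{M,} )"),           # 16
  list("A", "( L{P,} )"),           # 17
  list("A", "( L{Q,} )"),           # 18
  list("A", "( L{R,} )"),           # 19
  list("A", "( L{F,} )"),           # 20
  list("A", "( L{G,} )"),           # 21
  list("G", "A |"),                 # 22
  list("G", "A D"),                 # 23
  list("G", "| A"),                 # 24
  list("G", "D A"),                 # 25
  list("D", "B |"),                 # 26
  list("D", "B{|,} |"),             # 27
  list("B", "B |"),                 # 28
  list("B", "B{|,} |"),             # 29
  list("F", "| | |"),               # 30
  list("F", "| | | |"),             # 31
  list("F", "| | | | H"),           # 32
  list("F", "| | | | H{|,}"),       # 33
  list("H", "H |"),                 # 34
  list("H", "H{|,} |"),             # 35
  list("P", "| A |"),               # 36
  list("P", "| A | |"),             # 37
  list("P", "| | A |"),             # 38
  list("P", "| | A | |"),           # 39
  list("Q", "| | O | |"),           # 40
  list("Q", "| | V |"),             # 41
  list("R", "| O | |"),             # 42
  list("R", "| | W |"),             # 43
  list("V", "J O"),                 # 44
  list("V", "J{|,} O"),             # 45
  list("W", "J A"),                 # 46
  list("W", "J{|,} A"),             # 47
  list("O", "A K"),                 # 48
  list("O", "A K{|,}"),             # 49
  list("J", "J |"),                 # 50
  list("J", "J{|,} |"),             # 51
  list("K", "K |"),                 # 52
  list("K", "K{|,} |"),             # 53
  list("M", "X Y{Z,}"),             # 54
  list("M", "X Y{X,Z}"),            # 55
  list("M", "X Y{A,ZX}"),           # 56
  list("M", "X{A,} Y{Z,}"),         # 57
  list("M", "X{A,} Y{X,Z}"),        # 58
  list("M", "X{A,} Y{A,ZX}"),       # 59
  list("X", "U A"),                 # 60
  list("X", "U{|,} A"),             # 61
  list("Z", "X N{Z,}"),             # 62
  list("Z", "X N{U,}"),             # 63
  list("Z", "X N{|,U}"),            # 64
  list("Z", "X N{X,Z}"),            # 65
  list("Z", "X N{A,ZX}"),           # 66
  list("Z", "X{A,} N{Z,}"),         # 67
  list("Z", "X{A,} N{U,}"),         # 68
  list("Z", "X{A,} N{|,U}"),        # 69
  list("Z", "X{A,} N{X,Z}"),        # 70
  list("Z", "X{A,} N{A,ZX}"),       # 71
  list("U", "U |"),                 # 72
  list("U", "U{|,} |"))             # 73

star_chain_shapes <- function() list(
  list("E{S,}", "S"),     # 74
  list("E{A,S}", "A"),    # 75
  list("S{A,}", "A"),     # 76
  list("T{E,}", "E"),     # 77
  list("T{C,}", "C"),     # 78
  list("T{|,C}", "|"),    # 79
  list("T{S,E}", "S"),    # 80
  list("T{A,ES}", "A"),   # 81
  list("C{|,}", "|"),     # 82
  list("L{A,}", "A"),     # 83
  list("L{M,}", "M"),     # 84
  list("L{P,}", "P"),     # 85
  list("L{Q,}", "Q"),     # 86
  list("L{R,}", "R"),     # 87
  list("L{F,}", "F"),     # 88
  list("L{G,}", "G"),     # 89
  list("B{|,}", "|"),     # 90
  list("H{|,}", "|"),     # 91
  list("J{|,}", "|"),     # 92
  list("K{|,}", "|"),     # 93
  list("X{A,}", "A"),     # 94
  list("Y{Z,}", "Z"),     # 95
  list("Y{X,Z}", "X"),    # 96
  list("Y{A,ZX}", "A"),   # 97
  list("Z{X,}", "X"),     # 98
  list("Z{A,X}", "A"),    # 99
  list("N{Z,}", "Z"),     # 100
  list("N{U,}", "U"),     # 101
  list("N{|,U}", "|"),    # 102
  list("N{X,Z}", "X"),    # 103
  list("N{A,ZX}", "A"),   # 104
  list("U{|,}", "|"))     # 105

# 4-decimal weights of the 73 main rules, in units of 1/10000
star_weights_1e4 <- function() c(
  10000, 212, 3,
  9788, 134, 944, 13,
  8559, 1304, 126, 181, 2,
  9036, 871,
  7630, 402, 186, 367, 72, 858, 484,
  3038, 1884, 3081, 1996,
  10000, 3896,
  6104, 2378,
  575, 3409, 6016, 1211,
  7987, 1608,
  1085, 2144, 2011, 4760,
  1713, 8287,
  4150, 5850,
  10000, 3243,
  10000, 3243,
  10000, 2928,
  6757, 2191,
  7072, 2071,
  10000, 510, 36, 712, 36, 3,
  9288, 1968,
  4211, 5279, 1119, 215, 15, 300, 376, 80, 15, 1,
  7881, 1670)

# integer weights of the 73 main rules after reweighting with s = c = 10000
star_weights_int <- function() c(
  "10000", "212", "3",
  "9788", "134", "944", "13",
  "8559", "1304", "126", "181", "2",
  "9036", "871",
  "76300000", "4020000", "1860000", "3670000", "720000", "8580000", "4840000",
  "3038", "1884", "3081", "1996",
  "10000", "3896",
  "6104", "2378",
  "5750000", "340900000000", "6016000000000000", "1211000000000000",
  "7987", "1608",
  "10850000", "214400000000", "201100000000", "4760000000000000",
  "1713000000000000", "828700000000",
  "415000000000", "585000000000",
  "10000", "3243",
  "10000", "3243",
  "10000", "2928",
  "6757", "2191",
  "7072", "2071",
  "10000", "510", "36", "712", "36", "3",
  "9288", "1968",
  "4211", "5279", "1119", "215", "15", "300", "376", "80", "15", "1",
  "7881", "1670")

star_nonterminals <- function() {
  main <- c("S'", "E", "S", "C", "A", "G", "D", "B", "F", "H", "P", "Q", "R",
            "V", "W", "O", "J", "K", "M", "X", "Z", "U")
  chains <- vapply(star_chain_shapes(), `[[`, "", 1)
  c(main, chains)
}

build_star_grammar <- function(weights, weight_mode) {
  shapes <- c(star_main_shapes(), star_chain_shapes())
  rules <- lapply(seq_along(shapes), function(i) {
    w <- if (i <= 73) weights[[i]] else rq(1)
    r_(shapes[[i]][[1]], shapes[[i]][[2]], w)
  })
  wcfg(star_nonterminals(), "S'", rules, weight_mode = weight_mode)
}

#' Load one of the bundled grammars
#'
#' Available names:
#' \describe{
#'   \item{Gsto_hat}{the detailed 54-rule SCFG with exact rational
#'     relative-frequency probabilities (26 nonterminals, axiom S').}
#'   \item{Gsto_hat_star_rational}{its reweighting normal form with the
#'     4-decimal rational weights (73 main + 32 weight-1 chain rules).}
#'   \item{Gsto_hat_star_integer}{the same grammar with the integer weights
#'     obtained by scaling with s = c = 10,000.}
#'   \item{Gs}{the small unambiguous structure grammar (7 rules over
#'     S, A, B, C) used for derivation-count cross checks.}
#'   \item{Gd}{the epsilon-free five-rule example grammar used to illustrate
#'     the normal-form transformation.}
#' }
#' Gs and Gd have no published weights; stochastic placeholders are used.
#' Loads are referentially transparent: two loads compare equal rule by rule.
#'
#' @param name grammar name (see above).
#' @return a \code{\link{wcfg}}.
#' @examples
#' g <- load_builtin("Gsto_hat")
#' length(g$rules)  # 54
#' @export
load_builtin <- function(name) {
  switch(name,
    Gsto_hat = wcfg(GSTO_NONTERMINALS, "S'", gsto_hat_rules(),
                    stochastic = TRUE),
    Gsto_hat_star_rational = build_star_grammar(
      lapply(star_weights_1e4(), function(v) rq(v, 10000)), "rational"),
    Gsto_hat_star_integer = build_star_grammar(
      lapply(star_weights_int(), function(v) rq(bn(v), bn(1))), "integer"),
    Gs = wcfg(c("S", "A", "B", "C"), "S", list(
      r_("S", "C A", rq(1)),
      r_("A", "( B ) C", rq(1, 2)),
      r_("A", "( B ) C A", rq(1, 2)),
      r_("B", "| | | C", rq(1, 2)),
      r_("B", "C A", rq(1, 2)),
      r_("C", "", rq(1, 2)),
      r_("C", "| C", rq(1, 2))), allow_epsilon = TRUE, stochastic = TRUE),
    Gd = wcfg(c("S", "B", "C"), "S", list(
      r_("S", "B", rq(1)),
      r_("B", "( B )", rq(1, 2)),
      r_("B", "C", rq(1, 2)),
      r_("C", "|", rq(1, 3)),
      r_("C", "| C", rq(2, 3))), stochastic = TRUE),
    stop("unknown builtin grammar: ", name))
}
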