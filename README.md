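# rnaunrank

Non-uniform random generation of pseudoknot-free RNA secondary structures of
a fixed size, distributed according to a stochastic context-free grammar
(SCFG) trained on real structures — entirely in exact integer arithmetic.

## Who this is for

Anyone who needs realistic random secondary structures of a prescribed size
as a background model: motif over/under-representation studies, calibration
of structure-comparison scores, simulation input for algorithm benchmarks.
Uniform random structures are known to be unrealistic; this package samples
from the distribution a trained SCFG induces, conditioned on the structure
size.

## The method

Structures are bar-bracket words over `{ ( ) | }`: `|` an unpaired base,
`( )` a base pair, nested pairing, hairpin loops of at least 3 unpaired
bases, at least one pair. A detailed unambiguous SCFG (26 nonterminals, 54
rules, one or more rules per structural motif: hairpins, stacked pairs,
bulges, interior-loop families, multiloops, exterior strands) is trained by
relative frequencies — exact rationals, counted from the unique derivation
of each database structure. Sampling at fixed size n works by *weighted
unranking*:

1. transform the SCFG into **reweighting normal form** (unit-rule chains
   `A => ... => X` collapse into fresh weight-1 symbols; substituted rule
   variants carry the chain-product weights);
2. round the rule weights to 4 decimals and scale them to **integers**:
   axiom rules by `s`, any other rule `A -> alpha` by `c^(|alpha|-1)`, with
   `s`, `c` the least common denominators (10,000 for the bundled model) —
   relative weights of same-size words are preserved exactly;
3. translate the integer grammar into **weighted combinatorial classes**
   (atoms, binary products, weighted unions) and tabulate all exact class
   sizes `size(C, n)` up to the target size with big-integer arithmetic
   (quadratic preprocessing, persisted to disk);
4. draw a uniform big-integer rank below `size(root, n)` (bit-block
   rejection) and **unrank** it: a structure `w` occupies `weight(w)`
   consecutive ranks, so it is drawn with probability
   `weight(w) / size(root, n)`. Scanning product splits in boustrophedon
   order (`j = 0, n, 1, n-1, ...`) bounds the work per structure by
   O(n log n).

The published trained model (exact rational probabilities, the 4-decimal
normal-form weights, and the integer weights) ships with the package; any
other model can be trained from a plain-text structure database with
`train()`.

## Worked example

```r
library(rnaunrank)

g <- load_builtin("Gsto_hat")          # trained SCFG, exact rationals
as.character(weight_of(g, premise = "E", conclusion = "S"))
#> [1] "137/6476"

rnf <- to_rnf(g)                        # reweighting normal form
rnf
#> <rnf_report>
#>   unit rules removed: 22
#>   chains gathered:    32
#>   chain rules added:  32
#>   step-3 rules:       79
#>   dead symbols:       T L Y N
#>   dead rules removed: 6
#>   main rules kept:    73

rw <- reweight(round_weights(rnf$result, 4))
rw
#> <reweight_report> s = 10000  c = 10000  digits = 4

spec <- grammar_to_spec(rw$result)      # weighted combinatorial classes
tbl  <- build_tables(spec, 80)          # exact size tables to n = 80

sample_structures(spec, tbl, n = 50, m = 4, seed = 11)
#> [1] "||(((((((((((((((((((((||||)))))))))))))))))))))||"
#> [2] "||||||(((((((||||)))))))||||||||||||||||||||||||||"
#> [3] "|||||||||||||||||((((((||||||))))))|||(||||||)||||"
#> [4] "||((||||||))|(((((((((((|||||||||||)))))))))))||||"
```

Four independent structures of exactly 50 bases, distributed as the trained
model dictates: long helices dominate (the stacked-pair rule carries weight
0.763), hairpins hold 4-11 unpaired bases, unpaired strands sit in the
exterior loop. Summary statistics of a sample:

```r
st <- summarize_motifs(lapply(.Last.value, parse_dotbracket))
st[st$parameter %in% c("num_bps", "num_h", "num_s", "unp_h"), ]
#>  parameter      mean  variance n_obs
#>    num_bps 12.000000 33.000000     4
#>      num_h  1.500000  0.250000     4
#>      num_s 10.500000 35.250000     4
#>      unp_h  6.166667  5.472222     6
```

`num_*` rows are per-structure means/variances (12 pairs on average here);
`unp_h` pools the 6 hairpin instances (6.17 unpaired bases per hairpin).

Everything is also reachable from a shell through `exec/rnaunrank`
(subcommands `train`, `rnf`, `reweight`, `build`, `count`, `unrank`,
`sample`, `stats`, `fixtures`).

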