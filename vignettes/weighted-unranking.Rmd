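---
title: "Non-uniform generation of RNA secondary structures by weighted unranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-uniform generation of RNA secondary structures by weighted unranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaunrank)
```

## The problem

Random RNA secondary structures are used as background models: to decide
whether a motif frequency, a comparison score or an energy value observed in
real molecules is signal or noise, one needs structures of a *fixed size n*
drawn from a *realistic* distribution, not the uniform one. `rnaunrank`
generates pseudoknot-free secondary structures of a given size distributed
according to a stochastic context-free grammar (SCFG) trained on a database
of known structures, using exact integer arithmetic end to end.

Structures are abstracted from sequence and written in bar-bracket notation:
`|` is an unpaired base, `( )` a base pair. The structure language contains
every balanced, properly nested word with at least one pair in which every
hairpin loop holds at least three unpaired bases; completely unpaired words
are excluded.

## The model

The bundled grammar (`load_builtin("Gsto_hat")`) has 26 nonterminals and 54
rules, one or more per structural motif distinguished by nearest-neighbour
thermodynamic models: exterior-loop strands, helix initiation, stacked
pairs, hairpin loops by size class, left/right bulges, four interior-loop
families (1x1, 1x2, 2x1, 2x2, and the asymmetric generalisations), and
multiloop branching. Because every motif is produced by its own rules, the
trained rule probabilities give more frequent motifs higher generation
probability. The grammar is unambiguous — every structure has exactly one
derivation — which the package checks *empirically* rather than symbolically:
the number of derivation trees per word length equals the number of
structures of that length,

```{r unambiguity}
g <- load_builtin("Gsto_hat")
d <- count_derivations_by_length(g, 10)
all(d == vapply(1:10, function(n) length(enumerate_language(n)), 0L))
```

and the derivation-count generating function satisfies the closed polynomial
identity of the simple reference grammar (`verify_generating_function`),
which certifies that the detailed grammar counts words exactly like the
provably unambiguous simple one.

Training is maximum likelihood by relative frequencies: each database
structure is decomposed into its unique derivation (a linear-time,
motif-directed decomposer; a generic chart parser is kept as an independent
oracle and the two are cross-checked exhaustively on all short structures),
rule usages are counted, and probabilities are exact rationals
count/premise-total. Exactness matters: consistency (per-premise sums equal
to 1) is checked with no tolerance parameter, and all later transformations
start from these rationals. The bundled probabilities are the published
values trained on large and small subunit rRNA; they are shipped as data
(provenance), since that database cannot be redistributed here.

## From probabilities to integers

Fixed-size sampling uses the recursive method for decomposable structures:
order all size-n objects, draw a uniform rank, and reconstruct ("unrank")
the object with that rank. Non-uniformity is obtained by *weighting*:
a class counted with multiplicity w behaves like w disjoint copies, so a
structure of weight w occupies w consecutive ranks and is drawn with
probability proportional to w. Weights must be integers, hence the pipeline:

1. **Normal form** (`to_rnf`). All non-axiom rules with single-symbol
   conclusions are removed after collecting every non-lengthening derivation
   chain A => A1 => ... => X; each chain becomes a fresh symbol `A{X,via}`
   with a weight-1 rule to its target, and every surviving rule receives one
   substituted variant per chain combination, weighted by the product of the
   chain's rule probabilities. Symbols that lose all their rules are removed
   together with rules mentioning them; axiom rules with long conclusions
   are split through a fresh symbol. The result is word-equivalent: every
   word keeps its exact weight (tested by brute-force summation over all
   short words). On the bundled grammar this removes 22 unit rules, gathers
   32 chains, and leaves 73 main plus 32 chain rules, with the nonterminals
   T, L, N, Y retired.
2. **Rounding** (`round_weights`). Weights are rounded half away from zero
   to 4 decimals by default, stored again as exact rationals k/10^4. Four
   decimals reproduces the published tables; the rounding direction is
   pinned by golden values (0.013377 -> 0.0134). A weight that would round
   to zero would silently delete words, so precision escalates grammar-wide
   instead. Rules with training frequency exactly zero are refused here —
   retrain with a pseudocount if a motif is absent from a small database.
3. **Reweighting** (`reweight`). With s the least common multiple of the
   axiom-rule denominators and c the same over all other rules, axiom rules
   are scaled by s and every other rule A -> alpha by c^(|alpha|-1), so each
   word of size n accumulates exactly s*c^(n-1) regardless of derivation
   shape and relative weights within a size are untouched. For the bundled
   weights s = c = 10,000; integer weights reach 6.016e15 for the hairpin
   rules with 5-symbol conclusions.
4. **Weighted classes** (`grammar_to_spec`). The integer grammar becomes an
   admissible specification: an atomic class per terminal, binary products
   per conclusion (multi-factor conclusions are right-associated; the
   association direction is fixed globally because it is part of the rank
   order), and one weighted disjoint union per nonterminal. Chain symbols
   (single weight-1 unit rule) collapse onto their targets and structurally
   identical classes are shared, reproducing the simplified specification.
5. **Size tables** (`build_tables`). size(class, n) for all classes up to N,
   by the standard recursion (atoms at size 1; unions sum weight x part
   size; products convolve split sizes), in exact arbitrary-precision
   integers. This is the quadratic preprocessing step; tables persist as
   JSON-lines tagged with a grammar fingerprint so stale tables are refused.

## Unranking and sampling

`unrank_class` maps a 0-based rank below size(root, n) to a structure:
unions locate the summand block by cumulative weighted sizes (weight copies
are copy-major: copy = rank div size, element = rank mod size; the copy
index is discarded on reconstruction), products locate the split size j and
then the left/right components by div/mod. Split sizes are scanned either
sequentially (j = 0, 1, ..., n) or in boustrophedon order
(j = 0, n, 1, n-1, ...). Both orders realise a bijection between ranks and
weighted copies — full rank ranges hit every structure exactly weight-many
times — but the boustrophedon scan pays only min(j, n-j) probes per block,
bounding the work per generated structure by O(n log n) against the
sequential order's quadratic worst case. The package measures this rather
than assuming it: on an adversarial exterior-chain structure the probe
counter doubles with n under boustrophedon and quadruples under sequential
scanning.

`sample_structures` draws ranks uniformly by rejection on bitlen(size)
random bit blocks (unbiased for arbitrary-precision bounds, acceptance
probability above 1/2) through R's seeded RNG, then unranks. At n = 10,
50,000 samples pass a chi-square goodness-of-fit test against the exact
conditional distribution (alpha = 0.001), where the exact probabilities come
from brute-force per-word weights.

```{r pipeline}
pl <- build_pipeline(load_builtin("Gsto_hat"), N = 60)
as.character(class_size(pl$spec, n = 60, table = pl$table))
sample_structures(pl$spec, pl$table, n = 40, m = 3, seed = 7)
```

## The synthetic database generator

Offline testing needs a stand-in for the rRNA training database.
`generate_fixture_db` draws it from a *known* SCFG, so training becomes a
parameter-recovery experiment with known ground truth. The default mode is
ancestral sampling (expand the leftmost nonterminal by rule probability),
which reproduces the grammar's own unconditional distribution — under the
bundled probabilities the mean structure size is about 1.7 kb, matching the
rRNA scale of the training data, with sizes mixed exactly as the model
implies. A fixed-size mode through the unranking pipeline is also available.
Training on 10,000 ancestral structures recovers every rule probability with
expected usage of at least 50 to within 0.02 (seeded test), and 40-fold
re-training on random 90% subsamples of a 5,000-structure fixture keeps
every per-rule variance below 1e-3, the binomial-scale bound.

What the fixture does *not* emulate: real rRNA deviates from any SCFG
(long-range correlations, conserved cores, pseudoknots removed during
curation), so passing recovery tests validates the estimator and the
pipeline, not the biological fidelity of the model itself; the published
motif-statistics comparison against native data is the evidence for the
latter and needs the original database.

## Evaluation statistics

`decompose_motifs` classifies every pair by the loop it closes — hairpin,
stacked pair, bulge, interior loop, or multiloop — groups maximal stacks
into helices (an isolated pair is a helix of one pair), and counts maximal
unpaired runs. The loop taxonomy is pinned down precisely because published
summaries of these counters leave some conventions implicit: per-motif
unpaired counts pool motif instances across the sample by default (a
per-structure-mean alternative sits behind `pool_instances = FALSE`), the
variance is the population variance, structurally constant parameters
(pairs per stacked pair, bulge, interior loop) come out as mean 1, variance
0, and undefined cells (unpaired bases per stacked pair, pairs per hairpin)
are NA. Conservation laws — every unpaired base lies in exactly one loop,
every pair closes exactly one loop, helices partition the pairs — hold for
every structure of every size up to 14 by exhaustive test.
`size_matched_sample` draws one random structure per native structure of the
same size for two-sample comparisons.

## Numerical choices and edge cases

* All counting, ranking and weights use a base-2^15 limb big-natural layer
  (src/bignum.cpp) with exact rationals on top; no floating point enters
  the pipeline anywhere except final summaries and the rule-probability
  draws of the ancestral sampler.
* Derivation-count sequences (`count_derivations_by_length`) use doubles
  with an explicit 2^52 overflow guard; the identity checks live at n <= 20
  where counts are ~1e5. Class sizes — the quantities that actually grow
  astronomically — are always exact.
* Degenerate inputs: words below size 5 are not in the language (`n = 4`
  yields an empty class and sampling refuses); hairpins below 3 unpaired
  bases and completely unpaired words are rejected at parse time with the
  offending position.
* Rule ids follow the defining listings and break all ties (chain
  enumeration, substitution order, union order). Where multiple occurrences
  of chain sources are substituted, the leftmost occurrence varies slowest;
  published listings of the transformed grammar are compared rule-by-rule
  on (premise, conclusion) keys, which are unique, rather than positions.
* Problem sizes in the test-suite experiments: exhaustive language checks to
  n = 14 (2,287 structures), decomposer/parser cross-validation exhaustive
  to n = 11 and sampled at 12-14, goodness of fit at n = 10 with m = 50,000,
  recovery at 10,000 fixture structures, probe scaling at n = 64-256 and
  size-table positivity to N = 400. These are desk-scale choices that keep
  the full suite in minutes while exercising every code path; the pipeline
  itself is routinely used to N in the thousands since table construction is
  quadratic.

## Limitations

* Pseudoknots, nucleotide sequence, CT/BPSEQ formats and free-energy models
  are out of scope; the sampler abstracts structure from sequence entirely.
* The normal-form transformation requires an epsilon-free, loop-free input
  grammar (the bundled one is); general epsilon-elimination is not
  implemented.
* Exact-mode reweighting (skipping the rounding step) is available but the
  least common denominators of raw training fractions are astronomically
  large; the default 4-decimal rounding is the published compromise.
* A grammar trained on a small database can assign probability 0 to unused
  rules; such grammars are valid SCFGs but must be smoothed (pseudocount)
  before entering the integer pipeline.
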