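---
title: "Simple shared motifs: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simple shared motifs: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmotif)
```

## The problem and the model

Genes under common transcriptional control tend to carry similar
*cis*-regulatory material in their promoters. Rather than scanning for known
transcription-factor binding sites, `ssmotif` asks a database-wide,
motif-agnostic question: do two genes share an *exceptional* amount of
short, similar sequence among the evolutionarily conserved elements
("atomic motifs") of their promoters?

The unit of comparison is the **extended sequence**: a DNA word `w`
identified with its class `{w, w_c, w_r, w_rc}` under complementation,
reversal and reverse complementation, compared through the minimum Hamming
distance over members. This makes matching blind to strand and reading
orientation — appropriate for regulatory elements, which act from either
strand — at the cost of some fuzziness (the pure reversal `w_r` is included
deliberately; the method trades interpretability of individual matches for
sensitivity to composite signals). Because the four transforms form a group
under which Hamming distance is invariant, the class-to-class distance
reduces to four string comparisons, and it is zero exactly when the classes
coincide. A class always has 2 or 4 distinct members: the complement
differs from `w` everywhere, so a singleton class cannot occur.

For a gene pair and a **type** `(l, d)` — window length `l`, maximum
distance `d` — the algorithm:

1. slides a length-`l` window over every atomic motif of both genes
   (windows never span motif boundaries);
2. merges windows with identical extended classes into **PreSSM nodes**,
   tagged with the genes they came from;
3. builds the graph with an edge wherever the extended distance is at most
   `d`, and enumerates its **maximal cliques**;
4. keeps the cliques containing material from both genes.

Each surviving clique is one **simple shared motif (SSM)**: a maximal set
of mutually similar, orientation-degenerate subsequences present in both
promoters. An isolated node occurring in both genes is a valid singleton
SSM — at `d = 0` that is the only kind, since distinct classes are never
adjacent.

Raw SSM counts grow with the amount of motif material a gene carries, so
they are normalised by the **potential count**: the product over the pair
of their total numbers of length-`l` windows (a length-9 motif has two
length-8 windows, a length-10 motif three, so lengths `[9, 10]` against
`[10]` give `(2 + 3) × 3 = 15`). The ratio `SSMC = SSMs / potential` is
the quantity actually scored. Note the deliberate asymmetry: nodes merge
duplicate windows, the potential count does not — the denominator measures
material, the graph measures diversity. On simulated databases the raw
count correlates strongly with the potential count across random pairs
(Spearman ρ ≈ 0.86 in the packaged check) while the SSMC correlation is an
order of magnitude smaller; that residual dependence is why significance
is judged empirically rather than by a parametric model.

## Type grid

Types keep `l` in `[6, 14]` — the size range of classical regulatory
motifs — and `d` in `[0, 5]` with `d ≤ floor(l/3)`, so that similarity
never degenerates into chance alignment. Enumerating the rule gives 36
types, `(6,0)` through `(14,4)`. `d ≤ "a third of l"` is read as
`floor(l/3)` because distances are integers and this keeps `(14, 4)` — a
type used in the reference analyses — inside the grid.

## Empirical nulls, cp-values, CEXlists

Whether an SSMC is exceptional is judged against its empirical
distribution over random pairs of distinct genes from the same database
(sampled uniformly with replacement across pairs; one seeded pair list is
shared by all types, so the per-type nulls are comparable). The p-value is
the add-one-smoothed right tail `(r + 1)/(n + 1)` with `r` the number of
null values at or above the observation: a finite sample cannot certify
`p = 0`, ties count toward the tail, and the attainable range is
`[1/(n+1), 1]`. Pairs with no length-`l` window on either side are
degenerate; they contribute `SSMC = 0` to the null (excluding them would
bias the null toward motif-rich genes) and score `p = 1` when observed —
no material, no evidence.

The **cp-value** of a pair is the minimum p-value across the grid: the
most exceptional signal regardless of motif length or allowed degeneracy.
No multiplicity adjustment is applied across the 36 types — the cp-value
is a raw minimum by definition, and is therefore anti-conservative as an
absolute probability; it is meant to be compared against a threshold `t`,
not interpreted marginally. The **CEXlist** of a query gene at threshold
`t` contains every other gene whose cp-value against the query falls
strictly below `t`, ranked by cp-value with ties broken by gene id.
CEXlists nest as `t` tightens, which the writer asserts at export time.

## Downstream functional statistics

Candidate lists are characterised with flat per-category hypergeometric
upper-tail tests (`P(X ≥ k)`; categories with zero overlap are omitted; no
ontology-graph decorrelation and no multiple-testing correction — the
0.05 flag threshold is used as-is). Over-represented categories are
summarised by

\[ c = \sum_i \ln\!\left(\frac{1}{p_i} - 19\right), \]

anchored so a category at exactly `p = 0.05` contributes zero; the
logarithm is natural (the anchor holds in any base; a base had to be
fixed). The argument turns negative past `p = 1/19`, so the function
rejects p-values above 0.05 outright rather than silently dropping them.
c-scores are standardised into z-scores against nulls built from random
gene lists of matching size (200 lists by default); the null mean grows
with list size, so the size must match. Co-expression support is measured
as the density `|G ∩ S| / |S|` (undefined, not zero, for an empty list)
and by a two-sided Fisher test comparing co-expressed fractions inside
versus outside the list — two-sided because depletion is a real outcome,
reported alongside the ratio `(|G∩S|/|S|) / (|G∖S|/|U∖S|)`, which is 0
when the overlap is empty.

## The synthetic generator

`generate_db()` emulates the published shape of a genome-scale conserved
promoter-motif collection: per-gene motif counts with realised mean 12.7
and sd 8.9 (truncated at zero), motif lengths with realised mean 11.7 and
sd 4.1 on `[6, 30]` — bounds that reconcile the "typically 6–12 bp" motif
size with the reported spread — and i.i.d. backgrounds at GC 0.5 by
default. Truncating and discretising a normal shifts its moments (cutting
the count distribution at zero alone inflates the mean by more than 1), so
the generator solves for the underlying normal whose *discretised,
truncated* distribution has exactly the configured moments, and samples
from that distribution directly. `db_summary()` on a 2000-gene simulation
recovers the configured values within sampling error, which is the
packaged check of this property.

Planted modules insert a shared motif into chosen genes as standalone
additional atomic motifs (simpler ground-truth bookkeeping than embedding
into longer sequences, which is left as a configuration extension), with
an exact per-copy mutation count. The generator does **not** simulate
phylogenetic conservation, motif-discovery artefacts, compositional bias
along promoters, or homology between genes; passing recovery tests
therefore demonstrates the statistical machinery, not performance on real
promoter collections, where correlated backgrounds will inflate nulls.

## Numerical and algorithmic choices

* Maximal cliques via pivoting Bron–Kerbosch over nodes in canonical-key
  order inside the compiled kernel; output is deterministically ordered,
  and one distance matrix per `l` is reused across the `d` values of that
  length. Node counts are bounded by the distinct window classes of two
  genes (typically well under 200), so exact enumeration is cheap; the
  test suite checks the kernel against both an exhaustive
  subset-enumeration oracle and an independent graph library.
* All iteration orders (genes, motifs, nodes, CEXlist ties) are
  lexicographic, making every count and every output file reproducible;
  stochastic steps require an explicit seed and restore the caller's RNG
  state. Whole-database scans run serially — at the problem sizes this
  package targets they complete in seconds, and serial gene order makes
  deterministic output trivial.
* Degenerate inputs are surfaced, not coerced: empty databases summarise
  to `NA` markers, zero-potential pairs carry an `NA` SSMC, an empty list
  has undefined density, and a zero-variance c-score null is an error.
* Sequences are strictly `{A, C, G, T}`: complementation and Hamming
  distance are undefined for IUPAC ambiguity codes, so the reader rejects
  (default) or drops (opt-in) anything else rather than guessing.

## Problem sizes in the packaged checks

The end-to-end recovery experiment uses a 200-gene database with a 5-gene
module sharing an exact 10-mer, nulls from 2,000 random pairs per type
(p-value floor 1/2001), threshold `t = 0.01`, and a seeded sample of 15
non-module queries for the specificity median; it recovers at least 3 of
the 4 co-members while non-module CEXlists contain a median of zero module
members. The correlation diagnostic uses 1,000 random pairs from a
300-gene simulation at type `(8,1)`. The mutation-degradation property is
averaged over six seeds per mutation level on 50-gene databases. These
sizes are chosen so the whole suite documents the method's behaviour at
desk scale; genome-scale runs (~18,000 genes, 50,000 null pairs) use the
same code paths through the null cache.

## Limitations

cp-values are anti-conservative minima over correlated types; CEXlists
are rankings, not calibrated discoveries. The fuzziness that gives the
method its sensitivity also makes individual SSMs hard to map back to
named binding sites, especially for short, highly degenerate types. And
the empirical null is database-relative: scores from differently
constructed motif collections are not comparable.
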