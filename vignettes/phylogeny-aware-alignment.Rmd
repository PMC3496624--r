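---
title: "Phylogeny-aware short-read alignment: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware short-read alignment: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papara)
```

## The problem

Given a fixed reference multiple sequence alignment (RA) over a set of taxa
and a matching unrooted binary reference tree (RT), place short sequencing
reads (query sequences, QS) on the tree: for every edge of the tree, build a
profile of the sequence one would expect to observe at that point of the
phylogeny, align every read against every such profile, and keep the
best-scoring edge per read. Aligning against per-edge profiles rather than
against individual reference sequences lets a read be compared with the
*ancestral* signal at its true insertion point, including the local indel
structure of the reference.

## Per-edge profiles: parsimony states and the CGAP signal

Each edge profile is a *parsimony state vector*: at alignment column $i$ the
entry $A^i$ is the set of DNA bases consistent with a most-parsimonious
labeling of a "virtual root" inserted on that edge. Sets are encoded as 4-bit
vectors with the fixed bit order A=1, C=2, G=4, T=8; IUPAC ambiguity codes in
reference rows enter as their base sets, and the full set 15 behaves like N.

The sets are computed by unit-cost Fitch passes (the state-set form of
unit-cost Sankoff) over a five-symbol alphabet that includes the gap as a
fifth state. Two directional messages are computed per edge — one from each
side — in a single postorder/preorder sweep anchored at an arbitrary tip;
because every combine is a symmetric two-set operation on a binary tree, the
per-edge result is provably anchor-independent (and tested to be). The
virtual-root set of an edge is the Fitch combine (intersection if non-empty,
else union) of its two messages. The gap symbol is then projected out to give
the 4-bit DNA state; a set that is *only* the gap symbol becomes the full set
15 (such a column carries no base information at that point of the tree).

Alongside the states, every edge carries a per-site boolean CGAP flag — the
phylogenetic indel signal that calibrates the alignment scoring. The precise
flag derivation used by the original tool is defined in earlier work and not
restated in the account this package follows, so the rule here is an
explicit, documented stand-in with three selectable variants:

* `"parsimonious"` (default): CGAP is set where the gap symbol is a member of
  the combined virtual-root set. Members of a Fitch combine are exactly the
  states attaining minimal parsimony cost at that point, so this reads as
  "a gap is parsimonious here".
* `"strict"`: the gap symbol survives a non-empty intersection.
* `"gap_only"`: the combined set is exactly the gap symbol.

The default is the most inclusive phylogenetically justified reading; the
variants are kept because the boundary between "gap possible" and "gap
certain" is genuinely open.

## The scoring recurrence

Scores are costs; lower is better. With column $i$ in the reference profile
and position $j$ in the read:

$$
\begin{aligned}
CG_i &= \begin{cases}3 & \text{CGAP set at } i\\ 0 & \text{otherwise}\end{cases}
\qquad
(GPOE_i, GPE_i) = \begin{cases}(4,1) & CG_i = 0\\ (0,0) & \text{otherwise}\end{cases}\\
M_{i,j} &= \begin{cases}0 & A^i \cap B^j \neq \emptyset\\ 3 & \text{otherwise}\end{cases}
\qquad
I_{i,j} = S_{i,j-1} + 3\\
D_{i,j} &= \min(S_{i-1,j} + GPOE_i,\; D_{i-1,j} + GPE_i)\\
S_{i,j} &= \min(S_{i-1,j-1} + M_{i,j} + CG_i,\; D_{i,j},\; I_{i,j})
\end{aligned}
$$

The match test is bitwise-AND non-emptiness of the two state sets. At a CGAP
site, gaps in the read (reference-consuming $D$ moves) become free while the
diagonal pays a penalty: the profile actively steers reads around columns
where the phylogeny expects indels. Insertions ($I$) are linear, exactly as
the recurrence is stated — no insertion-open cost is invented.

**Boundary conditions** are this package's documented choice, since the
recurrence itself does not fix them: semi-global ("glocal") alignment with
the read consumed in full and both reference flanks free, i.e. $S_{i,0}=0$
for every $i$, $S_{0,j}=3j$, $D_{0,j}=\infty$, and the final score is
$\min_i S_{i,m}$. Short reads against long references would otherwise be
dominated by flank gaps.

All penalties are configurable through `scoring_params()`; the defaults above
are the published constants.

### Numerical choices

* The $\infty$ sentinel is half the maximum representable value of the score
  width (16383 for 16-bit cells, $2^{30}-1$ ish for 32-bit), so adding any
  penalty cannot overflow; stored values are clamped at the sentinel.
* In 16-bit mode a lane whose stored $S$ value reaches the sentinel is
  flagged and recomputed at 32 bits (detect-and-promote, rather than
  saturate): 16- and 32-bit results agree bit-exactly whenever no flag is
  raised, and flagged lanes are still correct after promotion.
* Traceback starts at the leftmost minimum of the last row and resolves
  ambiguous cells in the fixed order diagonal, then $D$, then $I$. Any order
  is score-equivalent; this one makes output deterministic and, together with
  the leftmost-minimum rule, keeps deletions out of the free flanks.
* Read characters consumed by insertion moves are kept in the emitted gapped
  query as lowercase by default (`keep_insertions = FALSE` drops them); how
  the original tool renders them is not documented in the account followed
  here, so both behaviours are provided.
* Best-edge ties are resolved to the lowest edge id — deterministic and
  independent of evaluation order.

## Verification strategy: four independent routes

The same quantity is computed by deliberately independent implementations and
required to agree bit-exactly:

1. `score_alignment()` — the C++ row kernel with single-row memory;
2. `fill_matrix()` — a pure-R full-matrix evaluation of the recurrence;
3. `brute_force_score()` — an exhaustive enumerator that never runs the
   recurrence: it enumerates (matched-position subset, strictly increasing
   reference columns) pairs and prices gap runs directly. A small lemma
   guarantees completeness: because $GPOE_i \ge GPE_i$ at every site,
   splitting a run of skipped columns is never cheaper than one run, so the
   enumerated family always contains an optimal path;
4. `batch_score()` / `blocked_batch_score()` — the W-lane engine below.

The tests drive thousands of random instances through routes 1 vs 3 (tiny
sizes) and 1 vs 2 vs 4 (realistic sizes).

## The batch engine

The throughput designs of the original implementations are re-expressed
portably, and required to be bit-exact rather than fast:

* **Inter-reference layout** — W references interleaved site-major (entry
  $iW+k$ is site $i$ of reference $k$), so one instruction stream can update
  W DP matrices in lockstep. Shorter references are padded with match-all
  sites; because such sites would otherwise admit free diagonal paths under
  the semi-global convention, each lane's final-row minimum is restricted to
  its true reference length (the block carries per-lane lengths for exactly
  this reason). Absent lanes are masked and report the sentinel.
* **5-bit packing** — an element is `state | cgap << 4`; six elements per
  32-bit word, element $t$ at bits $5t..5t+4$ (low bits first — the
  within-word order is a documented free choice covered by round-trip
  tests). An optional uncompressed head and tail bracket the packed middle,
  and all three segments are padded to multiples of 32 words, preserving the
  described stream geometry even though the motivating memory-coalescing
  concern does not exist here.
* **Blocked schedule** — columns are partitioned into a square head,
  fixed-width rectangular blocks of
  $\lfloor \text{budget} / (\text{groups} \times \text{bytes per cell})\rfloor$
  columns, and a square tail; with the published configuration (15 KB
  buffer, 320 references, 4-byte cells) this reproduces the 12-column
  blocks. The blocked scorer carries the per-row boundary column between
  blocks, which makes it arithmetically identical to the single-block order
  for any schedule — verified bit-exactly across block widths.

## The pipeline

The scoring phase performs exactly $R \times Q$ pairwise DPs ($R = 2T-3$
edges, $Q$ reads), organised as a work queue of W-sized reference blocks;
only each read's best (lowest) score and edge are retained. The alignment
phase then runs exactly $Q$ full-matrix fills and tracebacks — winners only —
and asserts that each recomputed score equals the recorded one. Both counts
are instrumented (`dp_counters()`) and asserted in the tests.

Queue consumption is a contract: blocks are delivered exactly once and the
per-query minimum is an order-free reduction, so results are invariant to
W, to queue order, and to how many workers would consume the queue. The
package executes single-threaded; the CLI's `--seed` merely shuffles the
queue to exercise that invariance, which is why outputs are byte-identical
across seeds.

## The synthetic generator

`simulate_reference()` / `simulate_reads()` produce the study inputs: a
random unrooted binary topology, a root sequence evolved edge-by-edge at a
per-site substitution rate, clade-structured gap blocks, and reads drawn as
ungapped substrings of reference rows with substitutions (replacement
uniform over all four bases, so rate 1 yields an expected mismatch fraction
of 3/4) and short indels. Defaults — 16 taxa, 400 columns, 20 reads of
length 100, 5% substitutions, 1% indels, 10% gap columns — are a deliberate
desk-scale rendition of the data shapes the method targets (hundreds to
thousands of reference sites, ~100 bp reads); the tests and the acceptance
script run at these sizes.

Gap events are constrained to pairwise-disjoint column blocks, one clade per
column. This is what makes "error-free reads place with score 0" a theorem
rather than a tendency: with a single connected gapped clade per column, the
Fitch message on the far side of a read's source tip always retains the
source base, so every covered column is either a free match or a
CGAP-flagged column the read can skip at zero cost. Overlapping events can
gap an entire side of the tree at a column, in which case the message
degenerates to the gap symbol and even a perfect read pays the CGAP diagonal
penalty — real reference alignments do contain such columns, which is a
known limitation of the generator's guarantee, not of the aligner.

What the generator does *not* emulate: realistic substitution models (GTR,
rate heterogeneity), sequencing-quality profiles, paired ends, and
alignment-error noise in the reference itself. Passing tests therefore
demonstrate correctness of the algorithmics, not placement accuracy on real
data.

## Known limitations

* DNA only; the bit-vector representation extends to proteins but that path
  is not implemented.
* The CGAP rule is a documented stand-in (see above), not a reproduction of
  the original derivation.
* Branch lengths are read and ignored; ancestral states are parsimony-based,
  not likelihood-based.
* The batch engine models the published memory layouts and schedules; it
  makes no attempt at SIMD/GPU performance parity.
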