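---
title: "Simulating indels and substitutions along a tree: models, bookkeeping and the true alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating indels and substitutions along a tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelsim)
```

## The indel process

`indelsim` simulates sequence evolution as two independent processes —
insertions/deletions and substitutions — and combines the results. The
indel process on a branch is a Gillespie simulation whose rates track
the evolving sequence length $n$:

* **Insertions.** A sequence of length $n$ has $n+1$ insertion slots
  (between adjacent characters and at both ends), so the sequence-wise
  insertion rate is $R_\mathrm{ins} = (n+1)\,r_\mathrm{ins}$. The slot
  is uniform; the inserted length is drawn from the length
  distribution.
* **Deletions and the edge-effect correction.** If deletion start
  points were uniform on $1..n$, positions near the start of the
  sequence would be deleted less often than interior ones (a position
  $i \ge S$ can be removed by events starting at any of
  $i-S+1, \dots, i$). We therefore draw the candidate deletion length
  $S_\mathrm{del}$ *first*, let the event start uniformly at one of the
  $n + S_\mathrm{del} - 1$ integers $2-S_\mathrm{del}..n$, and clip the
  event to the sequence. Every position is then deleted with
  probability exactly $S_\mathrm{del}/(n+S_\mathrm{del}-1)$, and the
  sequence-wise deletion rate is
  $R_\mathrm{del} = r_\mathrm{del}(n + S_\mathrm{del} - 1)$.
* **Waiting times.** Exponential with rate
  $\lambda = R_\mathrm{ins} + R_\mathrm{del}$; time is measured in
  expected substitutions per site, so a branch is exhausted when the
  cumulative time passes its length. An event whose waiting time
  overshoots the branch end is discarded (standard truncation of a
  Gillespie run).

Two conventions are worth stating explicitly, both of which the package
treats as its own design choices:

* The candidate $S_\mathrm{del}$ drawn at a step enters $R_\mathrm{del}$
  and the waiting time, and is *discarded* if the event turns out to be
  an insertion (the insertion length is drawn fresh). This keeps the
  per-position deletion probability exact at every step. Using the
  distribution's mean instead would only approximate it.
* When the sequence is empty ($n = 0$) no deletion is possible, so
  $R_\mathrm{del}$ is set to zero even though the
  $r_\mathrm{del}(n+S-1)$ formula would be positive; insertions can
  still rescue the sequence.

### Indel length distributions

Lengths follow a truncated Zipfian ($P(k) \propto k^{-a}$) or geometric
($P(k) \propto p(1-p)^{k-1}$) law on $1..M$. "Truncated at 50" is used
in the literature for both the inclusive support $1..50$ and the
exclusive $1..49$; for the Zipf exponent $a = 2.0$ the mean length is
2.77 under the former and 2.76 under the latter. The constructor
defaults to the inclusive reading and exposes
`truncation_inclusive = FALSE` for the exclusive one; the package's
reference value of 2.76 uses the exclusive reading, which is the one
that reproduces the published mean for this regime.

The default parameters — $r_\mathrm{ins} = 0.03$,
$r_\mathrm{del} = 0.09$, Zipf $a = 2.0$ truncated at 50 — are a regime
typical of empirical protein datasets.

## Block bookkeeping

The naive engine edits an explicit sequence after every event: O(n) per
event, O(k(n+k)) per branch. The block engines instead record, relative
to the branch's parent sequence, which stretches survived and how much
was inserted between them. A **block** $(S, L, I)$ is a run of $L$
contiguous undisturbed parent positions starting at parent coordinate
$S$ (the *original part*, OP), followed by $I$ characters inserted along
this branch (the *added part*, AP). A branch starts as the single block
$(0, n_0+1, 0)$: a virtual anchor at position 0 is counted inside the
first block so that insertions before the first character have a home.
Updating the list costs O(b) per event and the block count obeys
$b \le \min(k+1, n+1)$.

### Coordinate conventions

Events are located by scanning cumulative block totals $T_j = L_j + I_j$
("subtract $T_j$ while the residual exceeds it"). Because the anchor is
counted in the first block, the standalone update functions
(`apply_insertion_blocks`) follow an anchor-aware arithmetic: an OP
split in the *first* block at residual offset $r$ keeps $r+1$ elements
(anchor included) in the prefix, while in any later block it keeps $r$
elements. This is the unique reading consistent with both published
worked examples that the package reproduces (splitting
$[(0,30,5),(30,25,0)]$ at position 15 into $(0,16,4),(16,14,5)$, and at
position 45 — residual 10 in the second block — into
$(30,10,4),(40,15,0)$).

A consequence is that a raw scan position beyond the first block lands
one element to the left of the physical insertion slot. The branch
drivers therefore convert the physical slot $q$ (uniform on $0..n$,
"insert after character $q$") to the scan coordinate — $q$ if
$q \le T_1 - 1$, else $q+1$ — before applying the block update. With
this conversion all three engines consume the *same* event stream and
produce identical homology maps; the equivalence is asserted over
thousands of random streams in the test suite, with the naive engine as
the oracle. Deletion coordinates are consumed as element offsets and
need no adjustment.

Other tie-breaks, chosen once and fixed:

* An insertion whose residual lands at the end of a block's AP extends
  that AP rather than opening the next block (the scan uses strict
  comparisons, and APs are anonymous during the branch, so any position
  inside the AP is equivalent).
* A deletion that empties a block's OP but leaves part of its AP
  appends the orphan AP to the nearest surviving preceding block; the
  anchor block always survives (position 0 is never deletable), so a
  home always exists and the left-to-right order of inserted material
  is preserved.
* Blocks are never merged: two adjacent blocks with contiguous OPs can
  coexist (e.g. after a deletion removed the AP separating them). This
  costs at most one extra block per event and keeps updates local.

### The AVL block tree

For long branches with many events the O(b) scan dominates, so the same
blocks can be stored in an order-statistic AVL tree. Nodes are kept in
block order and augmented with two subtree aggregates: the element
total $\sum (L+I)$, which supports the cumulative-offset search, and
the node count, which supports rank addressing. No explicit keys are
stored — positions shift after every event, and cumulative aggregates
make renumbering unnecessary. Locate, split, insert and remove are all
O(log b); a deletion spanning $m$ blocks truncates the boundary blocks
in place and removes interior nodes one by one (O(m log b)). The
instrumented locate cost is measured in the test suite: visits grow
linearly with $b$ for the list and logarithmically for the tree over
$b = 2^3..2^{12}$, which is the qualitative content of a wall-clock
benchmark without timing claims.

## The true alignment

Simulating along the tree is a preorder recursion: the root sequence is
drawn, each branch's events are simulated from the parent, and every
node receives a sequence. The alignment implied by the history is built
through a **super-sequence**: a linked list of every position that ever
existed, seeded with the root positions. Each node keeps a pointer
sequence into it. When a branch's outcome is folded in, surviving
parent positions copy their references and each run of freshly inserted
characters becomes new super-sequence elements spliced immediately
after the element preceding the run. Every engine reports its branch
outcome in the same parent-relative form, so one pointer-sequence
builder serves all three — alignment output is engine-independent by
construction.

Where independent lineages insert after the same element, the relative
order of the runs in the alignment is biologically arbitrary (the
characters are non-homologous); the package splices each new run
immediately after its anchor, which makes the order a deterministic
function of the preorder traversal and the seed.

A column flag marks elements referenced by at least one *emitted* row
(leaves by default; ancestors optionally), and only flagged elements
become columns — the alignment never contains gap-only columns.
Degapping any emitted row recovers exactly that node's simulated
sequence; this round trip is property-tested across the random sweep.

## Substitutions

Substitutions are simulated independently of indels, which is exact
because the indel model is content-agnostic. The residue content is
generated at the template's alignment length $L$: the root row is drawn
i.i.d. from the stationary distribution $\pi$ and each child site from
the parent's row of $P(t) = e^{Qt}$, precomputed per branch by spectral
decomposition of the symmetrized generator
$D_\pi^{1/2} Q D_\pi^{-1/2}$. $Q$ is built from symmetric
exchangeabilities and $\pi$ ($Q_{ij} = s_{ij}\pi_j$), normalized to one
expected substitution per site per unit time, so branch lengths have
their usual meaning. Residues drawn at columns where a row is gapped
are simply discarded at superposition; simulating at all $L$ columns
rather than per ungapped stretch yields identically distributed
alignments and keeps the two processes fully separated. Shipped models:
JTT for amino acids (tables from phangorn), a one-parameter nucleotide
model, and custom PAML-layout rate files.

## Determinism and seeds

One master seed drives everything. Each branch derives a substream seed
from (seed, child node id), so event streams do not depend on traversal
order or engine choice; the substitution layer uses a separate salt.
Re-running with the same seed and configuration gives byte-identical
outputs, whichever engine is selected — this is also the package's own
strongest cross-check, exercised over a thousand random tree/seed
instances in the acceptance tests.

## What the synthetic data does and does not emulate

`generate_fixtures()` produces random topologies with exponentially
distributed branch lengths (default mean 0.038 substitutions per site,
40 leaves), emulating the scale of mammalian single-gene trees: short
branches, occasional long ones. Real gene trees differ in ways the
generator ignores — correlated branch lengths, non-uniform taxon
sampling, rate variation among sites and lineages, and
context-dependent indels (all indel models here are
content-independent). Passing tests therefore certify the
*algorithms* — engine equivalence, homology correctness, complexity
shape and sampling distributions — not the biological realism of any
particular dataset.

## Problem sizes and numerical choices

The test suite keeps simulations at desk scale as a deliberate design
choice: the equivalence sweep uses 1000 instances with up to 20 leaves
and root lengths up to 200; deletion-placement uniformity uses $10^6$
draws; locate scaling uses synthetic block sequences up to $b=2^{12}$.
Monte-Carlo assertions use 3–4 standard-error bands under fixed seeds.
Probability vectors are validated to $10^{-12}$; transition matrices
are clipped at zero and renormalized (deviations at the $10^{-15}$
level) so sampling never sees a negative probability; stationarity and
semigroup identities are asserted at $10^{-8}$ or tighter.

## Known limitations

* Indel rates and placement are context-independent, and there is no
  among-site or among-lineage rate variation.
* Insertions and deletions share one length distribution family per
  run (their rates are separate).
* The block engines are per-branch structures: each branch starts from
  a fresh single block, and no structure is reused across branches.
* The AVL engine's advantage is asymptotic; at the default regime's
  event counts the list engine is competitive, which is exactly the
  crossover the operation-count harness demonstrates.
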