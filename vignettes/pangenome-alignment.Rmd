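---
title: "Local alignment search in colored de Bruijn graph pangenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local alignment search in colored de Bruijn graph pangenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A pangenome collects the genomes of related individuals — bacterial strains
of one lineage, human haplotypes — into a single searchable entity. Because
the genomes are highly similar, storing them as a compacted colored de
Bruijn graph removes most redundancy: shared sequence is stored once, and
every k-mer carries the set of genomes ("colors") containing it. `pangaln`
finds *all statistically significant local alignments* between a DNA query
and such a graph, in the spirit of BLAST rather than of a read mapper: the
goal is not the single best placement of the query but every alignment
whose score is unlikely by chance, each annotated with the genomes that
support it.

# The graph model

The graph for k-mer size $k$ has unitigs (maximal non-branching paths of
the node-centric k-mer graph) as vertex labels; every k-mer of the input
occurs at exactly one (vertex, offset); there is an edge $v \to w$ exactly
when the $(k-1)$-suffix of $\lambda(v)$ equals the $(k-1)$-prefix of
$\lambda(w)$; and each k-mer carries its color set. Alignments live on
*truncated paths* $t = (p, b, e)$: a vertex path with the first label
entered at offset $b$ and the last left at offset $e$; the spelled sequence
$\lambda(t)$ drops the $(k-1)$-overlap between consecutive labels. The
*locations* of $t$ are all (vertex, position) pairs it covers — the overlap
characters count in both flanking vertices. The color set of a location is
the union over the k-mers overlapping it.

Two search controls restrict where alignments may lie:

* the **search color set** $C_{search}$ — only these genomes count;
* the **quorum** $m$ — every location of a reported path must be covered by
  at least $m$ colors of $C_{search}$.

Design choices where the model left room:

* **Strand model.** K-mers are stored in input orientation; no canonical
  form. Reverse-strand homology is found by searching the reverse
  complement of the query, so a bidirected graph is unnecessary.
* **Compaction and determinism.** Unitigs break at any k-mer junction
  whose in- or out-degree differs from one; isolated cycles break at their
  lexicographically smallest k-mer. Vertices are numbered by sorting
  unitigs by their smallest contained k-mer (ties by label), so identical
  inputs always produce identical graphs.
* **Ambiguity codes.** Characters outside A,C,G,T split the sequence; no
  k-mer spans them. This matches common de Bruijn graph practice and keeps
  the 4-letter rank arithmetic of the index valid.
* **Self-overlaps.** A vertex whose own suffix matches its prefix gets a
  self-edge; the graph may be cyclic. Extension cannot loop forever because
  every extension step consumes a query character.
* **Reference size.** The statistics use $M = \sum_v |\lambda(v)|$, the
  number of characters actually stored, as the reference length.

# Seeding: the PROF/OCC index

Seeds are exact matches of a minimal length $w \le k$. A dense cumulative
profile `PROF` over all $4^w$ w-mers (lexicographic, A<C<G<T) points into a
flat occurrence array `OCC`; the occurrences of one w-mer are contiguous
and sorted by (vertex, offset), so lookups are two array reads plus a
slice. A w-mer lying entirely inside the last $k-1$ characters of a vertex
that has outgoing edges is *suppressed* there — it reappears in the prefix
of every successor, which is where it is stored. (The rule is applied
whenever any out-edge exists, also at branchings, where each successor
holds its own copy.) The default $w = 11$ keeps the profile at $4^{11}
\approx 4.2$ million counters; $w$ much smaller than $k$ is what gives the
method sensitivity beyond plain k-mer matching.

Query w-mers are looked up, matches are kept only if all $w$ covered
locations pass the quorum test, and runs of consecutive matches (query and
label offset both advancing by one) merge into maximal seeds, held per
vertex in label order.

# Ungapped X-drop extension over the graph

Each seed is extended without gaps along the query and along truncated
paths, by depth-first search: rightward over outgoing edges and leftward
over incoming edges (local alignment requires both directions even though
a seed sits mid-path). Within a branch the running score moves by
match/mismatch per character; a branch stops when (i) the running score
falls more than $X$ below the branch best (the BLAST X-drop rule), (ii)
the next location fails the quorum test, (iii) the query is exhausted, or
(iv) a per-seed budget of visited vertices (`max_vertices`, default 1000)
is exhausted — dense graph regions can otherwise make the number of
truncated paths explode; budget-truncated HSPs carry a flag. Every
maximal branch contributes the best-scoring extent it saw; left and right
bests combine into one HSP per branch pair, whose path is trimmed to the
scoring extent. Duplicate and dominated HSPs (query interval and location
set both contained in an equal-or-higher-scoring HSP) are removed.

With an unlimited budget this DFS is equivalent to enumerating all maximal
quorum-fulfilling truncated paths through the seed and running the plain
two-sequence X-drop primitive on each spelled sequence — the test suite
checks exactly that equivalence against brute-force enumeration, and the
single-genome case reduces to ordinary pairwise extension.

# Gapped recomputation and checkpoints

Significant HSPs (by ungapped E-value) are re-aligned with banded global
dynamic programming under linear gap costs (no affine model). The band is
`clamp(8 + ceil(mismatches), 8, 64)` — wider for lower-quality HSPs, the
mismatch count recovered from the ungapped score. The query substring and
the path are extended by one band width on each side (clipped at the query
ends, the path's end vertices and the first quorum-failing location) so
the DP can recover alignment lost to the X-drop stop; the globally optimal
in-band transcript is then trimmed to its best-scoring window containing
the ungapped core, so the junk flanks never penalize the reported score.
If the trimmed banded score does not reach the ungapped score (the global
optimum may route the core off-diagonal to please the flanks), the
ungapped alignment itself is kept — a recalculation never worsens the
alignment it recalculates, and a query's best gapped score is therefore
never below its best ungapped score.

Every reported path carries **checkpoints**: the starts of maximal runs of
path positions sharing one color set (intersected with the search set).
For checkpoint coordinates each character of $\lambda(t)$ is owned by the
vertex that contributes it in the spelled-sequence decomposition (overlap
characters belong to the downstream vertex); the quorum test, in contrast,
always covers *all* locations including both copies of an overlap. The
checkpoint list partitions the path, adjacent color sets differ, and every
set has at least quorum-many members.

# Score statistics

For a random query of length $n$ against a reference of size $M$, the
number of chance hits with score $\ge s$ has expectation
$E_s \approx K M n e^{-\lambda s}$, and $p_s = 1 - e^{-E_s} \approx E_s$
in the small-$E$ regime — the familiar exponential-tail (Karlin–Altschul
style) law, hypothesized and observed to hold for graph alignment scores
as well, with separate $(\lambda, K)$ for the ungapped and gapped regimes.
Equivalently $\log p_s \approx C - \lambda s$ with $C = \log(K M n)$ at
the calibration sizes; `stat_params` stores both forms so E-values rescale
to other $M$ and $n$.

**Naive calibration** draws random queries, records each query's top
alignment score (without color or quorum constraints), and fits a line to
the log complementary cumulative distribution over the window of empirical
tail probabilities between $10^{-2}$ and $10^{-4}$.

**Importance sampling** reaches far smaller p-values. A Metropolis–
Hastings chain over length-$n$ sequences proposes single-character edits
(substitution, or an insertion/deletion balanced at a sequence end, edit
distance at most 2) and accepts with probability
$\min\{1, e^{\lambda_0 (s_y - s_x)}\}$, with $\lambda_0$ set to 0.95 times
the naive estimate so that the stationary distribution
$r_s \propto \pi_s e^{\lambda_0 s}$ is nearly flat across a broad score
range. $\lambda$ is re-estimated from the slope of
$\log T_s$, $T_s = \sum_{s' \ge s} R_{s'} e^{-\lambda_0 s'}$, over scores
with $R_s \ge 50$; $C$ comes from the top decile of the naive scores
(mean of $\log \hat p_s + \lambda s$ over the decile's distinct scores, an
estimator that is exact when the points lie on the fitted line). Absolute
tail probabilities are anchored by matching the reweighted masses to the
naive ccdf over the score range where both are well supported.

**Sampling schedule.** Samples must be far enough apart that the sequence
changes substantially; about $2n/3$ accepted moves suffice. The package
records the *current state at fixed proposal intervals* — the interval is
$2n/3$ divided by a nominal acceptance rate of one half, i.e. about $4n/3$
proposals per sample. Recording at every $2n/3$-th *acceptance* instead
(available as `sampling = "accepts"`) samples the chain's jump process,
which weights each state by its escape probability rather than by the time
the chain spends in it; when neighbor scores are uncorrelated — as for the
hash-based test score function below — holding times grow like
$e^{\lambda_0 s}$ and the jump sample severely under-represents high
scores, biasing $\hat\lambda$ upward. Time-uniform recording is the
weighting the $T_s$ estimator assumes, and with it the synthetic tail
rates are recovered to within a couple of percent.

# The synthetic data

Because all of this must be testable without downloads, the package ships
two generators.

`generate_pangenome()` draws a uniform ancestral sequence and derives each
genome by iid substitutions (default rate 0.01 per site, emulating a
within-lineage bacterial pangenome of strongly related genomes; defaults: 5
genomes of 50 kb) and optional geometric-length indels (off by default so
graph-oracle tests keep truncated-path enumeration small).
`generate_query()` plants a substring with controlled divergence, with a
ground-truth interval for recall checks. What this does *not* emulate:
recombination, horizontal transfer, repeat families, compositional bias,
sequencing error. Passing tests therefore demonstrate algorithmic
correctness on SNP-bubble graphs and calibrated statistics under the iid
null — not performance claims on real bacterial or human data.

`exp_tail_score_fn()` is a deterministic pseudo-score for validating the
calibration machinery in isolation: a polynomial hash (modulo the prime
$2^{26}-5$) maps a sequence to $u \in (0,1)$ and the score is
$\lfloor -\log(u)/\lambda^* \rfloor$, so $P[S \ge s] = e^{-\lambda^* s}$
exactly at integers while single-character edits rehash the sequence. The
seed is spread multiplicatively over the hash range so different seeds give
unrelated score functions.

# Numerical and procedural choices

* Integer scores throughout (match $+1$, mismatch $-2$, gap $-2$, $X=20$
  by default; the expected random-pair score must be negative, which the
  constructor enforces).
* Banded DP centers its band between the two corners
  ($\Delta = \lfloor (|a|-|b|)/2 \rfloor$) and errors if the corners do not
  fit; the band used is widened to $|{|a|-|b|}|$ when flank clipping makes
  the two sequences uneven.
* $T_s$ is accumulated on a log scale (factoring out
  $e^{-\lambda_0 s_{min}}$) to avoid underflow at large scores.
* Ties: co-optimal extension branches are all reported and deduplicated;
  ranking ties break on query start, then on the path.
* Combinatorial guards: on bubble-dense homologous paths the number of
  left/right branch combinations per seed grows combinatorially (every SNP
  bubble within X-drop reach doubles it), so `extend_seed()` caps the
  materialized combinations per seed (`max_hsps`, default 256, keeping the
  highest-gain branches so the best-scoring HSPs are exact; `Inf` restores
  full enumeration), and the quadratic dominance filter checks containment
  only among the top-scoring HSPs — both caps sit far above the reporting
  limit.
* Degenerate inputs: sequences shorter than $k$ are skipped with a
  warning; a constant score function makes calibration fail loudly (no
  tail window); an empty seed set yields an empty, well-typed result.
* Regime comparisons calibrate both regimes on one *shared* query sample
  (`calibrate_regimes()`): a query's gapped score is never below its
  ungapped score, so the paired design removes sampling noise from the
  comparison of the two tails that independent samples would re-introduce
  at desk-scale sample counts.

Problem sizes used by the test suite — chosen so the whole suite exercises
every oracle comfortably on one CPU: graph/index/extension oracles run on
hundreds of random instances of 1–5 genomes, 60–300 bp, $k \in \{5,7,9,
15\}$; the single-genome reduction uses 50 planted homologies on 1.5 kb
genomes; statistics recovery uses $10^6$ naive and $2 \times 10^4$
importance samples per tail rate; the regime-ordering check uses the
default 5-genome, 50 kb pangenome with $10^5$ shared calibration queries
of length 100.

# Known limitations

* Linear gap costs only; no affine model yet.
* The gapped stage never re-explores the graph: it stays on the ungapped
  HSP's truncated path (plus clipped flanks), so a gap cannot switch the
  alignment to a parallel bubble arm.
* Statistics are graph-specific: $(\lambda, K)$ must be calibrated per
  graph and scoring scheme, and `run_search()` refuses E-value filtering
  without them. How graph properties shape the parameters is an open
  question; nothing here models it.
* The dense $4^w$ profile caps $w$ at 13 in practice.
* Quorum checks are exact but per-location; none of the aggregation
  speed-ups one would want for very large color sets are implemented.
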