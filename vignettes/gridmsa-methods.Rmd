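---
title: "Methods: dual-mode progressive alignment and dynamic task scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-mode progressive alignment and dynamic task scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridmsa)
```

# The problem

Aligning a large sequence family progressively requires three stages:
an all-against-all pairwise distance matrix, a guide tree clustering those
distances, and profile merges along the tree.  The first stage dominates
both time and space: for `N` sequences it needs `N(N-1)/2` pairwise
alignments and the same number of distance cells, which for families in the
tens of thousands of sequences exceeds RAM (`pair_count(52750)` is about
`1.39e9` cells; at 8 bytes each that is beyond desktop memory).  `gridmsa`
addresses the two scalability pressure points explicitly: where the matrix
lives (memory versus an offset-addressed disk file) and how the pairwise
workload is spread over workers (dynamic self-scheduling versus static
chunks).

# Stage 1: pairwise distances

## Model

Each pair is aligned globally under the Gotoh three-state affine-gap
recursion; a gap of length $L$ costs $g_o + L\,g_e$ and terminal gaps are
penalised like internal ones (the simplest consistent global model).  The
distance is the per-cent-mismatch of the full alignment:

$$ d = 1 - \frac{\text{identical residue pairs}}{\text{columns with no gap}} , $$

defined as 1 when no gap-free column exists.  This is the classic
"slow-accurate" distance of the Clustal family; raw DP scores are kept on
the `pair_alignment` object so either quantity is available.

Determinism is part of the contract: traceback ties prefer a residue
pairing, then a gap in the second sequence, then a gap in the first, both
for the cell state and the predecessor state; and a pair is always aligned
in canonical (lexicographic) order before measuring the distance, making
$d(a,b) = d(b,a)$ exact rather than approximate.

## Parameters

* `gap_open` (default 10 protein / 15 DNA) and `gap_extend` (0.1 / 6.66),
  in score units of the chosen matrix — Clustal-family defaults.
* The default protein matrix is `DAYHOFF250`, a half-bit log-odds matrix of
  the Dayhoff replacement model at 250 PAM (1 PAM = 1% expected
  substitutions per site).  DNA uses identity scoring (match 1.9).

## The weight-matrix catalogue

The catalogue (`list_weight_matrices()`, 47 protein entries) has two
sources.  The ten classic tables (BLOSUM45–100, PAM30–250) come from
Biostrings.  The rest are computed, not transcribed: for an empirical
replacement model with exchangeabilities $s_{ij}$ and frequencies $\pi$
(Dayhoff, JTT, WAG, LG, VT, and twelve others), the rate matrix
$R = S\,\mathrm{diag}(\pi)$ is scaled to 1% expected change per PAM unit,
exponentiated to the requested distance $t$, and converted to half-bit
log-odds $\;s(a,b) = \mathrm{round}\,2\log_2 P(b \mid a, t)/\pi_b$, which is
symmetric by reversibility.  Computing the tables from the models avoids
hand-copied score grids (a notorious source of silent errors) and makes the
PAM distance a first-class, auditable parameter — `PAM350` really is the
Dayhoff chain at 350 PAM.  Two historical names are deliberately absent
rather than approximated: true BLOSUM30 and Gonnet-250 tables derive from
raw data (BLOCKS counts, Gonnet's 1992 exchangeabilities) that no installed
source provides; `BLOSUM45` and `DAYHOFF250` are the nearest honest
substitutes.  Unknown residues (`X`/`N`) score at the matrix minimum when
the source table has no entry, so they never outrank an informative match.

# The distance store

Both backends expose one contract — `put`/`get` on unordered pairs, a zero
diagonal, and an *incomplete matrix* error for any never-written cell — so
the rest of the pipeline is storage-agnostic and tests can demand
cell-for-cell equality between them.  The disk backend is a single
fixed-layout file (20-byte header: magic, version, `N`, cell width; body:
`8·N(N-1)/2` little-endian doubles at offset `pair_index(i,j,N)`),
sentinel-initialised with NaN so partial runs are detectable, and
reopenable after a process restart.  Indices are computed in doubles
(exact to $2^{53}$) because pair counts overflow 32-bit integers near
$N = 10^5$.  The per-pair FASTA spool (`spool_pairs`, `pair-%09d.fa`)
materialises work units for out-of-process workers; it supports windowed
generation so the spool never needs to exist in full.

# Scheduling the pairwise workload

Pair tasks have very unequal costs when lengths are non-uniform (DP work is
$O(mn)$, so the simulator's default cost model is the length product scaled
to unit mean).  Two policies are implemented:

* **insta** — idle-worker self-scheduling: each worker holds exactly one
  task and receives the next one the moment it finishes (ties to the lowest
  worker index).  This is greedy list scheduling, so its makespan is within
  $(2 - 1/m)$ of optimal; the tests verify that bound against brute-force
  optima on small instances.
* **fixed_chunk** — consecutive chunks of `chunk_size` tasks dealt
  round-robin before execution.  The default `chunk_size` is
  `ceiling(n_tasks / (5 * n_workers))` (no canonical value exists for the
  historical static schedulers; the choice is configurable and recorded in
  `result.par`).  Static assignment reproduces the imbalance pathology the
  dynamic policy removes: with heavy-tailed costs (log-normal with
  coefficient of variation near 2) on 20 workers, the dynamic speedup
  strictly exceeds the static one.

The discrete-event simulator returns per-task traces
`(worker, P, start, finish)` plus makespan, per-worker busy time and idle
fraction $1 - \sum \text{busy} / (m \cdot \text{makespan})$.  Idle
detection is event-driven (workers announce completion) rather than polled.
Real execution uses the same assignment contracts over a local fork pool
(`parallel::mclapply`; per-task dispatch for the dynamic policy, static
pre-partitioning for chunks).  Whatever the policy, worker count, executor
or storage mode, the distance phase must produce bit-identical stores —
the suite enforces this across all twelve configuration combinations.
A failed pair task is re-queued once before the job aborts naming the task.

# Stage 2: the guide tree

Saitou–Nei neighbor joining with the Q-criterion.  Numerical choices, all
deterministic:

* Q-ties resolve to the lexicographically lowest active-cluster pair, with
  clusters kept in creation order (a merged cluster takes the position of
  its earlier member), so the tree is invariant to input order up to
  genuinely tied topologies.
* A negative branch length from the closed-form estimate is clamped to 0
  and the deficit moved to the sibling branch, preserving the pair's total
  distance (Clustal-family convention).
* The final three-cluster star is resolved in closed form and the unrooted
  tree is midpoint-rooted — the root bisects the longest leaf-to-leaf
  path — yielding the rooted binary tree whose postorder is the merge
  schedule.  With two sequences the single join splits the distance evenly.

On additive matrices this recovers the generating topology exactly (tested
on 100 random 8-leaf trees, and with branch lengths to $10^{-9}$ on a
4-taxon case).  The implementation is the dense $O(N^3)$ algorithm with
store-streamed row loading; no fast-NJ heuristics, since correctness and
determinism outrank speed at desk scale.

Per-join checkpoints replay the join history into `N-1` stage-numbered
Newick snapshot files (nine-digit suffixes like the pair spool), each
holding the forest of active clusters; the last equals the final tree.

Sequence weights are the branch-sharing scheme: a leaf's weight sums, over
the branches on its root path, branch length divided by the number of
leaves below that branch; weights are normalised to max 1, and an all-zero
tree (identical sequences) degenerates to uniform weights.

# Stage 3: progressive alignment

Leaves start as single-row profiles carrying their weight.  Each merge
computes the weighted frequency vectors $f(a, c)$ per column (gap mass
excluded, total weight in the denominator), scores column pairs as
$\sum_{a,b} f_1(a,c_1) f_2(b,c_2)\, s(a,b)$, and runs the same affine DP as
stage 1 with plain `gap_open`/`gap_extend`.  A gap move inserts a whole gap
column into one side's rows, so earlier gaps are never removed.  This
deliberately omits the position-specific gap-penalty heuristics of the
classic interactive aligners (residue-specific penalties, hydrophilic-run
relaxation, short-gap discouragement) — the largest simplification in the
package: alignments of distant sequences will be somewhat more gap-scattered
than those of heuristic-laden tools, while the pipeline's structural
properties (determinism, de-gap exactness, schedule invariance) are easier
to state and test.

The SP score sums, over unordered row pairs, substitution scores on
residue–residue columns and affine penalties on maximal gap runs projected
onto the pair, ignoring gap–gap columns; the weighted variant multiplies
each pair term by $w_i w_j$ and reduces to the unweighted score at unit
weights.

`realign_region` re-runs the whole pipeline on the de-gapped fragments of a
column window and splices the result back, leaving outside columns
byte-identical.  The fragment set gets its own distance matrix and guide
tree (self-contained, rather than reusing the global tree, so the window's
result never depends on stale global structure); a row empty inside the
window returns as all gaps.

# The synthetic family generator

The generator emulates a large, divergent protein superfamily at
configurable scale: lengths follow a log-normal truncated to
`[min_length, max_length]` whose location parameter is fitted (by
`uniroot`) so the *truncated* mean hits `mean_length`; defaults are mean
440, bounds 10 and 11600, `sdlog` 0.6 — a spread that keeps draws inside
the bounds at `n = 10000` while giving a long right tail.  Each member
derives from one random ancestor by per-site substitutions (rate 0.3, never
to the same residue), indel events (rate 0.05 per site, geometric lengths
with `p = 0.3`), and a trim/pad to its own length draw.  These rates were
chosen once as a realistic divergent-family setting and are configurable.

What the generator does *not* model: phylogenetic correlation between
members (all derive from one ancestor in a star), rate heterogeneity across
sites, codon structure, or compositional bias.  Tests passing on these
families therefore demonstrate the pipeline's algorithmic contracts —
determinism, invariants, oracle agreement — not alignment accuracy on real
homologs; accuracy benchmarking would require curated reference alignments,
which is out of scope.

Task-cost generation (`gen_task_costs`) offers uniform, log-normal and
Pareto draws under a seed; the log-normal with $\sigma^2 = \ln 5$ (cost
CV 2) is the reference heavy-tailed workload for scheduler experiments.

# Problem sizes and reproducibility

All randomness flows from explicit integer seeds (`withr::with_seed`), so
every run, including parallel ones, is reproducible; `result.par` is
sufficient to reproduce a job byte for byte.  The test suite runs the
pipeline end to end at desk scale — 30 sequences across all twelve
scheduler/storage configurations, and 300 sequences of mean length 120 in
disk mode — and the statistical checks use `n = 10000` length draws and
$10^5$ Pareto draws; these sizes were chosen so the full suite completes in
minutes while keeping every estimate's sampling error far below its test
tolerance.

# Known limitations

* No k-tuple fast distance mode: every distance is a full DP alignment, so
  the distance phase is quadratic in `N` with a large constant; the disk
  store removes the memory ceiling, not the time cost.
* No local (Smith–Waterman) alignment, anchor or consistency schemes, or
  iterative refinement beyond the explicit `realign_region`.
* The profile DP uses plain affine penalties (see stage 3) and `-` as the
  only gap symbol (`.` is normalised on input).
* The fork executor is POSIX-only (it relies on process forking) and
  exists to honour the worker-pool contract; cluster transports are an
  interface for the caller, not a dependency.
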