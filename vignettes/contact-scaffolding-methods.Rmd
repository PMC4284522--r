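---
title: "Scaffolding genomes from chromosome contact data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding genomes from chromosome contact data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proximity-ligation assays (3C-seq, Hi-C) measure how often pairs of genomic
loci touch in the nucleus. Within a chromosome, contact frequency decays
steeply with genomic distance; between chromosomes it is roughly uniform and
low. A contact matrix computed against a *correct* assembly therefore shows
a strong diagonal and block structure, while misassemblies betray themselves
as off-diagonal blocks, and collapsed repeats as rows with about twice the
expected number of contacts. `proxiscaf` turns this observation around: it
searches the space of one-dimensional genome arrangements for structures
that make the observed contact matrix likely.

## The probabilistic model

The genome is represented as bins — runs of consecutive restriction
fragments — arranged into ordered, oriented scaffolds, possibly with
duplicated or deleted bins. Writing $G$ for an arrangement and $D$ for the
observed contact matrix, the posterior is $p(G \mid D) \propto p(D \mid G)$
under a flat prior over arrangements.

Expected contact intensities follow a power law with a plateau. For a cis
pair at genomic distance $s$ (midpoint to midpoint, in bp),

$$P_c(s) = P_t \,(s/s_0)^{b} \quad (s \le s_0), \qquad P_c(s) = P_t \quad (s \ge s_0),$$

with $b < 0$; trans pairs occur with the uniform intensity $P_t$ per
bp². The prefactor is fixed by continuity at $s_0$. The three nuisance
parameters $\xi = (b, s_0, P_t)$ are sampled jointly with the structure
under a flat prior inside box constraints; they are not fixed in advance
because published estimates vary across organisms and conditions.

Counts are Poisson: for a pair of elements $(i, j)$ with lengths $l_i, l_j$,

$$k_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
  \lambda_{ij} = E \cdot l_i\, l_j \sum_{\text{copy pairs}} P(\text{geometry}),$$

where $E$ is a fixed exposure constant matching the model to sequencing
depth. Exposure is deliberately *not* sampled: it is exactly confounded
with $P_t$, so the package keeps $E = 1$ and lets $P_t$ carry the absolute
intensity scale (contacts per bp²). `fit_exposure()` exists for
depth diagnostics. The sum over copy pairs means a bin placed twice is
expected to show twice the contacts with the rest of the genome — the
collapsed-duplication signature the sampler exploits. Deleted (unplaced)
bins are not dropped from the likelihood: their pairs keep a floor
intensity of $10^{-3} P_t$, so deleting a bin with real contacts costs
likelihood. Without such a floor, deletion would trivially "explain" any
data by removing terms.

### Why half-bin units

A likelihood computed on bin-level counts with midpoint distances is
invariant under flipping any single bin: integrating intensity over a bin's
extent gives the same answer in either orientation. Orientation only
becomes identifiable when the data are held at a resolution finer than the
moved unit. `proxiscaf` therefore stores contact matrices at *half-bin*
resolution: every orientable bin (two or more restriction fragments)
contributes two units — its two halves along the source sequence — and
flipping the bin swaps the scaffold positions of its halves. This is also
why a bin needs at least two restriction fragments to be orientable at all,
and why `make_bins(min_rf = 2)` is the default. Distances between units are
midpoint to midpoint, floored at `max(1, min(l_i, l_j)/2)` bp so coinciding
midpoints keep a finite intensity.

## The sampler

Each iteration visits one bin (cycles visit every bin exactly once, in
random order). For the visited bin, `m` partner bins are drawn without
replacement with probability proportional to their observed bin-level
contact counts with the focal bin plus a pseudocount `alpha = 0.01` (so
zero-contact partners stay reachable). Around the (bin, partner) pairs the
14-move catalogue is instantiated — transpositions, reciprocal
translocations, deletion, duplications and ejection; see
`?move_catalogue` — giving `14 m` candidate structures, plus the current
structure as a null candidate. One candidate is selected with probability
proportional to $\exp(\log L / T)$ and accepted unconditionally
(systematic acceptance, in the spirit of multiple-try Metropolis but
without the rejection step, which keeps one likelihood evaluation per
candidate). The temperature default $T = 1$ behaves near-greedily because
log-likelihood differences between candidates are typically large; $T \to
0$ gives exactly "retain a highest-likelihood candidate". After each
structure update the nuisance parameters get one Metropolis sweep (linear
random walk in $b$, log-scale walks in $s_0$ and $P_t$), with proposal
scales adapted towards ~0.3 acceptance during burn-in and frozen
afterwards.

When the focal bin has several placed copies, its *other* copies are legal
partners. This matters: a common local optimum has a chromosome torn in
two with a bin spuriously duplicated at both break ends, and the single
move that heals it is a translocation whose partner is the other copy of
the focal bin.

Each new cycle restarts from the highest-likelihood structure seen during
the previous cycle; within a cycle the chain moves freely. A burn-in of
two cycles is discarded from posterior summaries. All stochastic choices —
bin order, partner draws, copy choices, candidate selection, parameter
proposals — are drawn from one seeded generator in a fixed order, so runs
are reproducible bit for bit.

### Computational strategy

Scoring tens of candidates per iteration requires cheap likelihood
evaluations. The evaluation decomposes the Poisson log-likelihood against
an "everything trans" baseline whose data-side total is a constant of the
dataset: only same-scaffold pairs closer than $s_0$, and pairs involving
*special* units (unplaced or multi-copy), deviate from the baseline. The
expected-mass side uses a closed form for the trans total derived from
scaffold length sums. Each evaluation therefore costs
O(placements + intra-scaffold pairs + special rows) — independent of the
number of non-zero contact pairs — and is implemented in C++. The
brute-force scalar evaluation retained in the test suite verifies the fast
path to 1e-6 relative error across random structures, duplications and
deletions. `delta_log_likelihood()` is the difference of two such
evaluations.

## The simulator

`simulate_contacts()` draws independent Poisson counts from the expected
matrix of a known structure, rescaled so the expected total matches the
requested depth; because every intensity is proportional to $P_t$, the
rescaling is reported as an effective $P_t$, which is the ground truth for
parameter-recovery experiments. Counts are drawn pairwise Poisson rather
than read by read; the two are equivalent in distribution for independent
pairs at a given expected total. `scramble()` permutes placements (by
default into single-bin scaffolds with random orientations — the de novo
starting condition), and `inject_rearrangement()` produces translocations,
inversions, segmental duplications, and collapsed duplications (reads
simulated from a two-copy truth, mapped to a one-copy reference).

Default simulation conditions are yeast-like: 16 chromosomes with the
S. cerevisiae length ratios, 11 kb orientable bins, $b = -1.5$,
$s_0 = 10^5$ bp, and a sequencing depth of ~19,300 incident contacts per
bin (`depth_for_bins()`), the per-bin depth of a deeply sequenced
yeast-scale 3C-seq library. Depth is held *per bin* when the bin count is
scaled, because assembly quality is governed by the information available
per placed element. What the simulator does not emulate: mapping noise and
mapq filtering (synthetic counts are assigned directly to units), enzyme
site biases, copy-number variation beyond injected duplications, and
distance-decay exponents that vary along chromosomes. Closed-loop successes
on simulated data therefore demonstrate the estimator's correctness under
its own model assumptions, not robustness to every artefact of real
libraries.

## Experiment scales used by the tests and the acceptance script

Reassembly experiments run at reduced bin counts so a full posterior
exploration stays in the minutes range on one core: the test suite uses a
96-bin, 16-chromosome yeast-ratio genome for closed-loop and downsampling
experiments and a 160-bin, 4-chromosome genome (hg19 chr7/17/19/22 length
ratios) for the multi-chromosome assignment experiment;
`scripts/acceptance.R` uses 128 and 240 bins for the same designs.
Full-depth and 10%-depth runs use at least 5,000 sampler iterations over 3
seeds. The 0.1% condition uses 12 cycles over 2 seeds: at that sparsity
the chain reaches its wandering steady state within a few cycles — the
reported error is the plateau value — while per-iteration cost keeps
growing with the duplication load the sparse posterior accumulates. Parameter
recovery conditions on the true structure of a 128-bin four-chromosome
genome at 2×10⁶ contacts, where chromosome spans comfortably exceed
$s_0$ so the plateau is identifiable.

## Evaluation metrics

`reconstruction_error()` is the fraction of the reference's oriented bin
junctions missing from the assembly, where a junction matches directly or
as its reverse complement; it is 0 exactly when the assembly equals the
reference up to scaffold order, naming and whole-scaffold reversal, and
duplications are compared as multisets. `chromosome_assignment_accuracy()`
maps each scaffold to the reference chromosome contributing most of its
length and scores bins by that majority. `ordering_and_rank()` reports the
percentage of bins whose immediate-neighbour set matches the reference and
rank errors after aligning each scaffold's direction. Structure dispersion
is summarised by `dispersion()`, the interquartile range of the contig
count over post-burn-in iterations — zero when the chain has collapsed
onto a single structural mode, large when the data cannot pin the
structure down (as under heavy downsampling). This uncertainty readout
needs no reference genome, which is what makes it useful on real de novo
assemblies.

## Numerical and design choices

* Coordinates are 0-based half-open; distances in bp.
* Copy indices increase monotonically per bin and are never reused within
  a run, so traces and layouts are replayable.
* Translocation variants are parameterised by cut side (before/after both
  bins) × rejoin (direct/inverted); on a single scaffold they degenerate
  to scaffold splits (direct) or a segmental inversion (inverted).
* Orientation parameters of moves are relative (forward = keep, reverse =
  flip), so the move set commutes with whole-scaffold reversal.
* ξ initialisation is a least-squares fit of the distance-binned contact
  curve of the initial structure, falling back to mild defaults
  ($b = -1$, $s_0$ = 20 median bin lengths) when the start has too few
  cis pairs (e.g. a bag of singletons).
* The candidate count is always exactly `14 m`: degenerate candidates at
  scaffold ends are emitted rather than filtered, keeping the proposal
  distribution simple.
* Ties in greedy selection are broken uniformly at random.

## Known limitations

Junctions between bins that were not neighbours in the input are resolved
only to bin resolution; gap sizes between joined contigs are not
estimated (AGP output writes fixed 100-N scaffold gaps). One global ξ is
fitted, although decay exponents are known to differ between chromosomes
and near centromeres/telomeres. Very sparse matrices (per-bin depth of a
few tens of contacts) do not determine a unique structure; the sampler
then reports its uncertainty through a persistent spread in `n_contigs`
rather than converging, which is the intended behaviour, not a failure
mode. Mapping of reads and matrix balancing are out of scope: the package
consumes pre-mapped fragment-level pairs or ready-made matrices.
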