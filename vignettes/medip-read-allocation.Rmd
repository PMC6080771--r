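---
title: "Allocating MeDIP-seq reads to single CpG sites: model, algorithms, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating MeDIP-seq reads to single CpG sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipcpg)
```

## The inference problem

MeDIP-seq reads are evidence of methylation somewhere on the read, not at a
base. When CpG sites are farther apart than a read, each site's methylation
is read off directly: reads covering an isolated site imply it is
methylated. Trouble starts where neighbouring CpG sites are closer than the
read length, so one read covers several sites and the site that actually
bound antibody is unobserved. `medipcpg` treats that assignment as missing
data.

Sites are first segmented into **regions** by single-linkage chaining with
a linking distance equal to the (maximum) read length: two sites in
different regions can never share a read, so regions are independent
inference units. Within a region of $G$ sites and $n$ retained reads, the
observation is the covered span $[k_i, l_i]$ of each read; the binary
indicators $X_{ij}$ ("site $j$ contributed to the sequencing of read $i$")
are structural zeros outside the span and latent inside it.

## Model and assumptions

Each site has a contribution propensity $\lambda_j > 0$, and the $X_{ij}$
are assumed independent Bernoulli with
$q_j = \lambda_j / (1 + \lambda_j)$. Independence across sites of the same
read is admittedly strong — antibody binding at one CpG may interfere with
binding at a neighbour — and no correlation model is offered; this is the
main modelling caveat. Two conditioning regimes give the two fitted models:

* conditioning on exactly one contributor per read makes the row
  multinomial with $p_j = \lambda_j / \sum_s \lambda_s$
  (**single-contributor model**);
* conditioning on at least one contributor gives the truncated
  product-Bernoulli law
  $\prod_j q_j^{x_j}(1-q_j)^{1-x_j} \big/ \bigl(1 - \prod_j (1-q_j)\bigr)$
  (**at-least-one model**).

$\lambda_j$ is identified only through $p_j$ or $q_j$ and is never stored.

## The EM algorithms

**Multinomial.** E-step
$\tilde x_{ij} = p_j^- / \sum_{s=k_i}^{l_i} p_s^-$ for latent entries;
M-step $\hat p_j = \sum_i \tilde x_{ij} / n$. This is a genuine EM for the
observed-span likelihood $\sum_i \log \sum_{s=k_i}^{l_i} p_s$, so the
trace is non-decreasing (asserted in tests at $10^{-10}$ slack). Sites
covered by no read keep $\hat p_j = 0$ from the first iteration. The fit
is insensitive to the starting value (verified as a test property against
10 random seeded initialisations, not assumed); the default
initialisation is uniform.

**Truncated Bernoulli.** E-step
$\tilde x_{ij} = q_j^- / \bigl(1 - \prod_{s=k_i}^{l_i}(1-q_s^-)\bigr)$;
M-step
$\hat q_j = \bigl(\sum_i \tilde x_{ij}\bigr)\bigl(1 - \prod_{s=1}^{G}(1-q_s^-)\bigr)/n$.
The printed closed-form update descends from score equations carrying a
$\sum_j q_j = 1$ constraint that is alien to independent Bernoulli
probabilities; the implementation follows the printed updates verbatim
(they are self-contained) and deliberately does **not** impose
$\sum q_j = 1$ as an invariant. A consequence is a degenerate fixed point:
because the update multiplies by $1 - \prod_s(1 - q_s^-) < 1$, on many
inputs all $\hat q_j$ collapse geometrically toward 0 while their ratios —
and hence the allocation $n\,\hat q_j / (1 - \prod_s (1-\hat q_s))$, whose
denominator tends to $\sum_s \hat q_s$ — stabilise. The collapse is
detected (likelihood stagnation with parameters still shrinking below any
plausible contribution rate) and reported via `converged = FALSE`,
`degenerate = TRUE` rather than silently returned; allocated counts remain
well defined.

**Numerics.** Convergence is max-norm parameter change below `tol`
(default $10^{-8}$; $10^{-6}$ in the whole-sample wrapper), capped at
`max_iter` $= 10^4$. Span probabilities and the truncation denominators
are floored at $10^{-300}$ before logs and divisions. Per-iteration work is
$O(G^2)$ after collapsing identical spans with multiplicities, so
thousands of regions fit in seconds.

**Allocation bracket.** The integer allocation rounds half-even; in the
multinomial case the rounding residual is redistributed by largest
fractional remainder (ties to the lower index) so per-region allocated
counts conserve $n$ exactly — the source material never defines its
bracket nor addresses $\sum_j [n p_j] \ne n$, so conservation was chosen
as the defensible reading. No conservation correction applies to the
Bernoulli bracket, whose expected counts need not sum to $n$.

## Differential testing

The per-site statistic is deliberately boring: a two-sided exact
conditional (Fisher) test of the 2×2 table
$[c_A, T_A - c_A;\; c_B, T_B - c_B]$ with $T$ the sample's summed
allocated counts. It is exact at the small counts typical of single CpG
sites, and library size enters only through the totals. The statistic is a
pluggable function, so an integrative MeDIP+MRE statistic can be swapped
in; MRE counts are carried through the tables but do not enter the default
test. Multiplicity is handled by the package's own Benjamini–Hochberg
step-up (validated against `stats::p.adjust` exactly); "differentially
methylated" means $q$ (or, for false-positive profiling, $p$) below a
stated cutoff, with counts of sites strictly below each cutoff reported.

## What the simulator states, and why

The generator emulates the experiment's causal story on a synthetic
chromosome: clusters of `sites_per_region = 5` CpG sites with uniform
30–100 bp gaps, 2 kb apart; binary methylation states; sonication
fragments of ~200 bp; 50 bp sequenced reads; capture iff a methylated CpG
on the **read** bound antibody. Defaults worth defending:

* **Read length 50 bp, not fragment-extended.** Region coupling, capture
  and coverage are all read-interval notions here: a 50 bp read covers 1–3
  neighbouring sites at these gaps, which is the regime the model
  describes (the worked 5-site example has spans of 1–3). Extending reads
  to fragment length (a MEDIPS-style convention) makes nearly every read
  cover a whole cluster; the allocation MLE then carries 3–8× multinomial
  variance and per-site exact tests become badly anticonservative. The
  fragment length remains in the config as the sonication scale but plays
  no role in the allocation model.
* **Single-contributor draws are contributor-first.** The contributing
  site is drawn from $P$ (over methylated sites), then the read start is
  uniform among the $rl+1$ placements overlapping that site's
  dinucleotide. This reproduces the single-contributor law exactly and is
  equivalent to sonication-uniform placement with capture probability
  proportional to the summed affinity of covered methylated sites. The
  naive alternative — uniform placement, capture probability 1, contributor
  drawn afterwards — makes the observed spans carry no information about
  $P$ at all, so nothing could recover $P$ from such data; it would
  contradict the model it is meant to emulate. The at-least-one variant
  *is* span-first by nature: place the read, let each covered methylated
  site contribute Bernoulli($q_j$), keep the read iff at least one did.
* **Poisson per-cluster depth** (expected `reads_per_region`), because a
  sequencing library samples loci as a point process; fixed depth damps
  count variance below what an exact conditional test assumes and makes
  null p-values artificially conservative. `depth_model = "fixed"` exists
  for variance-free recovery experiments.
* **MRE-seq stand-in:** unmethylated sites are enzyme-compatible with
  probability `mre_avail` (a Bernoulli stand-in for cut-site sequence
  context) and compatible sites emit Poisson(`mre_depth`) reads anchored
  at the C.

Not emulated: sequencing error, PCR duplicates, mappability/GC bias,
between-library protocol differences, and antibody interference between
nearby CpGs. A green simulation test therefore establishes correctness of
the inference under the model's own assumptions — not robustness to
real-data artifacts.

## Replicate null calibration: an honest discrepancy

The replicate analogue of a false-positive table simulates two read sets
from one truth ($10^4$ fully methylated sites, mean 60 reads/site, seed
42) and runs both pipelines. The acceptance suite computes two properties:
the fraction of allocated-count p-values below 0.05 falls in the
conservative exact-test band $[0.03, 0.07]$ (it passes), and the
deconvolving pipeline reports no more sub-cutoff sites than the raw
comparator at each cutoff $10^{-3}..10^{-8}$ (it fails by a small margin,
and the expectation is left asserted and red). The failure is structural,
not a defect: in a perfect null, raw per-site counts are Poisson and the
conditional test is calibrated-to-conservative for them, while allocated
counts $n\hat p_j$ carry the EM estimator's variance, which strictly
exceeds multinomial variance wherever spans are ambiguous (information
inequality). The real-data ordering that motivated the expectation — raw
reporting several-fold more replicate false positives — rests on small
systematic differences between real libraries, whose rejection counts
scale with count magnitude (raw counts being multi-counted); an exactly
identical-truth simulation excludes that mechanism by construction.

## Degenerate inputs and tie-breaks

* Reads covering no CpG site are discarded and tallied, never dropped
  silently; empty read files produce all-zero outputs with a warning.
* A read whose covered sites straddle two regions is a hard error naming
  the remedy (raise `link_dist`).
* `N`-containing reference stretches yield no CpG sites; blacklist
  intervals remove sites by ≥1 bp dinucleotide overlap.
* Coverage requires ≥1 bp overlap with the 2 bp dinucleotide
  (`min_overlap = 2` switches to full containment).
* MRE reads anchor to the nearest CpG within the motif-derived shift of
  their 5′ end (strand-aware); equidistant ties resolve to the lower
  coordinate.
* Rounding ties in allocation go to the lower site index, making outputs
  deterministic; the whole pipeline is byte-identical under a fixed seed.

## Known limitations

Besides the independence assumption and the simulator gaps above: the
package does not calibrate absolute methylation levels (no CpG-density
coupling factors à la BATMAN/MEDIPS), does not call region-level DMRs,
does not model replicate dispersion (each comparison is two samples), and
the truncated-Bernoulli model inherits the printed update's degeneracy —
its allocations are usable, but its $q$ scale should not be interpreted.
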