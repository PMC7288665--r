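---
title: "Scanning for lineage-exclusive positive selection with dual-foreground branch-site tests"
author: "PSGscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for lineage-exclusive positive selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PSGscan)
```

## The problem

A recurring question in comparative genomics is which protein-coding
genes were driven by positive selection on *one particular lineage* —
for example, the branch leading to a blood-feeding insect whose closest
sequenced relative does not share the trait.  A site under positive
selection fixes amino-acid replacements faster than neutral drift
allows: the nonsynonymous/synonymous rate ratio
$\omega = d_N/d_S$ exceeds 1.  Most sites in most proteins are strongly
conserved ($\omega \ll 1$), so the signal of interest is a small set of
codon sites, on a single branch, hidden among purifying background.
PSGscan implements the full inferential chain for this design: the
branch-site codon model, its likelihood-ratio test, empirical Bayes
identification of the selected sites, and a genome-scale scan protocol
with false-discovery-rate control and a cross-validation rule that
makes the final gene set *exclusive* to the focal lineage.

## The codon substitution model

Substitutions run over the 61 sense codons of the standard nuclear
code (stop codons are excluded from the state space).  The
instantaneous rate from codon $i$ to codon $j$ follows the
Goldman–Yang parameterisation:

$$
q_{ij} \propto
\begin{cases}
0 & \text{more than one position differs}\\
\pi_j & \text{synonymous transversion}\\
\kappa \pi_j & \text{synonymous transition}\\
\omega \pi_j & \text{nonsynonymous transversion}\\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio and $\pi_j$ the
equilibrium frequency of the target codon.  Codon frequencies default
to the F3x4 estimator (position-specific nucleotide frequencies,
renormalised over sense codons) with a pseudocount of one observation
per nucleotide cell so that no frequency is exactly zero on short
alignments; `equal`, `F1x4` and empirical codon counting are also
available.  The matrix is time-reversible with respect to $\pi$, which
the likelihood machinery exploits: $P(t) = e^{Qt}$ is computed through
the symmetrised eigendecomposition
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$, with a dense
`Matrix::expm()` fallback if the decomposition ever misbehaves
numerically.

## The branch-site model and its test

Branches are partitioned into one *foreground* branch and background.
Model A assumes four latent site classes:

| class | proportion | background $\omega$ | foreground $\omega$ |
|-------|------------|--------------------|---------------------|
| 0     | $p_0$      | $\omega_0 < 1$     | $\omega_0$          |
| 1     | $p_1$      | $1$                | $1$                 |
| 2a    | $p_{2a}$   | $\omega_0$         | $\omega_2 \ge 1$    |
| 2b    | $p_{2b}$   | $1$                | $\omega_2$          |

with $p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1-p_0-p_1)\,p_1/(p_0+p_1)$.  The null hypothesis fixes
$\omega_2 = 1$ (model A1); twice the log-likelihood difference is
compared to $\chi^2_1$.  Because the null pins $\omega_2$ at the
boundary of its domain, $\chi^2_1$ is conservative; the 50:50
point-mass/$\chi^2_1$ mixture is available via `mixture = TRUE`, but
the $\chi^2_1$ convention is the default, matching the test's usual
usage.

**Rate scaling.**  One convention matters more than it looks: all four
class matrices are scaled by a *single* factor — the class-mixture
average rate using the background omegas — so that a branch length is
the expected number of substitutions per codon averaged over site
classes, and the $\omega_2$ class genuinely evolves faster than the
purifying classes.  Scaling each class to unit rate separately (a
tempting simplification) silently deletes most of the branch-site
signal, because only the substitution *composition*, not the rate,
would then distinguish a selected site.  The simulator uses the same
convention, so simulated data and fitted model agree about what a
branch length means.

## Likelihood evaluation and fitting

Site patterns are compressed (identical columns evaluated once) and
per-class site likelihoods are computed by Felsenstein pruning over
the 61-state space in compiled code.  Site classes differ only in
which rate matrix the foreground branch uses, so the pruning core
reuses the node partials of an already-computed class and recomputes
only the path from the foreground branch to the root.  Gap codons
(`---`) and any codon containing a non-`ACGT` character are treated as
fully missing data (partial likelihood 1 in every state); in-frame
stop codons are rejected when an alignment is constructed.

Maximum-likelihood fitting uses bounded L-BFGS-B on transformed
parameters: $\log\kappa$ (bounds $0.1$–$99$), a logistic transform of
$\omega_0$ on $(10^{-4}, 0.999)$, $\log(\omega_2 - 1)$ (upper bound
999), a softmax transform of $(p_0, p_1)$, and log branch lengths.
Three deterministic starts are screened with a few iterations each —
neutral-ish, strong-purifying (null) or strong-selection
(alternative), and a dispersed third start — then the best start is
polished in stages: the codon parameters at fixed branch lengths, a
bounded joint pass over codon parameters and branch lengths, and a
final codon-parameter polish to a relative log-likelihood tolerance of
about $10^{-6}$.  Capping the joint pass costs little statistically:
the null and alternative models are compared at the *same* branch
lengths, so residual branch-length error largely cancels from the LRT.
The third start is deterministic rather than randomly jittered so that
a scan is exactly reproducible without threading RNG state through the
optimiser.  Branch lengths are estimated under the null and reused,
fixed, under the alternative (re-optimisation is available with
`reoptBranchLengths = TRUE`); the alternative is additionally seeded
at the null optimum, which enforces the nesting inequality
$\ell_A \ge \ell_{A1}$ by construction.  A fit that still lands below
the null by more than $10^{-4}$ is flagged, refitted once with a
larger budget, and excluded from the final gene set if it remains
flagged — never silently accepted.

## Site identification

Given the alternative-model fit, the posterior probability that a site
belongs to the selected classes (2a or 2b) is computed by Bayes' rule
from the per-class site likelihoods.  `NEB` plugs in the
maximum-likelihood estimates and is the default surface for the scan.
`BEB` additionally averages over a discrete uniform prior grid — ten
midpoints per dimension on $\omega_0 \in (0,1)$,
$\omega_2 \in (1,11)$, and the admissible $(p_0, p_1)$ pairs of the
same grid — with $\kappa$, branch lengths and the mixture rate scale
held at their MLEs, mirroring how the established BEB treats nuisance
parameters.  Candidate sites are those with posterior above 0.95.

## The scan protocol

Each orthologous group passes through:

1. **Sequence-length filter** — sequences whose ungapped length is
   *strictly* below half the group's mean ungapped length (mean taken
   before any removal, single pass) are dropped.
2. **Minimum-taxa filter** — groups are excluded with fewer than five
   species, fewer than four ingroup species (the ingroup is every
   non-outgroup taxon, including the foreground and counter-foreground
   species), or a missing foreground species, counter-foreground
   species, or outgroup.
3. **Dual tests** — every surviving group is tested twice: test I with
   the foreground species' terminal branch as foreground, test II with
   the counter-foreground's.  The foreground is always the terminal
   branch of the designated species.
4. **Pooled FDR** — all $2N$ p-values form one Benjamini–Hochberg
   family.  With 3,318 groups the planner schedules exactly 6,636
   tests.
5. **Exclusivity rule** — a test is *positive* iff its q-value is at
   most $\alpha = 0.05$ *and* at least one site clears the 0.95
   posterior threshold.  A gene is a candidate iff test I is positive
   and test II is not; genes positive in both lineages are discarded
   even when the implicated codon sites differ.
6. **Site filters** — candidate sites in gap-rich regions (mean gap
   fraction over a ±5-codon window above 0.5) are removed, as are
   sites whose foreground codon translates to serine (both the TCN and
   AGY families), since serine's two disconnected codon families can
   mimic selection through parallel synonymous paths; a gapped
   foreground codon removes the site as indeterminate.
7. **Verdict** — a gene is reported as a lineage-exclusive PSG iff it
   survived the exclusivity rule with at least one site surviving both
   filters.

The $\alpha = 0.05$ threshold on q-values, the window half-width 5 and
the gap-fraction threshold 0.5 are configurable; the windowed gap rule
is an algorithmic stand-in for manual alignment curation and its
defaults were chosen to be permissive (only clearly gap-dominated
regions are excluded).

## What the simulator emulates — and what it does not

`simulateGroupSet()` generates ortholog-group collections under the
exact generative model the test assumes: per-site latent classes fixed
across the tree, a selection signal ($\omega_2 > 1$) confined to one
terminal branch in a stated fraction of groups, and nuisance variation
drawn per group from $\kappa \sim U[1,4]$,
$\omega_0 \sim U[0.05, 0.5]$, $\omega_2 \sim U[2,8]$ for selected
groups, class weights $p_0 \sim U[0.45, 0.75]$,
$p_1 \sim U[0.10, 0.25]$, branch lengths $U[0.05, 0.5]$ substitutions
per codon, 4–10 taxa and 200–600 codons per group.  These ranges are
typical of insect 1:1 ortholog sets at family-to-order divergences;
groups below the five-species threshold and truncated (mostly-gap)
sequences are generated on purpose to exercise the filters, and an
optional gap-block corruption exercises the alignment-quality rule.
Truth categories are allocated deterministically (first $k$ groups
after a seeded shuffle), so expected counts are exact, and one global
seed expands to per-group seeds through a counter scheme.

Passing tests on these data show that the pipeline recovers the model
it assumes; they cannot show robustness to what real alignments add on
top: alignment error, indel evolution, recombination, codon-usage bias
beyond F3x4, rate variation beyond the four-class mixture, or
misspecified tree topologies.  Those failure modes are documented
limitations of the branch-site framework itself, and the scan's
filters (length, taxon sampling, gap windows, serine exclusion, the
dual-foreground cross-validation) exist precisely to blunt them.

## Numerical choices

* Convergence: relative log-likelihood tolerance ~$10^{-6}$ (L-BFGS-B
  `factr`); LRT statistics are clamped at 0; ties between optimiser
  starts break to the first found.
* Eigendecompositions are memoised per $(\kappa, \omega)$ within a
  fit; pruning partials are rescaled per node to avoid underflow on
  deep trees.
* Branch-length bounds $[10^{-7}, 20]$ substitutions/codon; fitted
  lengths are reported in the input tree's edge order.
* Groups without a tree get a neighbour-joining topology from codon
  mismatch distances, flagged in the output (`treeFallback`).
* All report writers format floating-point numbers explicitly, so a
  rerun with identical inputs and seed is byte-identical.

## Problem sizes used in the validation experiments

The package's acceptance experiments run at desk scale, chosen once:
type-I error on 200 null groups of 6 taxa × 300 codons; parameter
recovery at $\omega_2 = 4$ on 8-taxon groups of 500/2,000/5,000 codons
(10 replicates each, branch lengths held at their known values to
isolate $\omega_2$ estimation); design-soundness and end-to-end
recovery on a 60-group set with planted foreground- and
counter-foreground-selected genes.  The genome-scale accounting
identity (3,318 groups → 6,636 scheduled tests in one FDR family) is
checked by enumeration on placeholder groups without fitting.

## Known limitations

* NEB is the default site-identification surface; BEB is available
  but costs ~100 pruning passes per gene.
* The chi-square null is conservative at the $\omega_2 = 1$ boundary;
  empirical type-I rates below the nominal level are expected.
* Power at a few hundred codons with moderate foreground branch
  lengths is modest — the branch-site test needs either long
  alignments or strong signals, which is why scan sensitivity is
  assessed at $\omega_2 \ge 4$.
* Only the standard nuclear genetic code ships, though the code table
  is pluggable.
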