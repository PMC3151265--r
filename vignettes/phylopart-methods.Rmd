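---
title: "Partitioned supermatrix maximum likelihood: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned supermatrix maximum likelihood: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phylopart)
```

# The model

`phylopart` analyses multigene nucleotide alignments under time-reversible
Markov substitution models. A model is defined by stationary frequencies
$\pi = (\pi_A, \pi_C, \pi_G, \pi_T)$ and exchangeabilities $r_{ij}$ for the
six unordered nucleotide pairs; the generator has off-diagonal entries
$q_{ij} = s\, r_{ij} \pi_j$ with $s$ chosen so that
$-\sum_i \pi_i q_{ii} = 1$, i.e. branch lengths are expected substitutions
per site. Three nested parameterizations are exposed:

* **JC** — equal frequencies, equal rates (0 free substitution parameters);
* **HKY** — free frequencies (3) plus a transition/transversion rate ratio
  $\kappa$ (1);
* **REV** (GTR) — free frequencies (3) plus five free exchangeabilities,
  with $r_{GT} \equiv 1$ as the identifiability reference.

Among-site rate variation uses the discrete gamma approximation: $K$
equal-probability categories (default $K = 6$) whose rates are the
conditional means of the gamma$(\alpha,\alpha)$ density on its quantile
bins, renormalized so the weighted mean is exactly 1. The conditional-mean
convention (rather than bin medians) was chosen for comparability with the
standard ML packages that popularized it. Note a numerical fact the test
suite encodes: the extreme-bin deviation from 1 scales as
$\approx 1.45/\sqrt{\alpha}$, so even at $\alpha = 200$ the outer category
rates differ from 1 by about 0.1; the rates approach 1 only for $\alpha$
in the tens of thousands.

The average transition/transversion ratio summarizing a fitted model is the
stationary flux ratio

$$R = \frac{\pi_A \pi_G r_{AG} + \pi_C \pi_T r_{CT}}
          {\pi_A \pi_C r_{AC} + \pi_A \pi_T r_{AT} +
           \pi_C \pi_G r_{CG} + \pi_G \pi_T r_{GT}},$$

which equals $1/2$ for JC and $\kappa/2$ for equal-frequency HKY, and is
invariant to joint rescaling of the exchangeabilities.

# Likelihood computation and optimization

Likelihoods are computed by Felsenstein pruning over compressed site
patterns, with gaps, `N` and IUPAC ambiguity codes marginalized (partial
likelihood 1 over the allowed states). Transition matrices come from the
spectral decomposition of the symmetrized generator
$B = \Pi^{1/2} Q \Pi^{-1/2}$, which is exact for reversible models.
Partials are rescaled per pattern whenever the per-node maximum drops below
$10^{-40}$, with accumulated log-scalers, so alignments of arbitrary depth
cannot underflow. Because the models are reversible, the likelihood is
invariant to root placement; trees are unrooted internally.

Maximization is coordinate ascent:

1. **Branch lengths** — each edge is maximized by Brent's method using
   cached "down" (subtree) and "up" (rest-of-tree) partials, so one edge
   evaluation costs $O(\text{patterns} \times \text{categories})$ rather
   than a full traversal. Edges are visited level by level (BFS) with the
   up-partials refreshed as lengths change, which keeps the sweep a true
   Gauss–Seidel pass. Bounds: $[0, 50]$ substitutions/site.
2. **Gamma shape and global scale** — $\log \alpha$ and a global
   branch-length scale factor are refined jointly (2-D quasi-Newton).
   These two directions are strongly correlated (raising $\alpha$ lowers
   inferred tree length); optimizing them jointly avoids the classic
   coordinate-ascent zigzag.
3. **Substitution parameters** — exchangeabilities (log scale, bounds
   $[10^{-4}, 10^4]$) and frequencies (multinomial logits) are refined as
   two bounded quasi-Newton blocks.

Sweeps repeat until the gain falls below `control$tol` (default $10^{-6}$
nats) or `max_sweeps` (200) is reached, in which case the fit is returned
flagged `converged = FALSE` — callers such as the gene-tree pipeline log
and exclude such genes rather than silently keeping them. Initialization
is deterministic: branch lengths 0.1, $\alpha = 0.5$, exchangeabilities 1,
frequencies at their empirical counts. Batch drivers (candidate-set
scoring, the CLI, the acceptance tests) pass `tol = 1e-3`: the residual
gain beyond that tolerance is below $10^{-2}$ nats in every workload we
measured, orders of magnitude below any statistic computed from the fits,
while halving runtime. Candidate-set scoring also warm-starts each tree
from the previous tree's parameter estimates; candidate order is fixed, so
results remain deterministic.

# Partitioned models

**Codon-position ladder.** Within an in-frame alignment the three codon
positions may share or separate parameter blocks. The ladder (conventional
labels G0–G4):

| label | branch lengths | frequencies | exchangeabilities | $\alpha$ |
|---|---|---|---|---|
| G0 | shared, scaled by $c_k$ | shared | shared | shared |
| G1 | shared, scaled | separate | shared | shared |
| G2 | shared, scaled | shared | separate | shared |
| G3 | shared, scaled | separate | separate | shared |
| G4 | fully separate | separate | separate | separate |

Position 1 is the scaling reference ($c_1 = 1$); any choice is
likelihood-equivalent. Under G0–G3 one $\alpha$ is shared across positions
(one gamma per gene); G4 estimates everything per position, which makes it
exactly separable into three independent fits — the implementation
exploits this, and the test suite asserts the equality. The engine
realizes G0–G3 as a grouped likelihood: each position is a pattern group
with its own generator and a branch-length multiplier, sharing the edge
lengths.

**Per-gene partitioning.** The supermatrix analyses score every candidate
tree $T$ as $\ell(T) = \sum_g \max \ell_g(T)$ with each gene free in
branch lengths, frequencies, exchangeabilities and $\alpha$ (optionally
crossed with a codon policy). Genes are optimized independently, so totals
are invariant to gene order and batching; the per-site log-likelihood
matrix (trees × sites) is retained for RELL.

**Parameter accounting.** Per independent block: $2n-3$ branch lengths, 3
frequencies, 5 (REV) or 1 (HKY) exchangeability parameters, 1 gamma shape,
and one scaling factor per non-reference codon position under proportional
rates. Totals are additive over gene partitions and are the degrees of
freedom used by every LRT.

# Model selection and support

* **Hierarchical LRTs**: JC+Γ vs HKY+Γ (4 df), HKY+Γ vs REV+Γ (4 df), at
  $\alpha = 0.05$ per test, no multiple-testing correction (configurable).
* **Per-partition AICc**:
  $-2\ell + \sum_i [2K_i + 2K_i(K_i+1)/(n_i - K_i - 1)]$, with $n_i$ the
  partition's alignment length; inputs violating $n_i > K_i + 1$ are
  rejected with the offending partition named.
* **Per-partition BIC**: $-2\ell + \sum_i K_i \ln n_i$. The exact
  per-partition BIC convention is an assumption (the mirror of the AICc
  construction); it is documented rather than hidden.
* **RELL bootstrap**: sites resampled with replacement (unstratified by
  default; stratified-by-partition available), per-tree log-likelihoods
  re-summed without re-optimization, the replicate awarded to the best
  tree, ties split equally. Supports form a probability distribution over
  the candidate set; bipartition support sums the supports of trees
  containing the split.
* **Nonparametric bootstrap**: columns resampled, the NNI search rerun.
  By default replicates keep substitution parameters fixed at the
  full-data estimates and re-optimize topology and branch lengths
  (`refit_model = TRUE` re-estimates everything); this is a standard
  speed/accuracy trade-off and is what the RELL-agreement acceptance test
  exercises.
* **Congruence**: distinct topologies counted by canonical unrooted
  Newick strings; mean pairwise normalized RF
  ($\mathrm{RF}/2(n-3)$); empirical p-value against the mean pairwise RF
  of equally many uniform random topologies, using the plain
  count$/n_{\text{sims}}$ convention.

# The synthetic world

The simulator is the package's stated world, not a tuning knob. Defaults
emulate the between-gene heterogeneity reported for real multigene yeast
datasets: per gene, $R \sim U[1.30, 4.22]$, $\alpha \sim U[0.25, 1.03]$,
GC $\sim U[0.38, 0.47]$, lengths uniform in whole codons (default
100–800; fixtures that need a stated length pin it), codon-position rate
multipliers $(1, 0.5, 3)$ — third positions fastest, second slowest, a
realistic coding-sequence profile. GC is controlled through
strand-symmetric frequencies ($\pi_A = \pi_T$, $\pi_C = \pi_G$);
transversion exchangeabilities get mild lognormal jitter (sd 0.2) so genes
are genuinely REV-distinct; with transversions fixed, $R$ is *linear* in
the joint transition scaling, so the nominal root-find for the target $R$
has a closed-form solution (the resampling guard remains for infeasible
jitter draws). Every generating parameter is recorded in a truth table.

What the simulator does **not** emulate: indels and alignment/trimming
error, codon structure beyond position-specific rates, compositional
non-stationarity, heterotachy. A green test therefore establishes
correctness of the inference machinery under the fitted model family and
realistic parameter heterogeneity — not robustness to model violation.

The default fixture mimics the shape of the 18-yeast problem: an outgroup
plus clades of 7, 4 and 6 taxa; a backbone with one polytomy in each of
two clades (9 candidates, containing the true tree); 4 genes of 5001 nt.
Taxon names follow the yeast species for readability; the data are
synthetic. The full backbone (`yeast_backbone()`) keeps the published
uncertainty structure — sensu stricto ladder resolved, a trifurcation at
the base of the post-WGD clade, a 4-way pre-WGD polytomy and a 5-way CTG
polytomy — giving $3 \times 15 \times 105 = 4725$ resolutions, and 3150
after excluding the *C. glabrata* + *S. castellii* sister arrangement.
That 3150 is even is itself informative: every rooted polytomy contributes
an odd factor $(2k-3)!!$, so the candidate count can only be even if one
arrangement class is excluded, which pins down the constraint's meaning.

# Numerical and design choices

* Frequencies below $10^{-8}$ are rejected, not clamped, so detailed
  balance can be asserted exactly in tests.
* Enumeration of backbone resolutions treats the tree as rooted; distinct
  resolutions are distinct *rooted* trees. When the root itself is a
  polytomy, rooted resolutions can coincide as unrooted topologies; the
  yeast backbone has a binary root, so its 4725/3150 are distinct both
  ways.
* `enumerate_resolutions` refuses above a configurable cap (default
  $10^6$) and reports the computed count in the error.
* NNI search scores neighbors with substitution parameters frozen at the
  current optimum (branch lengths re-optimized) and fully refits accepted
  moves; the default start is the neighbor-joining tree on JC distances.
  Deterministic given the seed; random restarts are available.
* Empirical p-values use count$/n$; RELL ties split fractionally;
  reference choices (scaling position 1, $r_{GT} = 1$) are arbitrary and
  likelihood-equivalent, and documented where they appear.
* Acceptance-test problem sizes follow the criteria where stated (e.g.
  20 genes × 1500 nt × 18 taxa; 200 type-I replicates at 300 nt; 100 kb
  for the single-fit precision check). Sizes the criteria leave open were
  fixed once for runtime on a single CPU: the homogeneous AICc control
  uses 8 taxa with 4 genes × 900 nt per replicate, and the 100 kb
  precision fit uses 8 taxa (precision is governed by alignment length).

# Known limitations

* Amino-acid models, codon models, covarion/heterotachy models and
  CAT-style site mixtures are out of scope.
* The supermatrix path is exhaustive scoring of an explicit candidate set;
  there is no heuristic search of the full tree space beyond per-gene NNI.
* Partition merging/selection (clustering genes into classes) is not
  implemented.
* The optimizer is coordinate ascent with quasi-Newton blocks; like all
  such schemes it can in principle stop at a non-global optimum of the
  likelihood surface, mitigated by the joint $\alpha$/scale step and by
  optional restarts in the tree search.
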