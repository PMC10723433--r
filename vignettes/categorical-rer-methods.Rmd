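---
title: "Methods: categorical trait reconstruction, RER association and permulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical trait reconstruction, RER association and permulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrer)
```

This vignette documents the models and algorithms implemented in `catrer`,
the choices made where the design was genuinely open, and what the
simulation-based tests do and do not demonstrate.

## The evolutionary model

A categorical trait with k unordered states is modelled as a continuous-time
Markov chain (the Mk model) running along the branches of a master
phylogeny whose branch lengths $t_i$ represent average genome-wide
evolutionary rates (expected substitutions per site). The instantaneous
rate matrix $Q$ has non-negative off-diagonal entries and zero row sums;
over a branch of length $t$ the transition probabilities are $e^{Qt}$. A
*rate model* constrains $Q$: entries indexed 0 are forbidden, entries
sharing a positive index share one free rate. ER (one shared rate), SYM
(symmetric pairs) and ARD (all rates free) are built in; `rate_model()`
accepts arbitrary index matrices. Zero-length branches are legal and
contribute an identity transition matrix.

Assumptions worth stating: the trait evolves independently of the genes
being tested; the master tree topology is correct and shared by all genes
(the package does not handle discordant gene trees); and branch lengths are
a meaningful common time scale for both trait and rate evolution.

### Fitting and reconstruction

`fit_mk()` maximises the Felsenstein pruning likelihood over free rates by
L-BFGS-B on log-rates, with three deterministic starts (0.1, 1 and 10 times
the reciprocal tree height) so that refits are reproducible without a
global optimiser; convergence tolerance is $10^{-8}$ on the relative
log-likelihood (`factr = 1e6`). Log-rates are box-constrained to
$[-25, 25]$, which in practice spans "effectively zero" to "effectively
instantaneous" for any sensible branch-length scale. The likelihood is
computed with per-message rescaling, so deep trees do not underflow.

The root prior is configurable: `"flat"` (1/k, the default — it keeps
likelihood-ratio tests well defined for non-reversible ARD fits and matches
common Mk implementations), `"stationary"` (left null vector of $Q$), or a
user vector. Marginal ancestral likelihoods are computed by the standard
two-pass (tipward/rootward) message-passing algorithm, which works
unchanged on polytomies; for a tree stored unrooted (basal multifurcation)
the marginals are invariant to the choice of pruning root when the prior is
the stationary distribution, and the test suite verifies this by rerooting.
Each node is assigned its maximum-marginal state — deliberately *not* the
joint maximum-likelihood history — with ties broken toward the lowest state
index and a warning, so the tie rule is visible rather than silent.

Rate models are compared with `likelihood_ratio_test()`. Nestedness is
detected structurally: the simpler model must be realisable by constraining
the complex model's parameters (forbidding only what it forbids, merging
whole equality classes). Nested pairs use $\chi^2$ with df equal to the
difference in free-parameter counts (forbidden transitions contribute no
df); non-nested pairs fall back to a parametric bootstrap under the simpler
fit. Bootstrap refits start from the generating rates (single start) — an
approximation that bounds runtime and is documented as such; the replicate
tip data are resimulated under the *simpler* model, the standard bootstrap
LRT convention.

### Branch labels and missing species

Branches take the category of their descendant node, so terminal branches
always carry the observed phenotype and the root's state never labels a
branch directly. Assignment is state-based rather than transition-based:
with k categories the number of transition types grows quadratically, while
states keep the downstream tests k-level.

When species are missing (from the phenotype table or a gene), degree-2
nodes created by pruning are suppressed and their incident master branches
concatenate into *composite* branches. `build_paths()` records, for every
composite branch, the ordered master branches it spans; the induced subtree
is rooted at the MRCA of the retained species (matching `ape::keep.tip()`),
which makes pruning idempotent and conserves total branch length. A
composite branch takes the state of its most *tipward* master branch, so
extant composite branches keep observed states.

## Association tests

Per gene, missing branches are dropped and the remaining RERs are compared
across categories. The default is the tie-corrected Kruskal–Wallis test
with effect size $\varepsilon^2 = H/(n-1)$, followed by pairwise Dunn tests
(mean-rank differences over the tie-corrected pooled SE, two-sided normal
p, Benjamini–Hochberg adjusted across the $k(k-1)/2$ pairs within a gene;
Holm/Bonferroni/none are available). The parametric alternative is one-way
ANOVA with $\eta^2 = SS_{\text{effect}}/SS_{\text{total}}$ and Tukey HSD.
Degenerate inputs are handled explicitly: all-tied values give $H = 0$;
zero residual variance leaves the ANOVA p undefined (`NA`) with a
`degenerate` flag while $\eta^2 = 1$ is still reported.

Genes are tested only with at least 8 usable branches overall and at least
2 usable branches in each of two categories (both configurable); others get
`NA` rows with a reason code. Internal and terminal branches are both used
— internal branches carry much of the convergence signal — and a
`branch_subset` argument supports extant-only comparisons.

Because permulation p-values re-run every gene's tests under hundreds of
null label vectors, the tests are implemented as a vectorised matrix engine:
ranks, tie corrections and missingness masks depend only on the RER matrix
and are computed once; each null labelling then costs two matrix products.
The engine is cross-checked in the tests against `stats::kruskal.test`,
`aov()`/`TukeyHSD()` and hand rank arithmetic.

## Permulations

Phylogenetic relatedness and shared technical factors make parametric null
distributions wrong for RERs. Null phenotypes are therefore generated to be
*evolutionarily plausible* (simulated from the fitted model on the real
tree) yet *matched* to the observed phenotype's category counts:

1. **Rejection sampling.** Tip states are simulated from $Q$ down the tree
   (root drawn from the prior) and kept only if every category's extant
   count is within `floor(relaxation × observed)` of the observed count.
   Relaxation 0 demands exact matches. The floor rule means a 10%
   relaxation gives a category of 10 a ±1 band but leaves a category of 5
   exact; rounding up would let small categories drift proportionally
   further than large ones, which is the opposite of what a percentage band
   intends. Simulation is batched and vectorised; a configurable ceiling
   (default $10^6$ attempts) aborts with advice to relax, since exact
   matching becomes slow for many categories.
2. **Internal permutation.** The simulated internal states are discarded;
   the *originally reconstructed* internal states are permuted onto the
   internal nodes. Nodes are visited in random order and draw from the
   remaining multiset with probability proportional to the node's ancestral
   likelihood (computed from the simulated tips) for each still-available
   state, renormalised per node. This conserves internal category counts
   exactly, every draw, while starting the next step far better than a
   blind shuffle.
3. **Annealing reorganisation.** The assignment is improved by swap
   proposals. For node $i$ in state $y$, $\text{ratio}_{i,x} = A_{i,x} /
   A_{i,y}$ measures how much it would prefer state $x$; a first candidate
   $(i, x)$ is drawn with probability proportional to these ratios
   (restricted to ratios above 1 when any exist, else uniform — a softmax
   alternative is trivial to configure), and a partner $j$ currently in $x$
   is drawn likewise by $\text{ratio}_{j,y}$. Swapping $i \to x, j \to y$
   changes only the edges incident to the two nodes, so the likelihood
   delta is local. Improvements are always kept; deteriorations are kept
   with probability $u = \exp(-dh/T_k)$ under the cooling schedule
   $T_k = T_0/(1 + \alpha k)$ with $T_0 = 10$, $\alpha = 0.9$, 100 cycles
   of 10 proposals. $dh$ is taken as the *log*-likelihood difference
   (before minus after): the raw likelihood ratio would give even a neutral
   swap an acceptance probability below 1 ($e^{-1/T_k}$), contradicting the
   annealing intent, so the log reading is the default and the ratio
   reading is available behind `dh_scale = "ratio"`. Swaps exchange two
   nodes' states, so no step of the algorithm can alter category counts.

The phenotype likelihood used throughout is
$\sum_i \log (e^{Q t_i})_{x_i, y_i}$ over branches (ancestor $x_i$,
descendant $y_i$); a forbidden transition yields $-\infty$, and a swap out
of an impossible configuration is always accepted. Every permulation
records its simulation, post-permutation and final log-likelihoods plus
attempt and swap counts, so the diagnostic comparing permulated likelihoods
with accepted-simulation likelihoods can always be drawn; the acceptance
suite checks that the annealed likelihoods recover to the simulated ones
(median improvement, KS statistic below 0.25 on 200 replicates of a 30-tip
fixture).

Empirical p-values are $(b+1)/(N+1)$ with $b$ the number of null
statistics at least as extreme — one-sided for the omnibus H, two-sided for
pairwise Z. The add-one estimator never returns 0 and is the default; the
plain proportion $b/N$ is available (`estimator = "proportion"`). Null
statistics reuse the observed RER matrix: only the branch labels change per
permulation (the complete-case design — one tree topology, no per-gene
subsetting of the null phenotypes).

## Pathway enrichment

Genes are scored $-\log_{10} p$ from the omnibus test (one-sided, unsigned)
or $\mathrm{sign}(Z)\,(-\log_{10} p)$ from a pairwise test, and each
pathway is tested by Wilcoxon rank-sum (normal approximation with tie and
continuity corrections) of in-set versus out-of-set scores. Set size bounds
default to 10–500 within the universe of genes with non-NA scores; the
universe is fixed to the observed analysis across all permulations. The
identical scoring and test are recomputed on every permulation's null gene
statistics, and the pathway permulation p is the add-one proportion of null
$|z|$ at least as extreme as observed. This is the correction that matters
in practice: clusters of genes that co-shift in rank (in real data, e.g.
large receptor families) inflate parametric rank-sum p-values, while the
permulation nulls inherit the same co-ranking and absorb it.

## The synthetic-data generator

`synthetic_spec()` defaults describe the package's reference condition: a
40-tip Yule tree (birth rate 1, so expected height ≈ log n), a 3-category
phenotype evolved under ER with rate 0.5 per branch-length unit (roughly
two expected transitions per root-to-tip path — enough that all categories
are usually present and the reconstruction is non-trivial, comparable in
spirit to a diet-like trait with a few dozen transitions on a hundred-tip
tree), 2,000 genes with unit normal branch noise, 5% of genes carrying a +2
SD shift on one category's branches, and 5% missing entries. A Student-t
(df 5) noise option provides heavier tails, and a clique option gives a
block of genes a shared branch-level latent factor (correlated nulls with
no mean shift) for testing the rank-correction property.

What the generator does *not* emulate: phylogenetic correlation of the
noise along the tree, branch-length-dependent RER variance, gene-specific
missingness structure (real missingness follows assembly quality, not a
uniform coin), and any dependence of RERs on the trait other than the
planted mean shifts. Passing tests therefore demonstrate algorithmic
correctness and calibration under exchangeable noise, not performance on
real alignments. Where tests need phylogenetic dependence itself, it is
induced through the phenotype (which is always simulated on the tree), not
the RERs.

Test problem sizes are deliberately modest — 40-tip trees, hundreds to
thousands of genes, 60–300 permulations — chosen so the full suite runs in
minutes while keeping Monte-Carlo error well inside each check's margin;
the relaxation-fidelity experiment, for instance, uses 300 permulations per
condition with matched seeds so that shared sampling noise cancels in the
paired comparison.

## Numerical details

* $e^{Qt}$ is computed once per unique branch length via eigendecomposition
  when $Q$ is diagonalisable to working precision, falling back to
  scaling-and-squaring (`Matrix::expm`); tiny negative entries are clamped
  and rows renormalised.
* Pruning and marginal passes rescale per message; likelihood equality with
  exhaustive enumeration is enforced to $10^{-10}$ on all trees up to 6
  tips and $k \le 3$ in the tests.
* Ancestral-likelihood ratios clamp $A$ at $10^{-12}$ before division so a
  zero marginal cannot produce infinite proposal weights.
* All permulation randomness flows through R's RNG from a single seed in
  `permulation_config()`; identical seeds give byte-identical permulation
  sets.

## Known limitations

* Only the complete-case permulation design is implemented; genes with many
  missing species reuse the master-tree null labels rather than
  species-subset-matched ones.
* The Monte-Carlo LRT's single-start refits can, in principle, understate
  the null LR on multimodal likelihoods.
* Rejection sampling at relaxation 0 scales poorly with the number of
  categories; the relaxation exists precisely for k ≥ 4, and its fidelity
  is quantified (not assumed) by the acceptance experiment.
* The annealing search optimises plausibility greedily under a fixed
  schedule; it guarantees count conservation, not a global likelihood
  optimum.
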