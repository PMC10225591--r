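---
title: "Multiplex network differential analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex network differential analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal microbiome studies usually compare taxon *abundances* over
time. This package targets a complementary quantity: how a taxon's local
*co-occurrence neighborhood* changes between two time points or conditions,
resolved per individual. The workflow has four stages:

1. **Individual-specific networks (ISNs).** A global association network is
   estimated on a pooled reference population (one sample per individual,
   per time point). For individual $n$, every edge is perturbed by the
   leave-one-out scheme
   $$w_n^{ij} = N\,w^{ij} - (N-1)\,\bar w_{-n}^{ij},$$
   where $w$ is the pooled estimate, $\bar w_{-n}$ the estimate without
   individual $n$, and $N$ the reference size. The ISN edge estimates the
   individual's contribution to the population edge; it can be negative
   even when both population weights are positive (exactly when
   $w < (N-1)\bar w_{-n}/N$). Because only unsigned association strength is
   of interest downstream, weights are replaced by absolute values in an
   explicit, separate step.

2. **Multiplexes and walk profiles.** Each individual's two ISNs are
   stacked into a two-layer multiplex over the shared taxon set. For every
   node of every layer we compute (a) its direct-neighbor vector (edge
   weights to all other taxa; no self-loops, which is what lets the encoder
   generalize to unseen nodes) and (b) its random-walk *reach profile*: the
   probability that each other taxon is visited at least once by a
   fixed-length weighted random walk started at the node.

3. **Joint embedding (EDNN).** A shallow encoder–decoder network — one
   hidden layer of rectifier units, logistic outputs, mean-squared-error
   loss — is trained to map neighbor vectors onto reach profiles for *all*
   nodes of *all* layers of *all* individuals jointly. The hidden
   activations are the node embeddings; training them jointly places every
   (individual, layer, taxon) point into one comparable space.

4. **Dynamics.** A taxon's neighborhood dynamics for an individual is the
   cosine distance $d_{\cos}(A,B) = 1 - A\cdot B/(|A||B|) \in [0,2]$
   between its two layer embeddings. These per-taxon distances feed taxa
   ranking, gap-based detection of extreme-dynamics taxa, ensemble
   consensus clustering of taxa and of individuals, and phenotype
   prediction (the "dynamic" feature view, $K$ columns regardless of the
   number of time points).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| CLR pseudocount | 0.5 | half-count convention before log-ratio transform |
| prevalence threshold | 0.15 | strict (>) fraction of samples with nonzero count |
| walk length | 5 | steps per random walk; reaches the 2–3-neighborhood of sparse graphs |
| walks per node | 100 | Monte-Carlo repeats; an exact absorbing-chain mode exists for any size |
| hidden dimension | 10 | reconstruction MSE bottoms out among {2, 5, 10, 15, 20}; `hidden_dim_sweep()` re-runs the comparison |
| epochs / learning rate / batch | 500 / 1e-2 / 32 | see "Numerical choices" |
| ensemble repeats | 50 (taxa analyses); 5 in the validation suites | EDNN retrainings averaged before ranking/clustering |
| consensus k-range | 2–6 | silhouette-selected per repeat and for the final cut |
| gap fraction `q` | 0.25 | tail fraction searched for the "first larger jump" |
| SVM / selection | RBF, no tuning; inner 5-fold CV; cap 10 features | standard components behind the prediction contract |

## Numerical choices

**EDNN optimization.** Glorot-uniform initialization, minibatch Adam
(`beta1 = 0.9`, `beta2 = 0.999`), loss averaged over all $n \times K$
output entries. Embedding distances only track neighborhood change when the
reconstruction is fit tightly; with the small row counts typical here
(hundreds to a few thousand rows) that requires more optimization than a
generic default, hence `epochs = 500`, `learning_rate = 1e-2`. At looser
settings (e.g. 100 epochs at 1e-3) the reconstruction MSE stays an order of
magnitude higher and planted-perturbation recovery degrades measurably.
Training is bit-reproducible for a fixed seed on one thread; different
seeds give different embeddings, which motivates the ensemble everywhere a
ranking or clustering is derived.

**Walk profiles.** Transition probabilities are proportional to edge
weights; a walk that reaches an isolated node terminates, and its earlier
visits still count. The Monte-Carlo mode advances all walkers of a start
node simultaneously (one multinomial draw per occupied node per step) with
per-(layer, node) RNG streams derived from one master seed, so results do
not depend on evaluation order. The exact mode computes first-visit
probabilities by an absorbing-chain recursion (remove the target's column,
propagate avoidance mass), which matches brute-force path enumeration to
machine precision and is used as the oracle in the tests.

**Zero-norm embeddings.** Rectifier units can die, so a node embedding can
be the zero vector, where cosine distance is undefined. Convention: both
vectors zero → distance 0 (identical, empty neighborhoods); exactly one
zero → 2 (maximal displacement). Bounded and monotone; the exported
`cosine_distance()` itself refuses zero-norm inputs so the convention never
leaks into user arithmetic silently.

**Consensus clustering.** The ensemble principle — partition per repeat,
record co-clustering frequencies, cut the consensus — is implemented with
standard components: k-means per repeat (k by silhouette over the k-range),
average-linkage hierarchical clustering of `1 - consensus` for the final
cut. Identical repeats yield a {0, 1} consensus matrix exactly.

**Degenerate inputs.** Constant taxa get zero association with a warning
(their correlation is undefined even though CLR centering makes the column
vary); asymmetric matrices are rejected beyond a 1e-8 relative tolerance
unless symmetrization is requested explicitly; conflicting duplicate edges
in edge lists are an error, exact duplicates are collapsed.

## The synthetic benchmarks

**Planted-rewiring multiplex** (`make_benchmark_multiplex()`). Layer 1 is a
configuration-model graph (Poisson degrees around mean 4, K = 95 by
default) with folded-normal weights (mean 0.3, sd 0.15, truncated to
(0, 1]). Layer 2 is a copy in which each of `m_control = 10` control nodes
has all incident edges deleted and replaced by the same number of edges to
re-drawn partners with re-sampled weights. Two guards keep the planted truth
well-defined: re-drawn partners exclude every control's former partners
(controls must end up with genuinely different neighbors, and no bystander
both loses and gains a control edge), and the control set is re-drawn if
some non-control node would lose its entire neighborhood (such a bystander
would legitimately be detected by any method, making perfect recovery
impossible by construction rather than by merit). Uniform noise sweeps add
independent `U(0, max)` draws to every upper-triangle adjacency entry —
including zeros, so noise densifies the graph — mirrored for symmetry.

**Synthetic cohort** (`make_synthetic_cohort()`). Taxa form latent
correlation modules (compound symmetry, within-module correlation 0.8);
counts are zero-inflated negative binomial marginals over the latent
Gaussian copula with uniformly drawn sequencing depths, reproducing
sparsity, overdispersion and compositionality. An individual's latent state
persists between the two time points (`persistence = 1` by default — the
perturbed-copy principle used by the benchmark: the second layer is the
first state plus the planted changes plus fresh measurement noise). For
subgroup 2, ten target taxa detach from their module and re-attach to a
different one with fresh residuals; the binary phenotype equals the
subgroup (`coupling = 1`; lower coupling adds label noise).

What passing these suites does and does not show: the generators plant
*neighborhood* change with everything else held fixed, so they validate
that the pipeline detects rewiring and ranks rewired taxa correctly; they do
not emulate real cohorts' confounding, compositional artifacts of strong
blooms, library-size extremes, or taxon-specific measurement error, so
performance numbers here are upper bounds on what comparable real data
would give.

## Known limitations

* **Individual-level dynamics are influence-limited.** An ISN is the pooled
  network plus the individual's single-sample influence term, so the
  magnitude of an individual's recoverable signal depends on their own
  latent draw. In the synthetic cohort at n = 60, K = 40, taxa-level
  recovery is strong (rewired taxa rank at the top; planted-node recovery
  on the global benchmark is essentially perfect), and the embedding
  outperforms raw neighbor-vector comparison; but consensus clustering of
  *individuals* by their dynamics profiles recovers the planted subgroups
  only weakly, and dynamic-view prediction lands near AUC 0.75–0.85. This
  is an information bound of single-sample leave-one-out perturbation, not
  an optimization failure: an individual whose affected taxa happen to sit
  near the population mean at both time points contributes almost no
  leverage to any edge, so their subgroup is not identifiable from their
  own networks.
* The absolute-value step discards the sign of an individual's
  contribution; signed-edge-aware dynamics are out of scope.
* Two layers only in the dynamics measure (cosine distance of one pair);
  more time points require a generalized angle and are out of scope.
* The fallback association estimator (CLR + correlation + quantile
  sparsification) is a testing device, not a compositional inference
  method; production use should supply networks from a dedicated tool via
  `read_network()`/`estimator_from_dir()`.

## Problem sizes in the test suites

The validation suites run the full pipelines at reduced but faithful
scales chosen as the package's own study conditions: 20 benchmark
replicates at K = 95 with 5-seed ensembles for planted-node recovery; 3
replicates per noise level across the nine-level sweep; the cohort at
n = 60, K = 40 with 5 embedding repeats, 10 prediction repeats and 150
training epochs (more rows per epoch make fewer epochs sufficient); 200
replicates for permutation-test calibration.
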