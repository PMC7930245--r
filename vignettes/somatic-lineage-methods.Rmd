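---
title: "Reconstructing somatic phylogenies across tumour and normal tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing somatic phylogenies across tumour and normal tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaclone)
```

## The problem

Every cell division leaves somatic mutations behind, and mutations acquired
during early embryogenesis are inherited by all descendant lineages. When a
tumour and several normal tissues from the same patient are whole-genome
sequenced at moderate depth (30--40x), the pattern of somatic mutations
shared between the tumour and each normal tissue reveals which embryonic
lineage the tumour came from: a mutation present in the tumour and in, say,
Schwann cells of a nerve root, but absent from blood and kidney, places the
tumour on the neural-crest side of an early lineage split. `somaclone`
implements this lineage-tracing analysis as a reusable pipeline operating on
per-sample variant read counts:

1. **Germline/somatic classification** -- a one-sided binomial exact test on
   aggregated counts with Benjamini--Hochberg correction;
2. **Depth filtering** -- removal of sites at consistently aberrant depth;
3. **Presence calling** -- a site-specific beta-binomial sequencing-error
   model separating true low-level presence from noise;
4. **Clustering** -- an N-dimensional Dirichlet-process mixture of binomials
   over all samples, fitted by collapsed Gibbs sampling;
5. **Tree reconciliation** -- assembly of mutation clusters into a clone
   tree under the pigeonhole principle, with per-tissue clone sizes and
   per-branch mutation burdens.

A synthetic-data generator emulating an embryonic clone tree sampled across
tissues makes the whole pipeline testable end to end without access to
controlled patient data.

## Models and procedures

### Germline versus somatic

A heterozygous germline variant has expected VAF 0.5 in every diploid
sample. For each site the alt reads and depths are aggregated across the
patient's samples (all of them by default; configurable to the designated
matched-normal subset) and the lower tail
$P(X \le a \mid n, \mathrm{VAF}_0 = 0.5)$ of the exact binomial is computed:
a small p-value means the aggregated VAF is too low for a germline variant.
P-values are BH-corrected across testable sites and a site is called somatic
at $q < 10^{-5}$. Sites are depth-filtered first (below 15x in *every*
sample, or above 50x in every sample; both bounds halved on X/Y for a male
patient), so the multiplicity correction counts only testable sites.

Two consequences of this design are worth knowing. First, a truly
*ubiquitous* somatic lineage -- mutations fixed during the first embryonic
divisions and therefore present at VAF ~0.5 in every tissue -- is
statistically indistinguishable from germline by any read-count test, and is
removed here together with the germline. The clone tree's root is therefore
re-introduced downstream as a unit root. Second, for a clone whose
aggregated VAF sits near the detection boundary, the test censors its
highest-VAF mutations (they look "too germline"), which biases the retained
mutations' VAF slightly low; see *Known limitations*.

### Presence calling

At 40x, a clone at 4% cellular prevalence generates less than one expected
variant read -- deciding whether two variant reads mean presence or
sequencing error requires an error model. For each somatic site we model the
alt count of a non-carrier sample as beta-binomial with mean error rate
$\mu$ and overdispersion $\rho$ ($\rho \to 0$ recovers the binomial). The
fit is by profiled likelihood: $\mu$ is the depth-weighted mean VAF of the
fitting samples (floored at a pooled cohort-wide error rate), and $\rho$ is
chosen on a 25-point logarithmic grid over $[10^{-6}, 0.89]$.

Three fitting rules keep the model calibrated:

* **Parsimony on $\rho$.** Among grid values within 1.92 log-likelihood
  units (half the 95% $\chi^2_1$ quantile) of the maximum, the smallest
  $\rho$ is used. Without this, small-sample variance masquerades as
  overdispersion about half the time, and all-zero fitting data drive
  $\rho$ to the top of the grid (the likelihood of zeros grows monotonically
  in $\rho$), fattening the null tail for no reason. All-zero fits return
  the grid floor directly.
* **Leave-one-out.** The model used to test sample $s$ never includes $s$
  itself, so a weakly supported carrier cannot deflate its own error
  estimate.
* **Iterative carrier exclusion.** Samples with naive VAF $\ge 0.1$ are
  excluded from fitting as candidate carriers, but a genuine carrier that
  drew few reads can slip under that cut-off. Calling therefore iterates:
  samples called present are removed from the remaining fits and the site is
  re-tested until the calls stabilise (presence calls only grow, so this
  terminates; two passes in practice).

A sample is called present when the upper-tail probability
$P(X \ge a)$ under its error model falls below $10^{-3}$ (no multiplicity
correction; the threshold is configuration). Pairwise shared-mutation counts
between tissues -- the headline statistic relating a tumour to each normal
tissue -- are counts of sites called present in both.

### Dirichlet-process clustering

Mutations belonging to one clone share a cellular prevalence profile across
samples, hence a VAF profile. We cluster mutations with a mixture of
per-sample binomials, $a_{ms} \sim \mathrm{Binom}(d_{ms}, \theta_{ks})$,
under a Dirichlet-process prior so the number of clusters is inferred.
Working on raw counts weighs deep and shallow samples correctly and needs no
VAF cut-offs. The collapsed Gibbs sampler integrates $\theta$ out
(Beta(1,1) conjugate priors), reassigns each mutation by the beta-binomial
posterior predictive under the Chinese-restaurant prior, and resamples the
concentration $\alpha$ by the usual Beta-augmentation under a Gamma(1,1)
prior. Defaults are 2000 sweeps with 500 burn-in; the point estimate is the
retained state of maximal joint posterior density, after which clusters
below `min_cluster_size = 5` are dissolved into their best surviving
cluster, and $\hat\theta_{ks} = (1 + \sum a)/(2 + \sum d)$ is the
conditional posterior mean. The co-assignment matrix over all retained
states is emitted for diagnostics.

The sampler initialises from singletons. Single-site Gibbs moves merge
clusters quickly but split an over-merged cluster extremely slowly, so a
one-big-cluster start can leave two adjacent clones fused for thousands of
sweeps; starting from singletons removes that failure mode at the cost of a
slightly more expensive first sweep.

### Clone-tree reconciliation

Under the heterozygous diploid assumption, cellular prevalence is
$\min(1, 2\hat\theta)$ per sample. The pigeonhole principle constrains the
tree: in every sample, the prevalences of a node's children cannot sum to
more than the node's own prevalence. The builder takes the cluster of
highest mean prevalence as root if it is clonal everywhere
(prevalence $\ge 1 - \varepsilon$), otherwise inserts a synthetic unit root;
remaining clusters are placed in descending mean-prevalence order, each
under the *deepest* node satisfying containment and residual capacity in
every sample (ties broken by minimal prevalence slack). A cluster with no
admissible parent raises an incompatibility error naming the violating
samples, rather than being placed silently. `check_pigeonhole()` re-verifies
the constraint independently of the builder. Per-node *clone sizes* --
prevalence minus the children's summed prevalence -- are the per-tissue
percentages reported on the tree, and branch lengths carry mutation burdens.

The tolerance $\varepsilon$ defaults to 0.05 on the prevalence scale, sized
to absorb binomial sampling noise on $2\hat\theta$ at 30--40x with a few
hundred mutations per cluster. Note a structural ambiguity of pigeonhole
reconciliation: when one cluster's prevalence dominates another's in every
sample, nesting them is always admissible, so the deepest-placement rule
nests; only profiles that *cross* (each exceeds the other somewhere) force a
sibling arrangement.

## The synthetic-data generator

`simulate_truth()` draws a random rooted tree (each new clone attaches to a
uniformly chosen existing clone), then draws per-sample prevalences by
recursive stick-breaking from the root down. Defaults describe the
benchmark cohort used throughout the tests: 5 samples, 4 clones, 150--300
mutations per branch, 40x Poisson depth (truncated at 1), per-read error
rate 0.002, 500 germline variants, and a female patient (no sex-chromosome
halving).

Constraints enforced by construction:

* **Pigeonhole with margin.** Every parent exceeds its children's summed
  prevalence by at least 0.02 in every sample. Internal nodes reserve the
  margin plus their descendants' needs before the Dirichlet split, so the
  margin is satisfiable at every level; configurations too deep for the
  margin raise an error rather than emitting an invalid tree.
* **Identifiability.** Prevalence draws are rejected until every clone pair
  is separated by more than 0.1 prevalence in at least one sample (both
  directions for non-ancestor pairs, one direction for ancestor pairs).
  Without this, sibling clones with near-proportional profiles admit
  spurious nestings that no reconciliation method could reject, and
  parent/child pairs 0.01 VAF apart cannot be resolved at 40x. When the
  geometry cannot support the margin (one sample, many siblings) it is
  progressively relaxed, so degenerate configurations still simulate.

`simulate_counts()` draws depths and binomially distributed alt reads with
expected VAF $f_k/2$ perturbed by the symmetric error rate;
`inject_germline()` appends variants at expected VAF 0.5 in every sample and
records their ids in the truth object. Everything is deterministic given the
configuration seed, with independent sub-streams per stage.

What the generator deliberately does **not** emulate: copy-number events and
LOH (all sites are diploid heterozygous; the real analysis handles CNVs with
dedicated callers upstream), mapping artefacts and strand bias (upstream
caller territory), indels and structural variants, correlated depth along
the genome, and contamination between tissues. Passing the recovery
benchmarks therefore demonstrates the statistical machinery under the
model's own assumptions, not robustness to these real-data complications.

## Benchmarks computed by the package

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact-test and BH agreement with brute-force oracles (every depth to
  200x; 1000 random p-vectors);
* depth-filter agreement with a hand-written predicate on a 12-site toy
  table including halved X/Y thresholds;
* presence-model calibration on 10^5 pure-noise site--sample pairs at
  error rate 0.002 (empirical call rate vs the 2 x 10^-3 bound) and the
  binomial limit of the beta-binomial tail;
* presence power for a clone at prevalence 0.4 shared by two of five
  tissues;
* recovery of a two-cluster benchmark (per-sample VAFs (0.5, 0) vs
  (0.25, 0.25), 100 + 100 mutations, 40x) by adjusted Rand index and VAF
  error, over five seeds;
* end-to-end tree recovery over twenty simulated patients at the default
  study conditions, scored against the truth collapsed to the clones that
  survive the germline step (the ubiquitous root always falls to it; its
  children re-attach to the nearest surviving ancestor);
* byte-identical reproduction of the artefact bundle under a repeated
  configuration and seed.

## A small worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 7)
dat <- simulate_dataset(cfg)
res <- run_pipeline(dat$table, dat$meta, pipeline_config(seed = 7),
                    outdir = "run7")
res$tree
#> clone_tree: 4 nodes over 5 samples (epsilon = 0.05)
#>   node_id parent_id burden   S1   S2   S3   S4   S5
#>      root      <NA>      0 56.7 45.3 62.3 49.8 10.7
#>  cluster1      root    262 14.4 18.8 17.2  4.0 24.9
#>  cluster3  cluster1    155 21.1  4.3  8.0 42.2 47.5
#>  cluster2  cluster1    271  7.8 31.6 12.4  4.0 16.8
```

Percentages are clone sizes per tissue; numbers on branches are mutation
burdens. The truth for this seed has four clones; the ubiquitous root
cluster is removed with the germline (as it must be) and reappears as the
unit root.

## Numerical and degenerate-input choices

* Binomial and beta-binomial tails are computed in log space from
  `lchoose`/`lbeta`; $\rho < 10^{-12}$ switches to the exact binomial.
* Depth 0 makes the germline test undefined (site reported
  unclassifiable) and presence trivially absent (p = 1, flagged).
* Sites where fewer than two usable samples remain for error fitting fall
  back to the pooled cohort model and are logged.
* The Gibbs sampler draws all randomness from R's RNG, so `set.seed`
  makes runs (and the written artefact bundle) byte-reproducible.
* Ties in the $\rho$ grid resolve to the smallest value; ties in tree
  placement resolve by minimal prevalence slack.

## Known limitations

* **Clone-size bias for hard cases.** Two effects bias recovered clone
  sizes for clones near the edge of what the data can resolve: the MAP
  partition splits weakly separated clone pairs along their observed
  counts, pushing the two conditional-mean VAFs apart (truncation bias up
  to ~0.07 prevalence at the 0.1 separation floor), and the germline
  cutoff censors the highest-VAF mutations of near-clonal clones, biasing
  them low by up to ~0.03. Across the twenty-simulation benchmark the mean
  absolute clone-size error is ~0.01 with ~97% of node-sample values
  within 0.05, but worst cases reach ~0.07.
* **Ubiquitous lineages are not reportable.** The mutation burden of the
  embryonic root cannot be recovered from read counts alone (see above).
* **Diploid assumption.** VAF-to-prevalence doubling is wrong inside CNV
  or LOH regions; such regions should be masked via the BED exclusion
  file.
* **One patient per run.** Cohort-level aggregation is out of scope.
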