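---
title: "Methods: cross-domain co-occurrence networks, keystones and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-domain co-occurrence networks, keystones and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(biofilmnet)
```

`biofilmnet` infers cross-domain (bacteria–phototroph–fungus)
co-occurrence networks from paired 16S/18S amplicon count tables and
characterises their stability. This vignette is the package's account of
the statistical machinery: the models, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices that were genuinely open.

## The inference problem

Amplicon counts are compositional: each sample's counts are a multinomial
draw from relative abundances, so naive correlations between taxa are
distorted by the closure to a constant sum. All three inference routes in
the ensemble address this differently, and all three assume associations
are (approximately) linear on the log scale:

- **SparCC** estimates correlations between latent "basis" abundances.
  From fractions it computes the log-ratio variance
  $t_{ij} = \mathrm{Var}[\log(x_i/x_j)] = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$.
  Under sparsity (most $\rho_{ij} \approx 0$), summing over partners
  gives a linear system $M\,\omega^2 = t$ with $M = \mathbf{1}\mathbf{1}^\top + (p-2)I$,
  solved for the basis variances; correlations follow by rearrangement
  and are clipped to $[-1, 1]$. Pairs with $|\rho| >$ 0.8 violate the
  sparsity assumption; they are excluded from the sums and the system is
  re-solved, up to 10 rounds, falling back to the previous round if the
  reduced system degenerates or a taxon would drop below two partners.
  Significance is a permutation pseudo-p: each taxon's counts are
  shuffled across samples independently (destroying associations,
  preserving margins), the whole estimator is re-run, and the two-sided
  exceedance rate over 100 permutations is reported.
- **Spearman correlation** on relative abundances is the
  assumption-light route: invariant to monotone transforms, blind to
  curvature. p-values use the $t$ approximation; BH adjustment runs over
  the upper triangle. Constant taxa are assigned $\rho = 0$, $p = 1$
  rather than NA so downstream voting needs no special cases.
- **Neighborhood selection (Meinshausen–Bühlmann)** regresses each
  taxon's CLR profile on all others with an L1 penalty, reading the
  sparse conditional-dependence graph off the nonzero coefficients,
  OR-combined across the two directions of each pair. The penalty is
  chosen by StARS: subsample the samples, refit the path, and pick the
  densest graph whose monotonised edge-selection instability stays at or
  below $\beta = 0.05$.

**Consensus.** A pair becomes an edge when at least `min_support = 2` of
the three methods call it (SparCC: $|\rho| \ge 0.3$ and pseudo-p < 0.05;
Spearman: $|\rho| \ge 0.5$ and q < 0.01; MB: membership in the selected
graph) *and* every supporting method reports a positive sign. Majority
voting with sign unanimity was chosen over averaging the three
statistics because the three quantities live on different scales (two
correlations, one indicator), and because the analysis is explicitly
about unambiguous positive co-occurrence; an averaging combiner is
nevertheless available (`ensemble_config(combine = "average")`). Each
method sees its native input: SparCC counts, Spearman relative
abundances, MB the CLR transform.

### Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `prevalence` | 0.05 | discard taxa present in < 5% of samples; equality retained (threshold is "fewer than") |
| sparcc `iterations` | 10 | Dirichlet resamples of fractions, element-wise median |
| sparcc `exclusion_threshold` | 0.8 | $|\rho|$ above which a pair leaves the basis system |
| sparcc `rho_cut`, `pseudo_p_cut` | 0.3, 0.05 | edge call |
| spearman `rho_cut`, `q_cut` | 0.5, 0.01 | edge call |
| mb `stars_beta` | 0.05 | instability budget; smaller = sparser graphs |
| mb `nlambda`, `lambda_min_ratio` | 20, 0.01 | log-spaced penalty grid |
| mb subsamples | 50 of size $\min(\lfloor 10\sqrt{n}\rfloor, 0.8n)$ | the canonical StARS subsample size, capped by a fraction so small studies keep enough samples |
| `min_support` | 2 | methods required per consensus edge |
| `min_size` (Louvain) | 5 | communities below this are recorded as pruned |
| keystone `k` | 10 | nodes ranked by degree-rank + betweenness-rank |
| `alpha`, `n_perm` (forward selection) | 0.01, 999 | permutation entry rule |

Two StARS details deserve a note. First, the subsample size follows the
method's own $b(n) = \lfloor 10\sqrt{n}\rfloor$ rule, capped at 80% of
$n$: at the sample sizes typical of a single stream stratum the two
coincide, while at large $n$ an 80% subsample understates instability
and over-selects edges. Second, the instability path is monotonised
(running maximum toward denser graphs) starting from its minimum within
the region where the mean subsampled graph density is below one half:
with few taxa the sparsest penalties flicker on single borderline edges,
and near-saturated graphs are spuriously stable, so both ends of the raw
path would otherwise mislead the selection.

Louvain community detection is greedy and node-order dependent; the
package runs 100 seeded restarts over random vertex permutations and
keeps the best-modularity partition. At the graph sizes involved this
costs milliseconds and makes the optimiser reliably reach the exhaustive
optimum on small graphs.

## Keystones and fragmentation

Degree and (unnormalised, endpoint-excluding) shortest-path betweenness
are ranked with dense ranks — ties share the better rank — and the ten
lowest rank-sums are the keystone list; ties break by higher
betweenness, then lexical id. Fragmentation is
$f = \#\text{components} / \#\text{nodes}$. The removal trajectory
deletes keystones in rank order, recomputing components, $f$, and the
Louvain cluster count after each step.

Two readings of the procedure are both implemented because the verbal
definition is ambiguous: the denominator of $f$ defaults to the *current*
node count ("the network" at measurement time), with
`original_n = TRUE` for the fixed pre-removal denominator; and the
keystone list is static by default, with `recompute = TRUE` re-ranking
the survivors after each removal. Defaults were fixed before any results
were inspected and are reported in every output.

## db-RDA and forward selection

Bray–Curtis dissimilarities
($d = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$) of the
Wisconsin-double-standardised bacterial table are double-centred into a
Gower matrix; the principal-coordinate space of positive eigenvalues is
regressed on the constraints; constrained inertia is the sum of
canonical eigenvalues. Bray–Curtis is non-Euclidean, so negative
eigenvalues occur: their inertia is excluded from the decomposition and
reported separately (no square-root or Lingoes correction by default),
which keeps explained fractions on the convention of the standard
capscale-style accounting; the identity
constrained + unconstrained = total positive inertia then holds to
1e-8 and is asserted in the tests against `vegan::capscale` as an
independent cross-check.

Forward selection starts from the null model and, per step, takes the
candidate with the largest marginal pseudo-F
($\Delta$inertia / (residual inertia / residual df)), testing it by
freely permuting that candidate's rows while conditioning on the terms
already selected; entry requires p < `alpha` strictly. Candidates
(near-)collinear with the selected set are skipped. Environmental
columns are log-transformed first; columns containing zeros (or negative
values, shifted to zero) receive an offset of half their smallest
positive value. Explained variance is reported both raw and adjusted
($R^2_{adj} = 1-(1-R^2)(n-1)/(n-1-q)$), since which of the two a given
report quotes is often unstated; the package asserts nothing about
which convention external numbers use.

The type-I error of the entry rule is measured (not assumed) in the
acceptance suite: 1000 null data sets with two i.i.d. Gaussian candidate
constraints each, 199 permutations. With 199 permutations the smallest
attainable p is 1/200, so the strict p < 0.01 rule admits a single noise
candidate with probability 0.005 and either of two with probability
just under 0.01 — the observed rate is required to land in
[0.005, 0.02].

## What the generator emulates — and what it does not

`plant_network()` + `simulate_counts()` produce data with the structure
the analysis assumes:

- a three-block graph (bacteria-rich, phototroph-rich, mixed
  fungal/bacterial) with within-block edges ~8× likelier, mimicking the
  dense cluster organisation of real cross-domain biofilm networks;
- hub taxa with degree ≥ 3× the non-hub median, wired half across
  blocks — the planted "keystones";
- a precision matrix with −U(0.2, 0.4) weights on planted edges and
  diagonal |row sum| + 0.5 (diagonal dominance certifies positive
  definiteness; negative off-diagonals make every planted edge a
  positive association);
- latent log-abundances from the implied Gaussian, an environmental
  gradient shifting 20% of taxa by 0.8 log units per gradient SD, and
  per-marker multinomial sampling at depths U(5 000, 20 000) reads —
  the logistic-normal-multinomial model under which CLR- and
  log-ratio-based inference is well-specified;
- metadata (GFS/TRIB, pre/post-2000) tied to the gradient with 15%
  label noise, so constrained ordination has recoverable structure.

Defaults (60 bacteria + 30 phototrophs + 10 fungi, 150 samples, edge
density 0.05, 3 hubs) describe one floodplain stratum at desk scale.
The generator does *not* emulate sequencing error, chimeras, taxonomic
misassignment, copy-number variation, overdispersion beyond the
multinomial, spatial/temporal autocorrelation between samples, or
zero-inflation beyond what sampling produces. Tests passing on this
generator therefore certify the algorithms and their bookkeeping — not
robustness of the biology to artefacts the generator omits.

One honest consequence, visible in the acceptance suite: with edge
weights U(0.2, 0.4) under diagonal dominance, planted edges carry
marginal latent correlations of only ~0.15–0.3. The default consensus
cuts (SparCC 0.3, Spearman 0.5) sit above much of that range, so
majority-vote recall of planted edges is ~0.2 and precision ~0.77 at the
default operating point; no operating point we searched reaches
precision 0.8 with recall 0.6 simultaneously under these effect sizes.
The defaults were kept (they are sensible for field data, where reported
associations should be strong), and the measured operating point is
reported by `scripts/acceptance.R` rather than tuned.

## Numerical choices and degenerate inputs

- SparCC basis variances are floored at 1e-10 before the square root;
  correlations clipped to [−1, 1]; a singular reduced system falls back
  to the previous exclusion round.
- CLR uses pseudocount 1 by default (configurable); the
  compositional-invariance property holds exactly only in the
  pseudocount→0 limit and is tested there.
- Ranks are dense (ties share the better rank), so tied centralities
  cannot push a node out of the keystone list by arbitrary ordering.
- Empty graphs: fragmentation errors (0/0); an edgeless graph has
  undefined modularity (reported NA) and one community per node.
- Strata with fewer than 10 samples are skipped with a logged reason;
  strata whose consensus network has no edges are recorded as `empty`
  rather than failing the run.
- All randomness flows from a single root seed, split deterministically
  per stage and stratum; two runs with the same configuration and seed
  produce byte-identical output files.

## Problem sizes used by tests and the acceptance script

Unit and property tests run at small sizes (p ≤ 60 taxa, n ≤ 500
samples; 300–1000 random graphs for exact combinatorial properties;
20-seed repetitions for stochastic recovery claims). The acceptance
script simulates three full study-scale data sets (60 taxa × 150
samples) for edge recovery, 20 planted networks for hub recovery, one
complete stratified pipeline run (100 taxa × 150 samples over 8 strata),
1000 null forward selections (199 permutations each) and one SparCC
recovery at n = 2000. These sizes were chosen so each quantity is
estimated with useful precision while a full run stays in the
couple-of-minutes range on a single CPU.

## Known limitations

- Co-occurrence is not interaction: the networks are correlational, and
  the keystone/fragmentation analysis characterises the *graph*, not a
  demonstrated ecological dependency.
- The 18S domain map (fungal and phototroph lineage keywords) is a
  reconstruction maintained as an editable list; lineages matching
  neither set are labelled `unknown` and excluded from nothing except
  domain-specific summaries.
- Negative associations are deliberately out of scope (positive-only
  consensus), as co-exclusion signals from amplicon data alone are hard
  to interpret.
- db-RDA constrained by keystone relative abundances partially
  conditions a community on its own members; the package follows that
  convention to keep the three constrained models comparable, but the
  bacterial-keystone explained fraction should be read as association,
  not as extrinsic forcing.
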