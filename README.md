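# biofilmnet

Cross-domain co-occurrence networks and community stability for stream
biofilm microbiomes.

Stream biofilms in proglacial floodplains host bacteria, eukaryotic
photoautotrophs (algae) and fungi whose interactions cannot be observed
directly at the scale of a sediment grain. What can be measured is
covariation: paired 16S (bacterial ASV) and 18S (eukaryotic OTU)
amplicon count tables across many stream sites. `biofilmnet` turns such
paired tables into cross-domain co-occurrence networks and asks which
taxa hold those networks together — the keystone question — and how much
of bacterial community composition those keystones explain relative to
the physical environment.

The package is aimed at microbial ecologists working with paired
amplicon datasets from streams, soils or any habitat where cross-domain
(prokaryote–eukaryote) associations matter.

## What it computes

**Ensemble network inference.** Because amplicon counts are
compositional, no single correlation measure is trustworthy on its own.
Three methods are run side by side and combined by majority vote over
positively-signed calls:

- *SparCC basis correlations*: from the log-ratio variances
  t_ij = Var[log(x_i/x_j)], basis variances ω_i² are solved from the
  linear system implied by sparsity, and
  ρ_ij = (ω_i² + ω_j² − t_ij) / (2 ω_i ω_j), with iterative exclusion of
  strongly correlated pairs and a permutation pseudo-p per edge.
- *Spearman rank correlation* on relative abundances with BH-adjusted
  p-values.
- *Meinshausen–Bühlmann neighborhood selection*: per-taxon L1-penalised
  regression of CLR-transformed profiles, penalty chosen by StARS
  (edge-instability target β over subsamples), OR-symmetrised.

An edge enters the consensus network when at least `min_support`
(default 2) methods call it and every supporting method reports a
positive association.

**Network characterisation.** Louvain communities (clusters of fewer
than five nodes pruned), topology metrics (nodes, edges, clusters,
diameter, edge density 2E/(N(N−1)), modularity Q, degree assortativity,
transitivity), and per-node degree and betweenness centrality.

**Keystones and fragmentation.** Keystone taxa are the top-10 nodes by
joint degree/betweenness rank-sum. Network stability is probed by
removing keystones one at a time and tracking fragmentation
f = (number of disconnected subgraphs) / (number of nodes).

**Variance partitioning.** Distance-based redundancy analysis (db-RDA)
on Wisconsin-standardised Bray–Curtis dissimilarities with
permutation-based forward selection (entry rule p < 0.01, 999
permutations by default) quantifies the bacterial community variance
explained by bacterial keystones, eukaryotic keystones and
log-standardised environmental variables, each as a separate constrained
model. Family-level shifts across stream type and deglaciation class are
tested with two-way ANOVA and BH adjustment.

**Synthetic data.** A generator plants a sparse three-block interaction
network with designated hub taxa, converts it to a diagonally dominant
precision matrix (negative off-diagonals, so planted edges are positive
associations), draws latent log-abundances from the implied Gaussian,
adds an environmental gradient to a taxon subset, and samples counts
multinomially per marker at realistic library depths
(logistic-normal-multinomial). Ground truth (adjacency, hubs, latent
draws) ships with every simulation, so the whole pipeline is testable
without sequencing data.

## Worked example

```r
library(biofilmnet)

cfg   <- sim_config(p_bacteria = 40, p_phototroph = 15, p_fungus = 5,
                    n_samples = 150, seed = 42)
truth <- plant_network(cfg)          # planted edges + hubs: bac008 pho008 bac036
sim   <- simulate_counts(truth, cfg)

stacked <- stack_tables(sim$t16, sim$t18)
net     <- infer_network(stacked, ensemble_config(seed = 42))
net
#> <cooccurrence_network> 36 nodes, 42 edges

glance(net)
#> # A tibble: 1 × 8
#>   n_nodes n_edges n_clusters diameter edge_density modularity assortativity
#>     <dbl>   <dbl>      <int>    <int>        <dbl>      <dbl>         <dbl>
#> 1      36      42          3        4       0.0667      0.638         0.248

keys <- select_keystones(centrality(net), k = 10,
                         tables = list(sim$t16, sim$t18))
head(keys, 5)
#> # A tibble: 5 × 5
#>   taxon_id degree betweenness rank_sum relative_abundance
#> 1 pho009        6        31.4        2            0.0282
#> 2 fun001        4        23.3        5            0.00360
#> 3 pho015        5        19.1        5            0.00880
#> 4 pho008        5        18.8        6            0.0245
#> 5 pho011        3        17.7        9            0.0516

traj <- removal_trajectory(net, keys, seed = 42)
glance(traj)
#> # A tibble: 1 × 3
#>   baseline_f f_mean n_removals
#> 1      0.194  0.363         10
autoplot(traj)   # fragmentation curve against keystones removed
```

Reading the numbers: the consensus network keeps 36 of 60 simulated taxa
with 42 positive cross-validated edges organised into 3 Louvain clusters
(Q = 0.64). The top keystones include a planted hub (`pho008`) and span
all three domains; note `fun001` ranks second while making up only 0.4%
of reads — keystones need not be abundant. Removing the ten keystones
nearly doubles fragmentation (0.19 → mean 0.36), the package's measure
of how much those taxa hold the network together.

The full chain over floodplain × stream-type × deglaciation strata, plus
the keystone-versus-environment db-RDA comparison, runs as one call:

```r
manifest <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
manifest$strata      # per-stratum network metrics and fragmentation
manifest$ordination  # explained variance per constraint set and floodplain
```

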