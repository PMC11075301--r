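# menet

Molecular ecological network (MEN) analysis for longitudinal microbiome
data.

Amplicon surveys yield ASV-by-sample count tables; the ecological signal
beyond diversity lies in the *co-occurrence structure* of the community —
which taxa covary, how modular the network is, which taxa are keystones,
and how fragile the network is to species loss. `menet` implements the
full analysis chain used to track such structure through a perturbation
and recovery time course (e.g. an antibiotic pulse followed by monthly
sampling of treated and control arms):

* **Preprocessing** — QIIME-style TSV IO, stratified low-abundance
  filtering, rarefaction, half-prevalence filtering, log transform.
* **Diversity** — chao1 `S_obs + F1(F1-1)/(2(F2+1))`, Shannon
  `-Σ p_i ln p_i`, dominance `Σ p_i²`; Bray–Curtis
  `d = Σ|x-y| / Σ(x+y)` with PCoA; ANOSIM, one-factor PERMANOVA and MRPP
  permutation tests; a Shapiro-gated t-test/Wilcoxon group contrast.
* **Network construction** — Pearson correlation of log abundances,
  thresholded by the random-matrix-theory transition: the cutoff is the
  smallest `s` at which the nearest-neighbour spacing distribution of the
  (unfolded, de-duplicated) eigenvalues of the thresholded |r| matrix
  leaves GOE (Wigner–Dyson) statistics and conforms to Poisson
  `P(d) = e^{-d}`.
* **Topology** — nodes, links, avgK = 2L/n, avgCC, geodesic distance over
  reachable pairs, connectedness, P/N link ratio, scale-free fit of
  `log P(k) ~ log k`, Maslov–Sneppen degree-preserving null ensembles with
  z-scores.
* **Modules and keystones** — fast-greedy modularity `M`, relative
  modularity `RM = (M - M_null)/M_null`, small/large module counts
  (boundary at 5 nodes), Zi–Pi roles (module hub `Zi > 2.5`, connector
  `Pi > 0.62`) and keystone counts.
* **Stability** — global efficiency `E = mean(1/d_ij)`, vulnerability
  `max_i (E - E_{-i})/E`, robustness to random 50% and targeted
  module-hub removal with pruning of isolated survivors.
* **Trends** — per-parameter regression against time, log2 fold-change
  A/C series, Spearman/Pearson complexity–stability correlation matrices.
* **Functional networks** — pathway Pearson networks and MCODE-style
  core-subnetwork extraction (degree cutoff 2, k-core 2, max depth 100).
* **Synthetic communities** — a compositional log-normal generator with
  planted correlation blocks and a decaying group effect, providing ground
  truth for every recovery test.

## Worked example

```r
library(menet)

cfg <- synthetic_config(seed = 42)     # 2 groups x 14 months x 8 samples
sim <- generate_counts(cfg)
sim$table
#> feature_table: 200 ASVs x 224 samples
#> groups: A, C; months: 1, 2, ..., 14

# month-1 network of the perturbed group
md  <- sim$table$metadata
ids <- md$sample_id[md$group == "A" & md$month == 1]
sub <- prevalence_filter(subset_samples(sim$table, samples = ids), 0.5)
sub$counts <- sub$counts[apply(sub$counts, 1, var) > 0, , drop = FALSE]
men <- build_network(pearson_matrix(log_transform(sub)), 0.75,
                     provenance = list(group = "A", month = 1))
round(t(network_indices(men, n_random = 30, n_reps = 100, seed = 1)), 4)
#> nodes                  132.0000
#> links                  340.0000
#> avg_degree               5.1515
#> avg_clustering           0.2751
#> geodesic                 3.8065
#> connectedness            0.9699
#> positive_links         272.0000
#> negative_links          68.0000
#> pn_ratio                 4.0000
#> modularity               0.5635
#> relative_modularity      0.4278
#> n_modules                8.0000
#> n_small_modules          1.0000
#> n_large_modules          7.0000
#> nodes_in_large_modules 130.0000
#> n_keystones             15.0000
#> robustness_random        0.4514
#> robustness_random_sd     0.0180
#> robustness_targeted      0.9773
#> vulnerability            0.0253
#> scale_free_r2            0.4924
#> scale_free_slope        -0.9095
```

Reading it: the month-1 perturbed-group network keeps 132 of 200 ASVs
(the richness effect removed the rest), has good modularity (M = 0.56 >
0.4) that sits 43% above its degree-preserving null, 15 keystone taxa,
and loses essentially half its species under random 50% removal
(robustness 0.45) while surviving targeted hub removal almost intact.
The group effect decays with its 3-month half-life:

```r
a <- alpha_diversity(sim$table)
tapply(a$chao1, paste(md$group, md$month), mean)[c("A 1","C 1","A 14","C 14")]
#>      A 1      C 1     A 14     C 14
#> 143.9075 192.6915 189.3088 194.6677
```

The month-1 chao1 deficit (A 144 vs C 193) has nearly closed by month 14.

## Pipeline CLI

```sh
Rscript inst/bin/menet.R all --config config.yaml --out results --seed 1
# subcommands: simulate filter diversity network stability trends funcnet all
```

Every stage writes TSV/GraphML outputs plus a JSON manifest (version,
config, config hash, seed); identical config + seed reproduce runs
byte-for-byte.

## Vignette

`vignettes/men-analysis.Rmd` documents the models, the RMT thresholding
machinery and its knobs, the synthetic generator's stated world and its
limits, and the design decisions.
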