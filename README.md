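# qsipgrowth

Taxon-specific soil bacterial growth from ¹⁸O-water quantitative stable
isotope probing (qSIP), with factorial climate-interaction typing and
phylogenetic clustering of response groups.

## Who this is for and what it does

Soil microbiologists running ¹⁸O-qSIP incubations under factorial
climate manipulations (warming × altered precipitation) need to go from
raw density-gradient measurements — per-fraction qPCR totals and 16S
amplicon relative abundances — to per-taxon growth rates, effect sizes,
and interaction classifications. `qsipgrowth` implements that chain as
a tested R pipeline, together with a forward simulator of the whole
experiment so every stage can be validated by parameter recovery
against known ground truth.

The core estimation chain, per taxon: the copy-weighted mean fraction
density (weighted-average buoyant density, WAD) of the unlabeled (¹⁶O)
tubes gives GC content via the linear GC–density relation, hence the
unlabeled molecular weight `m_light` and the fully-labeled maximum
`m_heavy`; the labeled (¹⁸O) WAD gives
`m_lab = m_light · (W_lab / W_light)`; then

```
EAF   = (m_lab − m_light) / (m_heavy − m_light) · (1 − p_nat)
n_light = n_total · (m_heavy − m_lab) / (m_heavy − m_light)
g     = ln(n_total / n_light) / t                 (per-capita, day⁻¹)
dN/dt = n_total · (1 − e^(−g·t)) / t              (copies g⁻¹ soil day⁻¹)
```

Confidence intervals come from resampling replicate tubes (percentile
bootstrap, B = 1000); a taxon is an *incorporator* when the lower 95%
bound of `g` exceeds zero. Climate effects are log response ratios
`lnRR = ln(X_t/X_c)` on per-replicate dN/dt; each 2×2 scenario's
interaction is Hedges'
`d_I = [(X_AB − X_A) − (X_B − X_c)] / (2s) · J(m)`, and every taxon is
classified as additive, synergistic, weak antagonistic, strong
antagonistic, or neutralizing, with an antagonism intensity scale
(−1…3) and a proportion-weighted community score. Groups of taxa
sharing a type are tested for phylogenetic clustering with the nearest
taxon index (NTI) against a random tip-set null.

## Worked example

The numbered scripts under `analysis/` run a complete simulated study
(100 taxa, 6 treatments × 3 replicates × 2 isotopes, 20 fractions per
tube) stage by stage, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_growth.R
Rscript analysis/03_effects.R
Rscript analysis/04_interactions.R
Rscript analysis/05_phylo.R
```

Output from this run:

```
Estimated growth for 600 taxon x treatment pairs.
Median |EAF error| = 0.0081; Spearman rho(g_est, g_true) = 0.987.
100 of 100 taxa are 18O incorporators in the ambient control.

Single-factor lnRR: 100% negative (growth suppression).
Interaction-type calls per scenario:
      additive neutralizing strong_antagonistic synergistic weak_antagonistic
  WxD       24           16                  21           5                32
  WxW       22           19                  18           7                34
Designed type recovered for 81% of 198 classified taxa.

Community antagonism: W x D = 1.19, W x W = 1.20 (scale -1..3).
98 incorporators classified in both scenarios; 37 with higher antagonism under W x W.
```

Reading this: the estimator recovers the simulator's true excess atom
fractions to well under 0.01 and ranks growth rates almost perfectly;
all single-factor effects are suppressive (as designed); about 70% of
classified taxa land in one of the three antagonistic categories, with
weak antagonism the largest class; and the community antagonism score
sits between "weak" (1) and "strong" (2) in both scenarios. The same
study in one call:

```r
library(qsipgrowth)
st  <- simulate_qsip_study(100, seed = 1)
res <- run_qsip_pipeline(st$table, tree = st$tree,
                         design = st$design,
                         config = qsip_config(n_bootstrap = 1000, rng_seed = 1))
res$community_antagonism
table(res$calls$scenario, res$calls$type)
```

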