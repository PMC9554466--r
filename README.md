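# fungalassembly

Community-assembly inference for abundant and rare soil fungi.

Soil fungal communities are dominated by a handful of abundant taxa
while most taxa are rare, and the two fractions need not be governed by
the same ecological processes. This package implements, as tested R
functions, the full inference chain used to ask that question from an
ASV count table and sample metadata:

- **Classification** of taxa into regionally abundant (mean relative
  abundance > 0.1%), rare (< 0.005%) and intermediate fractions, with
  local (per-sample, > 1% / < 0.01%) labels and occupancy.
- **Levins' niche breadth** B = 1 / Σ p_j² per taxon and its
  abundance-weighted community mean (Bcom) per sample.
- **Abundance-based null model**: 999 randomized communities that
  preserve each sample's richness and total reads while resampling
  individuals with pool-proportional probabilities, yielding the
  standardized **β-deviation** = (β_obs − mean β_null) / sd β_null per
  sample pair. Deviations ≫ 0 indicate dispersal limitation or
  heterogeneous selection; ≪ 0, homogenizing dispersal or homogeneous
  selection; ≈ 0, stochastic assembly.
- **Sloan neutral community model**: occurrence frequency
  freq(p) = 1 − I_d(N·m·p, N·m·(1−p)) fitted by least squares for the
  migration rate m, with R² as the neutrality yardstick.
- **Distance–decay** of similarity (1 − Bray–Curtis) with geographic
  distance (haversine, R = 6371 km), Mantel tests, PERMANOVA.
- **MRM with forward selection**, two-set **variation partitioning**
  (pure space / pure environment / shared / unexplained),
  **hierarchical partitioning** of plant / soil / climate / space
  groups, and a recursive **path analysis** separating direct from
  indirect effects on the β-deviations.
- A seeded **synthetic metacommunity generator** (30 sites × 3
  quadrats, 4 vegetation types, lognormal SAD, 9,080 reads/sample)
  whose knobs map one-to-one onto assembly processes, so every
  inference is validated against data with known truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
default mixed scenario (abundant tail neutral, rare tail
niche-selected), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_classify_taxa.R
Rscript analysis/04_null_model.R
Rscript analysis/05_neutral_model.R
Rscript analysis/07_drivers.R
```

prints, among other things:

```
abundant: 108 ASVs (15.3% of taxa) holding 90.87% of reads
rare: 259 ASVs (36.7% of taxa) holding 0.64% of reads
abundant: mean beta-deviation 26.41 (t-test vs 0: p = 0)
rare: mean beta-deviation 0.13 (t-test vs 0: p = 0.00641)
abundant: m = 0.034, R2 = 0.586 (108 taxa)
rare: m = 0.558, R2 = -0.432 (259 taxa)
neutral processes fit the abundant subcommunity better than the rare
abundant VPA: pure space 0.95%, pure env 5.05%, shared -0.81%, unexplained 94.82%
rare VPA: pure space 7.70%, pure env 9.82%, shared 10.05%, unexplained 72.43%
rare path model: outcome R2 = 27.25%
```

Read: a minority of taxa holds nearly all reads; the neutral model fits
the abundant subcommunity far better than the rare one (R² 0.59 vs
negative); environment explains a much larger share of rare than of
abundant β-deviation variance — exactly the contrast the generator was
built to produce, recovered end-to-end by the inference chain.

The same chain runs on real data by replacing the simulated inputs:
`read_community_table()` accepts taxa-by-sample TSV (or BIOM) and
`read_sample_metadata()` a CSV with `sample_id, site_id, lat, lon,
vegetation_type` plus covariate columns, after which
`run_pipeline(pipeline_config(...))` executes every stage and writes
all artifacts plus a manifest.

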