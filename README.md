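# ndmscan

Seed-region (epicentre) identification for neurodegenerative disease using
the network diffusion model on structural brain connectomes.

## What it does

In several neurodegenerative diseases, misfolded proteins appear to spread
trans-neuronally along white-matter pathways, so the spatial pattern of
grey-matter atrophy should be predictable from the wiring of the healthy
brain. `ndmscan` implements the standard computational form of that
hypothesis — the network diffusion model (NDM) — and the *repeated seeding*
analysis built on it:

1. **Diffusion model.** On a weighted connectome `C` (nodes = brain
   regions, weights = tractography streamline counts) pathology evolves as

   ```
   f(t) = exp(-α H t) f0,      H = I − D^{−1/2} C D^{−1/2}
   ```

   where `H` is the symmetric normalized graph Laplacian, `D` the diagonal
   matrix of weighted node degrees, `α` the diffusivity (default 1), and
   `f0` the seed pattern. The solution is computed through the eigenmodes
   of `H`: `f(t) = Σ_i e^{−α λ_i t} (u_iᵀ f0) u_i`.

2. **Measured atrophy.** Regional t-statistic maps of volume loss are
   computed from subject-level volumetric tables (FreeSurfer-style TSV)
   after intracranial-volume normalization: two-sample (patients vs
   controls) or paired (longitudinal) designs, loss-positive sign.

3. **Repeated seeding.** Diffusion is initiated from each bilateral
   homologous region pair in turn (41 seeds for the default 82-region
   bilateral parcellation), evolved over model times `t = 0..50`, and each
   prediction is correlated (Pearson, *excluding the seed regions*, 80
   regions retained) with the measured atrophy at every time point. Each
   seed is scored by its maximum correlation over time; p-values are
   family-wise corrected (Bonferroni) over the 41 seed hypotheses.

4. **Null networks.** The best correlation is benchmarked against the same
   scan run on randomized connectomes that preserve the binary degree
   sequence (Maslov–Sneppen rewiring), the exact edge-weight multiset, and
   approximately the nodal strength distribution; an empirical p-value is
   reported from K (default 1000) nulls.

A synthetic-data module generates bilateral connectomes and study-like
volume tables with a *planted* diffusion seed, so the whole pipeline is
testable end-to-end without any imaging data.

Audience: researchers in network neuroscience / computational neurology
who want a tested, scriptable reference implementation of the
repeated-seeding NDM analysis.

## Worked example

```r
library(ndmscan)

spec <- synthetic_spec(seed_pair = 12, t_star = 10, rng_seed = 42)
con  <- synth_connectome(spec)
con
#> ndm_connectome: 82 regions (41 bilateral pairs), 259 edges, total weight 11773.3

study   <- synth_volume_tables(spec, con)     # 14 patients vs 12 controls
atrophy <- t_map_two_sample(study$patients, study$controls)
atrophy
#> atrophy_map (two_sample): 82 regions, 24 with p < 0.05 (uncorrected)
#>  region_label    t        p
#>  rh_region_14 7.73 5.77e-08
#>  lh_region_14 6.93 3.64e-07
#>  lh_region_13 6.80 4.88e-07
#>  lh_region_11 6.34 1.50e-06
#>  rh_region_10 6.23 1.95e-06

scan <- repeated_seed_scan(con, atrophy)
scan
#> seed_scan: 41 seeds x 51 time points (alpha = 1, bonferroni FWE over seeds)
#> Top seeds:
#>  seed_label max_r t_star        p    p_fwe
#>   region_12 0.881     12 4.26e-27 1.75e-25
#>   region_13 0.855     12 5.66e-24 2.32e-22
#>   region_11 0.820     17 1.33e-20 5.47e-19
#>   region_14 0.798     13 7.87e-19 3.23e-17
#>   region_10 0.711     21 1.50e-13 6.15e-12

nulls <- null_distribution(con, atrophy, K = 200, rng_seed = 1,
                           observed = max(scan$seeds$max_r))
nulls
#> ndm_null: K = 200 randomized networks
#>   observed max r = 0.8812, null 95th percentile = 0.4067, empirical p = 0.004975
```

The planted epicentre (bilateral pair 12, planted model time 10) is
top-ranked: the scan's best seed is `region_12` with `max_r = 0.881` near
`t* = 12`, far above anything achievable on degree/strength-preserving
random networks (null 95th percentile 0.41, empirical p ≈ 0.005). The most
atrophic single regions (pair 14) are *not* the best seeds — the method
looks for the diffusion origin, not the damage peak.

With real data, replace the synthetic steps:

```r
con     <- load_connectome("connectome.txt", "regions.tsv")   # square matrix + label TSV
patients <- read_volume_table("patients.tsv", con)
controls <- read_volume_table("controls.tsv", con)
atrophy  <- t_map_two_sample(patients, controls)
scan     <- repeated_seed_scan(con, atrophy)
```

A small command-line front end is installed under `inst/cli/ndm`
(`ndm seed-scan ...`, `ndm simulate ...`).

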