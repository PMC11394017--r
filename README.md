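# dietshift

Dietary-shift analysis of paired owl pellet surveys.

`dietshift` is for ecologists comparing a raptor's diet spectrum between
two pellet collections made at the same roost with unequal effort — the
classic before/after design used to detect responses of small-mammal
communities to land-use change. It takes long-format prey count tables
(survey, taxon, count), normalises them to per-pellet abundances
`a_ij = n_ij / P_j`, and asks whether the diet changed, using:

- **Pielou evenness** `J = H / ln S` of each survey's prey proportions,
  tested as the paired difference `ΔJ = J_later − J_earlier`;
- **Petraitis specific niche overlap**
  `O_{A|B} = exp(−KL(p_A ‖ p_B))` between the two utilization
  distributions (both directions and their geometric mean are reported),
  tested left-sided against the null expectation;
- **feeding-guild abundance differences** `Δa_g` for insectivorous,
  herbivorous and omnivorous prey, in prey-per-pellet units;
- a **quantitative shuffle-and-swap permutation null model**: each of the
  9999 (default) replicates redraws *which* resource categories each
  survey uses — uniformly over occupancy patterns with the observed
  margins, so the per-survey number of unexploited categories (the
  observed niche breadth) is conserved — and then reshuffles the observed
  non-zero cell counts onto the occupied cells, conserving the grand total
  and the value multiset. Empirical p-values use the add-one convention
  `(r+1)/(n+1)`, and each test is summarised by the non-parametric probit
  standardized effect size `SES = sign(T_obs − T̄*) · |Φ⁻¹(p/2)|`, with
  `|SES| > 1.96` flagging 5% significance whatever the shape of the null;
- **NMDS** (Kruskal stress-1, pool-adjacent-violators monotone
  regression) of the taxa on Euclidean distances between their per-pellet
  abundance profiles, to identify the taxa that drive the shift. With two
  surveys the embedding is exact and the final stress is numerically zero.

A Dirichlet-multinomial synthetic generator (`generate_dataset()`,
`study_like_fixture()`) reproduces the design — two surveys with 535 vs
159 pellets, ~9 subfamily-level taxa, three guilds, a controllable
omnivore-up/insectivore-down shift — so the entire pipeline runs,
and is calibrated, without any external data.

## Worked example

```r
library(dietshift)

fx <- study_like_fixture(seed = 7)   # synthetic, study-shaped data
res <- run_pipeline(fx$counts, fx$surveys, fx$guilds,
                    later = "2012", earlier = "2004",
                    null_cfg = null_config(n_perm = 9999, seed = 42))
res
#> Dietary-shift analysis: 2012 vs 2004 (shuffle_samp null, 9999 replicates)
#>              feature  observed null_mean     ses      p alternative significant
#>  Prey taxon evenness -0.104760  -0.01874 -0.7858 0.4320   two_sided       FALSE
#>   Food niche overlap  0.000000   0.00000  0.0000 1.0000        left       FALSE
#>      Omnivorous prey  0.376512   0.79261 -0.4974 0.6189   two_sided       FALSE
#>     Herbivorous prey  0.004796   0.27406 -0.6373 0.5239   two_sided       FALSE
#>   Insectivorous prey -0.465479   0.57593 -1.3917 0.1640   two_sided       FALSE
#> NMDS stress-1: 0
```

The observed column is the data talking: evenness dropped by 0.105, the
omnivorous guild gained 0.38 prey per pellet while the insectivorous guild
lost 0.47 — the built-in omnivore-up/insectivore-down shift of the
fixture. The simulated columns are the null model talking: at this effect
size none of the paired differences clears the two-sigma bar against the
conservative shuffle-and-swap null. The geometric-mean overlap is 0
because two categories are unexploited in the 159-pellet survey (the
complete-separation limit of the index); the directed overlaps stay
informative:

```r
res$overlap_candidates
#> # A tibble: 1 × 3
#>   later_on_earlier earlier_on_later geometric_mean
#>              <dbl>            <dbl>          <dbl>
#> 1            0.764                0              0
```

The ordination singles out the taxa that moved most (here Murinae, the
dominant omnivore), and `stress ≈ 0` confirms the exact 2-D embedding:

```r
tidy(res$nmds)
#> # A tibble: 9 × 3
#>   taxon              NMDS1    NMDS2
#> 1 Murinae           0.631   0.0597
#> 2 Crocidurinae      0.134  -0.146
#> 3 Soricinae        -0.0582 -0.0960
#> # … 6 more rows

autoplot(res$nmds)     # ordination plot
autoplot(res)          # guild abundance bars
```

`run_pipeline(..., out_dir = "out")` additionally writes `results.tsv`
(the five-row table above, print-formatted), `nmds_coords.csv`,
`guild_abundance.csv` and a `run.log` recording seed, variant and
replicate count; the same config and seed give byte-identical results.

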