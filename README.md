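# dietshift

Diet indices, regime shifts and ordination for seabird diet time series.

## What this is for

Long-term collections of seabird regurgitates are among the few
multi-decadal records of prey communities in hard-to-sample Arctic
waters. In a fjord fed by both Arctic and Atlantic water masses, the
balance between Arctic prey (polar cod, *Themisto libellula*) and
Atlantic prey (capelin, herring, Atlantic cod, haddock) in kittiwake diet
samples indicates whether the ecosystem is drifting toward an Atlantic
state. `dietshift` turns per-bird regurgitate records into that
assessment:

* **Diet indices** per prey taxon or origin class: frequency of
  occurrence `FO = 100·N/n`, average wet weight `WW` (mean g per sample,
  zeros included), average meal mass `MM` (mean g over samples containing
  the item) and average mass percentage `AP` (mean per-sample mass
  fraction), linked by the exact identity `WW = MM·N/n`.
* **Regime detection**: change-point analysis over annual series with
  AICc selection among five OLS forms (constant, linear, and three
  change-point variants), change-points reported as the last year of the
  previous regime.
* **Within-year comparisons**: two-sample permutation tests (exact
  enumeration or Monte Carlo with the +1 validity correction,
  `p = (#{|T*| ≥ |T|} + 1)/(B + 1)`) of Arctic vs Atlantic per-sample
  masses.
* **Environmental coupling**: month-first sea-ice index construction,
  volume-weighted fjord temperature `ΣT(z)A(z)Δz / ΣA(z)Δz`, linear trend
  regressions, and Pearson correlations with Fisher-z 95% CIs on raw and
  detrended series.
* **Community ordination**: Bray-Curtis dissimilarity among years on the
  FO matrix, Ward (`ward.D2`) clustering, and nMDS with FO-weighted
  species scores.
* **Otolith morphometrics**: deterministic otolith pairing, linear
  otolith-to-fish-length regressions with extrapolation flags, and
  length-based age classes with drift-time brackets for 0+ fish.
* **A synthetic-data generator** with a two-regime occurrence process and
  lognormal meal masses, so the whole pipeline is testable end to end
  without any external data.

## Worked example

```r
library(dietshift)

x <- generate_samples(seed = 1)          # ~880 samples, 1997-2016
index_table(x, categories = c("polar_cod", "capelin", "arctic", "atlantic"))
#>    category fo_pct n_occ ww_g mm_g ap_pct
#> 1 polar_cod   55.1   485 9.51 17.3   57.6
#> 2   capelin   21.1   186 2.83 13.4   18.9
#> 3    arctic   58.4   514 9.85 16.9   62.7
#> 4  atlantic   22.8   201 3.01 13.2   20.4
```

Pooled over both regimes, polar cod turns up in 55% of samples and makes
up 58% of the average sample's mass. The annual Arctic FO series shows
the regime structure:

```r
select_model(fo_series(x, "arctic"))
#> Regime model for 'FO arctic': constant_changepoint (regimes 1997-2006 / 2007-2016)
#>   n = 20, residual df = 18, RSS = 754.1, AICc = 80.10
#>   model F = 293.0, p = 1.39e-12
#>                 term estimate   se    t        p
#>  Intercept 1997-2006    83.18 2.05 40.6 3.67e-19
#>  Intercept 2007-2016    33.64 2.05 16.4 2.77e-12
```

The step form wins the model selection, the change-point lands on 2006
(read: last Arctic-dominated year), and Arctic prey occurrence drops from
~83% to ~34% of samples. Per-year permutation tests show who dominates
the mass of the average regurgitate:

```r
annual_group_comparison(x, n_perm = 999, seed = 1)[1:4, c(1:3, 5:7)]
#>   year mean_arctic_g mean_atlantic_g     p significant dominant
#> 1 1997          14.3           0.000 0.001        TRUE   arctic
#> 2 1998          14.5           0.135 0.001        TRUE   arctic
#> 3 1999          12.4           0.170 0.001        TRUE   arctic
#> 4 2000          17.9           0.550 0.001        TRUE   arctic
```

`run_pipeline(run_config(out_dir = "out", seed = 1))` chains every stage
and writes one CSV per result (plus a Newick dendrogram, a MANIFEST and a
summary), each stamped with the package version and seed; identical
config and seed give byte-identical artifacts.

See `vignettes/dietshift-methods.Rmd` for the model assumptions, the
tunable parameters and their defaults, what the generator does and does
not emulate, and known limitations.

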