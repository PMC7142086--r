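# msdendro

Hierarchical clustering of untargeted MS/MS spectra with dynamic ion binning.

Untargeted LC-MS/MS experiments on a single sample routinely produce
thousands of fragmentation spectra, almost none of which match a spectral
library. Compounds of the same chemical class, however, share fragmentation
pathways, so their MS/MS spectra share product ions. `msdendro` groups
deconvoluted LC-MS features by the *presence pattern* of their fragment ions
and exposes the signature ions behind each group, so that a metabolomics
analyst can classify unknowns — for example, expanding a family of insect
defensive steroids (lucibufagins) from a handful of known members to the full
complement present in a firefly hemolymph extract (MetaboLights MTBLS698).

## Method

1. **Alignment.** Each feature (precursor m/z, retention time) is matched to
   at most one MS/MS scan with |Δm/z| ≤ 0.005 Th and |ΔRT| ≤ 6 s; among
   candidates the closest retention time wins (ties: smaller |Δm/z|, then
   scan order). One scan may serve several co-eluting isobaric features.
2. **Ion filtering.** Product ions below an absolute intensity floor
   (default 5000 counts) — or, alternatively, below a fraction of the base
   peak — are removed. Spectra may optionally be recast as neutral losses
   (precursor − fragment).
3. **Dynamic binning.** All surviving product-ion masses are pooled, sorted,
   and split into bins wherever two consecutive masses differ by more than
   ε = 0.0005 Th (equivalently: 1-D single-linkage clustering cut at ε).
   Bin widths adapt to the data instead of imposing a fixed grid, so
   instrument precision — not an arbitrary boundary — decides what "the same
   ion" means.
4. **Distances.** The binary feature × bin occurrence matrix is compared by
   Bray-Curtis dissimilarity, which on presence/absence vectors *u*, *v*
   with *a* shared and *b + c* private bins is (b+c)/(2a+b+c)
   (= Sørensen–Dice); Jaccard (b+c)/(a+b+c) is also available.
5. **Clustering.** Complete-linkage agglomeration
   D(A∪B, C) = max(D(A,C), D(B,C)), cut at a distance threshold
   (default 0.7, inclusive) into flat clusters.
6. **Interrogation.** Per-cluster ion-incidence tables (% of the cluster's
   features containing each bin, with raw-mass statistics), diagnostic-ion
   queries (bins at 100% in every cluster of interest, or unique to one),
   ion histograms, dendrogram export (newick/JSON).

Companion formula tools identify fragment and precursor ions by accurate
mass: exhaustive C/H/(N)/O composition enumeration within a ppm tolerance
(even-electron cation convention, m/z = Σ atomic masses − mₑ; RDBE
= C − H/2 + N/2 + 1), and adduct/aggregate-ion mass calculus for M+H, M+NH4,
M+ACN+H, 2M+H, 2M+NH4 and 3M+NH4.

## Worked example

```r
library(msdendro)

sim <- generate_dataset(synthetic_spec(seed = 42, shared_ions = 2,
                                       signature_ions_per_cluster = 8))
fit <- dendro_cluster(sim$features, sim$spectra)
fit
#> <dendro_clustering>
#>   features : 15 clustered, 0 unaligned, 0 dropped (no surviving ions)
#>   ion bins : 67 (gap threshold 0.0005 Th)
#>   clusters : 3 at braycurtis distance threshold 0.7 (complete linkage)
```

Fifteen synthetic features (3 planted clusters × 5 features) produce 67 ion
bins and recover exactly 3 clusters at the default cut. The two ions planted
in *every* cluster — emulating class-wide diagnostic fragments — are found by
the 100%-incidence query:

```r
diagnostic_ions(fit$ion_records, clusters = 1:3, require_percent = 100)
#> # A tibble: 2 × 2
#>   bin_id representative_mz
#>    <int>             <dbl>
#> 1     19              165.
#> 2     22              170.
```

Accurate-mass identification of a diagnostic fragment: the only C/H/O
composition within ±10 ppm of m/z 105.0701 is the styryl cation C8H9⁺,
observed 2.1 ppm high:

```r
enumerate_formulas(105.0701, tolerance_ppm = 10, mode = "CHO")
#> # A tibble: 1 × 8
#>   formula     c     h     n     o theoretical_mz ppm_error  rdbe
#> 1 C8H9        8     9     0     0           105.      2.13   4.5
```

And a precursor check: a diacetylated lucibufagin (C28H36O10) observed at
m/z 533.237885 as the protonated molecule is 0.45 ppm from theory:

```r
adduct_mz("C28H36O10", "M+H")
#> [1] 533.2381
round(ppm_error(533.237884521484, adduct_mz("C28H36O10", "M+H")), 2)
#> [1] -0.45
```

`tidy(fit)` returns the per-feature cluster table, `glance(fit)` a one-row
summary, `autoplot(fit)` the dendrogram with the cut line, and
`plot_ion_histogram(fit, 1)` a cluster's ion-incidence bar chart.
`inst/cli/msdendro.R` wraps the same functions as a shell tool
(`cluster`, `formula`, `annotate`, `count-scans`, `simulate` subcommands).

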