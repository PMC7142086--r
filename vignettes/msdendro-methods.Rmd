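---
title: "Clustering MS/MS spectra with msdendro: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering MS/MS spectra with msdendro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdendro)
```

## The problem

In data-dependent LC-MS/MS of a complex extract, most fragmentation spectra
match nothing in public libraries. What *is* conserved is chemistry:
structurally related compounds fragment along related pathways and therefore
share product ions. `msdendro` operationalises that observation. It groups
deconvoluted LC-MS features by the presence pattern of their fragment ions
and then lets the analyst interrogate each group's ion profile: which ions
occur in every member, which are unique to a subgroup, and what elemental
composition each diagnostic ion can carry.

This vignette explains the models and the parameters, why each default is
what it is, what the synthetic data generator does and does not emulate, and
where the genuinely open design decisions were resolved.

## Alignment

A feature is a (precursor m/z, retention time) pair from upstream peak
picking; a spectrum is an MS/MS scan. A spectrum is an alignment candidate
for a feature when |Δm/z| ≤ `mz_tol` and |ΔRT| ≤ `rt_tol`, *both boundaries
inclusive* (the tolerances are read as admissible deviations; nothing in the
semantics of an instrument tolerance suggests an open interval). The winner
among candidates is the scan closest in retention time; exact RT ties go to
the smaller |Δm/z|, and any remaining tie to the earlier scan in file order.
The file-order index is recorded at read time, so alignment is deterministic
and invariant to shuffling the spectrum table.

Defaults: `mz_tol` 0.005 Th and `rt_tol` 6 s, appropriate for a
high-resolution Orbitrap acquisition with stable chromatography. One scan
may serve several features (co-eluting isobars are real and common in DDA),
but each feature gets at most one scan — the workflow deliberately does not
merge same-precursor spectra across retention time, so isobaric compounds
stay distinct.

Features with no candidate scan are reported as `unaligned`, never silently
dropped.

Retention times are stored in seconds everywhere. Feature lists that embed
retention time in minutes (the widespread `sample_mz_rtminutes` identifier
convention) are converted on read; `read_feature_list()` defaults to
`rt_unit = "minutes"` because that convention dominates, and the unit is a
declared argument rather than a guess from the data.

## Intensity filtering and neutral loss

Exactly one intensity filter is active per run: an absolute floor (default
5000 counts) or a relative floor as a fraction of the spectrum base peak.
The floor is inclusive (an ion at exactly 5000 counts survives a 5000
floor). The relative filter normalises to the base peak rather than to total
ion current: the base peak is the stable reference an analyst inspects, and
TIC normalisation would couple the threshold to spectral complexity.

Spectra can be recast as neutral losses (precursor − fragment, non-positive
losses removed). Loss spectra emphasise shared eliminations (H2O, acetyl,
sugars) rather than shared fragments; the two representations answer
different questions, so a run uses one or the other, never a mixture, and a
spectrum table refuses a second conversion.

A feature whose spectrum loses every ion to the filter is excluded from
clustering and listed in the audit report: its occurrence row would be all
zeros, and the Bray-Curtis distance of an all-zero row is 0/0.

## Dynamic binning

All surviving product-ion masses, pooled across spectra, are sorted, and a
new bin opens wherever two consecutive masses differ by more than `bin_eps`
(default 0.0005 Th). Two properties follow:

* **It is exactly 1-D single-linkage clustering cut at `bin_eps`** — the
  test suite asserts this identity against `hclust(..., "single")` on
  thousands of random masses.
* **Bins chain.** Only consecutive gaps are constrained, so a dense run of
  masses can form a bin wider than `bin_eps` overall. This is intentional:
  the rule is stated on consecutive masses, and chaining is what lets a bin
  follow a slowly drifting ion across many spectra. The flip side — in very
  dense m/z regions unrelated ions can chain into one bin — is a known
  limitation users should keep in mind when `bin_eps` approaches the typical
  ion spacing.

`bin_eps` should reflect instrument precision, not resolution: it is the
spread you expect for *the same* ion re-measured, which for a well-calibrated
Orbitrap at these masses is a few ten-thousandths of a Thomson.

## Distances on presence/absence

The occurrence matrix is binary: a cell records whether a feature's spectrum
contributed at least one ion to a bin, never how intense it was. Intensity
is used only as a pre-filter. Two reasons: fragment intensities vary with
collision energy and precursor abundance far more than fragment *identities*
do, and the alternative metric offered (Jaccard) is only meaningful on
binary data, which pins the intended representation. On 0/1 vectors the
Bray-Curtis formula equals the Sørensen–Dice dissimilarity; the
documentation says so explicitly to avoid the (common) confusion with
abundance-weighted Bray-Curtis.

With shared count *a* and disagreement count *b + c*:
Bray-Curtis = (b+c)/(2a+b+c), Jaccard = (b+c)/(a+b+c), so
Jaccard ≥ Bray-Curtis always; both are 0 for identical and 1 for disjoint
ion sets. Computation is delegated to `vegan::vegdist()`; the test suite
re-derives both from the set counts independently.

## Complete linkage and the threshold cut

Complete linkage (D(A∪B, C) = max) is the conservative choice for this use:
a cluster's diameter never exceeds the largest pairwise dissimilarity, so
"every member of the cluster shares most of its ions with every other
member" — exactly the property the ion-incidence tables rely on. Complete
linkage is monotone, so merge heights never decrease and threshold cuts are
well defined.

The agglomeration is implemented in the package with an explicit tie-break:
among equal minimum distances, the pair with the smallest (node index, node
index) wins, leaves numbered in input order and internal nodes in creation
order. Floating-point distance ties are rare on real data but certain on
synthetic and resampled data; an unspecified tie order would make trees
platform-dependent. `stats::hclust` serves as an independent cross-check in
the tests (cophenetic identity over random matrices), never as the
implementation.

The cut joins merges with height ≤ *t* (inclusive — a merge *at* the
threshold is within it) and labels flat clusters 1, 2, … by the position of
each cluster's leftmost leaf in the dendrogram. Labels are therefore
reproducible but arbitrary; only the partition is meaningful, and the
partition is invariant to input permutation. Cluster numbers from any
particular historical run of a similar workflow are run artefacts and are
not reproduced.

The default cut of 0.7 has a direct reading on binary Bray-Curtis: for two
ion sets of equal size sharing a fraction *s* of their ions, the distance is
exactly 1 − *s*, so the cut admits pairs sharing at least 30% of their
ions — loose enough to hold a compound class with variable substitution,
tight enough to exclude unrelated spectra, and adjustable per analysis.

## Reporting

For each (cluster, bin) the incidence table reports the share of the
cluster's features containing the bin, m/z statistics over the *raw*
pre-binning masses those features contributed (average is the unweighted
mean over contributing ions — if one spectrum contributes two raw ions to a
bin, both enter the mean; the estimator is documented because several
defensible choices exist), and the bin's incidence across all clustered
features. The per-cluster statistics and the overall incidence are separate
column groups on purpose: the first asks "is this ion characteristic of the
cluster", the second "how widespread is it overall".

`diagnostic_ions()` formalises the two questions asked of such tables:
which bins reach a required incidence (default 100%) in *every* named
cluster, and which in addition never occur in the other named clusters
("unique to" one cluster of the set). Percentages are carried at full
precision internally and rounded to whole numbers only in written files.

## Formula identification

Fragment formulas are interpreted as the composition of the intact
even-electron cation, so the theoretical m/z subtracts one electron mass
(mₑ = 0.00054858 u) from the atomic mass sum. This convention is what makes
observed fragment masses land within ~2 ppm of their compositions; treating
the composition as a neutral would shift every candidate by ≈ +5 ppm at
m/z 100 and misreport the errors.

The enumeration is exhaustive over C 1–60, H 0–120, O 0–30 (N 0–3 in CHNO
mode) with RDBE = C − H/2 + N/2 + 1 constrained to [−0.5, 40] and no
hydrogen-parity rule; an even-electron cation has half-integer RDBE, so a
parity filter would have to know the ion type and none is assumed. The
implementation solves the admissible hydrogen-count window per (C, N, O)
cell analytically; the test suite proves identity with a literal
triple-loop brute force over the same bounds.

Adduct masses are `k·M + carrier` with carriers fixed in one constant
table: proton 1.00727646, NH4⁺ 18.03382555, CH3CN 41.02654910 (all adduct
arithmetic flows from these plus the atomic masses C 12, H 1.00782503,
N 14.00307401, O 15.99491462). Supported forms: M+H, M+NH4, M+ACN+H, 2M+H,
2M+NH4, 3M+NH4 — the aggregate (2M, 3M) forms matter because electrospray
of concentrated extracts produces abundant dimer and trimer ions that would
otherwise be misread as distinct large compounds.

The package bundles a curated reference table of annotated lucibufagin
features from the firefly hemolymph dataset (MetaboLights MTBLS698) under
`inst/extdata/`. Two remarks on that table, recorded rather than silently
corrected:

* For two of the nine tabulated diagnostic fragment ions (147.0805 and
  185.0961) the reported ppm errors are not reproduced from the tabulated
  average masses under the cation convention (recomputation gives ≈ +0.4
  and ≈ +0.1 ppm); the originally reported values were likely computed from
  unrounded averages. These two ions are excluded from the identification
  checks; the other seven reproduce exactly.
* The single 3M+NH4 aggregate row is ≈ +1.003 Da from its computed
  aggregate mass — consistent with the measured peak being the first
  ¹³C isotopologue — and is excluded from the ≤ 2 ppm assertions.

## The synthetic data generator

`synthetic_spec()`/`generate_dataset()` produce MGF + feature-list + label
files with planted structure so every pipeline stage is testable without
downloads. Per cluster, a distinct set of signature ions (default 6) is
realised in every member spectrum with Gaussian m/z jitter (sd 0.0001 Th);
optional shared ions appear in all clusters; background ions are uniform
per spectrum; a fraction of ions is generated below the 5000-count floor to
exercise the filter. Given a seed, output files are byte-identical across
calls.

Deliberate choices:

* **Jitter sd 0.0001 Th** is about instrument precision and is less than
  half of `bin_eps`, so each planted ion occupies exactly one bin across
  all spectra — the recovery guarantees are constructive, and the tests
  verify the bookkeeping.
* **Planted-ion intensities** are log-normal (median 20000, sigma 1)
  resampled to ≥ 5000 counts. Without the truncation ~8% of signature ions
  would fall below the default floor and the planted incidence would not be
  100% by construction; background-ion intensities are left untruncated.
* **Shared ions default to 0.** The default dataset is 3 clusters × 5
  features with 6 signature ions each. Shared ions are a pull toward
  merging: with 6 signature + 4 shared ions per spectrum, the
  between-cluster binary Bray-Curtis is 18/26 ≈ 0.69, *below* the 0.7 cut,
  and complete linkage correctly merges everything — an instructive
  property, but not a sensible default for a generator whose default
  output should carry recoverable structure. Shared ions are switched on
  explicitly where class-wide diagnostics are tested.
* **Feature coordinates** match their spectrum exactly in retention time
  and within 0.004 Th in m/z, so a constant RT shift of the spectra probes
  the alignment tolerance boundary cleanly (5.9 s keeps all alignments,
  6.1 s removes all).

What the generator does **not** emulate: real fragmentation chemistry
(planted ions are positionally random, not chemically related), isotope
envelopes, chimeric spectra from co-isolation, intensity correlation
between related ions, retention-time drift within a run, and realistic
background density. A perfect recovery score on synthetic data therefore
demonstrates the correctness of alignment, binning, distance, linkage and
reporting arithmetic — not that any particular real dataset will separate
as cleanly.

## Numerical and scale choices

* Distances live in [0, 1] and the linkage validates that; symmetry is
  checked to 1e-12.
* The agglomeration is the O(n³) direct algorithm; at the scale this
  workflow targets (hundreds of aligned features, e.g. ~500 spectra for a
  single-sample analysis) it completes in seconds, and determinism was
  prioritised over asymptotics.
* Test problem sizes: 2000 random masses for the binning identity, 100
  random matrices of up to 12 leaves for the linkage identity, 15-feature
  synthetic datasets for end-to-end recovery — each chosen as the smallest
  size at which the property under test is non-trivial.
* MGF round trips preserve peak m/z and intensity to 1e-6 and retention
  time to 1e-4 s (fixed-format writing); report percentages are rounded to
  whole numbers in files only.

## Known limitations

Presence/absence discards intensity structure; two spectra sharing weak
noise ions look as related as two sharing base peaks (the intensity filter
is the only defence — set it thoughtfully). Chained bins can bridge
unrelated ions in dense regions. The aligner assumes upstream deconvolution
is trustworthy and does not attempt chimera detection or isotope handling.
mzML support is limited to scan counting; spectra enter through MGF.
Formula enumeration covers C/H/N/O only, by design.
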