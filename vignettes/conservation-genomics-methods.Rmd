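---
title: "Models and methods behind charrcu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind charrcu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charrcu)
```

# The problem

Arctic charr (*Salvelinus alpinus*) in Britain and Ireland live as
land-locked lake populations with essentially no contemporary gene flow
between catchments. Many lakes hold sympatric trophic ecotypes (benthivore,
planktivore, piscivore) that are reproductively isolated despite sharing a
lake. Conservation planning for such a system needs three things that this
package provides in one tested pipeline:

1. **Quality-controlled SNP data** from reduced-representation sequencing,
   including an error filter driven by technical replicate pairs;
2. **Diversity, differentiation and vulnerability metrics** per population —
   heterozygosity, private alleles, pairwise and population-specific
   F~ST~, genotype–environment association (GEA) candidates, genetic offset
   under future climate, and a composite lake-sensitivity score;
3. **Rule-based delineation** of management units (MUs) and evolutionarily
   significant units (ESUs) from genetic, phenotypic and geographic
   evidence.

Because the raw sequencing data live in external archives, the package
carries a simulator that generates genotype matrices, population maps and
environment tables with the statistical structure the analyses assume, plus
a known truth object. Every downstream stage is tested against it.

# The simulator

`simulate_metapopulation()` draws allele frequencies down a
region → Hydrometric Area → lake → ecotype hierarchy using Balding–Nichols
beta distributions: at a level with drift intensity $F$, a child frequency
is drawn as $p' \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, so $\mathrm{E}[p'] = p$ and
$\mathrm{Var}[p'] = F\,p(1-p)$. Genotypes are $\mathrm{Binomial}(2, p)$
draws; frequencies are clipped to $[0.001, 0.999]$ first so no locus is
forced to fixation and the minor-allele-frequency filter stays exercisable.

Defaults define the package's reference conditions: 2 regions × 4
Hydrometric Areas × 2 lakes (16 lakes, a quarter with an ecotype pair, i.e.
20 populations), 10 individuals per unimodal population and 5 per ecotype,
2000 SNPs with 20 environment-associated loci, drift intensities
(region 0.05, HA 0.05, lake 0.20, ecotype 0.02), 2.6% replicate
discordance over 10 pairs, ~5% missing genotypes at ~15× depth. The drift
hierarchy deliberately puts most differentiation at the lake level with a
small regional component — that is the pattern the target system shows,
where the east–west split explains under 1% of molecular variance while
populations within catchments explain the most. Mean pairwise
Weir–Cockerham F~ST~ under these defaults is ≈ 0.26.

Three modelling choices deserve notes:

* **Latitude is independent of the region hierarchy.** The regional split
  in the study system is a (longitudinal) drainage divide; lakes on both
  sides span the full latitudinal range. Assigning latitudes independently
  of region keeps regional drift from masquerading as a climate signal in
  the GEA — exactly the confounding structure real data have, without
  making it total.
* **Adaptive loci are shifted post-drift.** Environment-associated loci get
  their logit frequency shifted by `gea_effect` per standard deviation of
  the driver variable (bio1, which carries the latitude gradient) *after*
  drift. A locus that has drifted near fixation in many lakes therefore
  tracks the environment only weakly — strong drift can genuinely swamp
  selection, so detection power depends on the ancestral frequency, as in
  real data. The reference recall check runs at `gea_effect = 4` (a
  strong-selection regime); at the moderate regime (`gea_effect = 2`)
  adaptive loci still exceed the 95th neutral quantile of
  environment-correlation in the majority of cases, but 3-SD-outlier recall
  is materially lower.
* **Missingness is heterogeneous per SNP** (a zero-inflated exponential
  rate, mean equal to `missing_rate`, capped at 1/3), emulating RAD locus
  dropout. Independent per-genotype missingness would leave no
  complete-case SNPs at realistic sample sizes, which would starve the
  phylogenetic branch of the pipeline; with dropout heterogeneity roughly a
  quarter of SNPs are complete, matching the ratio seen in practice.

What the simulator does **not** emulate: linkage disequilibrium and shared
RAD loci (SNPs are independent; loci are 1:1 with SNPs unless tests build
multi-SNP loci explicitly), coalescent genealogies, batch effects in depth,
and non-random missingness by genotype. Passing tests therefore say nothing
about robustness to LD pruning choices or allele dropout bias.

# Quality control

The SNP-retention cascade runs presence → MAF → maximum observed
heterozygosity → first SNP per locus → Hardy–Weinberg → depth → replicate
mismatch, each stage returning a one-row report that telescopes
(`snps_out = snps_in − snps_removed`, chained). Conventions, where the
field leaves room:

* Presence: a SNP must be called in ≥ 66% of individuals in *every*
  population and ≥ 66% overall. Applied literally even to tiny populations.
* MAF (0.01) and maximum H~O~ (0.5) are computed over all individuals
  pooled.
* HWE uses an exact conditional test (tail-summed probabilities of
  heterozygote counts given the minor-allele count). The removal rule —
  rejection at α = 0.001 in more than half the populations typed for the
  SNP — is configurable; on clean data no SNP should trip it.
* Depth bounds (10×–30×) are inclusive: only strict violations are removed.
  The 30× ceiling is the usual 2×-average rule at ~15× mean depth.
* Replicate discordance per pair is mismatches over co-called sites; SNPs
  discordant in more than one pair are dropped for all individuals, then
  one member of each pair is retained — the one with more non-missing
  genotypes ("higher coverage").

# Statistics

Pairwise and global per-locus differentiation use the Weir–Cockerham (1984)
θ with the a/b/c variance components, combined across loci as a ratio of
averages ($\sum_l a_l / \sum_l (a_l+b_l+c_l)$); sites monomorphic across
the compared populations are skipped. Population-specific F~ST~ is the
Weir–Goudet matching-proportion β: within-population matching without
replacement versus the mean between-population matching, again as a ratio
of averages over loci. Expected heterozygosity is $2p(1-p)$ without
small-sample correction, while nucleotide diversity at variant sites
carries the $n/(n-1)$ correction — the same distinction the standard
RADseq toolchain reports. Private alleles are counted on non-missing calls
only; a population with no calls at a SNP counts as "absent" there.

Structure analyses: PCA mean-imputes missing dosages, centres columns and
takes the SVD, with axis signs fixed by the largest-magnitude loading.
Population trees use Prevosti distance (mean absolute allele-frequency
difference; Nei's standard distance is available) on complete-case SNPs,
neighbour joining via the canonical Saitou–Nei agglomeration, and locus
(column) bootstrap for bipartition support. Negative NJ branches are
clamped to zero with the deficit moved to the adjacent branches below the
node, preserving path lengths — the standard cosmetic fix; additive input
matrices are reconstructed exactly. AMOVA partitions squared-Euclidean
genotype distances over nested strata; expected-mean-square coefficients
for unbalanced designs are computed exactly as traces of the nested
quadratic forms against the block structure, and the method-of-moments
system is solved directly (degenerate levels are dropped with a zero
component). Components may be negative; percentages are of the raw total.
The admixture surrogate is a single-linkage merge of populations below a
pairwise-F~ST~ threshold.

# Genotype–environment association

Predictors are pruned greedily in priority order at |ρ| ≥ 0.7; ten
uncorrelated variables is the expected end state on real inputs. Missing
genotypes are imputed with the modal genotype (ties toward the lower
dosage). The RDA itself is ordinary least squares of centred dosages on
standardised predictors followed by an SVD of the fitted values; the
partial variant residualises both sides on conditioning covariates first.
Axis significance is a free permutation of predictor rows, compared
eigenvalue-by-eigenvalue (marginal scheme). Candidates are SNPs whose
loading on any significant axis lies beyond 3 SD of that axis's loading
distribution (union across axes; intersection available), each attributed
to the predictor with the largest absolute correlation. Annotation expands
BED features by ±1 kbp (genes) or ±100 kbp (QTLs), inclusive at the window
edge, with VCF positions overlapping $[s,e)$ iff $s < p \le e$.

# Genetic offset

The turnover model is a from-scratch regression-tree ensemble in the
gradient-forest tradition: per SNP, 250 trees on bootstrap samples of
lakes, `mtry = ceiling(v/3)` predictors per split, leaves of at least 2
rows, responses being the frequency of the SNP's globally minor allele
(one fold per SNP, so columns stay monotone transforms of the data).
Each split contributes its impurity reduction at the threshold location to
that predictor's importance profile, weighted by the SNP's forest
out-of-bag R²; SNPs with non-positive out-of-bag R² contribute nothing.
Profiles are accumulated in 50 equal bins over each predictor's observed
range (binning stabilises the step functions when lakes are few) and
integrated into non-decreasing cumulative-importance functions anchored at
zero at the range minimum. Climate vectors are mapped through these
functions (clamped beyond the fitted range) and a lake's genetic offset is
the Euclidean distance between its transformed current and future
climates — one score per lake, shared by sympatric ecotypes.

Two behaviours are worth understanding before interpreting offsets. First,
recursive partitioning concentrates impurity reduction where splitting is
most profitable, so even a perfectly linear allele-frequency response
yields a sigmoid cumulative function; offsets therefore reflect *local
turnover rate* as well as displacement size. The planted-shift ranking
test consequently applies displacements from a common reference climate, so
that ranking isolates displacement magnitude; across lakes at different
gradient positions, equal displacements legitimately produce unequal
offsets. Second, values beyond the fitted climate range clamp, so offsets
saturate for lakes pushed past the warmest fitted conditions.

# Vulnerability and conservation units

The lake-sensitivity score bins maximum depth (4 = shallowest), surface
area (3 = smallest) and altitude (4 = lowest) and sums them to a composite
between 3 (least concern) and 11 (highest). Bin boundaries are
lower-inclusive (e.g. 10–30 m means [10, 30)); the published bins do not
state edge behaviour, so the convention is documented and configurable in
code.

Unit delineation builds a merge graph over populations: an edge when lakes
lie within 20 km (haversine distance; river-network distance is not
available) *and* pairwise F~ST~ falls below a gene-flow threshold (default
0.05, the magnitude seen between a known source–refuge translocation
pair) — proximity alone never merges strongly differentiated lakes — or
when populations share an explicit translocation or shared-history link.
Connected components become units. A unit is an ESU when any member is a
diverged-ecotype population (including parapatric divergence members and
lakes known to hold unsampled ecotypes) or the sole extant population of
its Hydrometric Area; otherwise an MU. The bundled metadata for the 58
Scottish populations encodes these flags and the four stated merge groups,
and the engine reproduces the published classification exactly: 52 units,
29 ESUs (34 populations) and 23 MU units covering 24 populations.

```{r units}
units <- delineate_units(charr_unit_metadata())
summarize_units(units)
```

# Numerical choices and problem sizes

All randomness flows from one integer seed; per-stage substreams are
derived deterministically, so seeded runs are bit-reproducible. The test
suite runs the reference simulation at 2000 SNPs / 20 populations,
estimator oracles on ≤ 10-population toys, NJ property tests at ≤ 12 taxa,
and turnover fits at 24–40 lakes × 25–40 SNPs × 60–100 trees; these sizes
keep the full suite under a few minutes on one CPU while leaving every
statistical check comfortably powered.

# Known limitations

* The real study's headline numbers (24,878 SNPs; 1104 adaptive SNPs;
  offsets 0.005–0.028; K = 50 clusters) derive from raw sequence data that
  are out of scope here; the package reproduces rules, estimators and
  table-level results, not archive-scale values.
* The admixture surrogate is not a likelihood model; it exists so the
  pipeline can run end-to-end without an external clustering tool.
* Gradient-forest turnover functions are a reimplementation of the idea,
  not a numerical port of the reference R package; hyperparameters beyond
  the tree count are declared defaults.
* WorldClim-style predictors are air climate; nothing in the model checks
  how well they proxy in-lake conditions.
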