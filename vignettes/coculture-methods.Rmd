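---
title: "Models and methods behind coculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coculture)
```

This vignette is the package's own account of its science: the models
each stage assumes, the tunable parameters that matter, what the
synthetic-data generators do and do not emulate, the numerical choices,
and the design decisions taken where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The experimental design being modelled

The unit of analysis is the ordered pair "focal strain X grown 1 cm
from partner Y", written `X-Y`; `A-C` and `C-A` are the two colonies of
one plate. The default design is four strains in all 16 ordered
pairings (self-pairings included as the axenic baseline), sampled on
days 2–6 with 3 replicates for metabolomics and days 2–4 for RNA-seq;
colony images are taken at day 6 with n = 4. All generators and the
pipeline honour this labelling convention — the attribution stage's
contrasts are *defined* on it.

## RNA-seq deconvolution

**Model.** RNA from several samples, each from a different strain, is
pooled into one sequencing library. Because the strains' genomes are
distinguishable, reads can be re-assigned: each read is scored per
strain by the number of its k-mers (default k = 21) found in that
strain's genome, forward and reverse-complement orientations scored
separately and the larger taken. The read goes to the unique strain
with a strictly maximal score at or above 50% of its k-mers; ties are
`AMBIGUOUS` and discarded (the defining step of mapping against
concatenated genomes); sub-threshold reads are `UNMAPPED`. An upstream
filter removes reads whose k-mer content is ≥ 50% rRNA (both strands of
the rRNA set are indexed). Counting is by anchor overlap: the genome
position of the read's first matching k-mer must fall inside a gene's
interval; anchors covered by two overlapping genes go to the gene with
the smaller start (a deterministic tie-break), anchors in no gene to an
"intergenic" sink, so every read is accounted for
(`total = rRNA + assigned + ambiguous + unmapped + unclassifiable`).

Exact k-mer matching stands in for a full aligner deliberately: on
error-free synthetic reads it is a *provably* faithful implementation
of the discard-ambiguous contract, which is what the tests exercise. It
does not model sequencing error, indels or quality scores
(`error_rate` exists in the generator for robustness experiments, but
the assigner has no mismatch tolerance). Coordinates are 1-based
inclusive on input and internally converted where needed.

**Normalization.** Median-of-ratios size factors: per sample, the
median over genes of the ratio to the gene's geometric mean across
samples, skipping genes with any zero; genes never observed are dropped
first. When no gene is observed in every sample the function refuses and
points to `pseudo_reference = TRUE`, which takes the geometric mean over
positive counts only. TPM is the standard length-normalized quantity;
all-zero columns are returned as zeros and flagged rather than NaN.

**Differential expression.** A deliberately transparent negative
binomial GLM, *not* a DESeq2 reimplementation (explicitly out of scope):

* per-gene dispersion by method of moments on normalized counts about
  the group means, floored at the pooled (median) dispersion across
  genes — the floor prevents the catastrophic variance underestimates
  that a 3-replicate MoM estimate otherwise produces;
* size factors enter as offsets; `mode = "wald"` fits `~ group` and
  refers the Wald z to the standard normal; `mode = "lrt"` fits
  `~ partner + day + partner:day` against the reduced `~ day` and
  refers the deviance difference to a chi-square on the parameter
  difference;
* BH adjustment across tested genes; genes below a normalized base-mean
  floor (`min_base_mean`, default 1) keep their p-value but get
  `padj = NA` (a simple independent-filtering rule); zero-variance
  genes are excluded and flagged.

The acceptance suite verifies the calibration this design claims:
empirical type-I error on null NB data (3 vs 3, dispersion 0.05) within
the two-standard-error band of 0.05. No shrinkage means log2FC
estimates at low counts are noisier than DESeq2's — the planted-effect
test budgets ±0.3 log2 units at depth 500. For the LRT a single
`log2FC` column is still reported (the largest-magnitude
partner-related coefficient), as a ranking aid, not an effect estimate.

**Multiplex fidelity.** The design question "does pooling samples
change expression?" is answered operationally: build both arms from the
same per-sample reads (each sample's reads are generated under a child
seed, so the multiplexed library is exactly the concatenation), run the
full deconvolution on each, and compare — Pearson r on log normalized
counts, identity on unique genes, and the count of genes flagged DE
between arms. With no shared genes the arms are identical by
construction and the test demands exactly that; with shared genes both
arms lose the same reads to `AMBIGUOUS`.

## LC-MS preprocessing

The chain is fixed and logged in the table object:
`filter → group → drift → PQN → impute → glog → tests`. Missing values
are deliberately *not* imputed before drift correction or PQN — both
operate on observed cells only — because imputation belongs after
normalization in the stated order.

* **Feature filter.** Keep a feature iff observed in ≥ 2/3 of the
  replicates of at least one condition × day group *and* its mean
  biological intensity is ≥ 3× its mean blank intensity. The exact
  thresholds of the upstream peak-picking tool are not public, so both
  numbers are parameters.
* **Related-peak collapsing.** Single-linkage groups of features within
  a 5 s retention-time window whose profiles correlate ≥ 0.9
  (Pearson, pairwise-complete); the most intense member represents the
  group ("one peak per molecule"). Group membership is retained in the
  output metadata.
* **Drift/batch correction.** Per feature and batch, a smoother of log2
  QC intensity vs injection order (GCV cubic smoothing spline at ≥ 6
  usable QCs, else a linear fit); each injection is divided by the
  interpolated fit and rescaled to the feature's *grand* QC median.
  Rescaling to the grand rather than per-batch median is what removes
  step offsets between batches; a per-batch rescale would flatten
  drift but preserve the offset. Features with < 4 usable QCs in a
  batch pass through flagged.
* **PQN.** Reference spectrum = feature-wise median of QC injections
  (or of all samples); per sample, the dilution factor is the median
  quotient over shared features, and the sample is divided by it. One
  subtlety is deliberate: the reference is computed on
  *column-median-prescaled* intensities, making it invariant under
  per-sample dilution. That yields two exact properties — re-running
  PQN on its own output gives factors of 1 (idempotence), and
  multiplying any sample by a constant changes nothing after
  normalization (scale equivariance) — which plain PQN only satisfies
  approximately (its recomputed reference drifts, and the fixed point
  is approached only geometrically).
* **kNN imputation.** Missing `I[f, s]` = mean over the k = 5 nearest
  samples (Euclidean distance on co-observed features, normalized by
  their number) that observe f. The generator's missingness is
  intensity-dependent (probit on log intensity with a floor, calibrated
  to the requested overall rate), so imputation is non-trivially
  structured, as in real tables.
* **glog.** `g(x) = log2((x + sqrt(x^2 + λ))/2)`; λ = 0 is exactly
  log2. `λ = "auto"` minimizes the absolute slope of the SD-vs-mean
  trend across feature bins of the QC injections by a 1-D bounded
  search on log10 λ. With purely multiplicative (log-normal) noise the
  objective decreases towards small λ and the search returns its lower
  bound — correct behaviour, since log2 is then the ideal transform.

## Producer attribution (the dual contrast)

For "features produced by X in response to Y": per feature and day,
Welch two-sample t-tests on the glog scale compare `X-Y` with `X-X` and
`X-Y` with `Y-X`; fold changes are computed from pre-glog normalized
group means, because glog compresses large ratios and the 1.5 log2
threshold is only meaningful on the intensity scale. BH runs per
contrast per day across features (each day is an independent screen;
`bh_scope = "global"` pools days). Selection requires, for *each*
contrast, some day with `padj ≤ 0.05` and `log2FC ≥ +1.5` — an
increase only, since the target is induced production. Decisions taken
on genuinely open points:

* *Same day in both contrasts?* The source wording ("in at least one
  time point in each of the following two comparisons") is ambiguous;
  the default reads it literally (per contrast independently), and
  `strict_same_day = TRUE` provides the conservative reading.
* *Fold-change scale:* pre-glog normalized (see above); not stated in
  the source.
* *Decreases:* available behind `direction = "both"`, off by default.

The mirror contrast is the built-in control for diffusion: a compound
that has diffused across the plate is elevated in `X-Y` and `Y-X`
alike, its mirror log2FC is ~0, and it can never be selected — the
generator plants exactly this scenario (a constitutive, diffusible,
DFO-B-like ion from one strong producer at m/z 281.184) and the tests
assert it is rejected.

Positive- and negative-mode tables are processed independently and only
concatenated for reporting.

## Targeted annotation

A small adduct-mass matcher stands in for probabilistic annotation
(explicitly out of scope): monoisotopic masses from a built-in element
table; `[M+nH]n+` at `(M + n·1.0072765)/n`, `[M+Na]+` with the Na⁺ ion
mass (electron subtracted), `[M−H]−` analogously; results rounded
half-even to 3 decimals; features match a target within a ppm tolerance
and consistent polarity.

## Colony quantification

Grayscale conversion uses the Rec. 601 luma weights. Binarization is
Otsu by default (parameter-free and reproducible on the synthetic
fixtures; the source states only "a binary threshold"), with a fixed
threshold available; foreground polarity (colonies brighter vs darker
than agar) is a flag, default brighter. Connected components are
labelled with 8-connectivity by row-run union-find; per-component pixel
areas, centroids and bounding boxes are returned sorted by area. The
plate rim — a thin ring whose bounding-box fill ratio is far below a
disk's π/4 — is recognised by a fill-ratio cutoff (default 0.3),
excluded from the colony list, and reused to estimate the rim diameter
for the mm conversion `c = plate_mm / plate_px`, areas scaling with
`c²` exactly. Colonies grown into contact are separated by a
user-supplied vertical split at the inter-inoculum midline (the inocula
are 1 cm apart by design); watershed splitting is out of scope.
Discretization bias shrinks with radius; the suite asserts ≤ 2% area
error at r ≥ 20 px.

Statistics are all pairwise Welch t-tests among partner conditions with
BH across the pair family, plus a Tukey HSD mode on the one-way layout;
for well-separated effects the two agree on the significant set (an
asserted property). Well-scan grids (30 × 30 OD readings per well) are
summarised per well (mean/median/integrated) and joined to declared
concentrations into a dose table with a linear fit.

## Pathway enrichment

Hypergeometric upper tail `P(X ≥ k)` for overlap k between the query
and each pathway's K background genes, out of N background genes and a
query of size n, computed in log space via `lchoose` (no overflow at
large N). The background universe is the set of genes carrying a KO
annotation — the convention of KO-based over-representation tools — with
an all-annotated-genes option. Pathways with K < 10 are not tested;
BH across tested pathways; up- and down-regulated query sets are
analysed separately; queries are deduplicated. The suite checks the
tail against independent pmf summation to 1e-12, the N=4, K=2, n=2,
k=2 case against direct enumeration (1/6), and super-uniformity of the
discrete null at its achievable cutoffs.

## Synthetic data: what a green test establishes

The generators state the world the tests live in:

* Genomes are uniform random sequence with equal-length genes and one
  rRNA-like sequence embedded per strain; a `shared_fraction` of genes
  is copied byte-identically across strains to exercise the ambiguity
  discard. At k = 21 random cross-strain k-mer collisions are
  negligible, so with no shared genes every gene-body read is uniquely
  assignable — which is what makes the 100%-oracle criterion meaningful.
* Reads are uniform within gene bodies, error-free by default, Poisson
  per gene with expected count `depth · 2^lfc` under planted effects.
* Peak intensities are log-normal (σ = 0.2 on the log2 scale by
  default, the regime where the t-test calibration was designed);
  planted producer features add their log2 effect in the producing
  samples, and diffusible features also in the mirrored partner
  samples; QCs are pooled-mean replicates every 6th injection; blanks
  sit at a 2⁻⁶ offset; drift is multiplicative-linear in injection
  order; missingness is intensity-dependent with a floor, calibrated to
  the requested rate.
* Plate images are filled disks plus a rim ring and Gaussian noise.

None of this emulates chimeric reads, isotope envelopes, retention-time
warping, correlated feature noise, or real colony texture. A green
suite therefore establishes that the *procedures* implement their
contracts and recover truth under the stated noise model — not that the
thresholds are optimal for any particular instrument.

## Numerical choices and degenerate inputs

* BH is `stats::p.adjust(method = "BH")`, verified against a
  brute-force step-up implementation to 1e-12.
* Welch df uses the Satterthwaite formula; two constant equal groups
  return t = 0, p = 1 rather than NaN.
* Constant rows under Z-scoring return zeros and are flagged; zero-SD
  never divides.
* The hypergeometric tail sums in log space with a max-shift; `k = 0`
  returns exactly 1.
* Seeds: every generator takes a seed, restores the caller's RNG state,
  and derives per-sample child seeds below 2³¹, making multiplexing a
  true concatenation and the pipeline byte-deterministic (manifest
  hashes are asserted identical across reruns).
* Flat or empty images return empty contour lists; Otsu is undefined on
  a constant image and is guarded.

## Known limitations

* The NB test's MoM-with-floor dispersion is calibrated for type-I
  error but less efficient than shrinkage estimators; at 2–3 replicates
  its power is below DESeq2's.
* The k-mer assigner has no mismatch tolerance; real reads would need
  an error-tolerant mapper upstream.
* kNN imputation's sample-distance matrix is O(n²) in samples — fine at
  this design's scale (hundreds of injections), not for thousands.
* The plate-rim detector assumes a single dominant ring; decorated or
  cropped plates need an explicit `plate_diameter_px`.
* One replicate count per timepoint is assumed for metabolomics
  (triplicate, the stated default); the generator takes it as a
  parameter rather than hard-coding it.
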