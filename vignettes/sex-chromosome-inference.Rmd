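---
title: "Inferring sex chromosomes, inversions and early Y degeneration from male-female contrasts"
author: "sdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex chromosomes, inversions and early Y degeneration from male-female contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Young sex chromosomes look like ordinary autosomes: no depth loss, no
heteromorphy, little degeneration.  What betrays them is the *contrast
between the sexes*.  If males are heterogametic (XY), every male carries one
haplotype that never recombines over the sex-determination region (SDR) and
is absent from females.  Three signatures follow:

1. **Allele-frequency differentiation between the sexes.**  At a site fixed
   between X and Y, every male is heterozygous and every female homozygous
   reference, so male-female Fst is elevated in the SDR.
2. **Diversity excess in the heterogametic sex.**  X-Y fixed differences are
   permanent heterozygotes in males, so male nucleotide diversity rises where
   female diversity does not.  (Under ZW the mirror image holds.)
3. **Sex-specific sequence.**  k-mers spanning Y-specific alleles occur in
   (nearly) all males and no females.

`sdrscan` computes these three evidence tracks from a genotype matrix and
per-sample sequences, decides XY vs ZW vs none per chromosome, and
delineates the SDR as their intersection.  On top of that it detects and
genotypes polymorphic chromosomal inversions from linked-read barcode
sharing, classifies them as X-linked, Y-linked or autosomal, and quantifies
early Y degeneration (depth-ratio flags, fixed loss-of-function rules,
Nei-Gojobori dN/dS for X/Y gene pairs).

Every stage is testable without external data because the package ships a
seeded synthetic-cohort generator whose statistical structure is exactly the
structure the analysis assumes; truth sidecars make recovery checks exact.

## Estimators

### Site and windowed Fst

Three estimator families are provided because they genuinely disagree at the
configuration this analysis cares about most — a fully sex-linked SNP
(females 0/0, males 0/1, i.e. group frequencies 0 and 0.5):

* **Hudson plug-in**: `1 - Hw/Hb`, `Hw = p1(1-p1) + p2(1-p2)`,
  `Hb = p1(1-p2) + p2(1-p1)`.  Value at the sex-linked site: exactly
  **0.5**, for any sample sizes.  The corrected variant replaces each
  `p(1-p)` with its unbiased version `p(1-p)·n/(n-1)` and converges to 0.5
  from below.
* **Weir-Cockerham (1984)** variance components a/b/c, windowed as
  `sum(a)/sum(a+b+c)`.  We verified symbolically (and against an
  independently derived nested-ANOVA transcription, in the test suite) that
  at the fully sex-linked site this estimator also equals exactly **0.5 at
  every sample size**.  A folk claim puts its plateau at 1/3; that value
  actually belongs to the next family.
* **Nei-style pool estimator** `(Ht - Hs)/Ht` used for pool-seq read
  counts.  At pool frequencies 0 and 0.5: `Hs = 0.25`, `Ht = 0.375`, Fst
  = **1/3**.  This is the documented divergence between the estimator
  families: 0.5 (Hudson, W-C) vs 1/3 (Nei/pool).

The default windowed estimator is Weir-Cockerham, matching common
VCF-toolchain practice; Hudson is exposed for analytic checks.  Negative
window values are reported as-is.  Monomorphic sites drop out of the sums;
windows with no usable site are `NA`, never 0.

### Nucleotide diversity

Site diversity is the fraction of mismatching unordered allele pairs,
`2p(1-p)·n/(n-1)` for `n` non-missing alleles — identical to brute-force
pair counting, which the tests assert exactly.  Window diversity divides the
site sum by window *length* (not by site count), so monomorphic sequence
dilutes diversity as it should.

### Windows

All tracks use a sliding grid of 20 kb windows advanced by 10 kb (0-based,
half-open; configurable).  The barcode analysis uses non-overlapping 10 kb
tiles.

### Variant QC

The four-rule filter (sample mean coverage >= 6; site mean depth in
[4, 40]; site missingness <= 0.2; MAF >= 0.05) is applied in that order and
reports per-rule removal counts, making QC auditable.

## The synthetic world

The generator states a world once; tests measure recovery inside it.

* **Background variation**: biallelic sites placed by a Poisson process so
  that expected per-bp heterozygosity equals `theta` (default 0.002, a
  typical small-fish diversity).  Population frequencies are uniform on
  [0.05, 0.95] (a pragmatic spectrum: every site passes a 5% MAF filter, so
  filter effects can be tested separately); genotypes are drawn in
  Hardy-Weinberg, which a chi-square property test verifies.
* **SDR**: X-Y fixed differences at per-bp density `sdr_divergence`
  (default 0.005).  Every male is heterozygous at each such site, giving a
  male:female diversity ratio around `1 + 0.5·sdr_divergence/theta ≈ 2.2`
  — comfortably above the verdict threshold of 2 without being cartoonish.
* **Inversions**: orientations differ at density `theta·het_boost`
  (default `het_boost = 8`).  For an inversion a million generations old in
  a moderate-Ne fish, between-orientation divergence of several-fold the
  background diversity is realistic; 8 also keeps the male:female diversity
  ratio inside an almost-fixed X-linked inversion above 2, which is what
  the real data show.  Genotype composition per sex is either *fixed*
  (rounded frequency-by-count products — used by recovery tests so truth
  counts are exact integers) or *sampled*.
* **Linked reads**: one barcode = one molecule interval (molecule-level
  model; read-level artifacts are out of scope).  Molecules live on the
  sample's true haplotype, so on an inverted haplotype a molecule spanning
  a breakpoint covers two distal reference windows — the screening signal.
  Lengths are exponential (mean 50 kb) truncated at 10x the mean: the
  untruncated tail is astronomically unlikely at full scale but would leak
  past a shrunken distal threshold on desk-scale genomes.  Barcodes come
  from a finite per-sample pool (default 1e6), so occasional collisions
  produce the distance-independent background sharing a real null must
  absorb.
* **Desk scaling**: the bundled presets scale genome length, inversion
  intervals, molecule length and molecule count by a single factor, which
  preserves the geometry that matters (molecule length : tile : distal
  threshold, and molecule coverage per breakpoint).  The acceptance script
  runs the presets at full scale (20 Mb sex chromosome); the test suite at
  0.2-0.25.
* **Errors**: symmetric one-allele flips at `error_rate` (default 0.01 in
  the presets).  No sequencing-read simulation, no mapping artifacts, no
  repeats: a green test here establishes statistical correctness of the
  estimators and decision rules, not robustness to alignment pathology.
* **Crosses**: each offspring receives one unrecombined haplotype per
  parent, with obligate X-to-daughter / Y-to-son transmission.
  Recombination in the father outside the SDR (which in real crosses makes
  some autosomal-region SNPs look sex-linked) is deliberately off: the
  cross module's job is segregation-class logic, not linkage-map realism.

## Inversion screen

The screen scores *distal* window pairs (>= 500 kb apart at full scale) by
their summed shared-barcode count against a distance-decay null:
per log-spaced distance bin, the median and MAD-derived sigma of shared
counts **including the implicit zero pairs** that never materialize in a
sparse join, with sigma floored at `sqrt(max(mean, 0.25))` so bins whose
median is zero still yield finite z-scores.  Pairs with `z >= 5` are
single-linkage clustered (Chebyshev gap of 6 tiles, about one molecule
length); clusters need >= 3 pairs.  Breakpoints are shared-count-weighted
centroids of the left and right window groups — molecules crossing a
breakpoint populate windows symmetrically on both flanks, so the centroid
tracks the breakpoint to sub-window accuracy in practice.

Genotyping uses the heterozygous-site density inside the candidate,
normalized by flanking density (pseudocount 0.5 per region to keep sparse
flanks finite).  The ratios split by a deterministic two-means (centers
initialized at the extremes; threshold at the midpoint of the cluster
means); the upper cluster is called Ref/Inv only if its mean is at least
twice the lower mean, otherwise the cohort is all-homozygous.
SNP-density cannot distinguish Ref/Ref from Inv/Inv, so homozygotes are
polarized by majority junction support (molecules spanning the reference vs
the inverted junction); fewer than 3 junction molecules leaves the sample
`NA`.  Linkage classification then follows the segregation model: an
inversion confined to male heterozygotes is Y-linked; one homozygous in
females but never in males is X-linked; sex-independent genotype tables
(Fisher exact p > 0.05) are autosomal.

## Heterogamety verdicts

Per chromosome, windows whose Fst exceeds the 0.99 quantile of the *other*
chromosomes' windows are "elevated" (scale-free, robust to genome size; the
source analyses used no explicit threshold).  A chromosome is called only if
it has a run of >= 3 consecutive elevated windows — single-window spikes
are noise.  Within elevated windows the median male:female diversity ratio
decides: >= 2 is XY, <= 1/2 is ZW, otherwise none.  When cross markers are
supplied, their XY- vs ZW-consistent counts must agree with the verdict or
it is downgraded to none.  The marker classifier itself is a deterministic
rule set (father het + mother hom + sons het + daughters maternal-hom, up to
an error tolerance, and the sex mirror) standing in for probabilistic
EM-based tools, which the source analyses used only as corroborating counts.

## SDR delineation

Three flags per window: Fst elevated (quantile vs other chromosomes, as
above), male diversity excess (ratio >= 2), and male-specific k-mer density
(>= 1 per window when sequences are available).  The SDR is the longest run
where all flags hold, bridging gaps of at most one window (evidence tracks
are visually contiguous but window-noisy).  Note that inside a large
sex-linked inversion the Fst and diversity channels are legitimately
elevated beyond the SDR; it is the k-mer channel — driven only by fixed X-Y
differences — that trims the call back to the SDR, which is why the
pipeline treats k-mers as first-class evidence rather than decoration.

k-mer extraction is exact-match, canonical-strand, k = 40; "male-specific"
is read literally as presence in >= 90% of male samples (tolerating one
dropout) and 0% of female samples.

## Degeneration metrics

* **Depth ratio**: each sample's depth is normalized by its own
  autosome-wide median (making the ratio invariant to library size), then
  the male:female mean ratio is thresholded at **< 0.75** (strict); a gene
  deleted from the Y sits at 0.5.
* **Fixed LoF**: fixed-on-X iff female allele frequency > 0.9; fixed-on-Y
  iff male frequency > 0.45 *and* female frequency <= 0.05.  The 0.45
  threshold targets Y-fixed alleles, whose male-frequency ceiling is 0.5;
  the female co-condition is this package's choice — a genuinely Y-limited
  allele cannot segregate in females, and without the condition a common
  autosomal allele at frequency 0.5 would pass.
* **dN/dS**: Nei-Gojobori (1986) counting with pathway averaging for
  multi-hit codons (pathways through stop codons excluded; mutations *to*
  stop codons count as nonsynonymous in site counting) and Jukes-Cantor
  correction, undefined at mismatch fractions >= 3/4.  The ratio is
  reported missing when dS = 0 — the situation of a gene with only
  nonsynonymous X-Y differences, which genuinely occurs.  NG86 replaces
  likelihood-based codon models deliberately: it is closed-form and
  verifiable against exhaustive path enumeration at desk scale, which the
  tests do exactly.

## Numerical and design choices

* Coordinates are 0-based half-open internally; VCF emission converts to
  1-based.
* All randomness flows through seed-derived, stream-specific child seeds;
  equal (config, seed) gives byte-identical outputs, including FASTA and
  VCF files.  Seeds derived from the user's seed stay below 2^31.
* Two-means tie-break: centers initialized at min and max, so the split is
  deterministic and order-independent.
* The distal threshold scales with simulated genome length
  (`max(500 kb × L/20 Mb, 5 tiles)`) so desk-scale runs keep the same
  geometry.
* VCF reading uses `VariantAnnotation` when installed (with a minimal
  fallback parser for the package's own GT-only files); writing is a
  20-line text emitter under the package's control, which doubles as an
  independent route for round-trip tests.

## Known limitations

* The generator's uniform frequency spectrum is not a neutral SFS; rare
  variants are underrepresented.  Tests that depend on the spectrum shape
  (none of the acceptance checks do) should not lean on it.
* The barcode model has no per-read error, chimeric molecules, or mapping
  ambiguity; real linked-read data would add a noise floor the null would
  have to absorb.
* The SDR call inside a population fixed for a large sex-linked inversion
  extends over the whole inversion unless k-mer evidence is supplied (see
  above) — the same ambiguity the real analyses resolve with multi-source
  evidence.
* Cross simulation omits recombination, so cross-based marker counts are
  cleaner than real pool-seq crosses would be.
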