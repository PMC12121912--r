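# sdrscan

Sex-chromosome inference from male/female sequencing contrasts, for
population geneticists working on young or cryptic sex chromosome systems
(fish, amphibians, insects — anywhere the X and Y still look alike).

Given diploid genotypes, linked-read barcode maps, depth tracks and
haplotype sequences for a cohort of known-sex individuals, `sdrscan`:

* computes windowed male–female **Fst** (Weir–Cockerham, Hudson, and a
  Nei-style pool-seq estimator), per-sex **nucleotide diversity (π)**,
  **SNP density**, and normalized **male:female depth ratios**
  (20 kb windows, 10 kb step by default);
* decides **XY vs ZW vs none** per chromosome, and classifies cross markers
  by sex-linked segregation pattern;
* detects **chromosomal inversions** from excess barcode sharing between
  distal windows, genotypes every sample (Ref/Ref, Ref/Inv, Inv/Inv) from
  heterozygous-site density plus breakpoint-junction support, and
  classifies each inversion as X-linked, Y-linked or autosomal;
* delineates the **sex-determination region (SDR)** by intersecting
  elevated Fst, male π excess, and male-specific 40-mer density;
* quantifies early **Y degeneration**: genes with male:female depth ratio
  < 0.75, loss-of-function variants fixed on X (female AF > 0.9) or Y
  (male AF > 0.45, female AF ≈ 0), and Nei–Gojobori (1986) dN/dS for
  X/Y gene pairs.

A seeded synthetic-cohort generator (`sim_config()`, `sim_preset()`)
emulates the full data structure — XY SDR, polymorphic X- and Y-linked
inversions with configurable genotype-frequency tables, linked-read
molecules that respect inversion orientation, cross pools, depth and LoF
annotations — with truth sidecars, so the entire pipeline is testable
offline.

## The statistics in brief

At a fully sex-linked SNP (females 0/0, males 0/1) the Hudson plug-in Fst

    Fst = 1 − [p₁(1−p₁) + p₂(1−p₂)] / [p₁(1−p₂) + p₂(1−p₁)]

equals exactly **0.5**, as does Weir–Cockerham's a/(a+b+c) (we verify this
symbolically in the tests — it does *not* plateau at 1/3; that value
belongs to the Nei pool estimator (Ht−Hs)/Ht). Site π is the exact
pairwise-mismatch fraction `2p(1−p)·n/(n−1)`; window π divides by window
length. See the vignette (`vignettes/sex-chromosome-inference.Rmd`) for
the estimator derivations, the synthetic model, and every threshold with
its rationale.

## Worked example

Simulate a cohort with an almost-fixed X-linked inversion (20 females, 20
males, genotype composition fixed; 5 Mb sex chromosome at quarter scale)
and run the whole pipeline:

```r
library(sdrscan)
cfg <- sim_preset("CT", seed = 1, scale = 0.25)
bundle <- run_pipeline(pipeline_config(sim = cfg))
report(bundle)
```

```
== heterogamety ==
    chrom verdict region_start region_end
   <char>  <char>        <num>      <num>
1:   chr1      XY      1860000    3140000
2:   chr2    none           NA         NA

== SDR ==
chr1:1.87e+06-3.12e+06

== inversions ==
chr1:1.87528e+06-3.12551e+06  linkage: X-linked
                Ref/Ref Ref/Inv Inv/Inv
Female (n = 20)    0.00    0.15    0.85
Male (n = 20)      0.15    0.85    0.00
```

Reading the output: chromosome 1 is called XY (male-biased diversity inside
the elevated-Fst region), chromosome 2 is an ordinary autosome.  The
barcode screen found one inversion whose breakpoints (1.875–3.126 Mb)
match the simulated truth (1.875–3.125 Mb) to sub-window accuracy, and
per-sample genotyping recovered the configured genotype table exactly:
85% of females homozygous-inverted, 17/20 males heterozygous — the
signature of an X-linked inversion, which the classifier reports.
The SDR call spans the inversion because Fst and π are genuinely elevated
across it; adding the k-mer evidence channel (`emit_kmers = TRUE`, for
desk-scale genomes) trims the call to the true SDR.

A command-line driver with per-stage subcommands
(`simulate`, `windows`, `heterogamety`, `invscan`, `sdr`, `degen`, `all`)
is installed at `system.file("cli/sdrscan.R", package = "sdrscan")`.

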