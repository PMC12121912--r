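#' Specify a chromosomal inversion for simulation
#'
#' @param chrom chromosome name.
#' @param start,end inversion interval, 0-based half-open bp.
#' @param linkage `"X"`, `"Y"` or `"autosomal"`.  A Y-linked inversion is
#'   carried hemizygously on the Y haplotype of males only, so its carriers
#'   are always Ref/Inv heterozygotes.
#' @param geno_freq_female,geno_freq_male length-3 numeric vectors of
#'   genotype frequencies (Ref/Ref, Ref/Inv, Inv/Inv) per sex; each must sum
#'   to 1.  For Y-linked inversions the female row must be `c(1, 0, 0)` and
#'   the male Inv/Inv entry 0.
#' @param name label used in truth records and calls.
#' @return an `inversion_spec` list.
#' @export
inversion_spec <- function(chrom, start, end, linkage = c("X", "Y", "autosomal"),
                           geno_freq_female = c(1, 0, 0),
                           geno_freq_male = c(1, 0, 0),
                           name = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(end > start, length(geno_freq_female) == 3,
            length(geno_freq_male) == 3)
  if (abs(sum(geno_freq_female) - 1) > 1e-8 || abs(sum(geno_freq_male) - 1) > 1e-8)
    stop_cfg("inversion genotype frequencies must sum to 1 per sex")
  if (linkage == "Y") {
    if (any(geno_freq_female[2:3] > 0))
      stop_cfg("a Y-linked inversion cannot be carried by females")
    if (geno_freq_male[3] > 0)
      stop_cfg("a Y-linked inversion is hemizygous: male Inv/Inv is impossible")
  }
  if (linkage == "X" && geno_freq_male[3] > 0)
    stop_cfg("males carry one X: male Inv/Inv is impossible for an X-linked inversion")
  structure(list(chrom = chrom, start = round(as.double(start)),
                 end = round(as.double(end)),
                 linkage = linkage,
                 geno_freq = rbind(female = geno_freq_female,
                                   male = geno_freq_male),
                 name = name %||% sprintf("inv_%s_%g_%g", chrom, start, end)),
            class = "inversion_spec")
}

#' Configuration of the synthetic cohort generator
#'
#' Describes the genome, cohort, sex-determination region (SDR), inversions
#' and noise model of a simulated population.  Coordinates are 0-based
#' half-open throughout; the VCF writer converts to 1-based.
#'
#' @param n_chromosomes number of chromosomes; the SDR chromosome is one of
#'   them, the rest are autosomes.
#' @param chrom_length length of every chromosome in bp (single value or
#'   vector of `n_chromosomes`).
#' @param window_size,step sliding-window parameters in bp (defaults
#'   20,000 / 10,000).
#' @param sdr_chrom,sdr_start,sdr_end the true SDR interval; set
#'   `sdr_chrom = NA` for a fully autosomal genome.
#' @param heterogamety `"XY"` (males carry the sex-limited haplotype) or
#'   `"ZW"` (females do).
#' @param inversions list of [inversion_spec()] objects.
#' @param theta per-bp expected background heterozygosity.
#' @param het_boost multiplicative elevation of divergence between inverted
#'   and reference orientations inside an inversion (opposite orientations
#'   differ at density `theta * het_boost`, same orientation at `theta`).
#' @param sdr_divergence per-bp density of fixed X-Y differences inside the
#'   SDR (each such site is heterozygous in every male of an XY system).
#' @param n_females,n_males cohort composition.
#' @param composition `"fixed"` (genotype counts are the rounded
#'   frequency-by-count products, for exact truth-recovery tests) or
#'   `"sampled"` (multinomial draw per sex).
#' @param seed integer seed; equal (config, seed) gives byte-identical output.
#' @param error_rate per-genotype probability of flipping one allele.
#' @param depth_mean mean diploid read depth per sample.
#' @param depth_noise logical; `FALSE` makes depth tracks exactly equal their
#'   expectation (used by noise-free oracle tests).
#' @param barcode_molecules_per_sample number of linked-read molecules drawn
#'   per sample.
#' @param molecule_length_mean mean molecule length in bp (exponential).
#' @param barcode_pool_size number of distinct barcodes per sample; two
#'   molecules can collide on a barcode, which creates the distance-independent
#'   background sharing the detection null has to absorb.
#' @param population population label written to the sample table.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 5e6,
                       window_size = 20000,
                       step = 10000,
                       sdr_chrom = "chr1",
                       sdr_start = 1.5e6,
                       sdr_end = 2.2e6,
                       heterogamety = c("XY", "ZW"),
                       inversions = list(),
                       theta = 0.002,
                       het_boost = 8,
                       sdr_divergence = 0.005,
                       n_females = 20,
                       n_males = 20,
                       composition = c("fixed", "sampled"),
                       seed = 1,
                       error_rate = 0,
                       depth_mean = 20,
                       depth_noise = TRUE,
                       barcode_molecules_per_sample = 10000,
                       molecule_length_mean = 50000,
                       barcode_pool_size = 1e6,
                       population = "SIM") {
  heterogamety <- match.arg(heterogamety)
  composition <- match.arg(composition)
  chrom_length <- round(rep_len(as.double(chrom_length), n_chromosomes))
  chroms <- paste0("chr", seq_len(n_chromosomes))
  names(chrom_length) <- chroms
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              chroms = chroms, window_size = as.double(window_size),
              step = as.double(step), sdr_chrom = sdr_chrom,
              sdr_start = round(as.double(sdr_start)),
              sdr_end = round(as.double(sdr_end)),
              heterogamety = heterogamety, inversions = inversions,
              theta = theta, het_boost = het_boost,
              sdr_divergence = sdr_divergence,
              n_females = n_females, n_males = n_males,
              composition = composition, seed = seed, error_rate = error_rate,
              depth_mean = depth_mean, depth_noise = depth_noise,
              barcode_molecules_per_sample = barcode_molecules_per_sample,
              molecule_length_mean = molecule_length_mean,
              barcode_pool_size = barcode_pool_size, population = population)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$step <= 0 || cfg$step > cfg$window_size)
    stop_cfg("need 0 < step <= window_size")
  if (cfg$theta < 0 || cfg$theta >= 1) stop_cfg("theta must be in [0, 1)")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop_cfg("error_rate must be in [0, 1)")
  if (!is.na(cfg$sdr_chrom)) {
    if (!cfg$sdr_chrom %in% cfg$chroms)
      stop_cfg("sdr_chrom '%s' is not a simulated chromosome", cfg$sdr_chrom)
    if (cfg$sdr_start < 0 || cfg$sdr_end > cfg$chrom_length[[cfg$sdr_chrom]] ||
        cfg$sdr_end <= cfg$sdr_start)
      stop_cfg("sdr interval outside its chromosome")
  }
  if (cfg$molecule_length_mean >= min(cfg$chrom_length))
    stop_cfg("molecule_length_mean must be shorter than every chromosome")
  for (iv in cfg$inversions) {
    if (!iv$chrom %in% cfg$chroms)
      stop_cfg("inversion chromosome '%s' not simulated", iv$chrom)
    if (iv$start < 0 || iv$end > cfg$chrom_length[[iv$chrom]])
      stop_cfg("inversion %s outside its chromosome", iv$name)
  }
  ## overlapping inversions on the same haplotype class are not representable
  if (length(cfg$inversions) > 1) {
    ivs <- cfg$inversions
    for (i in seq_along(ivs)) for (j in seq_len(i - 1)) {
      a <- ivs[[i]]; b <- ivs[[j]]
      same_class <- a$linkage == b$linkage ||
        all(c(a$linkage, b$linkage) %in% c("X", "autosomal")) # X lives beside autosomal haps in females
      if (a$chrom == b$chrom && same_class &&
          a$start < b$end && b$start < a$end)
        stop_cfg("inversions %s and %s overlap on the same haplotype class",
                 a$name, b$name)
    }
  }
  invisible(cfg)
}

#' Bundled simulation presets
#'
#' Three cohorts covering the analysis paths: `"CT"` (an almost-fixed
#' X-linked inversion segregating in both sexes, 20 females / 20 males),
#' `"NS"` (a male-limited Y-specific inversion, 15 females / 14 males), and
#' `"autosomal"` (no SDR, no inversion; the negative control).  Genotype
#' composition is fixed, so realized counts equal the rounded
#' frequency-by-count products (CT females 0/3/17 RR/RI/II, CT males 3/17/0,
#' NS males 1/13/0).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param scale genome scale factor; 1 is a 20 Mb sex chromosome plus a 4 Mb
#'   autosome.  Lengths, the SDR and inversion intervals scale linearly;
#'   tests use smaller scales to stay fast.
#' @param error_rate per-genotype allele flip probability.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("CT", "NS", "autosomal"), seed = 1,
                       scale = 1, error_rate = 0.01) {
  name <- match.arg(name)
  s <- function(x) x * scale
  ## the linked-read geometry scales with the genome so that the ratio of
  ## molecule length to the distal threshold (and molecule coverage) is
  ## preserved at desk scale
  common <- list(n_chromosomes = 2, chrom_length = c(s(20e6), s(4e6)),
                 sdr_chrom = "chr1", sdr_start = s(7.5e6), sdr_end = s(8.21e6),
                 molecule_length_mean = s(50000),
                 barcode_molecules_per_sample = max(2000, round(s(10000))),
                 seed = seed, error_rate = error_rate, composition = "fixed")
  cfg <- switch(name,
    CT = c(common, list(
      n_females = 20, n_males = 20, population = "CT",
      inversions = list(inversion_spec(
        "chr1", s(7.5e6), s(12.5e6), linkage = "X",
        geno_freq_female = c(0, 0.15, 0.85),
        geno_freq_male = c(0.15, 0.85, 0), name = "invX")))),
    NS = c(common, list(
      n_females = 15, n_males = 14, population = "NS",
      inversions = list(inversion_spec(
        "chr1", s(4.72e6), s(12.44e6), linkage = "Y",
        geno_freq_female = c(1, 0, 0),
        geno_freq_male = c(0.07, 0.93, 0), name = "invY")))),
    autosomal = utils::modifyList(c(common, list(
      n_females = 20, n_males = 20, population = "AUTO")),
      list(sdr_chrom = NA))
  )
  do.call(sim_config, cfg)
}
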