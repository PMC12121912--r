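## Shared fixtures are generated in code and cached per test run.  Preset
## runs use scale 0.25 (a 5 Mb sex chromosome + 1 Mb autosome): large enough
## that every signal the analysis keys on is present, small enough that the
## whole suite stays fast.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

## population + barcodes + windows for a preset at test scale
preset_run <- function(name, seed = 1, scale = 0.25, error_rate = 0.01) {
  key <- sprintf("%s_%d_%g_%g", name, seed, scale, error_rate)
  cached(key, {
    cfg <- sim_preset(name, seed = seed, scale = scale,
                      error_rate = error_rate)
    pop <- simulate_population(cfg)
    bc <- simulate_barcode_maps(pop$gm, pop$truth, cfg)
    windows <- make_windows(cfg$chrom_length, cfg$window_size, cfg$step)
    list(cfg = cfg, gm = pop$gm, truth = pop$truth,
         barcode_map = bc$barcode_map, junctions = bc$junctions,
         windows = windows)
  })
}

## distal threshold scaled the same way run_pipeline scales it
scaled_distal <- function(cfg) {
  max(500000 * max(cfg$chrom_length) / 20e6, 5 * cfg$step)
}

run_inversion_scan <- function(run, z_min = 5, min_pair_cluster = 3) {
  sm <- build_sharing_matrix(run$barcode_map, tile = run$cfg$step,
                             distal_min = scaled_distal(run$cfg))
  null <- distance_decay_null(sm)
  cands <- detect_inversion_candidates(sm, null, z_min = z_min,
                                       min_pair_cluster = min_pair_cluster)
  list(sm = sm, null = null, cands = cands)
}

## tiny multi-chromosome config without inversions, for SDR / verdict tests
small_sdr_config <- function(seed, sdr_chrom = "chr1", heterogamety = "XY",
                             n = 6, chrom_length = 6e5, n_chromosomes = 2) {
  sim_config(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
             sdr_chrom = sdr_chrom,
             sdr_start = round(chrom_length / 3),
             sdr_end = round(chrom_length * 7 / 15),
             heterogamety = heterogamety,
             n_females = n, n_males = n, seed = seed, error_rate = 0,
             barcode_molecules_per_sample = 2000,
             molecule_length_mean = min(10000, chrom_length / 10))
}

## brute-force pairwise-mismatch nucleotide diversity for one site
brute_pi_site <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  mism <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    mism <- mism + (alleles[i] != alleles[j])
  mism / choose(n, 2)
}

## expand a dosage vector into alleles (0/1), NA dropped
dosage_to_alleles <- function(g) {
  g <- g[!is.na(g)]
  unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
}
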