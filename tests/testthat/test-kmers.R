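## brute-force oracle: set algebra over all substrings
brute_specific <- function(target, other, k) {
  canon <- function(s) {
    subs <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- sapply(strsplit(chartr("ACGT", "TGCA", subs), ""),
                 function(v) paste(rev(v), collapse = ""))
    unique(pmin(subs, rc))
  }
  t_sets <- lapply(target, canon)
  o_all <- unique(unlist(lapply(other, canon)))
  shared <- Reduce(intersect, t_sets)
  sort(setdiff(shared, o_all))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("sex-specific k-mer extraction equals brute-force set algebra", {
  set.seed(55)
  ## males share a 60 bp tract absent in females: 60 - 40 + 1 = 21 k-mers
  tract <- rand_dna(60)
  males <- lapply(1:3, function(i) paste0(rand_dna(100), tract, rand_dna(100)))
  females <- lapply(1:3, function(i) rand_dna(260))
  got <- sex_specific_kmers(as.list(males), as.list(females), k = 40,
                            min_presence = 1)
  oracle <- brute_specific(males, females, 40)
  expect_equal(got, oracle)
  expect_equal(length(got), 21)

  ## identical male and female sets: empty
  expect_length(sex_specific_kmers(as.list(males), as.list(males), k = 40),
                0)

  ## reverse-complementing every female sequence changes nothing
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  got_rc <- sex_specific_kmers(as.list(males), lapply(females, rc), k = 40,
                               min_presence = 1)
  expect_equal(got_rc, got)

  ## random sequence pairs: exact agreement with the oracle
  for (i in 1:5) {
    m2 <- lapply(1:2, function(.) rand_dna(80))
    f2 <- lapply(1:2, function(.) rand_dna(80))
    expect_equal(sex_specific_kmers(m2, f2, k = 11, min_presence = 1),
                 brute_specific(m2, f2, 11))
  }

  expect_error(sex_specific_kmers(list("ACGT"), list("ACGTACGT"), k = 6),
               "shortest")
})

test_that("k-mer density counts match positions and sum to the total", {
  set.seed(56)
  target <- rand_dna(50000)
  kmers <- canonical <- sex_specific_kmers(
    list(substr(target, 10001, 10400)), list(rand_dna(500)), k = 40,
    min_presence = 1)
  w <- make_windows(c(t = 50000), 10000, 10000)
  w$chrom <- "t"
  kd <- kmer_density(kmers, target, w)
  ## all matches fall in the window containing 10000..10400
  expect_equal(kd[start == 10000, density], length(10001:10361))
  expect_equal(sum(kd$density), 361)
  ## no matches: all zero
  kd0 <- kmer_density(character(), target, w)
  expect_true(all(kd0$density == 0))
})

test_that("simulated Y k-mer density peaks over the true SDR", {
  cfg <- small_sdr_config(seed = 42, n = 4, chrom_length = 3e5)
  pop <- simulate_population(cfg)
  seqs <- emit_sequences(pop$truth, cfg)
  nm <- names(seqs)
  per_sample <- function(ids)
    setNames(lapply(ids, function(s)
      as.character(seqs[grepl(paste0("^", s, "_hap"), nm)])), ids)
  males <- pop$gm$samples$sample[pop$gm$samples$sex == "M"]
  females <- pop$gm$samples$sample[pop$gm$samples$sex == "F"]
  mk <- sex_specific_kmers(per_sample(males), per_sample(females), k = 40)
  expect_gt(length(mk), 100)
  w <- make_windows(cfg$chrom_length, cfg$window_size,
                    cfg$step)[chrom == "chr1"]
  kd <- kmer_density(mk, as.character(seqs[["ref_chr1_Y"]]), w)
  peak <- kd[which.max(density)]
  expect_true(peak$start >= cfg$sdr_start - cfg$window_size &
                peak$end <= cfg$sdr_end + cfg$window_size)
  ## female haplotypes contain no Y-derived tract: no male-specific k-mer
  ## occurs in any female sequence
  fem_seq <- unlist(per_sample(females))
  expect_false(any(vapply(mk[1:20], function(km)
    any(grepl(km, fem_seq, fixed = TRUE)), logical(1))))
})

test_that("emitted FASTA round-trips", {
  cfg <- small_sdr_config(seed = 43, n = 2, chrom_length = 5e4)
  pop <- simulate_population(cfg)
  fa <- tempfile(fileext = ".fa")
  seqs <- emit_sequences(pop$truth, cfg, fasta = fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back), as.character(seqs))
  ## identical seed, identical bytes
  fa2 <- tempfile(fileext = ".fa")
  emit_sequences(pop$truth, cfg, fasta = fa2)
  expect_identical(readLines(fa), readLines(fa2))
  unlink(c(fa, fa2))
})
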