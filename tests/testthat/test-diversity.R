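test_that("windowed pi equals brute-force pair counting", {
  ## closed-form example: 8 alleles, 4 alt -> 16/28 mismatching pairs
  g <- c(2L, 2L, 0L, 0L)           # 4 diploids = 8 alleles, 4 alt
  expect_equal(brute_pi_site(dosage_to_alleles(g)), 16 / 28)
  gm1 <- genotype_matrix(matrix(g, nrow = 1),
                         data.frame(chrom = "c", pos = 10),
                         data.frame(sample = paste0("s", 1:4),
                                    sex = c("F", "F", "M", "M")))
  w1 <- make_windows(c(c = 100), 100, 100)
  expect_equal(windowed_pi(gm1, w1)$pi, (16 / 28) / 100)

  ## random windows: exact equality with brute force
  run <- preset_run("CT", seed = 1)
  set.seed(33)
  males <- run$gm$samples$sample[run$gm$samples$sex == "M"]
  mmask <- run$gm$samples$sample %in% males
  tr <- windowed_pi(run$gm, run$windows, males)
  picks <- sample(which(tr$n_sites_used > 0), 100)
  for (k in picks) {
    wrow <- tr[k]
    idx <- which(run$gm$sites$chrom == wrow$chrom &
                   run$gm$sites$pos >= wrow$start &
                   run$gm$sites$pos < wrow$end)
    bp <- sum(vapply(idx, function(i)
      brute_pi_site(dosage_to_alleles(run$gm$geno[i, mmask])), numeric(1)),
      na.rm = TRUE)
    expect_equal(wrow$pi, bp / (wrow$end - wrow$start), tolerance = 1e-12)
  }

  ## identical haplotypes: zero
  gm0 <- genotype_matrix(matrix(2L, 3, 4),
                         data.frame(chrom = "c", pos = c(1, 5, 9)),
                         data.frame(sample = paste0("s", 1:4),
                                    sex = c("F", "F", "M", "M")))
  expect_equal(windowed_pi(gm0, w1)$pi, 0)
})

test_that("male diversity exceeds female diversity inside the SDR", {
  run <- preset_run("NS", seed = 1)
  m <- windowed_pi(run$gm, run$windows,
                   run$gm$samples$sample[run$gm$samples$sex == "M"])
  f <- windowed_pi(run$gm, run$windows,
                   run$gm$samples$sample[run$gm$samples$sex == "F"])
  sdr <- m$chrom == run$cfg$sdr_chrom & m$start >= run$cfg$sdr_start &
    m$end <= run$cfg$sdr_end
  expect_true(all(m$pi[sdr] > f$pi[sdr]))
  expect_gt(median(m$pi[sdr] / f$pi[sdr]), 2)
})

test_that("SNP density contrasts inversion genotype groups", {
  run <- preset_run("CT", seed = 1)
  g <- run$truth$inversion_genotypes$invX
  het <- run$gm$samples$sample[g == 1]
  dh <- snp_density(run$gm, run$windows, het)
  iv <- run$cfg$inversions[[1]]
  inside <- dh$chrom == iv$chrom & dh$start >= iv$start & dh$end <= iv$end
  ## heterozygotes beat each homozygous orientation class (a mixed RR+II
  ## group would itself segregate at orientation-diagnostic sites)
  for (hom_class in c(0, 2)) {
    hom <- run$gm$samples$sample[g == hom_class]
    dm <- snp_density(run$gm, run$windows, hom)
    expect_gt(mean(dh$density[inside]), 2 * mean(dm$density[inside]))
  }
  ## outside the inversion the groups agree (sample-size permitting)
  hom_all <- run$gm$samples$sample[g == 2]
  dm2 <- snp_density(run$gm, run$windows, hom_all)
  outside <- dh$chrom == "chr2"
  expect_lt(abs(mean(dh$density[outside]) / mean(dm2$density[outside]) - 1),
            0.25)
  ## no variants -> zero everywhere
  gm0 <- genotype_matrix(matrix(integer(), 0, nrow(run$gm$samples)),
                         run$gm$sites[0], run$gm$samples)
  expect_true(all(snp_density(gm0, run$windows)$density == 0))
  ## overlapping windows double-count: column sums exceed the site count
  expect_gte(sum(dh$density), dh[, sum(density[start %% 20000 == 0])])
  expect_error(snp_density(run$gm, run$windows, character(0)), "empty")
})

test_that("depth ratio is normalized and flags hemizygous loss", {
  run <- preset_run("CT", seed = 1, error_rate = 0)
  cfg <- run$cfg
  cfg$depth_noise <- FALSE
  genes <- data.frame(
    gene = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(cfg$sdr_start + 1e4, cfg$sdr_start + 5e4, 1e5),
    end = c(cfg$sdr_start + 2e4, cfg$sdr_start + 6e4, 1.2e5),
    deleted_on_y = c(TRUE, FALSE, FALSE))
  dl <- simulate_depth_and_lof(run$gm, run$truth, genes, cfg)
  dr <- depth_ratio(dl$gene_depth, run$gm$samples, norm_exclude = "gA")
  expect_equal(dr[gene == "gA", ratio], 0.5)
  expect_equal(dr[gene == "gB", ratio], 1)
  expect_equal(dr[gene == "gC", ratio], 1)

  ## doubling male raw depth leaves ratios unchanged
  gd2 <- data.table::copy(dl$gene_depth)
  males <- run$gm$samples$sample[run$gm$samples$sex == "M"]
  gd2[sample %in% males, depth := depth * 2]
  dr2 <- depth_ratio(gd2, run$gm$samples, norm_exclude = "gA")
  expect_equal(dr2$ratio, dr$ratio)

  ## Y-origin LoF: male allele frequency at most 0.5
  lofY <- dl$lof[origin == "Y"]
  expect_equal(nrow(lofY), 3)
  idx <- which(paste(run$gm$sites$chrom, run$gm$sites$pos) %in%
                 paste(lofY$chrom, lofY$pos))
  mmask <- run$gm$samples$sex == "M"
  af_m <- rowMeans(run$gm$geno[idx, mmask]) / 2
  expect_true(all(af_m <= 0.5))

  expect_error(simulate_depth_and_lof(
    run$gm, run$truth,
    data.frame(gene = "gX", chrom = "chr9", start = 1, end = 10), cfg),
    "outside")
})

test_that("windowed depth ratio integrates into the track set", {
  run <- preset_run("CT", seed = 1, error_rate = 0)
  cfg <- run$cfg; cfg$depth_noise <- FALSE
  dl <- simulate_depth_and_lof(run$gm, run$truth, data.frame(
    gene = "g", chrom = "chr2", start = 1, end = 100), cfg)
  tr <- compute_window_stats(run$gm, run$windows,
                             window_depth = dl$window_depth,
                             sex_chrom = "chr1")
  expect_true("mf_depth_ratio" %in% names(tr))
  ## no deletions anywhere: ratio 1 on both chromosomes
  expect_equal(unique(tr$mf_depth_ratio), 1)
})

test_that("the four QC rules remove exactly the engineered subsets", {
  ## 10-site toy matrix with known casualties per rule
  samples <- data.frame(sample = paste0("s", 1:6),
                        sex = rep(c("F", "M"), 3))
  geno <- matrix(1L, nrow = 10, ncol = 6,
                 dimnames = list(NULL, samples$sample))
  geno[1, ] <- c(0L, 0L, 0L, 0L, 0L, 1L)       # maf 1/12 >= 0.05, survives
  geno[2, ] <- 0L                              # monomorphic: rule 4
  geno[3, 1:3] <- NA                           # missingness: rule 3
  geno[4, ] <- c(0L, 2L, 1L, 1L, 0L, 2L)
  sites <- data.frame(chrom = "c", pos = 1:10)
  site_depth <- rep(10, 10)
  site_depth[5] <- 41                          # rule 2 (too high)
  site_depth[6] <- 3.9                         # rule 2 (too low)
  sample_cov <- setNames(c(5.9, rep(20, 5)), samples$sample) # s1: rule 1
  gm <- genotype_matrix(geno, sites, samples)
  res <- variant_qc_filter(gm, sample_cov, site_depth)
  expect_equal(res$report$removed, c(1, 2, 1, 1))
  ## hand enumeration: 10 sites - 2 (depth) - 1 (missingness, site 3 keeps
  ## 2 NAs of 5 after s1 leaves) - 1 (monomorphic site 2) = 6 survive
  expect_equal(nrow(res$gm$geno), 6)
  expect_equal(ncol(res$gm$geno), 5)
  expect_false("s1" %in% res$gm$samples$sample)
  expect_false(any(c(2, 3, 5, 6) %in% res$gm$sites$pos))
  expect_error(variant_qc_filter(gm, sample_cov, site_depth,
                                 min_sample_cov = -1), "positive")
})
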