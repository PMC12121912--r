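test_that("cross segregation follows obligate sex-chromosome transmission", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length = 2e6, sdr_chrom = "chr1",
    sdr_start = 4e5, sdr_end = 6e5, seed = 12, error_rate = 0,
    inversions = list(inversion_spec("chr1", 4e5, 1.4e6, "X",
                                     geno_freq_female = c(0, 0, 1),
                                     geno_freq_male = c(0, 1, 0),
                                     name = "invX")))
  ## mother Inv/Inv, father X-inv / Y-ref: all daughters II, all sons RI
  cross <- cross_config(mother_hap1 = c(invX = TRUE),
                        mother_hap2 = c(invX = TRUE),
                        father_hapX = c(invX = TRUE),
                        father_hapY = c(invX = FALSE),
                        n_sons = 15, n_daughters = 15, pool_depth = 40)
  cp <- simulate_cross_pools(cross, cfg)
  g <- cp$truth$inversion_genotypes$invX
  expect_true(all(g[cp$truth$sex == "F"] == 2))
  expect_true(all(g[cp$truth$sex == "M"] == 1))

  ## Mendelian conservation: every offspring dosage is a sum of one
  ## maternal and the sex-appropriate paternal haplotype; Y-limited SDR
  ## alleles appear in sons only
  sdr_sites <- cp$sites$class_ == "sdr"
  sons <- cp$truth$sex == "M"
  expect_true(all(cp$geno[sdr_sites, sons] >= 1))
  expect_true(all(cp$geno[sdr_sites, !sons] <= 1)) # daughters never get Y

  ## pool frequencies: daughter pool has zero alt reads at Y-limited sites
  ## where the mother is ref (all SDR fixed differences)
  dp <- cp$pools[pool == "daughters"]
  sp <- cp$pools[pool == "sons"]
  sdr_pos <- cp$sites[sdr_sites, pos]
  expect_true(all(dp[pos %in% sdr_pos, alt_reads] == 0))
  ## son pool alt frequency near 0.5
  sfrac <- sp[pos %in% sdr_pos, sum(alt_reads) / sum(alt_reads + ref_reads)]
  expect_lt(abs(sfrac - 0.5), 0.05)
})

test_that("a heterozygous mother transmits the inversion to both sexes", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length = 1e6, sdr_chrom = "chr1",
    sdr_start = 1e5, sdr_end = 2e5, seed = 13, error_rate = 0,
    inversions = list(inversion_spec("chr1", 3e5, 9e5, "X",
                                     geno_freq_female = c(0, 1, 0),
                                     geno_freq_male = c(1, 0, 0),
                                     name = "invX")))
  cross <- cross_config(mother_hap1 = c(invX = TRUE),
                        n_sons = 400, n_daughters = 400, pool_depth = 30)
  cp <- simulate_cross_pools(cross, cfg)
  g <- cp$truth$inversion_genotypes$invX
  f_sons <- mean(g[cp$truth$sex == "M"] == 1)
  f_dau <- mean(g[cp$truth$sex == "F"] == 1)
  ## both sexes inherit at 50%; 3 binomial SEs
  se <- sqrt(0.25 / 400)
  expect_lt(abs(f_sons - 0.5), 3 * se)
  expect_lt(abs(f_dau - 0.5), 3 * se)
})

test_that("cross configuration is validated", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5e5,
                    sdr_chrom = "chr1", sdr_start = 1e5, sdr_end = 2e5,
                    seed = 1,
                    inversions = list(inversion_spec(
                      "chr1", 2e5, 4e5, "Y",
                      geno_freq_male = c(0.5, 0.5, 0), name = "invY")))
  expect_error(cross_config(n_sons = 0, n_daughters = 0), "offspring")
  bad <- cross_config(mother_hap1 = c(invY = TRUE), n_sons = 5,
                      n_daughters = 5)
  expect_error(simulate_cross_pools(bad, cfg), "non-Y")
  ## father's Y may carry it: sons 100% RI, daughters 100% RR
  ok <- cross_config(father_hapY = c(invY = TRUE), n_sons = 8,
                     n_daughters = 8)
  cp <- simulate_cross_pools(ok, cfg)
  g <- cp$truth$inversion_genotypes$invY
  expect_true(all(g[cp$truth$sex == "M"] == 1))
  expect_true(all(g[cp$truth$sex == "F"] == 0))
})

test_that("cross inversion patterns are predicted correctly", {
  p1 <- predict_cross_inversion_pattern(cross_config(
    mother_hap1 = c(inv = TRUE), mother_hap2 = c(inv = TRUE),
    father_hapX = c(inv = TRUE), father_hapY = c(inv = FALSE)))
  expect_equal(unname(p1$daughters["II"]), 1)
  expect_equal(unname(p1$sons["RI"]), 1)
  expect_equal(p1$differentiation, "sex-differentiated")
  expect_equal(p1$diversity, "male-diverse")

  p2 <- predict_cross_inversion_pattern(cross_config(
    mother_hap1 = c(inv = TRUE)))
  expect_equal(unname(p2$sons["RI"]), 0.5)
  expect_equal(unname(p2$daughters["RI"]), 0.5)
  expect_equal(p2$differentiation, "undifferentiated")
  expect_equal(p2$diversity, "both")

  p3 <- predict_cross_inversion_pattern(cross_config(
    father_hapY = c(inv = TRUE)))
  expect_equal(unname(p3$sons["RI"]), 1)
  expect_equal(unname(p3$daughters["RR"]), 1)
})
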