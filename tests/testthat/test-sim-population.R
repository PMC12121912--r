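test_that("simulation is deterministic and respects the configured world", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 3e5, sdr_chrom = "chr1",
                    sdr_start = 1e5, sdr_end = 1.5e5, n_females = 6,
                    n_males = 6, seed = 7, error_rate = 0)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$gm$geno, b$gm$geno)
  expect_identical(a$truth$hap_alleles, b$truth$hap_alleles)

  ## different seed changes the realization
  cfg2 <- sim_config(n_chromosomes = 2, chrom_length = 3e5,
                     sdr_chrom = "chr1", sdr_start = 1e5, sdr_end = 1.5e5,
                     n_females = 6, n_males = 6, seed = 8, error_rate = 0)
  c2 <- simulate_population(cfg2)
  expect_false(identical(dim(a$gm$geno), dim(c2$gm$geno)) &&
                 identical(a$gm$geno, c2$gm$geno))

  ## every male heterozygous at every SDR fixed-difference site (pre-error)
  sdr_idx <- which(a$gm$sites$class_ == "sdr")
  males <- a$gm$samples$sex == "M"
  females <- a$gm$samples$sex == "F"
  expect_true(length(sdr_idx) > 50)
  expect_true(all(a$gm$geno[sdr_idx, males] == 1L))
  expect_true(all(a$gm$geno[sdr_idx, females] == 0L))
})

test_that("fixed composition reproduces the configured genotype counts", {
  run <- preset_run("CT", seed = 1)
  g <- run$truth$inversion_genotypes$invX
  sex <- run$truth$samples$sex
  expect_equal(unname(table(factor(g[sex == "F"], levels = 0:2))),
               c(0L, 3L, 17L), ignore_attr = TRUE)
  expect_equal(unname(table(factor(g[sex == "M"], levels = 0:2))),
               c(3L, 17L, 0L), ignore_attr = TRUE)
  ns <- preset_run("NS", seed = 1)
  gy <- ns$truth$inversion_genotypes$invY
  sexy <- ns$truth$samples$sex
  expect_equal(unname(table(factor(gy[sexy == "M"], levels = 0:2))),
               c(1L, 13L, 0L), ignore_attr = TRUE)
  expect_true(all(gy[sexy == "F"] == 0))
})

test_that("background sites are in Hardy-Weinberg when sampled", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e6, sdr_chrom = NA,
                    n_females = 25, n_males = 25, seed = 11, error_rate = 0,
                    composition = "sampled")
  pop <- simulate_population(cfg)
  bg <- which(pop$gm$sites$class_ == "background")
  expect_gte(length(bg), 1000)
  ## chi-square goodness of fit per site against HW at the true frequency,
  ## summed: sum of independent chi2(2) variables
  n <- ncol(pop$gm$geno)
  chi_tot <- 0
  for (i in bg) {
    p <- pop$gm$sites$p[i]
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- tabulate(pop$gm$geno[i, ] + 1, nbins = 3)
    chi_tot <- chi_tot + sum((o - e)^2 / e)
  }
  pval <- pchisq(chi_tot, df = 2 * length(bg), lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("inversion heterozygotes carry het_boost-fold heterozygosity", {
  run <- preset_run("CT", seed = 1, error_rate = 0)
  iv <- run$cfg$inversions[[1]]
  inside <- run$gm$sites$chrom == iv$chrom & run$gm$sites$pos >= iv$start &
    run$gm$sites$pos < iv$end
  g <- run$truth$inversion_genotypes$invX
  het_rate <- function(samples_idx)
    mean(colMeans(run$gm$geno[inside, samples_idx, drop = FALSE] == 1))
  ri <- het_rate(which(g == 1))
  hom <- het_rate(which(g != 1))
  ## per-bp het of RI is theta * het_boost, of RR/II theta; as a site
  ## fraction the ratio is the same.  3 MC standard errors of the ratio.
  expect_gt(ri / hom, run$cfg$het_boost * 0.8)
  expect_lt(ri / hom, run$cfg$het_boost * 1.2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(step = 0), "step")
  expect_error(sim_config(theta = 1.2), "theta")
  expect_error(sim_config(sdr_chrom = "chr9"), "chr9")
  expect_error(
    sim_config(inversions = list(
      inversion_spec("chr1", 1e5, 2e5, "X", c(0, 0, 1), c(0, 1, 0)),
      inversion_spec("chr1", 1.5e5, 3e5, "X", c(0, 0, 1), c(0, 1, 0)))),
    "overlap")
  expect_error(inversion_spec("chr1", 0, 1e5, "Y",
                              geno_freq_female = c(0.5, 0.5, 0)),
               "females")
  expect_error(inversion_spec("chr1", 0, 1e5, "Y",
                              geno_freq_male = c(0, 0.5, 0.5)),
               "hemizygous")
  expect_error(inversion_spec("chr1", 0, 1e5, "X",
                              geno_freq_male = c(0.4, 0.3, 0.3)), "one X")
})

test_that("genotype errors hit at the configured rate", {
  cfg0 <- sim_config(n_chromosomes = 1, chrom_length = 1e6, sdr_chrom = NA,
                     n_females = 10, n_males = 10, seed = 5, error_rate = 0)
  cfg1 <- sim_config(n_chromosomes = 1, chrom_length = 1e6, sdr_chrom = NA,
                     n_females = 10, n_males = 10, seed = 5, error_rate = 0.05)
  g0 <- simulate_population(cfg0)$gm$geno
  g1 <- simulate_population(cfg1)$gm$geno
  frac <- mean(g0 != g1)
  expect_gt(frac, 0.04); expect_lt(frac, 0.06)
})
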