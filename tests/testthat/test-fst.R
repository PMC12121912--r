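## independent Weir-Cockerham oracle: nested ANOVA on allele indicators
## (individuals within groups), derived from scratch rather than from the
## published a/b/c formulas
wc_anova_oracle <- function(g1, g2) {
  gl <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  ns <- sapply(gl, length); r <- 2; N <- sum(ns)
  ps <- sapply(gl, function(g) mean(g) / 2)
  pbar <- sum(ns * ps) / N
  SSP <- sum(2 * ns * (ps - pbar)^2)
  SSI <- sum(unlist(mapply(function(g, p) 2 * (g / 2 - p)^2, gl, ps)))
  SSG <- sum(sapply(gl, function(g) sum(g == 1))) / 2
  MSP <- SSP / (r - 1); MSI <- SSI / (N - r); MSG <- SSG / N
  nc <- (N - sum(ns^2) / N) / (r - 1)
  sG <- MSG; sI <- (MSI - MSG) / 2; sP <- (MSP - MSI) / (2 * nc)
  sP / (sP + sI + sG)
}

test_that("Hudson site Fst matches its closed forms", {
  ## fully sex-linked SNP: females fixed ref, males all het -> exactly 0.5
  expect_identical(site_fst_hudson(0, 40, 0.5, 40), 0.5)
  expect_identical(site_fst_hudson(0, 8, 0.5, 6), 0.5)
  ## no differentiation and fixed difference
  expect_equal(site_fst_hudson(0.3, 20, 0.3, 20), 0)
  expect_equal(site_fst_hudson(0, 20, 1, 20), 1)
  ## identical monomorphic groups: undefined
  expect_true(is.na(site_fst_hudson(0, 20, 0, 20)))
  ## corrected form converges to the plug-in 0.5 from below, monotonically
  ns <- c(4, 10, 40, 100, 1000, 1e5)
  vals <- sapply(ns, function(n) site_fst_hudson(0, n, 0.5, n, corrected = TRUE))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 0.5))
  expect_equal(vals[length(vals)], 0.5, tolerance = 1e-4)
})

test_that("Weir-Cockerham equals an independent ANOVA transcription", {
  set.seed(101)
  for (i in 1:100) {
    g1 <- sample(0:2, sample(4:40, 1), replace = TRUE)
    g2 <- sample(0:2, sample(4:40, 1), replace = TRUE)
    if (all(c(g1, g2) == g1[1]) && g1[1] != 1) next # monomorphic, undefined
    r <- site_fst_wc(g1, g2)
    o <- wc_anova_oracle(g1, g2)
    if (is.na(r$fst)) { expect_true(is.na(o) || is.nan(o)); next }
    expect_equal(r$fst, o, tolerance = 1e-6)
  }
})

test_that("W-C at a fully sex-linked SNP is 0.5 for every n (oracle-frozen)", {
  ## the symbolic oracle (and the ANOVA transcription) give exactly 1/2 at
  ## every sample size -- W-C agrees with Hudson here, it does not plateau
  ## lower
  for (n in c(2, 5, 20, 100)) {
    r <- site_fst_wc(rep(0L, n), rep(1L, n))
    expect_equal(r$fst, 0.5, tolerance = 1e-12)
    expect_equal(wc_anova_oracle(rep(0L, n), rep(1L, n)), 0.5,
                 tolerance = 1e-12)
  }
  ## HWE groups at equal frequency: near zero
  set.seed(7)
  g1 <- rbinom(50, 2, 0.4); g2 <- rbinom(50, 2, 0.4)
  expect_lt(abs(site_fst_wc(g1, g2)$fst), 0.05)
})

test_that("windowed Fst is a ratio of sums, order-invariant, NA when empty", {
  run <- preset_run("CT", seed = 1)
  tr <- windowed_fst(run$gm, run$windows)
  ## autosome-wide mean near zero
  expect_lt(abs(mean(tr[chrom == "chr2", fst], na.rm = TRUE)), 0.02)
  ## top windows overlap the true SDR or inversion
  top <- tr[order(-fst)][1:10]
  expect_true(all(top$chrom == "chr1"))
  expect_true(all(top$end > run$cfg$sdr_start - run$cfg$window_size))

  ## sample order invariance
  perm <- sample(ncol(run$gm$geno))
  gm2 <- genotype_matrix(run$gm$geno[, perm], run$gm$sites,
                         run$gm$samples[perm])
  tr2 <- windowed_fst(gm2, run$windows)
  expect_equal(tr$fst, tr2$fst)

  ## a window with no sites is NA, not zero
  gm3 <- run$gm
  keep <- !(gm3$sites$chrom == "chr2" & gm3$sites$pos < 40000)
  gm3 <- genotype_matrix(gm3$geno[keep, ], gm3$sites[keep], gm3$samples)
  tr3 <- windowed_fst(gm3, run$windows)
  expect_true(is.na(tr3[chrom == "chr2" & start == 0, fst]))
  expect_identical(tr3[chrom == "chr2" & start == 0, n_sites_used], 0L)

  expect_error(windowed_fst(run$gm, run$windows, group1 = "F01",
                            group2 = c("F01", "M01")), "disjoint")
  expect_error(windowed_fst(run$gm, run$windows, estimator = "nope"))
})

test_that("pool Fst matches the Nei closed form and flags the sex chromosome", {
  ## daughter pool p = 0, son pool p = 0.5: Hs = 0.25, Ht = 0.375 -> 1/3
  w <- make_windows(c(chrA = 1000), 1000, 1000)
  pA <- data.table::data.table(chrom = "chrA", pos = 500, ref_reads = 100,
                               alt_reads = 0)
  pB <- data.table::data.table(chrom = "chrA", pos = 500, ref_reads = 50,
                               alt_reads = 50)
  expect_equal(pool_fst(pA, pB, w)$fst, 1 / 3)
  ## equal frequencies: zero
  expect_equal(pool_fst(pB, pB, w)$fst, 0)

  ## simulated XY cross: elevated windows sit on the sex chromosome
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 1e6, sdr_chrom = "chr1",
                    sdr_start = 3e5, sdr_end = 5e5, n_females = 2, n_males = 2,
                    seed = 21, error_rate = 0)
  cross <- cross_config(n_sons = 20, n_daughters = 20, pool_depth = 60)
  cp <- simulate_cross_pools(cross, cfg)
  ww <- make_windows(cfg$chrom_length, 20000, 10000)
  tr <- pool_fst(cp$pools[pool == "sons"], cp$pools[pool == "daughters"], ww)
  top <- tr[order(-fst)][1:5]
  expect_true(all(top$chrom == "chr1"))
  expect_true(all(top$start >= 3e5 - 20000 & top$end <= 5e5 + 20000))
})
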