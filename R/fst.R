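#' Hudson-type site Fst between two groups
#'
#' Plug-in form `1 - Hw/Hb` with `Hw = p1(1-p1) + p2(1-p2)` and
#' `Hb = p1(1-p2) + p2(1-p1)`.  At a fully sex-linked SNP (one group fixed
#' reference, the other all heterozygous, so `p = 0` vs `p = 0.5`) the
#' plug-in value is exactly 0.5 for any sample sizes.  The corrected form
#' replaces each within-group term by its unbiased estimate
#' `p(1-p) * n/(n-1)` (Bhatia et al. style) and converges to the plug-in
#' value as `n` grows.
#'
#' @param p1,p2 alt-allele frequencies in the two groups.
#' @param n1,n2 number of non-missing *alleles* per group (>= 2).
#' @param corrected use the unbiased within-group heterozygosity.
#' @return site Fst, or `NA` when both groups are identically monomorphic
#'   (`Hb = 0`, undefined).
#' @export
site_fst_hudson <- function(p1, n1, p2, n2, corrected = FALSE) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  if (corrected) {
    hw <- p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)
  } else {
    hw <- p1 * (1 - p1) + p2 * (1 - p2)
  }
  ifelse(hb == 0, NA_real_, 1 - hw / hb)
}

## Weir & Cockerham (1984) variance components for one biallelic site and
## two groups, vectorized over sites.  Inputs per group: n (individuals with
## a call), p (alt frequency), h (observed heterozygote frequency).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham site Fst between two groups of diploid genotypes
#'
#' Returns the variance components `a` (among groups), `b` (among
#' individuals within groups) and `c` (within individuals) of Weir &
#' Cockerham (1984) and `fst = a / (a + b + c)`.  Monomorphic sites have all
#' components zero and `fst = NA`; window aggregation uses the
#' ratio-of-sums `sum(a) / sum(a + b + c)`.
#'
#' Note: at a fully sex-linked SNP (one group fixed, the other all
#' heterozygous) this estimator equals 0.5 exactly for every sample size,
#' agreeing with the Hudson plug-in value; the Nei-style pool estimator
#' ([pool_fst()]) plateaus at 1/3 in the same configuration.
#'
#' @param g1,g2 integer vectors of alt dosages (0/1/2, `NA` allowed) for the
#'   two groups at one site.
#' @return list with `a`, `b`, `c`, `fst`.
#' @export
site_fst_wc <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2 || length(g2) < 2)
    stop("need >= 2 genotyped diploid samples per group")
  n1 <- length(g1); n2 <- length(g2)
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  tot <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = if (isTRUE(tot > 0) || isTRUE(tot < 0)) comp$a / tot else NA_real_)
}

## per-site group summaries for a genotype matrix and a logical sample mask
group_site_stats <- function(geno, mask) {
  sub <- geno[, mask, drop = FALSE]
  n <- rowSums(!is.na(sub))
  ac <- rowSums(sub, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, ac / (2 * n), NA_real_),
       h = ifelse(n > 0, rowSums(sub == 1, na.rm = TRUE) / n, NA_real_))
}

#' Windowed male-female Fst
#'
#' Aggregates site Fst over sliding windows as a ratio of sums:
#' Weir-Cockerham uses `sum(a) / sum(a+b+c)`; Hudson uses
#' `1 - sum(Hw) / sum(Hb)`.  Windows with no usable site get `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @param windows window grid from [make_windows()].
#' @param group1,group2 sample names of the two groups (defaults: females
#'   and males from the sample table).
#' @param estimator `"wc"` (default, matches VCFtools usage) or `"hudson"`.
#' @return `data.table(chrom, start, end, fst, n_sites_used)`.
#' @export
windowed_fst <- function(gm, windows, group1 = NULL, group2 = NULL,
                         estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  group1 <- group1 %||% gm$samples$sample[gm$samples$sex == "F"]
  group2 <- group2 %||% gm$samples$sample[gm$samples$sex == "M"]
  if (length(intersect(group1, group2)))
    stop("groups must be disjoint")
  m1 <- gm$samples$sample %in% group1
  m2 <- gm$samples$sample %in% group2
  s1 <- group_site_stats(gm$geno, m1)
  s2 <- group_site_stats(gm$geno, m2)
  ok <- s1$n >= 2 & s2$n >= 2

  if (estimator == "wc") {
    comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    num <- s1$p * (1 - s1$p) + s2$p * (1 - s2$p)        # Hw
    den <- s1$p * (1 - s2$p) + s2$p * (1 - s1$p)        # Hb
  }
  use <- ok & !is.na(den) & den != 0
  map <- site_window_map(windows, gm$sites$chrom, gm$sites$pos)
  map <- map[use[site]]
  agg <- map[, .(num = sum(num[site]), den = sum(den[site]), n = .N),
             by = win]
  out <- copy(windows)[, `:=`(fst = NA_real_, n_sites_used = 0L)]
  val <- if (estimator == "wc") agg$num / agg$den else 1 - agg$num / agg$den
  out[agg$win, `:=`(fst = val, n_sites_used = agg$n)]
  out[]
}

#' Pool-seq Fst between two pools (Nei form)
#'
#' Classic `(Ht - Hs) / Ht` with `Hs` the mean of the two pools'
#' `2p(1-p)` and `Ht = 2 pbar (1 - pbar)`.  Sites must reach `min_reads`
#' coverage in both pools and a minor-allele read count of `min_count`
#' summed across pools.  Windowed as a ratio of sums.  At a fully
#' sex-linked site (pool frequencies 0 and 0.5) the value is 1/3.
#'
#' @param poolA,poolB `data.table(chrom, pos, ref_reads, alt_reads)`.
#' @param windows window grid.
#' @param min_reads minimum reads per pool per site.
#' @param min_count minimum minor-allele read count across pools.
#' @return `data.table(chrom, start, end, fst, n_sites_used)`.
#' @export
pool_fst <- function(poolA, poolB, windows, min_reads = 4, min_count = 2) {
  a <- as.data.table(poolA); b <- as.data.table(poolB)
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  m[, `:=`(cov_a = ref_reads_a + alt_reads_a, cov_b = ref_reads_b + alt_reads_b)]
  m <- m[cov_a >= min_reads & cov_b >= min_reads]
  m[, `:=`(alt_tot = alt_reads_a + alt_reads_b,
           ref_tot = ref_reads_a + ref_reads_b)]
  m <- m[pmin(alt_tot, ref_tot) >= min_count]
  m[, `:=`(pa = alt_reads_a / cov_a, pb = alt_reads_b / cov_b)]
  m[, hs := (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2]
  m[, ht := 2 * ((pa + pb) / 2) * (1 - (pa + pb) / 2)]
  m <- m[ht > 0]
  map <- site_window_map(windows, m$chrom, m$pos)
  agg <- map[, .(num = sum(m$ht[site] - m$hs[site]), den = sum(m$ht[site]),
                 n = .N), by = win]
  out <- copy(windows)[, `:=`(fst = NA_real_, n_sites_used = 0L)]
  out[agg$win, `:=`(fst = agg$num / agg$den, n_sites_used = agg$n)]
  out[]
}
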