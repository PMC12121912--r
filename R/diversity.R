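#' Windowed nucleotide diversity (pi) within a group
#'
#' Per-site pi is the fraction of mismatching unordered allele pairs among
#' the `n` non-missing alleles, `2 p (1-p) n / (n-1)`, identical to
#' brute-force pair counting.  Window pi divides the sum of site pi by the
#' window length in bp (monomorphic positions contribute zero).  Sites with
#' fewer than two called alleles are skipped.
#'
#' @param gm a `genotype_matrix`.
#' @param windows window grid from [make_windows()].
#' @param group sample names (default: all samples).
#' @return `data.table(chrom, start, end, pi, n_sites_used)`.
#' @export
windowed_pi <- function(gm, windows, group = NULL) {
  group <- group %||% gm$samples$sample
  if (!length(group)) stop("empty group")
  st <- group_site_stats(gm$geno, gm$samples$sample %in% group)
  nal <- 2 * st$n
  site_pi <- ifelse(nal >= 2, 2 * st$p * (1 - st$p) * nal / (nal - 1), NA_real_)
  use <- !is.na(site_pi)
  map <- site_window_map(windows, gm$sites$chrom, gm$sites$pos)
  map <- map[use[site]]
  agg <- map[, .(s = sum(site_pi[site]), n = .N), by = win]
  out <- copy(windows)[, `:=`(pi = 0, n_sites_used = 0L)]
  out[agg$win, `:=`(pi = agg$s, n_sites_used = agg$n)]
  out[, pi := pi / (end - start)]
  out[]
}

#' Windowed SNP density within a sample subset
#'
#' Counts sites that segregate within the subset with minor allele frequency
#' at least `maf_min` (computed within the subset).
#'
#' @param gm a `genotype_matrix`.
#' @param windows window grid.
#' @param samples sample names of the subset.
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @return `data.table(chrom, start, end, density)` (site count per window).
#' @export
snp_density <- function(gm, windows, samples = NULL, maf_min = 0.05) {
  samples <- samples %||% gm$samples$sample
  if (!length(samples)) stop("empty sample subset")
  st <- group_site_stats(gm$geno, gm$samples$sample %in% samples)
  maf <- pmin(st$p, 1 - st$p)
  use <- !is.na(maf) & maf >= maf_min & st$p > 0 & st$p < 1
  map <- site_window_map(windows, gm$sites$chrom, gm$sites$pos)
  map <- map[use[site]]
  agg <- map[, .(n = .N), by = win]
  out <- copy(windows)[, density := 0L]
  out[agg$win, density := agg$n]
  out[]
}

#' Normalized male:female depth ratio per window or gene
#'
#' Each sample's depth is first divided by its own autosome-wide median
#' (rows not on `sex_chrom`), removing library-size differences; the ratio
#' is then mean normalized male depth over mean normalized female depth.
#' Doubling every male sample's raw depth leaves the ratio unchanged.
#'
#' @param depth long `data.table` with columns `sample`, `depth` and either
#'   (`chrom`, `start`, `end`) for windows or `gene` for genes.
#' @param samples sample table with `sample` and `sex`.
#' @param sex_chrom chromosome(s) excluded from the per-sample normalizer;
#'   required for window input, ignored for gene input (genes normalize by
#'   each sample's median over all genes not flagged in `norm_exclude`).
#' @param norm_exclude for gene input: genes excluded from the normalizer.
#' @return input units with a `ratio` column (`NA` where female depth is 0).
#' @export
depth_ratio <- function(depth, samples, sex_chrom = NULL,
                        norm_exclude = character()) {
  d <- as.data.table(depth)
  samples <- as.data.table(samples)
  by_gene <- "gene" %in% names(d)
  d <- samples[, .(sample, sex)][d, on = "sample"]
  if (by_gene) {
    normd <- d[!gene %in% norm_exclude,
               .(norm = median(depth)), by = sample]
  } else {
    if (is.null(sex_chrom)) stop("sex_chrom required for window depth")
    normd <- d[!chrom %in% sex_chrom, .(norm = median(depth)), by = sample]
  }
  d <- normd[d, on = "sample"]
  if (any(is.na(d$norm) | d$norm == 0))
    stop("cannot normalize: a sample has no usable depth")
  d[, nd := depth / norm]
  keyv <- if (by_gene) "gene" else c("chrom", "start", "end")
  out <- d[, .(male = mean(nd[sex == "M"]), female = mean(nd[sex == "F"])),
           by = keyv]
  out[, ratio := ifelse(female == 0, NA_real_, male / female)]
  out[]
}

#' The four-rule variant QC filter
#'
#' Applies, in order: (1) drop samples whose mean site coverage is below
#' `min_sample_cov`; (2) drop sites whose across-sample mean depth is below
#' `min_site_depth` or above `max_site_depth`; (3) drop sites with a
#' missing-genotype proportion above `max_missing`; (4) drop sites with
#' minor allele frequency below `maf_min`.  Defaults are 6 / 4x / 40x /
#' 0.2 / 0.05.
#'
#' @param gm a `genotype_matrix`.
#' @param sample_cov named numeric: mean coverage per sample.
#' @param site_depth numeric: mean depth per site (same order as sites).
#' @param min_sample_cov,min_site_depth,max_site_depth,max_missing,maf_min
#'   thresholds.
#' @return list with the filtered `genotype_matrix` (`gm`) and a `report`
#'   data.frame of removals per rule.
#' @export
variant_qc_filter <- function(gm, sample_cov, site_depth,
                              min_sample_cov = 6, min_site_depth = 4,
                              max_site_depth = 40, max_missing = 0.2,
                              maf_min = 0.05) {
  if (min_sample_cov <= 0 || min_site_depth <= 0 || max_site_depth <= 0 ||
      max_missing <= 0 || maf_min <= 0)
    stop("QC thresholds must be positive")
  stopifnot(length(site_depth) == nrow(gm$geno))
  geno <- gm$geno; sites <- copy(gm$sites); samples <- copy(gm$samples)

  keep_s <- sample_cov[samples$sample] >= min_sample_cov
  n_rule1 <- sum(!keep_s)
  geno <- geno[, keep_s, drop = FALSE]
  samples <- samples[keep_s]

  keep2 <- site_depth >= min_site_depth & site_depth <= max_site_depth
  n_rule2 <- sum(!keep2)
  geno <- geno[keep2, , drop = FALSE]; sites <- sites[keep2]

  miss <- rowMeans(is.na(geno))
  keep3 <- miss <= max_missing
  n_rule3 <- sum(!keep3)
  geno <- geno[keep3, , drop = FALSE]; sites <- sites[keep3]

  n <- rowSums(!is.na(geno))
  p <- rowSums(geno, na.rm = TRUE) / (2 * n)
  keep4 <- !is.na(p) & pmin(p, 1 - p) >= maf_min
  n_rule4 <- sum(!keep4)
  geno <- geno[keep4, , drop = FALSE]; sites <- sites[keep4]

  report <- data.frame(
    rule = c("sample_mean_coverage", "site_mean_depth", "site_missingness",
             "minor_allele_frequency"),
    removed = c(n_rule1, n_rule2, n_rule3, n_rule4),
    unit = c("samples", "sites", "sites", "sites"))
  list(gm = genotype_matrix(geno, sites, samples), report = report)
}
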