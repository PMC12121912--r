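#' Simulate per-sample depth tracks and loss-of-function annotations
#'
#' Depth is Poisson around `depth_mean`, scaled by a per-sample library-size
#' factor (log-normal, cv ~ 10%).  Genes flagged `deleted_on_y` lose the Y
#' haplotype's contribution in samples of the heterogametic sex, halving
#' their expected depth there.  With `cfg$depth_noise = FALSE` depth equals
#' its expectation exactly (oracle mode).  LoF annotations are attached to
#' simulated variants: Y-origin LoF alleles are the SDR fixed differences
#' (male allele frequency 0.5, female 0); X-origin LoF alleles are drawn
#' from high-frequency background sites inside the SDR.
#'
#' @param gm,truth output of [simulate_population()].
#' @param genes `data.frame(gene, chrom, start, end, deleted_on_y)`;
#'   `deleted_on_y` logical, optional (default all `FALSE`).
#' @param cfg the [sim_config()].
#' @param n_lof_y,n_lof_x number of LoF variants to annotate per origin.
#' @return list with
#'   \describe{
#'     \item{gene_depth}{`data.table(gene, sample, depth)`}
#'     \item{window_depth}{`data.table(chrom, start, end, sample, depth)` on
#'       the config's window grid}
#'     \item{lof}{`data.table(chrom, pos, origin)` of annotated LoF variants}
#'     \item{truth}{input truth with `deleted_genes` and `lof` filled in}
#'   }
#' @export
simulate_depth_and_lof <- function(gm, truth, genes, cfg,
                                   n_lof_y = 3, n_lof_x = 2) {
  genes <- as.data.table(genes)
  if (!"deleted_on_y" %in% names(genes)) genes[, deleted_on_y := FALSE]
  bad <- !genes$chrom %in% cfg$chroms
  if (any(bad))
    stop_cfg("gene(s) outside simulated chromosomes: %s",
             paste(genes$gene[bad], collapse = ", "))
  with_seed(child_seed(cfg$seed, 4), {
    samples <- gm$samples
    n <- nrow(samples)
    het_sex <- if (cfg$heterogamety == "XY") "M" else "F"
    scale <- if (cfg$depth_noise) exp(rnorm(n, 0, 0.1)) else rep(1, n)

    expected <- function(deleted, sex) {
      copies <- ifelse(deleted & sex == het_sex, 1, 2)
      cfg$depth_mean * copies / 2
    }
    draw <- function(mu) if (cfg$depth_noise) rpois(length(mu), mu) else mu

    gd <- CJ(gene = genes$gene, sample = samples$sample, sorted = FALSE)
    gd <- genes[, .(gene, deleted_on_y)][gd, on = "gene"]
    gd <- samples[, .(sample, sex)][gd, on = "sample"]
    gd[, depth := draw(expected(deleted_on_y, sex) * scale[match(sample, samples$sample)])]

    windows <- make_windows(cfg$chrom_length, cfg$window_size, cfg$step)
    wd <- CJ(win = seq_len(nrow(windows)), sample = samples$sample,
             sorted = FALSE)
    wd <- cbind(windows[wd$win], wd[, .(sample)])
    wd <- samples[, .(sample, sex)][wd, on = "sample"]
    ## windows overlapping a deleted gene on the sex chromosome lose the
    ## deleted fraction of their length in the heterogametic sex
    wd[, del_frac := 0]
    for (k in which(genes$deleted_on_y)) {
      g <- genes[k]
      ov <- wd$chrom == g$chrom & wd$start < g$end & wd$end > g$start
      wd[ov, del_frac := pmin(1, del_frac +
                                (pmin(end, g$end) - pmax(start, g$start)) /
                                (end - start))]
    }
    wd[, mu := cfg$depth_mean * (1 - del_frac * (sex == het_sex) / 2) *
         scale[match(sample, samples$sample)]]
    wd[, depth := draw(mu)]
    window_depth <- wd[, .(chrom, start, end, sample, depth)]

    ## LoF annotations
    sdr_idx <- which(gm$sites$class_ == "sdr")
    lof_y <- head(sdr_idx, n_lof_y)
    x_pool <- which(gm$sites$class_ == "background" &
                      gm$sites$chrom == cfg$sdr_chrom &
                      gm$sites$pos >= cfg$sdr_start &
                      gm$sites$pos < cfg$sdr_end)
    if (length(x_pool)) {
      fem <- samples$sex == "F"
      af_f <- rowMeans(gm$geno[x_pool, fem, drop = FALSE], na.rm = TRUE) / 2
      x_pool <- x_pool[order(-af_f)]
    }
    lof_x <- head(x_pool, n_lof_x)
    lof <- rbind(
      if (length(lof_y)) data.table(chrom = gm$sites$chrom[lof_y],
                                    pos = gm$sites$pos[lof_y], origin = "Y"),
      if (length(lof_x)) data.table(chrom = gm$sites$chrom[lof_x],
                                    pos = gm$sites$pos[lof_x], origin = "X"))
    truth$deleted_genes <- genes$gene[genes$deleted_on_y]
    truth$lof <- lof
    list(gene_depth = gd[, .(gene, sample, depth)],
         window_depth = window_depth, lof = lof, truth = truth)
  })
}
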