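#' Configure a single-pair genetic cross
#'
#' Parental haplotypes are described per inversion by orientation flags.
#' The father's second haplotype is his Y; sons always receive it and
#' daughters always receive his X (no recombination: each offspring gets one
#' unrecombined haplotype per parent, a deliberate simplification).
#'
#' @param mother_hap1,mother_hap2 named logical vectors (inversion name ->
#'   carries inverted orientation) for the mother's two X haplotypes.
#' @param father_hapX,father_hapY same for the father's X and Y.
#' @param n_sons,n_daughters offspring counts; their sum must be positive.
#' @param pool_depth sequencing reads per site per offspring pool.
#' @return a `cross_config` list.
#' @export
cross_config <- function(mother_hap1 = c(), mother_hap2 = c(),
                         father_hapX = c(), father_hapY = c(),
                         n_sons = 20, n_daughters = 20, pool_depth = 50) {
  if (n_sons + n_daughters <= 0)
    stop_cfg("a cross needs at least one offspring")
  as_flags <- function(x) {
    x <- unlist(x)
    if (is.null(x)) setNames(logical(), character()) else
      setNames(as.logical(x), names(x))
  }
  structure(list(mother = list(as_flags(mother_hap1), as_flags(mother_hap2)),
                 father = list(X = as_flags(father_hapX),
                               Y = as_flags(father_hapY)),
                 n_sons = n_sons, n_daughters = n_daughters,
                 pool_depth = pool_depth),
            class = "cross_config")
}

hap_carries <- function(flags, inv_name) isTRUE(unname(flags[inv_name]))

#' Simulate pool-seq of the sons and daughters of a single-pair cross
#'
#' Offspring haplotypes are drawn by Mendelian transmission with obligate
#' X-to-daughter / Y-to-son inheritance from the father.  Pool read counts
#' at each site are binomial around the realized offspring allele frequency.
#' A Y-linked inversion on `father_hapY` must not appear on a maternal
#' haplotype (configuration error).
#'
#' @param cross a [cross_config()].
#' @param cfg a [sim_config()] describing the genome (sites, SDR,
#'   inversions); its `seed` drives the draw.
#' @return list with `pools` (`data.table(pool, chrom, pos, ref_reads,
#'   alt_reads)` for pools `"sons"` and `"daughters"`), `sites`, and `truth`
#'   (per-offspring sex, transmitted haplotypes and inversion genotypes).
#' @export
simulate_cross_pools <- function(cross, cfg) {
  stopifnot(inherits(cross, "cross_config"), inherits(cfg, "sim_config"))
  for (iv in cfg$inversions) {
    if (iv$linkage == "Y" &&
        (hap_carries(cross$mother[[1]], iv$name) ||
         hap_carries(cross$mother[[2]], iv$name) ||
         hap_carries(cross$father$X, iv$name)))
      stop_cfg("Y-linked inversion %s cannot ride a non-Y haplotype", iv$name)
  }
  with_seed(child_seed(cfg$seed, 3), {
    sites <- gen_sites(cfg)
    S <- nrow(sites)

    ## parental haplotype allele vectors
    par_hap <- function(flags, is_Y) {
      al <- integer(S)
      bg <- sites$class_ == "background"
      al[bg] <- rbinom(sum(bg), 1, sites$p[bg])
      if (is_Y) al[sites$class_ == "sdr"] <- 1L
      for (iv in cfg$inversions)
        if (hap_carries(flags, iv$name))
          al[which(sites$inv == iv$name)] <- 1L
      al
    }
    H <- list(m1 = par_hap(cross$mother[[1]], FALSE),
              m2 = par_hap(cross$mother[[2]], FALSE),
              fX = par_hap(cross$father$X, FALSE),
              fY = par_hap(cross$father$Y, TRUE))

    n_off <- cross$n_sons + cross$n_daughters
    sex <- rep(c("M", "F"), c(cross$n_sons, cross$n_daughters))
    m_pick <- sample.int(2, n_off, replace = TRUE)  # maternal haplotype
    geno <- matrix(0L, nrow = S, ncol = n_off)
    for (j in seq_len(n_off)) {
      pat <- if (sex[j] == "M") H$fY else H$fX
      geno[, j] <- H[[m_pick[j]]] + pat
    }

    pool_counts <- function(cols, label) {
      p <- rowMeans(geno[, cols, drop = FALSE]) / 2
      alt <- rbinom(S, cross$pool_depth, p)
      data.table(pool = label, chrom = sites$chrom, pos = sites$pos,
                 ref_reads = cross$pool_depth - alt, alt_reads = alt)
    }
    pools <- rbind(pool_counts(which(sex == "M"), "sons"),
                   pool_counts(which(sex == "F"), "daughters"))

    inv_geno <- list()
    for (iv in cfg$inversions) {
      mom_c <- c(hap_carries(cross$mother[[1]], iv$name),
                 hap_carries(cross$mother[[2]], iv$name))
      pat_c <- ifelse(sex == "M", hap_carries(cross$father$Y, iv$name),
                      hap_carries(cross$father$X, iv$name))
      inv_geno[[iv$name]] <- mom_c[m_pick] + pat_c
    }
    truth <- list(sex = sex, maternal_hap = m_pick,
                  inversion_genotypes = inv_geno,
                  sdr = if (is.na(cfg$sdr_chrom)) NULL else
                    list(chrom = cfg$sdr_chrom, start = cfg$sdr_start,
                         end = cfg$sdr_end))
    list(pools = pools, sites = sites, geno = geno, truth = truth)
  })
}
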