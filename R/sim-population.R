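## Site generator shared by the population and cross simulators.
##
## Three site classes:
##   background  - Poisson(theta / E[2p(1-p)]) per bp genome-wide; population
##                 allele frequency p ~ U(0.05, 0.95); genotypes drawn in HWE
##   inversion   - orientation-diagnostic fixed differences inside each
##                 inversion at density theta * (het_boost - 1), so opposite
##                 orientations differ at theta * het_boost and same
##                 orientation at theta (the background)
##   sdr         - fixed X-Y differences inside the SDR at density
##                 sdr_divergence; the alt allele rides the sex-limited
##                 haplotype (Y in an XY system, W in ZW)
##
## With p ~ U(0.05, 0.95), E[2p(1-p)] = 0.365, hence the rate rescaling.
BG_HET_PER_SITE <- 0.365

gen_sites <- function(cfg) {
  site_list <- list()
  lambda_bg <- cfg$theta / BG_HET_PER_SITE
  for (ch in cfg$chroms) {
    L <- cfg$chrom_length[[ch]]
    n_bg <- rpois(1, lambda_bg * L)
    if (n_bg > 0)
      site_list[[length(site_list) + 1L]] <- data.table(
        chrom = ch, pos = sample.int(L, n_bg), class_ = "background",
        p = runif(n_bg, 0.05, 0.95), inv = NA_character_)
  }
  for (iv in cfg$inversions) {
    d <- cfg$theta * (cfg$het_boost - 1)
    n_iv <- rpois(1, d * (iv$end - iv$start))
    if (n_iv > 0)
      site_list[[length(site_list) + 1L]] <- data.table(
        chrom = iv$chrom,
        pos = iv$start + sample.int(iv$end - iv$start, n_iv),
        class_ = "inversion", p = NA_real_, inv = iv$name)
  }
  if (!is.na(cfg$sdr_chrom)) {
    n_sdr <- rpois(1, cfg$sdr_divergence * (cfg$sdr_end - cfg$sdr_start))
    if (n_sdr > 0)
      site_list[[length(site_list) + 1L]] <- data.table(
        chrom = cfg$sdr_chrom,
        pos = cfg$sdr_start + sample.int(cfg$sdr_end - cfg$sdr_start, n_sdr),
        class_ = "sdr", p = NA_real_, inv = NA_character_)
  }
  sites <- rbindlist(site_list)
  sites[, pos := pos - 1]                       # 0-based
  sites <- unique(sites, by = c("chrom", "pos")) # drop colliding positions
  setorder(sites, chrom, pos)
  sites[]
}

## draw per-sex genotype counts (0/1/2 inverted haplotypes) for one inversion
draw_inv_genotypes <- function(iv, n_by_sex, composition) {
  out <- list()
  for (sx in c("female", "male")) {
    n <- n_by_sex[[sx]]
    fr <- iv$geno_freq[sx, ]
    if (composition == "fixed") {
      cnt <- floor(fr * n)
      rem <- n - sum(cnt)
      if (rem > 0) { # assign remainders to largest fractional parts
        frac <- fr * n - cnt
        add <- order(frac, decreasing = TRUE)[seq_len(rem)]
        cnt[add] <- cnt[add] + 1
      }
      g <- rep(0:2, times = cnt)
    } else {
      g <- sample(0:2, n, replace = TRUE, prob = fr)
    }
    out[[sx]] <- sample(g)  # random order within sex
  }
  out
}

#' Simulate a diploid male/female cohort
#'
#' Generates genotypes for `n_females + n_males` diploid samples under the
#' configured sex-chromosome model.  In an XY system every male carries one X
#' and one Y haplotype; inside the SDR the Y carries fixed differences at
#' density `sdr_divergence`, making males heterozygous there.  Inversion
#' genotypes are drawn per sex from the configured frequency rows
#' (fixed or sampled composition); orientation-diagnostic sites make
#' inversion heterozygotes het-dense.  Genotype errors flip one allele with
#' probability `error_rate`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{gm}{a `genotype_matrix`: integer alt-dosage matrix
#'       (sites x samples, `NA` = missing), a `sites` table and a `samples`
#'       table (`sample`, `sex`, `population`).}
#'     \item{truth}{truth sidecar: per-sample sex and inversion genotypes,
#'       the true SDR interval, per-haplotype allele matrix (pre-error), and
#'       per-haplotype inversion orientations.}
#'   }
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, 1), {
    nF <- cfg$n_females; nM <- cfg$n_males
    n <- nF + nM
    samples <- data.table(
      sample = c(sprintf("F%02d", seq_len(nF)), sprintf("M%02d", seq_len(nM))),
      sex = rep(c("F", "M"), c(nF, nM)),
      population = cfg$population)
    sites <- gen_sites(cfg)
    S <- nrow(sites)

    ## per-sample inversion genotypes
    inv_geno <- list()
    for (iv in cfg$inversions) {
      g <- draw_inv_genotypes(iv, list(female = nF, male = nM),
                              cfg$composition)
      inv_geno[[iv$name]] <- c(g$female, g$male)
    }

    ## haplotype-level alleles: columns 2i-1, 2i are sample i's haplotypes;
    ## haplotype 2 of the heterogametic sex is the sex-limited one (Y or W)
    hap <- matrix(0L, nrow = S, ncol = 2 * n)
    bg <- sites$class_ == "background"
    if (any(bg)) {
      pm <- matrix(rbinom(sum(bg) * 2 * n, 1, rep(sites$p[bg], 2 * n)),
                   nrow = sum(bg))
      hap[bg, ] <- pm
    }
    het_sex <- if (cfg$heterogamety == "XY") "M" else "F"
    is_het_sex <- samples$sex == het_sex
    sdr <- sites$class_ == "sdr"
    if (any(sdr)) # alt allele on the sex-limited haplotype only
      hap[sdr, which(is_het_sex) * 2] <- 1L

    ## orientation per haplotype per inversion (TRUE = inverted)
    orient <- list()
    for (iv in cfg$inversions) {
      g <- inv_geno[[iv$name]]
      o <- matrix(FALSE, nrow = n, ncol = 2)
      if (iv$linkage == "Y") {
        o[, 2] <- is_het_sex & g >= 1     # carried on the Y haplotype
      } else {
        ## X-linked or autosomal: place carried copies; in males (XY) the X
        ## is haplotype 1, so a single copy goes there first
        o[, 1] <- g >= 1
        o[, 2] <- g == 2
      }
      orient[[iv$name]] <- o
      idx <- which(sites$inv == iv$name)
      if (length(idx)) {
        hap[idx, seq(1, 2 * n, by = 2)] <- matrix(rep(as.integer(o[, 1]),
                                                      each = length(idx)),
                                                  nrow = length(idx))
        hap[idx, seq(2, 2 * n, by = 2)] <- matrix(rep(as.integer(o[, 2]),
                                                      each = length(idx)),
                                                  nrow = length(idx))
      }
    }

    geno <- hap[, seq(1, 2 * n, by = 2), drop = FALSE] +
      hap[, seq(2, 2 * n, by = 2), drop = FALSE]

    ## symmetric one-allele flip errors
    if (cfg$error_rate > 0) {
      flip <- matrix(runif(S * n) < cfg$error_rate, nrow = S)
      up <- flip & geno == 0L
      dn <- flip & geno == 2L
      hetf <- flip & geno == 1L
      geno[up] <- 1L
      geno[dn] <- 1L
      geno[hetf] <- ifelse(runif(sum(hetf)) < 0.5, 0L, 2L)
    }
    colnames(geno) <- samples$sample

    gm <- genotype_matrix(geno, sites[, .(chrom, pos, class_, inv)], samples)
    truth <- list(
      samples = copy(samples),
      inversion_genotypes = inv_geno,
      inversions = cfg$inversions,
      sdr = if (is.na(cfg$sdr_chrom)) NULL else
        list(chrom = cfg$sdr_chrom, start = cfg$sdr_start, end = cfg$sdr_end),
      heterogamety = if (is.na(cfg$sdr_chrom)) "none" else cfg$heterogamety,
      sites = copy(sites),
      hap_alleles = hap,
      orientations = orient,
      deleted_genes = character(),
      lof = NULL)
    list(gm = gm, truth = truth)
  })
}

#' Construct a genotype matrix container
#'
#' @param geno integer matrix of alt-allele dosages (sites x samples; values
#'   0, 1, 2 or `NA`).
#' @param sites `data.frame` with at least `chrom` and `pos` (0-based).
#' @param samples `data.frame` with at least `sample` and `sex`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  sites <- as.data.table(sites)
  samples <- as.data.table(samples)
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == nrow(samples),
            all(c("chrom", "pos") %in% names(sites)),
            all(c("sample", "sex") %in% names(samples)))
  structure(list(geno = geno, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d F / %d M), %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), sum(x$samples$sex == "F"),
              sum(x$samples$sex == "M"), length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)
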