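#' Classify cross markers by sex-linked segregation pattern
#'
#' Deterministic rules standing in for probabilistic sex-linkage callers:
#' a marker is XY-consistent iff the father is heterozygous, the mother
#' homozygous, all sons heterozygous and all daughters homozygous for the
#' maternal allele (allowing up to a fraction `error_eps` of offspring
#' mismatches); ZW-consistent is the sex-mirrored rule; autosomal iff the
#' offspring genotype counts fit the Mendelian expectation from the parents
#' irrespective of sex (chi-square goodness of fit, p > 0.05); otherwise
#' uninformative.  Markers with a missing parent genotype are uninformative.
#'
#' @param mother_gt,father_gt integer alt dosages (0/1/2, `NA` allowed), one
#'   per marker.
#' @param offspring_gt matrix markers x offspring of alt dosages.
#' @param offspring_sex character vector `"M"`/`"F"` per offspring (>= 2 of
#'   each).
#' @param error_eps tolerated fraction of mismatching offspring.
#' @return `data.table(marker, class, mismatch)` with class in
#'   `XY-consistent`, `ZW-consistent`, `autosomal`, `uninformative`.
#' @export
classify_cross_markers <- function(mother_gt, father_gt, offspring_gt,
                                   offspring_sex, error_eps = 0) {
  offspring_gt <- as.matrix(offspring_gt)
  stopifnot(length(mother_gt) == nrow(offspring_gt),
            length(father_gt) == nrow(offspring_gt),
            length(offspring_sex) == ncol(offspring_gt))
  if (sum(offspring_sex == "M") < 2 || sum(offspring_sex == "F") < 2)
    stop("need at least two offspring of each sex")
  sons <- offspring_sex == "M"; daughters <- offspring_sex == "F"
  n_off <- ncol(offspring_gt)

  sex_rule <- function(het_parent, hom_parent, het_kids, hom_kids) {
    ## het_parent heterozygous, hom_parent homozygous; het_kids all het,
    ## hom_kids all homozygous for hom_parent's allele
    ok_par <- !is.na(het_parent) & !is.na(hom_parent) &
      het_parent == 1 & hom_parent %in% c(0, 2)
    mm <- rowSums(offspring_gt[, het_kids, drop = FALSE] != 1, na.rm = TRUE) +
      rowSums(offspring_gt[, hom_kids, drop = FALSE] != hom_parent,
              na.rm = TRUE)
    list(ok = ok_par & mm <= error_eps * n_off, mm = mm)
  }
  xy <- sex_rule(father_gt, mother_gt, sons, daughters)
  zw <- sex_rule(mother_gt, father_gt, daughters, sons)

  ## Mendelian goodness of fit, sexes pooled
  mend_p <- vapply(seq_along(mother_gt), function(i) {
    m <- mother_gt[i]; f <- father_gt[i]
    if (is.na(m) || is.na(f)) return(NA_real_)
    gam <- function(g) if (g == 0) c(1, 0) else if (g == 2) c(0, 1) else c(0.5, 0.5)
    pm <- gam(m); pf <- gam(f)
    exp_p <- c(pm[1] * pf[1],                       # genotype 0
               pm[1] * pf[2] + pm[2] * pf[1],       # genotype 1
               pm[2] * pf[2])                       # genotype 2
    obs <- tabulate(offspring_gt[i, ] + 1, nbins = 3)
    keep <- exp_p > 0
    if (any(obs[!keep] > 0)) return(0)              # impossible genotype seen
    if (sum(keep) == 1) return(1)                   # fixed cross, always fits
    chi2 <- sum((obs[keep] - sum(obs) * exp_p[keep])^2 /
                  (sum(obs) * exp_p[keep]))
    pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  }, numeric(1))

  cls <- rep("uninformative", length(mother_gt))
  cls[!is.na(mend_p) & mend_p > 0.05] <- "autosomal"
  cls[zw$ok] <- "ZW-consistent"
  cls[xy$ok] <- "XY-consistent"
  cls[is.na(mother_gt) | is.na(father_gt)] <- "uninformative"
  data.table(marker = seq_along(mother_gt), class = cls,
             mismatch = ifelse(xy$ok, xy$mm, ifelse(zw$ok, zw$mm, NA_real_)))
}

#' Pearson chi-square test of genotype-sex association
#'
#' Plain Pearson chi-square on a genotype x sex contingency table, no
#' continuity correction.
#'
#' @param counts matrix of counts, at least 2 x 2.
#' @return list with `chi2`, `df`, `p`.
#' @export
marker_sex_association <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: chi-square undefined")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Decide XY vs ZW vs none per chromosome
#'
#' Elevated windows are those whose male-female Fst exceeds the
#' `elevated_quantile` quantile of windows on the other chromosomes
#' (scale-free threshold).  A chromosome is called only when it has a run of
#' at least `min_run` consecutive elevated windows; within the elevated
#' windows, the verdict is XY when the median `pi_male / pi_female` is at
#' least `pi_ratio_min`, ZW when the reciprocal holds, none otherwise.
#' When cross marker classes are supplied they must agree (more
#' XY-consistent than ZW-consistent markers for an XY verdict and vice
#' versa) or the verdict is downgraded to none.  Chromosomes with fewer
#' than `min_windows` scored windows are `none` with a warning.
#'
#' @param tracks `data.table(chrom, start, end, fst, pi_male, pi_female)`;
#'   [compute_window_stats()] produces it.
#' @param elevated_quantile quantile defining "elevated" Fst (default 0.99).
#' @param pi_ratio_min minimum median diversity ratio (default 2).
#' @param min_run minimum consecutive elevated windows (default 3).
#' @param min_windows minimum scored windows per chromosome (default 10).
#' @param markers optional result of [classify_cross_markers()].
#' @return `data.table(chrom, verdict, region_start, region_end,
#'   n_elevated, pi_ratio_median, frac_male_excess, frac_female_excess)`.
#' @export
infer_heterogamety <- function(tracks, elevated_quantile = 0.99,
                               pi_ratio_min = 2, min_run = 3,
                               min_windows = 10, markers = NULL) {
  tr <- as.data.table(tracks)
  stopifnot(all(c("chrom", "start", "end", "fst", "pi_male", "pi_female")
                %in% names(tr)))
  marker_pref <- NULL
  if (!is.null(markers)) {
    nxy <- sum(markers$class == "XY-consistent")
    nzw <- sum(markers$class == "ZW-consistent")
    marker_pref <- if (nxy > nzw) "XY" else if (nzw > nxy) "ZW" else "tie"
  }
  out <- list()
  for (ch in unique(tr$chrom)) {
    mine <- tr[chrom == ch][order(start)]
    scored <- mine[!is.na(fst)]
    res <- data.table(chrom = ch, verdict = "none",
                      region_start = NA_real_, region_end = NA_real_,
                      n_elevated = 0L, pi_ratio_median = NA_real_,
                      frac_male_excess = NA_real_,
                      frac_female_excess = NA_real_)
    if (nrow(scored) < min_windows) {
      warning(sprintf("chromosome %s: fewer than %d scored windows", ch,
                      min_windows))
      out[[ch]] <- res; next
    }
    other <- tr[chrom != ch & !is.na(fst)]
    if (!nrow(other)) { out[[ch]] <- res; next }
    thr <- quantile(other$fst, elevated_quantile, na.rm = TRUE, names = FALSE)
    mine[, elev := !is.na(fst) & fst > thr]
    r <- rle(mine$elev)
    if (!any(r$values & r$lengths >= min_run)) { out[[ch]] <- res; next }
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths >= min_run)
    idx <- unlist(lapply(runs, function(k) (ends[k] - r$lengths[k] + 1):ends[k]))
    elev <- mine[idx]
    ratio <- ifelse(elev$pi_female > 0, elev$pi_male / elev$pi_female,
                    ifelse(elev$pi_male > 0, Inf, NA_real_))
    med <- median(ratio, na.rm = TRUE)
    vd <- if (is.na(med)) "none" else if (med >= pi_ratio_min) "XY"
      else if (med <= 1 / pi_ratio_min) "ZW" else "none"
    if (vd != "none" && !is.null(marker_pref) && marker_pref != vd)
      vd <- "none"
    res <- data.table(
      chrom = ch, verdict = vd,
      region_start = if (vd == "none") NA_real_ else min(elev$start),
      region_end = if (vd == "none") NA_real_ else max(elev$end),
      n_elevated = nrow(elev), pi_ratio_median = med,
      frac_male_excess = mean(ratio > 1, na.rm = TRUE),
      frac_female_excess = mean(ratio < 1, na.rm = TRUE))
    out[[ch]] <- res
  }
  rbindlist(out)
}
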