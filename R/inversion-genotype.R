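#' Genotype samples at an inversion candidate
#'
#' Each sample's heterozygous-site density inside the candidate interval is
#' normalized by its density in flanking regions of `flank_bp` on each side
#' (pseudocounted).  The inside:flank ratios are split into two groups by a
#' deterministic two-means (threshold at the midpoint of the two cluster
#' means, initialized at the extremes); the upper group is called Ref/Inv
#' when its mean exceeds `min_het_ratio` times the lower mean, otherwise
#' everyone is homozygous.  Homozygotes are polarized Ref/Ref vs Inv/Inv by
#' majority junction support; a homozygote with fewer than `min_molecules`
#' junction molecules is `NA`.
#'
#' @param candidate list or one-row table with `chrom`, `start`, `end`.
#' @param gm a `genotype_matrix`.
#' @param junction optional `data.table(sample, ref_junction_molecules,
#'   inv_junction_molecules)`; without it homozygotes cannot be polarized
#'   and are `NA`.
#' @param flank_bp flank width (default: candidate length, capped at 2 Mb).
#' @param min_molecules junction molecules needed to polarize (default 3).
#' @param min_het_ratio separation factor distinguishing a real het cluster
#'   (default 2).
#' @return named character vector per sample: `"RR"`, `"RI"`, `"II"` or
#'   `NA`.
#' @export
genotype_inversion <- function(candidate, gm, junction = NULL,
                               flank_bp = NULL, min_molecules = 3,
                               min_het_ratio = 2) {
  ch <- candidate$chrom[1]; s <- candidate$start[1]; e <- candidate$end[1]
  if (e - s <= 0) stop("degenerate candidate interval")
  flank_bp <- flank_bp %||% min(e - s, 2e6)
  sites <- gm$sites
  inside <- sites$chrom == ch & sites$pos >= s & sites$pos < e
  chlen_hint <- max(sites$pos[sites$chrom == ch]) + 1
  fl_lo <- max(0, s - flank_bp); fl_hi <- min(chlen_hint, e + flank_bp)
  flank <- sites$chrom == ch &
    ((sites$pos >= fl_lo & sites$pos < s) | (sites$pos >= e & sites$pos < fl_hi))
  len_in <- e - s
  len_fl <- (s - fl_lo) + (fl_hi - e)
  if (len_fl <= 0) stop("candidate has no flanking sequence to normalize by")

  het_in <- colSums(gm$geno[inside, , drop = FALSE] == 1, na.rm = TRUE)
  het_fl <- colSums(gm$geno[flank, , drop = FALSE] == 1, na.rm = TRUE)
  ## pseudocount keeps ratios finite on sparse flanks
  ratio <- (het_in / len_in + 0.5 / len_in) / (het_fl / len_fl + 0.5 / len_fl)

  ## deterministic 1-D two-means, centers initialized at the extremes
  cl <- rep(1L, length(ratio))
  if (length(unique(ratio)) > 1) {
    c1 <- min(ratio); c2 <- max(ratio)
    for (it in 1:100) {
      assign2 <- abs(ratio - c2) < abs(ratio - c1)
      nc1 <- mean(ratio[!assign2]); nc2 <- mean(ratio[assign2])
      if (isTRUE(all.equal(c(c1, c2), c(nc1, nc2)))) break
      c1 <- nc1; c2 <- nc2
    }
    if (c2 >= min_het_ratio * c1) cl[assign2] <- 2L
  }
  geno <- rep(NA_character_, length(ratio))
  names(geno) <- gm$samples$sample
  geno[cl == 2L] <- "RI"

  hom <- which(cl == 1L)
  if (length(hom)) {
    if (is.null(junction)) {
      geno[hom] <- NA_character_
    } else {
      j <- as.data.table(junction)
      j <- j[match(gm$samples$sample[hom], sample)]
      tot <- j$ref_junction_molecules + j$inv_junction_molecules
      pol <- ifelse(is.na(tot) | tot < min_molecules, NA_character_,
                    ifelse(j$inv_junction_molecules >
                             j$ref_junction_molecules, "II", "RR"))
      geno[hom] <- pol
    }
  }
  geno
}

#' Classify an inversion as X-linked, Y-linked or autosomal
#'
#' Rules mirror the sex-limited segregation logic: Y-linked iff Ref/Inv
#' occurs in males at frequency >= `y_min`, Inv/Inv is (essentially) absent
#' and the female Ref/Inv frequency is <= `f_max`; X-linked iff Inv/Inv
#' occurs in females while male Inv/Inv is absent and male Ref/Inv is
#' common (>= `y_min`); autosomal iff the genotype distribution is
#' sex-independent (Fisher exact p > 0.05); otherwise unknown.  Fewer than
#' 5 called samples per sex gives `unknown`.
#'
#' @param genotypes named vector of `"RR"`/`"RI"`/`"II"`/`NA` calls.
#' @param sexes named vector (`"M"`/`"F"`) or sample table with `sample`,
#'   `sex`.
#' @param y_min minimum male Ref/Inv frequency (default 0.5).
#' @param f_max maximum female Ref/Inv frequency for the Y rule (default 0.1).
#' @param tol tolerated frequency of contradicting genotypes (default 0.05).
#' @return list with `linkage` and `freq_table` (rows female/male, columns
#'   Ref/Ref, Ref/Inv, Inv/Inv; frequencies over called samples).
#' @export
classify_inversion_linkage <- function(genotypes, sexes, y_min = 0.5,
                                       f_max = 0.1, tol = 0.05) {
  if (is.data.frame(sexes)) sexes <- setNames(sexes$sex, sexes$sample)
  sx <- sexes[names(genotypes)]
  lv <- c("RR", "RI", "II")
  tab <- rbind(
    female = table(factor(genotypes[sx == "F"], levels = lv)),
    male = table(factor(genotypes[sx == "M"], levels = lv)))
  freq <- tab / pmax(rowSums(tab), 1)
  called_f <- sum(tab["female", ]); called_m <- sum(tab["male", ])
  linkage <- "unknown"
  if (called_f >= 5 && called_m >= 5) {
    ii_freq <- sum(tab[, "II"]) / (called_f + called_m)
    if (freq["male", "RI"] >= y_min && ii_freq <= tol &&
        freq["female", "RI"] <= f_max) {
      linkage <- "Y-linked"
    } else if (freq["female", "II"] > 0 && freq["male", "II"] <= tol &&
               freq["male", "RI"] >= y_min) {
      linkage <- "X-linked"
    } else {
      p <- tryCatch(fisher.test(tab[, colSums(tab) > 0, drop = FALSE])$p.value,
                    error = function(e) NA_real_)
      if (!is.na(p) && p > 0.05) linkage <- "autosomal"
    }
  }
  list(linkage = linkage, freq_table = freq)
}

#' Predict inversion segregation in a single-pair cross
#'
#' Deterministic Mendelian expectation with obligate X-to-daughter /
#' Y-to-son transmission.  Returns the expected offspring inversion
#' genotype distribution per sex plus the qualitative pattern the cross
#' would display: whether the sexes are differentiated at the inversion and
#' which sex shows elevated diversity inside it.
#'
#' @param cross a [cross_config()].
#' @param inv_name inversion to predict (default: the single configured
#'   name across parental haplotypes).
#' @return list with `sons`, `daughters` (named numeric over RR/RI/II),
#'   `differentiation` (`"sex-differentiated"` or `"undifferentiated"`) and
#'   `diversity` (`"male-diverse"`, `"female-diverse"`, `"both"`, or
#'   `"none"`).
#' @export
predict_cross_inversion_pattern <- function(cross, inv_name = NULL) {
  stopifnot(inherits(cross, "cross_config"))
  all_names <- unique(c(names(cross$mother[[1]]), names(cross$mother[[2]]),
                        names(cross$father$X), names(cross$father$Y)))
  inv_name <- inv_name %||% all_names[1]
  if (is.null(inv_name) || is.na(inv_name)) stop("no inversion configured")
  m <- c(hap_carries(cross$mother[[1]], inv_name),
         hap_carries(cross$mother[[2]], inv_name))
  fX <- hap_carries(cross$father$X, inv_name)
  fY <- hap_carries(cross$father$Y, inv_name)

  dist_for <- function(pat) {
    d <- setNames(numeric(3), c("RR", "RI", "II"))
    for (mi in 1:2) {
      g <- m[mi] + pat
      d[g + 1] <- d[g + 1] + 0.5
    }
    d
  }
  sons <- dist_for(fY); daughters <- dist_for(fX)
  diff_sex <- !isTRUE(all.equal(unname(sons), unname(daughters)))
  het_s <- sons["RI"]; het_d <- daughters["RI"]
  diversity <- if (het_s > 0 && het_d > 0) "both"
    else if (het_s > 0) "male-diverse"
    else if (het_d > 0) "female-diverse" else "none"
  list(sons = sons, daughters = daughters,
       differentiation = if (diff_sex) "sex-differentiated" else
         "undifferentiated",
       diversity = diversity)
}
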