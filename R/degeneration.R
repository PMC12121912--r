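#' Flag degenerate genes by male:female depth ratio
#'
#' A gene is degenerate iff its normalized male:female depth ratio is
#' strictly below `threshold` (default 0.75; a gene deleted from the Y sits
#' at 0.5).  Missing ratios yield `NA` flags.
#'
#' @param ratios `data.table(gene, ratio)` (from [depth_ratio()]).
#' @param threshold strict upper bound (default 0.75; exactly 0.75 is not
#'   degenerate).
#' @return input with logical `degenerate` column.
#' @export
flag_degenerate_genes <- function(ratios, threshold = 0.75) {
  out <- copy(as.data.table(ratios))
  out[, degenerate := ifelse(is.na(ratio), NA, ratio < threshold)]
  out[]
}

#' Flag fixed loss-of-function variants
#'
#' A LoF variant is fixed-on-X iff its female allele frequency exceeds
#' `f_thresh` (default 0.9); fixed-on-Y iff its male allele frequency
#' exceeds `m_thresh` (default 0.45, just under the hemizygous maximum of
#' 0.5) while the female frequency is at most `f_absent` (a Y-limited
#' allele cannot appear in females).
#'
#' @param lof `data.table(chrom, pos, af_male, af_female)` of LoF-annotated
#'   variants with sex-specific allele frequencies in `[0, 1]`.
#' @param f_thresh,m_thresh,f_absent thresholds.
#' @return input with logical `fixed_on_x`, `fixed_on_y` columns.
#' @export
fixed_lof <- function(lof, f_thresh = 0.9, m_thresh = 0.45, f_absent = 0.05) {
  out <- copy(as.data.table(lof))
  stopifnot(all(c("af_male", "af_female") %in% names(out)))
  if (any(out$af_male < 0 | out$af_male > 1 |
          out$af_female < 0 | out$af_female > 1, na.rm = TRUE))
    stop("allele frequencies must be in [0, 1]")
  out[, fixed_on_x := af_female > f_thresh]
  out[, fixed_on_y := af_male > m_thresh & af_female <= f_absent]
  out[]
}

## codon translation table (standard code), indexed by codon string
GENETIC_CODE_MAP <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1,
                  paste0, collapse = "")
  setNames(aas, codons)
})

translate_codon <- function(codon) unname(GENETIC_CODE_MAP[codon])

## synonymous fraction of the 3 possible changes at each codon position;
## mutations creating stop codons count as nonsynonymous
codon_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  aa <- translate_codon(codon)
  s <- 0
  for (i in 1:3) {
    for (b in setdiff(bases, substr(codon, i, i))) {
      mut <- codon
      substr(mut, i, i) <- b
      if (translate_codon(mut) == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

## average synonymous/nonsynonymous differences between two codons over all
## minimal mutation pathways; pathways passing through stop codons are
## excluded (unless all do, then all pathways count)
codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(Sd = 0, Nd = 0))
  paths <- if (nd == 1) list(pos) else
    lapply(seq_len(factorial(nd)), function(i) perm_index(pos, i))
  count_path <- function(order_) {
    cur <- c1; s <- 0; n <- 0; has_stop <- FALSE
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- translate_codon(cur); a2 <- translate_codon(nxt)
      if (a2 == "*" || a1 == "*") has_stop <- TRUE
      if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n, stop = has_stop)
  }
  res <- t(vapply(paths, count_path, numeric(3)))
  ok <- res[, "stop"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(Sd = mean(res[ok, "s"]), Nd = mean(res[ok, "n"]))
}

## i-th permutation of x (lexicographic by index); tiny n only
perm_index <- function(x, i) {
  n <- length(x)
  out <- integer(0)
  avail <- x
  i <- i - 1
  for (k in n:1) {
    f <- factorial(k - 1)
    j <- i %/% f + 1
    out <- c(out, avail[j])
    avail <- avail[-j]
    i <- i %% f
  }
  out
}

#' Nei-Gojobori (1986) dN/dS between two coding sequences
#'
#' Counts synonymous and nonsynonymous sites per codon by the fraction of
#' possible changes that preserve the amino acid, averages observed
#' differences over all minimal mutation pathways (pathways through stop
#' codons excluded), and applies the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4/3 p)`.  The ratio is reported missing when `dS = 0`
#' (no synonymous differences) and each distance is missing when its
#' proportion reaches 3/4 (correction undefined).
#'
#' @param cds_x,cds_y equal-length, gap-free, codon-aligned sequences
#'   (characters, A/C/G/T only, no internal stops).
#' @return list with `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `ratio`.
#' @export
ng86_dnds <- function(cds_x, cds_y) {
  cds_x <- toupper(cds_x); cds_y <- toupper(cds_y)
  if (nchar(cds_x) != nchar(cds_y)) stop("sequences must be equal length")
  if (nchar(cds_x) %% 3 != 0) stop("length must be divisible by 3")
  if (grepl("[^ACGT]", cds_x) || grepl("[^ACGT]", cds_y))
    stop("only unambiguous A/C/G/T sequences are supported")
  nc <- nchar(cds_x) / 3
  starts <- 3 * (seq_len(nc) - 1) + 1
  cx <- substring(cds_x, starts, starts + 2)
  cy <- substring(cds_y, starts, starts + 2)
  if (any(translate_codon(cx) == "*") || any(translate_codon(cy) == "*"))
    stop("internal stop codon in input")
  sites_x <- vapply(cx, codon_sites, numeric(2))
  sites_y <- vapply(cy, codon_sites, numeric(2))
  S <- (sum(sites_x["S", ]) + sum(sites_y["S", ])) / 2
  N <- (sum(sites_x["N", ]) + sum(sites_y["N", ])) / 2
  d <- mapply(function(a, b) codon_diffs(a, b), cx, cy)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  ratio <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS, ratio = ratio)
}
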