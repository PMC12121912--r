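#' Delineate the shared sex-determination region
#'
#' Intersects three evidence channels on a common window grid:
#' male-female Fst above the `fst_quantile` quantile of non-candidate
#' windows, male diversity excess `pi_male / pi_female >= pi_ratio_min`,
#' and male-specific k-mer density >= `kmer_min`.  The SDR is the longest
#' run of windows where all three flags hold, merged across gaps of at most
#' `gap_windows` windows; the result is empty when no run reaches
#' `min_run`.
#'
#' @param fst_track,pi_male_track,pi_female_track,kmer_track window tables
#'   with value columns `fst`, `pi`, `pi`, `density` on the same grid.
#' @param fst_quantile quantile of the Fst distribution defining
#'   "elevated" (default 0.95, over all windows with a value).
#' @param pi_ratio_min male:female diversity ratio floor (default 2).
#' @param kmer_min minimum k-mers per window (default 1; `NULL` drops the
#'   k-mer channel, e.g. when no sequences exist).
#' @param min_run minimum run length in windows (default 3).
#' @param gap_windows tolerated gap inside a run (default 1).
#' @return list with `interval` (`chrom`, `start`, `end`, or `NULL` when
#'   empty), `windows` (per-window evidence flags) and `boundary_confidence`
#'   (windows from each boundary to the nearest failing window outside).
#' @export
delineate_sdr <- function(fst_track, pi_male_track, pi_female_track,
                          kmer_track = NULL, fst_quantile = 0.95,
                          pi_ratio_min = 2, kmer_min = 1, min_run = 3,
                          gap_windows = 1) {
  f <- as.data.table(fst_track)
  pm <- as.data.table(pi_male_track)
  pf <- as.data.table(pi_female_track)
  key <- c("chrom", "start", "end")
  same_grid <- function(a, b) identical(a[, ..key], b[, ..key])
  if (!same_grid(f, pm) || !same_grid(f, pf) ||
      (!is.null(kmer_track) && !same_grid(f, as.data.table(kmer_track))))
    stop("evidence tracks are on different window grids")

  ev <- f[, .(chrom, start, end, fst)]
  ev[, pi_male := pm$pi]
  ev[, pi_female := pf$pi]
  ## elevated relative to the rest of the genome: each chromosome is scored
  ## against the quantile of the other chromosomes' windows (falling back to
  ## its own distribution for single-chromosome input)
  ev[, fst_elevated := FALSE]
  for (ch in unique(ev$chrom)) {
    bg <- ev[chrom != ch & !is.na(fst), fst]
    if (!length(bg)) bg <- ev[!is.na(fst), fst]
    thr <- quantile(bg, fst_quantile, na.rm = TRUE, names = FALSE)
    ev[chrom == ch, fst_elevated := !is.na(fst) & fst > thr]
  }
  ev[, male_pi_excess := pi_female > 0 & pi_male / pi_female >= pi_ratio_min |
       (pi_female == 0 & pi_male > 0)]
  if (!is.null(kmer_track) && !is.null(kmer_min)) {
    ev[, kmer_dense := as.data.table(kmer_track)$density >= kmer_min]
  } else ev[, kmer_dense := TRUE]
  ev[, all_flags := fst_elevated & male_pi_excess & kmer_dense]

  best <- NULL
  for (ch in unique(ev$chrom)) {
    e <- ev[chrom == ch][order(start)]
    flags <- e$all_flags
    ## merge runs across short gaps
    filled <- flags
    r <- rle(flags)
    pos <- cumsum(r$lengths)
    for (k in seq_along(r$values))
      if (!r$values[k] && r$lengths[k] <= gap_windows &&
          k > 1 && k < length(r$values))
        filled[(pos[k] - r$lengths[k] + 1):pos[k]] <- TRUE
    r2 <- rle(filled)
    ends2 <- cumsum(r2$lengths)
    runs <- which(r2$values & r2$lengths >= min_run)
    for (k in runs) {
      i0 <- ends2[k] - r2$lengths[k] + 1; i1 <- ends2[k]
      if (is.null(best) || (i1 - i0) > (best$i1 - best$i0))
        best <- list(chrom = ch, i0 = i0, i1 = i1, e = e)
    }
  }
  if (is.null(best))
    return(list(interval = NULL, windows = ev, boundary_confidence = NA))
  e <- best$e
  interval <- list(chrom = best$chrom, start = e$start[best$i0],
                   end = e$end[best$i1])
  conf <- min(best$i0 - 1, nrow(e) - best$i1)
  list(interval = interval, windows = ev, boundary_confidence = conf)
}
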