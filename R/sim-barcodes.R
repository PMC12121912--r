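## Map a molecule interval from haplotype coordinates to reference intervals.
## An inverted haplotype equals the reference with [s, e) reversed, so
## haplotype position h in [s, e) maps to reference s + e - 1 - h.  A molecule
## crossing a breakpoint therefore splits into two reference intervals, which
## is exactly what creates barcode sharing between distal windows.
## Returns data.table(id, start, end) of reference intervals for molecules
## [a, b) on a haplotype inverted over [s, e).
hap_to_ref_intervals <- function(id, a, b, s, e) {
  dt <- data.table(id = id, a = a, b = b)
  pieces <- list(
    dt[a < s, .(id, start = a, end = pmin(b, s))],
    dt[b > s & a < e, .(id, start = s + e - pmin(b, e),
                        end = s + e - pmax(a, s))],
    dt[b > e, .(id, start = pmax(a, e), end = b)]
  )
  rbindlist(pieces)
}

#' Simulate per-sample linked-read barcode maps and junction support
#'
#' Draws `barcode_molecules_per_sample` molecule intervals per sample
#' (exponential lengths, uniform starts, chromosome picked proportional to
#' length) on one of the sample's two haplotypes.  Molecules live on the true
#' haplotype, so on an inverted haplotype a molecule spanning a breakpoint
#' covers two distal reference windows - the signal the inversion screen
#' keys on.  Barcodes are drawn from a finite per-sample pool, so unrelated
#' molecules occasionally share a barcode (background sharing).
#'
#' @param gm,truth,cfg output of [simulate_population()] plus its config.
#' @return list with
#'   \describe{
#'     \item{barcode_map}{`data.table(sample, chrom, window_start, barcode)`,
#'       windows being `step`-sized tiles (default 10 kb).}
#'     \item{junctions}{`data.table(sample, inv, ref_junction_molecules,
#'       inv_junction_molecules)`: molecules spanning the reference junction
#'       (on non-inverted haplotypes) vs the inverted junction.}
#'   }
#' @export
simulate_barcode_maps <- function(gm, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$molecule_length_mean >= min(cfg$chrom_length))
    stop_cfg("molecule length must be below chromosome length")
  with_seed(child_seed(cfg$seed, 2), {
    samples <- gm$samples$sample
    n <- length(samples)
    M <- cfg$barcode_molecules_per_sample
    tile <- cfg$step
    probs <- cfg$chrom_length / sum(cfg$chrom_length)

    maps <- vector("list", n)
    jlist <- list()
    invs <- truth$inversions
    for (i in seq_len(n)) {
      chrom_i <- sample(cfg$chroms, M, replace = TRUE, prob = probs)
      hap_i <- sample.int(2, M, replace = TRUE)
      ## exponential lengths truncated at 10x the mean (survival 5e-5): the
      ## unbounded tail would otherwise leak molecules past the distal
      ## threshold on shrunken desk-scale genomes
      len_i <- pmax(1, pmin(rexp(M, 1 / cfg$molecule_length_mean),
                            10 * cfg$molecule_length_mean,
                            cfg$chrom_length[chrom_i] - 1))
      start_i <- floor(runif(M, 0, cfg$chrom_length[chrom_i] - len_i))
      bc_i <- sample.int(cfg$barcode_pool_size, M, replace = TRUE)
      mol <- data.table(id = seq_len(M), chrom = chrom_i, hap = hap_i,
                        a = start_i, b = start_i + len_i, barcode = bc_i)

      ref_parts <- list()
      handled <- rep(FALSE, M)
      for (iv in invs) {
        o <- truth$orientations[[iv$name]][i, ]
        for (h in 1:2) {
          if (!o[h]) next
          sel <- mol$chrom == iv$chrom & mol$hap == h & !handled &
            mol$a < iv$end & mol$b > iv$start
          if (!any(sel)) next
          sub <- mol[sel]
          ref_parts[[length(ref_parts) + 1L]] <- cbind(
            chrom = iv$chrom,
            hap_to_ref_intervals(sub$id, sub$a, sub$b, iv$start, iv$end))
          handled[sel] <- TRUE
        }
      }
      rest <- mol[!handled]
      ref_parts[[length(ref_parts) + 1L]] <-
        rest[, .(chrom, id, start = a, end = b)]
      parts <- rbindlist(ref_parts, use.names = TRUE)

      ## expand intervals to covered tiles
      k0 <- floor(parts$start / tile)
      k1 <- floor((parts$end - 1) / tile)
      nw <- as.integer(k1 - k0 + 1)
      map_i <- data.table(
        chrom = rep(parts$chrom, nw),
        window_start = (sequence(nw) - 1 + rep(k0, nw)) * tile,
        id = rep(parts$id, nw))
      map_i <- unique(map_i)
      map_i[, barcode := mol$barcode[id]]
      maps[[i]] <- map_i[, .(sample = samples[i], chrom, window_start, barcode)]

      ## junction support per inversion
      for (iv in invs) {
        o <- truth$orientations[[iv$name]][i, ]
        onchr <- mol$chrom == iv$chrom
        spans <- function(x) (mol$a < x & mol$b > x) & onchr
        ref_j <- sum((spans(iv$start) | spans(iv$end)) & !o[mol$hap])
        inv_j <- sum((spans(iv$start) | spans(iv$end)) & o[mol$hap])
        jlist[[length(jlist) + 1L]] <- data.table(
          sample = samples[i], inv = iv$name,
          ref_junction_molecules = ref_j, inv_junction_molecules = inv_j)
      }
    }
    list(barcode_map = rbindlist(maps),
         junctions = if (length(jlist)) rbindlist(jlist) else
           data.table(sample = character(), inv = character(),
                      ref_junction_molecules = integer(),
                      inv_junction_molecules = integer()))
  })
}
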