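#' Emit reference and per-sample haplotype sequences
#'
#' Builds a random (seeded) reference sequence per chromosome, then applies
#' each haplotype's alternate alleles (stored in the truth sidecar by
#' [simulate_population()], pre-error) by substitution.  The reference
#' sex-limited chromosome ("Y") carries the SDR fixed-difference alleles, so
#' k-mers specific to the heterogametic sex exist by construction.
#' Orientation is not applied at the sequence level: substitutions alone
#' determine k-mer content, which is all the downstream k-mer stage uses.
#'
#' Intended for desk-scale genomes; refuse to materialize > 100 Mb of
#' sequence.
#'
#' @param truth truth sidecar from [simulate_population()].
#' @param cfg the [sim_config()].
#' @param fasta optional path; when given, sequences are also written as
#'   uncompressed FASTA via [Biostrings::writeXStringSet()].
#' @return a [Biostrings::DNAStringSet]: `ref_<chrom>` references, a
#'   `ref_<sdr_chrom>_Y` sex-limited reference, and `<sample>_hap1/2`
#'   per-sample haplotypes.
#' @export
emit_sequences <- function(truth, cfg, fasta = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n_samp <- nrow(truth$samples)
  total <- sum(cfg$chrom_length) * (2 + 2 * n_samp)
  if (total > 1e8)
    stop_cfg("refusing to emit %.1f Mb of sequence; use a smaller genome",
             total / 1e6)
  with_seed(child_seed(cfg$seed, 5), {
    bases <- c("A", "C", "G", "T")
    ref_chars <- lapply(cfg$chrom_length, function(L)
      sample(bases, L, replace = TRUE))
    refs <- lapply(ref_chars, paste, collapse = "")

    sites <- truth$sites
    if (is.null(sites)) stop_cfg("truth sidecar lacks site table")
    ref_base <- character(nrow(sites))
    for (ch in cfg$chroms) {
      idx <- which(sites$chrom == ch)
      ref_base[idx] <- ref_chars[[ch]][sites$pos[idx] + 1]
    }
    alt_base <- bases[(match(ref_base, bases)) %% 4 + 1]

    apply_alleles <- function(alleles) {
      out <- refs
      for (ch in names(out)) {
        idx <- which(sites$chrom == ch & alleles == 1L)
        if (length(idx)) {
          chars <- ref_chars[[ch]]
          chars[sites$pos[idx] + 1] <- alt_base[idx]
          out[[ch]] <- paste(chars, collapse = "")
        }
      }
      out
    }

    seqs <- list()
    for (ch in cfg$chroms) seqs[[paste0("ref_", ch)]] <- refs[[ch]]
    ## sex-limited reference: SDR alt alleles applied
    if (!is.na(cfg$sdr_chrom)) {
      y_alleles <- as.integer(sites$class_ == "sdr")
      ych <- apply_alleles(y_alleles)
      seqs[[paste0("ref_", cfg$sdr_chrom, "_Y")]] <- ych[[cfg$sdr_chrom]]
    }
    for (i in seq_len(n_samp)) {
      for (h in 1:2) {
        al <- truth$hap_alleles[, 2 * (i - 1) + h]
        hs <- apply_alleles(al)
        for (ch in cfg$chroms)
          seqs[[sprintf("%s_hap%d_%s", truth$samples$sample[i], h, ch)]] <-
            hs[[ch]]
      }
    }
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    if (!is.null(fasta)) Biostrings::writeXStringSet(dss, fasta)
    dss
  })
}
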