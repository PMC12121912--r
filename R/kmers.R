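revcomp_str <- function(s) stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", s))

## canonical form of k-mer strings: lexicographic min of the k-mer and its
## reverse complement
canonical_kmers <- function(kmers) pmin(kmers, revcomp_str(kmers))

## all k-mers of one sequence string (character), as a character vector
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  stringi::stri_sub(s, 1:(n - k + 1), length = k)
}

## canonical k-mers of a sequence without per-k-mer reverse complement: the
## reverse complement of the k-mer at position i is the k-mer at position
## n-k+2-i of the reverse-complemented sequence
seq_canonical_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  f <- stringi::stri_sub(s, 1:(n - k + 1), length = k)
  r <- stringi::stri_sub(revcomp_str(s), (n - k + 1):1, length = k)
  pmin(f, r)
}

#' Extract sex-specific k-mers
#'
#' Canonical k-mers present in at least `min_presence` of target-sex
#' samples and at most `max_contam` of other-sex samples.  A sample's
#' k-mer set is the union over all its sequences (both haplotypes).
#' Matching is exact and strand-canonical, so reverse-complementing any
#' input leaves the result unchanged.
#'
#' @param target_seqs,other_seqs named lists: one character vector of
#'   sequences per sample.
#' @param k k-mer length (default 40).
#' @param min_presence minimum fraction of target-sex samples containing
#'   the k-mer (default 0.9).
#' @param max_contam maximum fraction of other-sex samples (default 0, read
#'   literally as "sex-specific").
#' @return character vector of canonical k-mers.
#' @export
sex_specific_kmers <- function(target_seqs, other_seqs, k = 40,
                               min_presence = 0.9, max_contam = 0) {
  stopifnot(length(target_seqs) >= 1, length(other_seqs) >= 1)
  shortest <- min(nchar(c(unlist(target_seqs), unlist(other_seqs))))
  if (k > shortest) stop("k exceeds the shortest input sequence")
  sample_set <- function(seqs)
    unique(unlist(lapply(seqs, seq_canonical_kmers, k = k)))
  tgt_sets <- lapply(target_seqs, sample_set)
  cnt <- data.table(kmer = unlist(tgt_sets))[, .N, by = kmer]
  cand <- cnt[N >= min_presence * length(tgt_sets), kmer]
  if (!length(cand)) return(character())
  oth_counts <- integer(length(cand))
  for (seqs in other_seqs)
    oth_counts <- oth_counts + as.integer(cand %chin% sample_set(seqs))
  sort(cand[oth_counts <= max_contam * length(other_seqs)])
}

#' Windowed density of k-mer matches in a target sequence
#'
#' Counts exact canonical matches of the k-mer set by start position per
#' window.
#'
#' @param kmers character vector of canonical k-mers.
#' @param target one sequence (character).
#' @param windows window grid restricted to / interpreted on the target's
#'   coordinates (`chrom` column is kept as-is).
#' @param k k-mer length; inferred from `kmers` when omitted.
#' @return `data.table(chrom, start, end, density)`.
#' @export
kmer_density <- function(kmers, target, windows, k = NULL) {
  k <- k %||% (if (length(kmers)) nchar(kmers[1]) else 0L)
  out <- copy(as.data.table(windows))[, density := 0L]
  if (!length(kmers) || k == 0 || nchar(target) < k) return(out[])
  tk <- seq_canonical_kmers(target, k)
  hit_pos <- which(tk %chin% kmers) - 1   # 0-based start positions
  if (!length(hit_pos)) return(out[])
  map <- site_window_map(out, rep(out$chrom[1], length(hit_pos)), hit_pos)
  agg <- map[, .(n = .N), by = win]
  out[agg$win, density := agg$n]
  out[]
}
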