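#' Count shared barcodes between window pairs
#'
#' For every ordered same-chromosome pair of 10 kb tiles (i < j) that share
#' at least one barcode in at least one sample, counts
#' `|barcodes(i) intersect barcodes(j)|` summed over samples.  Pairs are
#' classified `adjacent` (distance < `distal_min`) or `distal`
#' (window-start distance >= `distal_min`, default 500 kb).  Pairs with no
#' sharing are implicit zeros; [distance_decay_null()] accounts for them.
#'
#' @param barcode_map `data.table(sample, chrom, window_start, barcode)`
#'   with `window_start` on a `tile`-sized grid.
#' @param tile tile width in bp (must match the map's grid).
#' @param distal_min distance threshold for the distal class.
#' @return `data.table(chrom, win_i, win_j, shared, distance, pair_class)`
#'   with attributes `tile`, `distal_min` and `n_windows` (tiles per
#'   chromosome, for implicit-zero accounting).
#' @export
build_sharing_matrix <- function(barcode_map, tile = 10000,
                                 distal_min = 500000) {
  bm <- as.data.table(barcode_map)
  stopifnot(all(c("sample", "chrom", "window_start", "barcode") %in% names(bm)))
  if (any(bm$window_start %% tile != 0))
    stop("barcode map windows are not on the given tile grid")
  bm <- unique(bm[, .(sample, chrom, window_start, barcode)])
  pairs <- bm[bm, on = .(sample, chrom, barcode), allow.cartesian = TRUE,
              .(chrom, win_i = x.window_start, win_j = i.window_start)]
  pairs <- pairs[win_i < win_j]
  sm <- pairs[, .(shared = .N), by = .(chrom, win_i, win_j)]
  sm[, distance := win_j - win_i]
  sm[, pair_class := ifelse(distance >= distal_min, "distal", "adjacent")]
  setorder(sm, chrom, win_i, win_j)
  n_windows <- bm[, .(n = max(window_start) / tile + 1), by = chrom]
  setattr(sm, "tile", tile)
  setattr(sm, "distal_min", distal_min)
  setattr(sm, "n_windows", n_windows)
  sm[]
}

#' Distance-decay null for barcode sharing
#'
#' Robust location/scale of shared-barcode counts per log-spaced distance
#' bin, *including* the implicit zero pairs that never materialize in the
#' sharing matrix.  Location is the median, scale is the MAD-derived sigma
#' floored at `sqrt(max(mu, sigma_min))` so that bins whose median sharing
#' is zero (typical beyond the molecule length) still yield finite
#' z-scores.  Bins with fewer than 20 pairs are merged with their left
#' neighbor.
#'
#' @param sm sharing matrix from [build_sharing_matrix()].
#' @param n_bins number of log-spaced distance bins.
#' @param sigma_min variance floor for degenerate bins.
#' @param exclude optional `data.table(chrom, start, end)` of candidate
#'   regions whose windows are excluded on re-iteration.
#' @return `data.table(dmin, dmax, mu, sigma, n_pairs)`.
#' @export
distance_decay_null <- function(sm, n_bins = 16, sigma_min = 0.25,
                                exclude = NULL) {
  tile <- attr(sm, "tile")
  nw <- attr(sm, "n_windows")
  s <- as.data.table(sm)
  if (!is.null(exclude)) {
    ex <- as.data.table(exclude)
    for (k in seq_len(nrow(ex)))
      s <- s[!(chrom == ex$chrom[k] &
                 ((win_i >= ex$start[k] & win_i < ex$end[k]) |
                    (win_j >= ex$start[k] & win_j < ex$end[k])))]
  }
  dmax_all <- max(s$distance)
  edges <- unique(round(exp(seq(log(tile), log(dmax_all + tile),
                                length.out = n_bins + 1))))
  if (length(edges) < 3) edges <- c(tile, dmax_all + tile)
  ## total pairs per distance (in tiles): sum over chroms of (n - k)
  bins <- list()
  for (b in seq_len(length(edges) - 1)) {
    lo <- edges[b]; hi <- edges[b + 1]
    ks <- seq(ceiling(lo / tile), floor((hi - 1) / tile))
    ks <- ks[ks >= 1]
    if (!length(ks)) next
    tot <- sum(vapply(ks, function(k) sum(pmax(nw$n - k, 0)), numeric(1)))
    obs <- s[distance >= lo & distance < hi, shared]
    n_zero <- max(0, tot - length(obs))
    vals_mu <- if (tot > 0 && n_zero > tot / 2) 0 else {
      ## median over explicit+implicit values
      all_sorted <- sort(c(rep(0, n_zero), obs))
      median(all_sorted)
    }
    dev <- abs(c(rep(0, n_zero), obs) - vals_mu)
    sg <- 1.4826 * median(dev)
    mu_mean <- if (tot > 0) sum(obs) / tot else 0
    sg <- max(sg, sqrt(max(mu_mean, sigma_min)))
    bins[[length(bins) + 1L]] <- data.table(dmin = lo, dmax = hi, mu = vals_mu,
                                            sigma = sg, n_pairs = tot)
  }
  out <- rbindlist(bins)
  ## merge sparse bins leftward
  while (nrow(out) > 1 && any(out$n_pairs < 20)) {
    k <- which(out$n_pairs < 20)[1]
    j <- if (k == 1) 2 else k - 1
    merged <- out[c(k, j),
                  .(dmin = min(dmin), dmax = max(dmax),
                    mu = sum(mu * n_pairs) / sum(n_pairs),
                    sigma = max(sigma), n_pairs = sum(n_pairs))]
    out <- rbind(out[-c(k, j)], merged)
    setorder(out, dmin)
  }
  out[]
}

#' Detect inversion candidates from distal barcode sharing
#'
#' Scores every distal pair against the distance-decay null,
#' `z = (shared - mu(d)) / sigma(d)`; pairs with `z >= z_min` are clustered
#' by single linkage (left windows within `cluster_gap` tiles of each other
#' and likewise right windows).  A cluster of at least `min_pair_cluster`
#' pairs becomes a candidate; its breakpoints are the shared-count-weighted
#' centroids of the left and right window groups (molecules crossing a
#' breakpoint populate windows symmetrically around it on both flanks, so
#' the centroid tracks the true breakpoint).
#'
#' @param sm sharing matrix from [build_sharing_matrix()].
#' @param null from [distance_decay_null()].
#' @param z_min z-score threshold (default 5).
#' @param min_pair_cluster minimum pairs per candidate (default 3).
#' @param cluster_gap linkage distance in tiles (default 6; about one
#'   molecule length).
#' @return `data.table(chrom, start, end, n_pairs, peak_z)`, possibly empty.
#' @export
detect_inversion_candidates <- function(sm, null, z_min = 5,
                                        min_pair_cluster = 3,
                                        cluster_gap = 6) {
  tile <- attr(sm, "tile")
  s <- as.data.table(sm)[pair_class == "distal"]
  empty <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), n_pairs = integer(),
                      peak_z = numeric())
  if (!nrow(s)) return(empty)
  idx <- findInterval(s$distance, null$dmin)
  idx[idx < 1] <- 1; idx[idx > nrow(null)] <- nrow(null)
  s[, z := (shared - null$mu[idx]) / null$sigma[idx]]
  hits <- s[z >= z_min]
  if (!nrow(hits)) return(empty)

  out <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[chrom == ch]
    ## single-linkage clustering on (win_i, win_j) with Chebyshev gap
    n <- nrow(h)
    cl <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        near <- abs(h$win_i - h$win_i[i]) <= cluster_gap * tile &
          abs(h$win_j - h$win_j[i]) <= cluster_gap * tile
        grp <- min(cl[near], cl[i])
        if (any(cl[near] != grp)) { cl[near] <- grp; changed <- TRUE }
      }
      if (!changed) break
    }
    h[, cl := cl]
    cand <- h[, .(n_pairs = .N, peak_z = max(z),
                  start = sum(win_i * shared) / sum(shared) + tile / 2,
                  end = sum(win_j * shared) / sum(shared) + tile / 2),
              by = cl]
    cand <- cand[n_pairs >= min_pair_cluster]
    if (nrow(cand))
      out[[ch]] <- data.table(chrom = ch, start = cand$start,
                              end = cand$end, n_pairs = cand$n_pairs,
                              peak_z = cand$peak_z)
  }
  if (!length(out)) return(empty)
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}
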