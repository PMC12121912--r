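#' Compute the standard window tracks for a cohort
#'
#' One pass producing the track set downstream stages consume: male-female
#' Fst (chosen estimator), per-sex nucleotide diversity, per-sex SNP
#' density and (when depth is supplied) the normalized male:female depth
#' ratio.
#'
#' @param gm a `genotype_matrix` with both sexes.
#' @param windows window grid from [make_windows()].
#' @param estimator Fst estimator (see [windowed_fst()]).
#' @param window_depth optional long depth table (`chrom`, `start`, `end`,
#'   `sample`, `depth`).
#' @param sex_chrom chromosome(s) excluded from depth normalization.
#' @return `data.table(chrom, start, end, fst, n_sites_used, pi_male,
#'   pi_female, snp_density_male, snp_density_female[, mf_depth_ratio])`.
#' @export
compute_window_stats <- function(gm, windows, estimator = "wc",
                                 window_depth = NULL, sex_chrom = NULL) {
  males <- gm$samples$sample[gm$samples$sex == "M"]
  females <- gm$samples$sample[gm$samples$sex == "F"]
  tr <- windowed_fst(gm, windows, group1 = females, group2 = males,
                     estimator = estimator)
  tr[, pi_male := windowed_pi(gm, windows, males)$pi]
  tr[, pi_female := windowed_pi(gm, windows, females)$pi]
  tr[, snp_density_male := snp_density(gm, windows, males)$density]
  tr[, snp_density_female := snp_density(gm, windows, females)$density]
  if (!is.null(window_depth)) {
    dr <- depth_ratio(window_depth, gm$samples, sex_chrom = sex_chrom)
    tr <- dr[, .(chrom, start, end, mf_depth_ratio = ratio)][tr,
      on = c("chrom", "start", "end")]
  }
  tr[]
}

#' Configuration of the full pipeline
#'
#' Collects every stage threshold with defaults equal to the published
#' values where one exists: 20 kb / 10 kb windows, 500 kb distal threshold,
#' z >= 5 sharing screen, k = 40 with 0.9 presence, depth-ratio
#' degeneration cut 0.75, LoF fixation 0.9 (female) / 0.45 (male), MAF
#' 0.05, QC 6x sample / 4-40x site / 0.2 missingness.
#'
#' @param sim a [sim_config()] (simulation-driven run) or `NULL` when
#'   inputs are loaded from files.
#' @param ... threshold overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, ...) {
  cfg <- list(
    sim = sim,
    window_size = 20000, step = 10000,
    estimator = "wc",
    distal_min = 500000, z_min = 5, min_pair_cluster = 3,
    elevated_quantile = 0.99, pi_ratio_min = 2, min_run = 3,
    k = 40, min_presence = 0.9, max_contam = 0,
    depth_threshold = 0.75, lof_f_thresh = 0.9, lof_m_thresh = 0.45,
    maf_min = 0.05,
    qc_min_sample_cov = 6, qc_min_site_depth = 4, qc_max_site_depth = 40,
    qc_max_missing = 0.2,
    emit_kmers = FALSE,
    seed = if (!is.null(sim)) sim$seed else 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline option(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages, in dependency order: simulate (population, barcodes, depth) ->
#' window statistics -> heterogamety verdict -> inversion scan
#' (sharing matrix, null, candidates, genotyping, linkage) -> SDR
#' delineation -> degeneration report.  Sequence emission and k-mer
#' evidence run only when `emit_kmers = TRUE` (desk-scale genomes); without
#' them the SDR intersection uses the Fst and diversity channels.
#'
#' Reruns with an identical configuration reproduce identical bundles; the
#' bundle carries the seed and a configuration hash.
#'
#' @param cfg a [pipeline_config()] with a `sim` entry.
#' @param genes optional gene table for the degeneration stage.
#' @return result bundle: `tracks`, `verdicts`, `candidates`,
#'   `inversion_calls`, `sdr`, `degeneration`, `truth`, `log`.
#' @export
run_pipeline <- function(cfg, genes = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$sim)) stop("run_pipeline currently drives simulated inputs;",
                             " use load_inputs() + stage functions for files")
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[sdrscan] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sim <- cfg$sim

  pop <- stage("simulate", simulate_population(sim))
  say("simulated %d sites x %d samples", nrow(pop$gm$geno), ncol(pop$gm$geno))
  bc <- stage("simulate_barcodes", simulate_barcode_maps(pop$gm, pop$truth, sim))
  say("barcode map: %d entries", nrow(bc$barcode_map))

  windows <- make_windows(sim$chrom_length, cfg$window_size, cfg$step)
  tracks <- stage("windows", compute_window_stats(pop$gm, windows,
                                                  estimator = cfg$estimator))
  say("computed %d windows", nrow(tracks))

  verdicts <- stage("heterogamety", infer_heterogamety(
    tracks, elevated_quantile = cfg$elevated_quantile,
    pi_ratio_min = cfg$pi_ratio_min, min_run = cfg$min_run))
  say("heterogamety: %s", paste(verdicts$chrom, verdicts$verdict,
                                collapse = ", ", sep = "="))

  ## scale the distal threshold to the simulated genome (desk-scale runs)
  distal_min <- max(cfg$distal_min * max(sim$chrom_length) / 20e6,
                    5 * sim$step)
  sm <- stage("sharing", build_sharing_matrix(bc$barcode_map, tile = sim$step,
                                              distal_min = distal_min))
  null <- stage("null", distance_decay_null(sm))
  cands <- stage("candidates", detect_inversion_candidates(
    sm, null, z_min = cfg$z_min, min_pair_cluster = cfg$min_pair_cluster))
  say("inversion candidates: %d", nrow(cands))

  calls <- list()
  for (k in seq_len(nrow(cands))) {
    cand <- cands[k]
    g <- stage("genotype", genotype_inversion(cand, pop$gm, bc$junctions))
    lk <- stage("linkage", classify_inversion_linkage(g, pop$gm$samples))
    calls[[k]] <- list(interval = cand, genotypes = g,
                       linkage = lk$linkage, freq_table = lk$freq_table)
  }

  kmer_track <- NULL
  if (isTRUE(cfg$emit_kmers)) {
    seqs <- stage("sequences", emit_sequences(pop$truth, sim))
    nm <- names(seqs)
    per_sample <- function(sel_samples) {
      sets <- lapply(sel_samples, function(sid)
        as.character(seqs[grepl(paste0("^", sid, "_hap"), nm)]))
      names(sets) <- sel_samples
      sets
    }
    males <- pop$gm$samples$sample[pop$gm$samples$sex == "M"]
    females <- pop$gm$samples$sample[pop$gm$samples$sex == "F"]
    mk <- stage("kmers", sex_specific_kmers(per_sample(males),
                                            per_sample(females), k = cfg$k,
                                            min_presence = cfg$min_presence,
                                            max_contam = cfg$max_contam))
    say("male-specific k-mers: %d", length(mk))
    ych <- sim$sdr_chrom
    tgt <- as.character(seqs[[paste0("ref_", ych, "_Y")]])
    wsub <- windows[chrom == ych]
    setattr(wsub, "window_size", attr(windows, "window_size"))
    setattr(wsub, "step", attr(windows, "step"))
    kd <- stage("kmer_density", kmer_density(mk, tgt, wsub, k = cfg$k))
    kmer_track <- rbind(
      data.table(chrom = windows[chrom != ych]$chrom,
                 start = windows[chrom != ych]$start,
                 end = windows[chrom != ych]$end, density = 0L),
      kd[, .(chrom, start, end, density)])
    setorder(kmer_track, chrom, start)
  }

  grid <- tracks[order(chrom, start)]
  sdr <- stage("sdr", delineate_sdr(
    grid[, .(chrom, start, end, fst)],
    grid[, .(chrom, start, end, pi = pi_male)],
    grid[, .(chrom, start, end, pi = pi_female)],
    if (!is.null(kmer_track)) kmer_track[order(chrom, start)],
    pi_ratio_min = cfg$pi_ratio_min, min_run = cfg$min_run))
  say("SDR: %s", if (is.null(sdr$interval)) "none" else
    sprintf("%s:%g-%g", sdr$interval$chrom, sdr$interval$start,
            sdr$interval$end))

  degeneration <- NULL
  if (!is.null(genes)) {
    dl <- stage("depth", simulate_depth_and_lof(pop$gm, pop$truth, genes, sim))
    gr <- depth_ratio(dl$gene_depth, pop$gm$samples,
                      norm_exclude = genes$gene[genes$chrom == sim$sdr_chrom])
    flags <- flag_degenerate_genes(gr, cfg$depth_threshold)
    af <- lof_allele_freqs(pop$gm, dl$lof)
    lofr <- fixed_lof(af, f_thresh = cfg$lof_f_thresh,
                      m_thresh = cfg$lof_m_thresh)
    degeneration <- list(genes = flags, lof = lofr)
    pop$truth <- dl$truth
    say("degeneration: %d/%d genes flagged", sum(flags$degenerate, na.rm = TRUE),
        nrow(flags))
  }

  bundle <- list(tracks = tracks, verdicts = verdicts, candidates = cands,
                 inversion_calls = calls, sdr = sdr,
                 degeneration = degeneration, truth = pop$truth,
                 gm = pop$gm, junctions = bc$junctions,
                 seed = sim$seed,
                 config_hash = config_hash(cfg), log = log)
  class(bundle) <- "sdrscan_bundle"
  bundle
}

## sex-specific allele frequencies of annotated LoF variants
lof_allele_freqs <- function(gm, lof) {
  lof <- as.data.table(lof)
  idx <- gm$sites[, which(paste(chrom, pos) %in% lof[, paste(chrom, pos)])]
  males <- gm$samples$sex == "M"; females <- gm$samples$sex == "F"
  af <- function(rows, mask) {
    sub <- gm$geno[rows, mask, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  }
  out <- data.table(chrom = gm$sites$chrom[idx], pos = gm$sites$pos[idx],
                    af_male = af(idx, males), af_female = af(idx, females))
  lof[out, on = c("chrom", "pos")]
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  ## small polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Summarize a pipeline result bundle
#'
#' Prints the heterogamety verdicts, the SDR, and one genotype-frequency
#' table per inversion call with columns Ref/Ref, Ref/Inv, Inv/Inv per sex
#' (the shape of the study-style frequency table); returns the frequency
#' tables invisibly.
#'
#' @param bundle result of [run_pipeline()].
#' @return invisibly, a list of frequency tables.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "sdrscan_bundle"))
  cat("== heterogamety ==\n")
  print(bundle$verdicts[, .(chrom, verdict, region_start, region_end)])
  cat("\n== SDR ==\n")
  if (is.null(bundle$sdr$interval)) cat("(none)\n") else
    cat(sprintf("%s:%g-%g\n", bundle$sdr$interval$chrom,
                bundle$sdr$interval$start, bundle$sdr$interval$end))
  cat("\n== inversions ==\n")
  tabs <- list()
  if (!length(bundle$inversion_calls)) {
    cat("(no inversion calls)\n")
  } else for (cl in bundle$inversion_calls) {
    cat(sprintf("%s:%g-%g  linkage: %s\n", cl$interval$chrom,
                cl$interval$start, cl$interval$end, cl$linkage))
    ft <- cl$freq_table
    colnames(ft) <- c("Ref/Ref", "Ref/Inv", "Inv/Inv")
    n_by_sex <- table(bundle$gm$samples$sex)
    rownames(ft) <- c(sprintf("Female (n = %d)", n_by_sex[["F"]]),
                      sprintf("Male (n = %d)", n_by_sex[["M"]]))
    print(round(ft, 2))
    tabs[[length(tabs) + 1L]] <- ft
  }
  invisible(tabs)
}
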