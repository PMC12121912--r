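#' Write a genotype matrix as VCF v4.2
#'
#' Biallelic SNPs with GT only; internal 0-based positions become 1-based.
#' Missing genotypes are `./.`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (plain text).
#' @param ref,alt optional per-site allele characters (defaults A/T).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, ref = NULL, alt = NULL) {
  sites <- gm$sites
  ref <- ref %||% (if ("ref" %in% names(sites)) sites$ref else
                     rep("A", nrow(sites)))
  alt <- alt %||% (if ("alt" %in% names(sites)) sites$alt else
                     rep("T", nrow(sites)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt_str[is.na(gm$geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sdrscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample), collapse = "\t"))
  body <- if (nrow(sites) == 0) character() else
    paste(sites$chrom, sites$pos + 1, ".", ref, alt, ".", "PASS", ".",
          "GT", apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF of biallelic SNPs into a genotype matrix
#'
#' Uses `VariantAnnotation::readVcf()` when available (the robust path),
#' otherwise a minimal fallback for the package's own GT-only files.
#' Multi-allelic records are dropped with a warning.
#'
#' @param path VCF path.
#' @param sample_table `data.frame(sample, sex, population)`; every VCF
#'   sample must appear in it.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, sample_table) {
  sample_table <- as.data.table(sample_table)
  all_lines <- readLines(path)
  n_records <- sum(!startsWith(all_lines, "#"))
  if (n_records == 0) {
    warning("empty VCF: no variant records")
    hdr <- all_lines[startsWith(all_lines, "#CHROM")]
    vcf_samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
    missing_samples <- setdiff(vcf_samples, sample_table$sample)
    if (length(missing_samples))
      stop("VCF sample(s) absent from sample table: ",
           paste(missing_samples, collapse = ", "))
    return(genotype_matrix(
      matrix(integer(), 0, length(vcf_samples),
             dimnames = list(NULL, vcf_samples)),
      data.table(chrom = character(), pos = numeric(), ref = character(),
                 alt = character()),
      sample_table[match(vcf_samples, sample)]))
  }
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    keep <- lengths(VariantAnnotation::alt(v)) == 1
    if (!all(keep)) {
      warning("dropping multi-allelic records")
      v <- v[keep]
    }
    gt <- VariantAnnotation::geno(v)$GT
    rr <- SummarizedExperiment::rowRanges(v)
    sites <- data.table(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                        pos = BiocGenerics::start(rr) - 1,
                        ref = as.character(rr$REF),
                        alt = as.character(unlist(rr$ALT)))
    vcf_samples <- colnames(gt)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t")[[1]]
    vcf_samples <- cols[-(1:9)]
    body <- lines[!startsWith(lines, "#")]
    if (!length(body)) {
      warning("empty VCF")
      sites <- data.table(chrom = character(), pos = numeric(),
                          ref = character(), alt = character())
      gt <- matrix(character(), 0, length(vcf_samples),
                   dimnames = list(NULL, vcf_samples))
    } else {
      f <- fread(text = body, sep = "\t", header = FALSE)
      keep <- !grepl(",", f[[5]])
      if (!all(keep)) warning("dropping multi-allelic records")
      f <- f[keep]
      sites <- data.table(chrom = as.character(f[[1]]), pos = f[[2]] - 1,
                          ref = f[[4]], alt = f[[5]])
      gt <- as.matrix(f[, -(1:9)])
      colnames(gt) <- vcf_samples
    }
  }
  missing_samples <- setdiff(vcf_samples, sample_table$sample)
  if (length(missing_samples))
    stop("VCF sample(s) absent from sample table: ",
         paste(missing_samples, collapse = ", "))
  to_dosage <- function(x) {
    g <- substr(x, 1, 3)
    out <- rep(NA_integer_, length(x))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- apply(gt, 2, to_dosage)
  if (is.null(dim(geno)))
    geno <- matrix(geno, nrow = nrow(sites),
                   dimnames = list(NULL, vcf_samples))
  if (nrow(sites) == 0) {
    warning("empty VCF: no variant records")
    geno <- matrix(integer(), 0, length(vcf_samples),
                   dimnames = list(NULL, vcf_samples))
  }
  samples <- sample_table[match(vcf_samples, sample)]
  genotype_matrix(geno, sites, samples)
}

#' @rdname read_write_tables
#' @param track window table.
#' @param path file path.
#' @name read_write_tables
#' @title Plain-TSV readers/writers for tracks, sample tables, barcode maps
#' @details Tracks are BED-graph-style TSV (`chrom`, `start`, `end`,
#'   value columns), 0-based half-open.  All writers emit plain text.
#' @export
write_track <- function(track, path) {
  fwrite(as.data.table(track), path, sep = "\t")
  invisible(path)
}

#' @rdname read_write_tables
#' @export
read_track <- function(path) fread(path, sep = "\t")

#' @rdname read_write_tables
#' @param x table to write.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname read_write_tables
#' @export
read_sample_table <- function(path) {
  st <- fread(path, sep = "\t")
  need <- c("sample", "sex")
  if (!all(need %in% names(st)))
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  if (!all(st$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  st
}

#' @rdname read_write_tables
#' @export
read_barcode_map <- function(path) {
  bm <- fread(path, sep = "\t")
  need <- c("sample", "chrom", "window_start", "barcode")
  if (!all(need %in% names(bm)))
    stop("barcode map needs columns: ", paste(need, collapse = ", "))
  bm
}

#' Serialize / parse a pipeline or simulation configuration as JSON
#'
#' Round-trips through `jsonlite`; serialize-parse-serialize is
#' byte-identical.
#'
#' @param cfg configuration list.
#' @param path JSON path.
#' @return [read_config()] returns the list; [write_config()] the path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

#' @rdname write_config
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Load and cross-validate pipeline inputs
#'
#' Reads a VCF + sample table (and optional barcode map) and checks
#' cross-file consistency: VCF samples must be a subset of the sample
#' table; barcode-map samples and chromosomes must match the VCF's.
#'
#' @param vcf,samples,barcode_map file paths (`barcode_map` optional).
#' @return list with `gm` and optional `barcode_map`.
#' @export
load_inputs <- function(vcf, samples, barcode_map = NULL) {
  st <- read_sample_table(samples)
  gm <- read_vcf(vcf, st)
  bm <- NULL
  if (!is.null(barcode_map)) {
    bm <- read_barcode_map(barcode_map)
    extra <- setdiff(unique(bm$sample), st$sample)
    if (length(extra))
      stop("barcode map sample(s) absent from sample table: ",
           paste(extra, collapse = ", "))
    extra_chr <- setdiff(unique(bm$chrom), unique(gm$sites$chrom))
    if (length(extra_chr) && nrow(gm$sites) > 0)
      warning("barcode map chromosomes absent from VCF: ",
              paste(extra_chr, collapse = ", "))
  }
  list(gm = gm, barcode_map = bm)
}
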