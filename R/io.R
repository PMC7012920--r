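#' Write / read the package's tab-separated tables
#'
#' All tables are tab-delimited with a single header line beginning `#`.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_tsv_hash()` returns `path` invisibly; `read_tsv_hash()`
#'   the data.frame.
#' @export
write_tsv_hash <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_hash
#' @export
read_tsv_hash <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  utils::read.table(path, sep = "\t", skip = 1, col.names = cols,
                    stringsAsFactors = FALSE)
}

#' Writers for simulator outputs
#'
#' `write_marker_map()` stores the marker backbone (`chrom`, `pos`,
#' `alleleA`, `alleleB`); `write_genotypes()` stores the genotype matrix one
#' marker per row (`chrom`, `pos`, then one 0/1/2 column per individual,
#' counting parent-B alleles); `write_phenotypes()` stores `individual`,
#' `phenotype`; `write_allele_depths()` stores `chrom`, `pos`, `pool`,
#' `countA`, `countB`.
#'
#' @param ms,pop,depths the objects to serialize.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(ms, path) write_tsv_hash(ms$markers, path)

#' @rdname write_marker_map
#' @export
write_genotypes <- function(pop, path) {
  g <- t(pop$genotypes)
  colnames(g) <- sprintf("ind%03d", seq_len(nrow(pop$genotypes)))
  write_tsv_hash(cbind(pop$marker_set$markers[c("chrom", "pos")],
                       as.data.frame(g)), path)
}

#' @rdname write_marker_map
#' @export
write_phenotypes <- function(pop, path) {
  write_tsv_hash(data.frame(individual = sprintf("ind%03d",
                              seq_along(pop$phenotypes)),
                            phenotype = pop$phenotypes), path)
}

#' @rdname write_marker_map
#' @export
write_allele_depths <- function(depths, path) write_tsv_hash(depths, path)

#' Read an allele-depth table
#'
#' @param path TSV written by [write_allele_depths()] (columns `chrom`,
#'   `pos`, `pool`, `countA`, `countB`).
#' @return The allele-depth data.frame.
#' @export
read_allele_depths <- function(path) {
  x <- read_tsv_hash(path)
  stopifnot(all(c("chrom", "pos", "pool", "countA", "countB") %in% names(x)))
  x
}

#' Write a minimal VCF for a simulated cross
#'
#' Emits a VCFv4.2 file with parent A's allele as REF and parent B's as ALT,
#' the two parents as homozygous GT/DP sample columns, and one sample column
#' per pool carrying GT (missing) plus the AD allele-depth pair, so the
#' real-data entry point of the pipeline can be exercised on synthetic
#' output.
#'
#' @param ms a [marker_set()].
#' @param depths allele-depth data.frame with both pools.
#' @param path output file.
#' @param parent_names,parent_depth names and nominal DP of the parent
#'   columns.
#' @param qual QUAL value written for every record (default 60).
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(ms, depths, path,
                           parent_names = c("parentA", "parentB"),
                           parent_depth = 30, qual = 60) {
  pools <- unique(depths$pool)
  stopifnot(length(pools) == 2)
  key <- paste(depths$chrom, depths$pos)
  mk <- ms$markers
  mkey <- paste(mk$chrom, mk$pos)
  ad <- function(p) {
    d <- depths[depths$pool == p, ]
    i <- match(mkey, paste(d$chrom, d$pos))
    sprintf("./.:.:%d,%d", d$countA[i], d$countB[i])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>",
                       ms$chromosomes$chrom, ms$chromosomes$length),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", parent_names, pools),
                     collapse = "\t")), con)
  body <- paste(mk$chrom, mk$pos, ".", mk$alleleA, mk$alleleB, qual, "PASS",
                ".", "GT:DP:AD",
                sprintf("0/0:%d:.", parent_depth),
                sprintf("1/1:%d:.", parent_depth),
                ad(pools[1]), ad(pools[2]), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read pool allele depths from a VCF
#'
#' Extracts the AD field of the two pool sample columns of a VCF (as written
#' by [write_pool_vcf()], or any biallelic VCF with pool AD fields) into the
#' allele-depth table layout.
#'
#' @param path VCF file.
#' @param pool_samples names of the two pool sample columns.
#' @param pool_labels labels for the output `pool` column (default
#'   `c("high", "low")`, matched to `pool_samples` order).
#' @return Allele-depth data.frame (`chrom`, `pos`, `pool`, `countA`,
#'   `countB`).
#' @export
read_pool_vcf <- function(path, pool_samples = c("high", "low"),
                          pool_labels = pool_samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  missing <- setdiff(pool_samples, colnames(ad))
  if (length(missing))
    stop("VCF lacks pool sample column(s): ", paste(missing, collapse = ", "))
  out <- lapply(seq_along(pool_samples), function(i) {
    parts <- strsplit(ad[, pool_samples[i]], ",", fixed = TRUE)
    data.frame(chrom = as.character(v@fix[, "CHROM"]),
               pos = as.numeric(v@fix[, "POS"]),
               pool = pool_labels[i],
               countA = as.integer(vapply(parts, `[`, "", 1)),
               countB = as.integer(vapply(parts, `[`, "", 2)))
  })
  do.call(rbind, out)
}

#' Filter parental variants to informative homozygous SNP markers
#'
#' Applies the standard parental-line marker filters: records are flagged
#' (and fail) when QUAL is below `min_qual` or missing, when either parent's
#' DP is below `min_depth` or missing, when the record is multi-allelic,
#' when either parent is heterozygous or has a missing genotype, or when
#' both parents are homozygous for the same allele (not polymorphic).
#' Retained sites are biallelic, homozygous in both parents, and polymorphic
#' between them.
#'
#' @param vcf a `vcfR` object or a VCF file path with both parent samples.
#' @param parent_a,parent_b parent sample names (defaults `"parentA"`,
#'   `"parentB"`).
#' @param min_qual minimum QUAL (default 10).
#' @param min_depth minimum per-parent DP (default 5).
#' @return A `parental_variants` data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `gt_a`, `gt_b`, `dp_a`, `dp_b`, one logical flag column per
#'   rule (`low_qual`, `low_depth`, `multiallelic`, `heterozygous`,
#'   `non_polymorphic`) and `pass`.
#' @export
filter_parent_variants <- function(vcf, parent_a = "parentA",
                                   parent_b = "parentB",
                                   min_qual = 10, min_depth = 5) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, "GT")
  for (p in c(parent_a, parent_b))
    if (!p %in% colnames(gt))
      stop("VCF lacks parent sample column: ", p)
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  qual <- suppressWarnings(as.numeric(vcf@fix[, "QUAL"]))
  alt <- as.character(vcf@fix[, "ALT"])

  split_gt <- function(g) strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
  ga <- split_gt(gt[, parent_a])
  gb <- split_gt(gt[, parent_b])
  is_het <- function(g) vapply(g, function(a)
    length(a) != 2 || anyNA(a) || any(a == ".") || a[1] != a[2], logical(1))
  hom_allele <- function(g) vapply(g, function(a)
    if (length(a) == 2 && !anyNA(a) && all(a != ".") && a[1] == a[2])
      a[1] else NA_character_, character(1))

  low_qual <- is.na(qual) | qual < min_qual
  dpa <- dp[, parent_a]
  dpb <- dp[, parent_b]
  low_depth <- is.na(dpa) | is.na(dpb) | dpa < min_depth | dpb < min_depth
  multiallelic <- grepl(",", alt, fixed = TRUE)
  heterozygous <- is_het(ga) | is_het(gb)
  aa <- hom_allele(ga)
  ab <- hom_allele(gb)
  non_polymorphic <- !is.na(aa) & !is.na(ab) & aa == ab

  out <- data.frame(chrom = as.character(vcf@fix[, "CHROM"]),
                    pos = as.numeric(vcf@fix[, "POS"]),
                    ref = as.character(vcf@fix[, "REF"]),
                    alt = alt, qual = qual,
                    gt_a = gt[, parent_a], gt_b = gt[, parent_b],
                    dp_a = dpa, dp_b = dpb,
                    low_qual = low_qual, low_depth = low_depth,
                    multiallelic = multiallelic,
                    heterozygous = heterozygous,
                    non_polymorphic = non_polymorphic)
  out$pass <- !(low_qual | low_depth | multiallelic | heterozygous |
                non_polymorphic)
  rownames(out) <- NULL
  class(out) <- c("parental_variants", "data.frame")
  out
}

#' Write window statistics as a BED-compatible table
#'
#' First three columns are `chrom`, 0-based `start`, `end` (half-open, as in
#' BED); the remaining statistic columns follow unchanged.
#'
#' @param windows a `window_stats` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(windows, path) {
  out <- as.data.frame(windows)
  out$start <- out$start - 1
  write_tsv_hash(out, path)
}
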