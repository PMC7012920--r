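#' Construct a marker set
#'
#' A marker set is the coordinate backbone of the pipeline: an ordered map of
#' biallelic SNPs segregating between two homozygous parents ("A" and "B"),
#' laid out over a set of named chromosomes.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp, numeric).
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp),
#'   `alleleA`, `alleleB` (single nucleotides). Positions must be strictly
#'   increasing within each chromosome and every `chrom` must appear in
#'   `chromosomes`.
#' @return An object of class `marker_set`: a list with elements
#'   `chromosomes` and `markers` (markers ordered by chromosome, position).
#' @export
marker_set <- function(chromosomes, markers) {
  chromosomes <- as.data.frame(chromosomes)
  markers <- as.data.frame(markers)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            all(c("chrom", "pos", "alleleA", "alleleB") %in% names(markers)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names")
  bad <- setdiff(unique(markers$chrom), chromosomes$chrom)
  if (length(bad))
    stop("markers on unknown chromosome(s): ", paste(bad, collapse = ", "))
  ord <- order(match(markers$chrom, chromosomes$chrom), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  incr <- unlist(tapply(markers$pos, factor(markers$chrom, chromosomes$chrom),
                        function(p) length(p) > 1 && any(diff(p) <= 0)),
                 use.names = FALSE)
  if (any(incr, na.rm = TRUE))
    stop("marker positions must be strictly increasing within a chromosome")
  if (any(markers$alleleA == markers$alleleB))
    stop("alleleA and alleleB must differ at every marker")
  if (any(markers$pos < 1) || any(markers$pos >
        chromosomes$length[match(markers$chrom, chromosomes$chrom)]))
    stop("marker positions must lie within the chromosome")
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "marker_set")
}

#' Default synthetic marker map
#'
#' A desk-scale stand-in for a dense parental SNP map: `n_chrom` chromosomes
#' of equal length carrying uniformly spaced markers. Allele pairs alternate
#' deterministically (A/G, C/T) so no random number generation is involved.
#'
#' @param n_chrom number of chromosomes (default 10).
#' @param chrom_length chromosome length in bp (default 30 Mb).
#' @param markers_per_chrom markers per chromosome (default 5000).
#' @return A [marker_set()].
#' @export
default_marker_set <- function(n_chrom = 10, chrom_length = 30e6,
                               markers_per_chrom = 5000) {
  stopifnot(n_chrom >= 1, chrom_length >= markers_per_chrom,
            markers_per_chrom >= 1)
  chroms <- data.frame(chrom = sprintf("A%02d", seq_len(n_chrom)),
                       length = rep(chrom_length, n_chrom))
  pos <- round(seq_len(markers_per_chrom) *
               (chrom_length / (markers_per_chrom + 1)))
  pair <- (seq_len(markers_per_chrom) %% 2) == 1
  mk <- data.frame(
    chrom = rep(chroms$chrom, each = markers_per_chrom),
    pos = rep(pos, n_chrom),
    alleleA = rep(ifelse(pair, "A", "C"), n_chrom),
    alleleB = rep(ifelse(pair, "G", "T"), n_chrom))
  marker_set(chroms, mk)
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers\n")
  invisible(x)
}

n_markers <- function(ms) nrow(ms$markers)
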