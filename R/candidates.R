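#' Read gene models from a GFF3 file
#'
#' Thin wrapper around [rtracklayer::import()] that keeps one row per
#' feature of the requested type. GFF3 coordinates are 1-based inclusive and
#' are kept as such.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return A gene annotation data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == feature]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(id)) id <- sprintf("%s_%d", feature, seq_along(gr))
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Packaged anthocyanin-pathway gene table
#'
#' Curated table of anthocyanin-biosynthesis regulators of *Brassica rapa*
#' used to annotate candidate genes: the negative regulator *BrMYBL2.1* and
#' the positive regulators *BrEGL3.1* / *BrEGL3.2*, with their gene-body
#' coordinates. The table is user-extensible: pass your own data.frame with
#' the same columns wherever a `pathway_table` argument is accepted.
#'
#' @return data.frame: `gene_id`, `pathway_role`, `chrom`, `start`, `end`.
#' @export
anthocyanin_genes <- function() {
  path <- system.file("extdata", "anthocyanin_pathway_genes.tsv",
                      package = "poolmap")
  read_tsv_hash(path)
}

#' Attach pathway roles to a gene annotation
#'
#' @param annotation gene annotation data.frame (`gene_id`, ...).
#' @param pathway_table data.frame with `gene_id` and `pathway_role`
#'   (default [anthocyanin_genes()]).
#' @return `annotation` with a `pathway_role` column (`"none"` where the
#'   gene is not in the table).
#' @export
annotate_pathway <- function(annotation, pathway_table = anthocyanin_genes()) {
  i <- match(annotation$gene_id, pathway_table$gene_id)
  annotation$pathway_role <- ifelse(is.na(i), "none",
                                    pathway_table$pathway_role[i])
  annotation
}

interval_bounds <- function(interval) {
  if (inherits(interval, "candidate_interval") || is.data.frame(interval)) {
    list(chrom = interval$chrom[1],
         start = if (!is.null(interval$refined_start))
           interval$refined_start[1] else interval$start[1],
         end = if (!is.null(interval$refined_end))
           interval$refined_end[1] else interval$end[1])
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(interval)))
    interval
  }
}

#' Genes overlapping a candidate interval
#'
#' Returns annotation genes overlapping the interval's refined bounds by at
#' least `min_overlap` bp, sorted by start. Overlap is computed with
#' [GenomicRanges::findOverlaps()] on 1-based inclusive coordinates.
#'
#' @param interval a `candidate_interval` (refined bounds are used) or a
#'   list/data.frame with `chrom`, `start`, `end`.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`, optionally `strand`, `pathway_role`).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return The overlapping annotation rows, sorted by `start`. A chromosome
#'   absent from the annotation yields an empty result with a warning.
#' @export
genes_in_interval <- function(interval, annotation, min_overlap = 1) {
  b <- interval_bounds(interval)
  annotation <- as.data.frame(annotation)
  if (!nrow(annotation)) return(annotation)
  if (!b$chrom %in% annotation$chrom) {
    warning("chromosome ", b$chrom, " absent from the annotation")
    return(annotation[0, , drop = FALSE])
  }
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end))
  q <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  hits <- GenomicRanges::findOverlaps(q, genes, minoverlap = min_overlap)
  out <- annotation[S4Vectors::subjectHits(hits), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked candidate-gene report
#'
#' Joins candidate intervals, their overlapping genes, pathway roles, and
#' depth-dip calls contained in gene bodies into one ranked table. Genes
#' with both a pathway role and an in-body dip rank first, then
#' pathway-role-only genes, then dip-only genes, then the rest; within a
#' rank genes are ordered by position.
#'
#' @param intervals one `candidate_interval` or a data.frame of several.
#' @param dipcalls a `dip_calls` data.frame (may have zero rows).
#' @param annotation gene annotation data.frame; a `pathway_role` column is
#'   added from [anthocyanin_genes()] when absent.
#' @param pathway_table passed to [annotate_pathway()] when needed.
#' @param min_overlap minimum gene/interval overlap in bp (default 1).
#' @return data.frame: `interval`, `gene_id`, `chrom`, `start`, `end`,
#'   `pathway_role`, `has_dip`, `rank`.
#' @export
report_candidates <- function(intervals, dipcalls = NULL, annotation,
                              pathway_table = anthocyanin_genes(),
                              min_overlap = 1) {
  annotation <- as.data.frame(annotation)
  if (is.null(annotation$pathway_role))
    annotation <- annotate_pathway(annotation, pathway_table)
  rows <- list()
  for (i in seq_len(nrow(as.data.frame(intervals)))) {
    iv <- as.data.frame(intervals)[i, , drop = FALSE]
    b <- interval_bounds(iv)
    hits <- genes_in_interval(b, annotation, min_overlap)
    if (!nrow(hits)) next
    has_dip <- vapply(seq_len(nrow(hits)), function(j) {
      !is.null(dipcalls) && nrow(dipcalls) > 0 &&
        any(dipcalls$chrom == hits$chrom[j] &
            dipcalls$start >= hits$start[j] &
            dipcalls$end <= hits$end[j])
    }, logical(1))
    role <- hits$pathway_role != "none"
    rank <- ifelse(role & has_dip, 1L,
                   ifelse(role, 2L, ifelse(has_dip, 3L, 4L)))
    rows[[length(rows) + 1]] <- data.frame(
      interval = sprintf("%s:%d-%d", b$chrom, b$start, b$end),
      gene_id = hits$gene_id, chrom = hits$chrom,
      start = hits$start, end = hits$end,
      pathway_role = hits$pathway_role,
      has_dip = has_dip, rank = rank)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(interval = character(0), gene_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               pathway_role = character(0), has_dip = logical(0),
               rank = integer(0))
  out <- out[order(out$rank, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
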