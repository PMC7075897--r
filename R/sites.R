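#' Construct a site set
#'
#' Genomic intervals (peaks, enhancers, TSSs) held as a `GRanges`.  Input
#' coordinates follow BED conventions (0-based half-open); the stored
#' `GRanges` is 1-based as usual in Bioconductor.  An optional per-site
#' summit (absolute bp) is kept as metadata and used as the pile-up anchor
#' when present.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval coordinates (`start < end`).
#' @param summit optional absolute summit positions in bp (`NA` where
#'   unknown).
#' @param name optional set name.
#' @return A `GRanges` with optional `summit` metadata column.
#' @export
site_set <- function(chrom, start, end, summit = NULL, name = NULL) {
  if (any(start >= end)) stopf("site intervals need start < end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (!is.null(summit)) gr$summit <- summit
  if (!is.null(name)) S4Vectors::metadata(gr)$name <- name
  gr
}

#' Read a site set from BED or narrowPeak
#'
#' narrowPeak files (detected by extension or `format = "narrowPeak"`)
#' contribute their column-10 summit offset as an absolute summit position;
#' a value of -1 (no summit called) becomes `NA`.
#'
#' @param path BED3/BED6 or narrowPeak file.
#' @param format `"auto"`, `"bed"` or `"narrowPeak"`.
#' @return A `GRanges` (see [site_set()]).
#' @export
read_sites <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
    gr$summit <- ifelse(gr$peak >= 0,
                        GenomicRanges::start(gr) - 1L + gr$peak, NA)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  gr
}

#' Anchor point of each site
#'
#' The summit where one is recorded, otherwise the interval midpoint
#' (0-based bp).
#'
#' @param sites a `GRanges` site set.
#' @return Numeric vector of anchor positions in bp.
#' @export
site_anchors <- function(sites) {
  mid <- (GenomicRanges::start(sites) - 1 + GenomicRanges::end(sites)) / 2
  if (!is.null(sites$summit)) ifelse(is.na(sites$summit), mid, sites$summit)
  else mid
}

#' Overlap between two peak sets
#'
#' Counts how many intervals of each set share at least one bp with any
#' interval of the other.
#'
#' @param a,b `GRanges` site sets.
#' @return List with `count_a`, `count_b`, `overlapping_a`, `overlapping_b`.
#' @export
peak_overlap <- function(a, b) {
  list(count_a = length(a), count_b = length(b),
       overlapping_a = sum(GenomicRanges::countOverlaps(a, b) > 0),
       overlapping_b = sum(GenomicRanges::countOverlaps(b, a) > 0))
}

#' Construct gene models
#'
#' @param gene_id character vector of identifiers.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes transcription start/end sites in bp (for minus-strand
#'   genes `tss > tes`).
#' @param exons list (one element per gene) of two-column matrices of
#'   0-based half-open exon intervals, non-overlapping and sorted.
#' @return A `gene_models` data.frame with a list-column of exons.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tes, exons) {
  stopifnot(all(strand %in% c("+", "-")), length(exons) == length(gene_id))
  for (i in seq_along(exons)) {
    ex <- exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2) stopf("exons[[%d]] must be a 2-column matrix", i)
    if (any(ex[, 1] >= ex[, 2])) stopf("gene %s: empty exon", gene_id[i])
    if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1)
      stopf("gene %s: exons must be sorted", gene_id[i])
    if (nrow(ex) > 1 && any(ex[-nrow(ex), 2] > ex[-1, 1]))
      stopf("gene %s: overlapping exons", gene_id[i])
  }
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = tss, tes = tes)
  df$exons <- exons
  structure(df, class = c("gene_models", "data.frame"))
}

#' Read gene models from a BED12 file
#'
#' Exon blocks come from the block columns; strand from column 6.  The TSS
#' is the 5' end of the interval on the annotated strand.
#'
#' @param path BED12 file.
#' @return A [gene_models()] data.frame.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$blocks)) stopf("'%s' has no exon blocks (need BED12)", path)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  exons <- lapply(seq_along(gr), function(i) {
    bl <- gr$blocks[[i]]
    cbind(start0[i] + GenomicRanges::start(bl) - 1L,
          start0[i] + GenomicRanges::end(bl))
  })
  gene_models(gene_id = if (!is.null(gr$name)) gr$name else
                paste0("gene", seq_along(gr)),
              chrom = as.character(GenomicRanges::seqnames(gr)),
              strand = strand,
              tss = ifelse(strand == "+", start0, end0),
              tes = ifelse(strand == "+", end0, start0),
              exons = exons)
}
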