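#' Binned genome coverage track
#'
#' A fixed-bin-size container for per-chromosome coverage (raw read counts,
#' normalised coverage, or a ChIP/input enrichment ratio).  Each chromosome
#' holds `ceiling(length / bin_size)` bins.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param kind `"coverage"` for read-derived tracks, `"enrichment"` for a
#'   ratio track.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(values, bin_size, chrom_sizes, kind = "coverage") {
  stopifnot(is.list(values), bin_size > 0, length(chrom_sizes) > 0,
            !is.null(names(chrom_sizes)))
  if (!setequal(names(values), names(chrom_sizes)))
    stopf("track chromosomes do not match chrom_sizes")
  values <- values[names(chrom_sizes)]
  for (ch in names(chrom_sizes)) {
    nb <- n_bins(chrom_sizes[[ch]], bin_size)
    v <- values[[ch]]
    if (length(v) != nb)
      stopf("chromosome '%s': expected %d bins, got %d", ch, nb, length(v))
    if (any(!is.finite(v)))
      stopf("chromosome '%s': non-finite bin values", ch)
    if (kind == "coverage" && any(v < 0))
      stopf("chromosome '%s': negative coverage", ch)
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, kind = kind),
            class = "coverage_track")
}

n_bins <- function(chrom_length, bin_size) as.integer(ceiling(chrom_length / bin_size))

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track:%s> bin %d bp; %d chromosome(s), %d bins\n",
              x$kind, x$bin_size, length(x$values),
              sum(lengths(x$values))))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' @param path two-column tab-separated file: chromosome name, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "size"))
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Read a binned bedGraph file into a coverage track
#'
#' Intervals are imported with rtracklayer and projected onto the fixed bin
#' grid; each bin takes the score of the interval covering its start (the
#' writer emits exactly bin-aligned intervals, so round-trips are exact).
#'
#' @param path bedGraph file.
#' @inheritParams coverage_track
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes, kind = "coverage") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(names(chrom_sizes), function(ch) {
    nb <- n_bins(chrom_sizes[[ch]], bin_size)
    v <- numeric(nb)
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(sel)) {
      starts <- GenomicRanges::start(sel) - 1L   # back to 0-based
      ends <- GenomicRanges::end(sel)
      for (k in seq_along(sel)) {
        i0 <- starts[k] %/% bin_size + 1L
        i1 <- min(nb, as.integer(ceiling(ends[k] / bin_size)))
        v[i0:i1] <- sel$score[k]
      }
    }
    v
  })
  names(values) <- names(chrom_sizes)
  coverage_track(values, bin_size, chrom_sizes, kind)
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    starts <- (seq_along(v) - 1L) * track$bin_size
    ends <- pmin(starts + track$bin_size, track$chrom_sizes[[ch]])
    data.frame(chrom = ch, start = starts + 1L, end = ends, score = v)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' RPGC (1x genomic content) normalisation parameters
#'
#' @param total_mapped_reads total mapped reads in the library.
#' @param fragment_length sequenced-fragment length in bp.
#' @param effective_genome_size mappable genome size in bp; the default is
#'   the conventional value for the Drosophila genome.
#' @return An `rpgc_params` list.
#' @export
rpgc_params <- function(total_mapped_reads, fragment_length,
                        effective_genome_size = 120e6) {
  if (total_mapped_reads <= 0 || fragment_length <= 0 ||
      effective_genome_size <= 0)
    stopf("all RPGC parameters must be positive")
  structure(list(total_mapped_reads = total_mapped_reads,
                 fragment_length = fragment_length,
                 effective_genome_size = effective_genome_size),
            class = "rpgc_params")
}

#' Normalise a raw-count track to 1x genomic content (RPGC)
#'
#' Each bin's read count is divided by the expected per-base coverage,
#' `total_mapped_reads * fragment_length / effective_genome_size`, so a
#' uniformly covered genome normalises to 1 everywhere.
#'
#' @param track a [coverage_track()] of raw reads per bin.
#' @param params an [rpgc_params()].
#' @return A [coverage_track()] of normalised coverage.
#' @export
rpgc_normalize <- function(track, params) {
  stopifnot(inherits(track, "coverage_track"), inherits(params, "rpgc_params"))
  scale <- params$total_mapped_reads * params$fragment_length /
    params$effective_genome_size
  coverage_track(lapply(track$values, function(v) v / scale),
                 track$bin_size, track$chrom_sizes, kind = "coverage")
}

#' ChIP enrichment over input
#'
#' Per-bin ratio `(chip + pseudocount) / (input + pseudocount)` of two
#' tracks with identical geometry, both conventionally RPGC-normalised
#' first so the pseudocount acts on the 1x-coverage scale.
#'
#' @param chip,input [coverage_track()]s with identical bin size and
#'   chromosomes.
#' @param pseudocount value added to numerator and denominator (default 1).
#' @return A [coverage_track()] with `kind = "enrichment"`.
#' @export
enrichment_over_input <- function(chip, input, pseudocount = 1) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_size != input$bin_size)
    stopf("bin sizes differ (%d vs %d)", chip$bin_size, input$bin_size)
  for (ch in union(names(chip$values), names(input$values)))
    if (is.null(chip$values[[ch]]) || is.null(input$values[[ch]]) ||
        length(chip$values[[ch]]) != length(input$values[[ch]]))
      stopf("geometry mismatch on chromosome '%s'", ch)
  vals <- Map(function(a, b) (a + pseudocount) / (b + pseudocount),
              chip$values, input$values)
  coverage_track(vals, chip$bin_size, chip$chrom_sizes, kind = "enrichment")
}
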