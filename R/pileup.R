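#' Site-centred pile-up profile of an enrichment track
#'
#' Every site contributes the window `[anchor - flank, anchor + flank)`
#' around its anchor (summit if recorded, interval midpoint otherwise), at
#' the track's bin resolution.  The per-column summary is the median (robust
#' display of binding-level distributions) or the mean.  Sites whose window
#' would leave the chromosome are dropped with a logged count; heatmap rows
#' are ordered by descending row mean.
#'
#' @param track an enrichment [coverage_track()].
#' @param sites a `GRanges` site set (see [site_set()]).
#' @param flank half-window in bp; must be a positive multiple of the
#'   track's bin size (default 2000).
#' @param stat `"median"` or `"mean"`.
#' @return A `pileup_profile`: list with `matrix` (sites x positions),
#'   `summary`, `positions` (bp offsets of bin starts from the anchor),
#'   `stat` and `n_dropped`.
#' @export
site_pileup <- function(track, sites, flank = 2000, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(track, "coverage_track"))
  if (length(sites) == 0) stopf("no usable sites")
  bs <- track$bin_size
  if (flank <= 0 || flank %% bs != 0)
    stopf("flank must be a positive multiple of the bin size (%d bp)", bs)
  k <- flank %/% bs
  anchors <- site_anchors(sites)
  chroms <- as.character(GenomicRanges::seqnames(sites))
  rows <- vector("list", length(sites))
  used <- logical(length(sites))
  for (i in seq_along(sites)) {
    v <- track$values[[chroms[i]]]
    if (is.null(v)) next
    ib <- as.integer(anchors[i] %/% bs) + 1L
    lo <- ib - k; hi <- ib + k - 1L
    if (lo < 1L || hi > length(v)) next
    rows[[i]] <- v[lo:hi]
    used[i] <- TRUE
  }
  if (!any(used)) stopf("no usable sites")
  n_dropped <- sum(!used)
  if (n_dropped > 0) msg(n_dropped, " site(s) dropped at chromosome bounds")
  m <- do.call(rbind, rows[used])
  ord <- order(rowMeans(m), decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- which(used)[ord]
  positions <- seq(-flank, flank - bs, by = bs)
  new_pileup_profile(m, positions, stat, n_dropped)
}

new_pileup_profile <- function(m, positions, stat, n_dropped = 0L) {
  summary <- apply(m, 2L, if (stat == "median") median else mean)
  structure(list(matrix = m, summary = summary, positions = positions,
                 stat = stat, n_dropped = n_dropped),
            class = "pileup_profile")
}

#' @export
print.pileup_profile <- function(x, ...) {
  cat(sprintf("<pileup_profile> %d sites x %d positions (%s); peak summary %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$stat, max(x$summary)))
  invisible(x)
}

#' Write a pile-up profile (or its heatmap matrix) as TSV
#'
#' @param profile a `pileup_profile`.
#' @param path output TSV; columns are positions, first row the summary,
#'   remaining rows the per-site matrix.
#' @return `path`, invisibly.
#' @export
write_pileup_profile <- function(profile, path) {
  out <- rbind(summary = profile$summary, profile$matrix)
  colnames(out) <- profile$positions
  write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Metagene profile over exon-concatenated gene bodies
#'
#' For each gene the exonic bins are concatenated 5' to 3' (introns
#' ignored; minus-strand genes reversed), linearly rescaled to `body_bins`
#' columns, and flanked by unscaled windows upstream of the TSS and
#' downstream of the TES.  Genes whose flanks leave the chromosome or with
#' zero exonic bins are skipped with a warning count.
#'
#' @param track an enrichment [coverage_track()].
#' @param genes a [gene_models()] data.frame.
#' @param body_bins number of rescaled gene-body columns (default 100).
#' @param flank flank size in bp, a multiple of the bin size (default 2000).
#' @param stat `"mean"` or `"median"`.
#' @return A `pileup_profile`; `positions` are `-flank..-1` bp offsets for
#'   the upstream columns, `1..body_bins` metagene coordinates for the
#'   body, and `+1..+flank` offsets downstream.
#' @export
metagene_profile <- function(track, genes, body_bins = 100, flank = 2000,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(track, "coverage_track"), nrow(genes) > 0, body_bins >= 2)
  bs <- track$bin_size
  if (flank %% bs != 0 || flank <= 0)
    stopf("flank must be a positive multiple of the bin size (%d bp)", bs)
  k <- flank %/% bs
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    v <- track$values[[genes$chrom[i]]]
    if (is.null(v)) { skipped <- skipped + 1L; next }
    ex <- genes$exons[[i]]
    exon_bins <- unlist(lapply(seq_len(nrow(ex)), function(j) {
      lo <- as.integer(ex[j, 1] %/% bs) + 1L
      hi <- as.integer((ex[j, 2] - 1) %/% bs) + 1L
      lo:hi
    }))
    exon_bins <- unique(exon_bins)
    minus <- genes$strand[i] == "-"
    # TSS/TES follow half-open convention: for minus-strand genes the TSS
    # coordinate is the exclusive right edge, so the TSS base is tss - 1.
    tssb <- as.integer((genes$tss[i] - minus) %/% bs) + 1L
    tesb <- as.integer((genes$tes[i] - !minus) %/% bs) + 1L
    up <- if (minus) (tssb + 1L):(tssb + k) else (tssb - k):(tssb - 1L)
    down <- if (minus) (tesb - k):(tesb - 1L) else (tesb + 1L):(tesb + k)
    if (length(exon_bins) == 0 || min(up, down, exon_bins) < 1L ||
        max(up, down, exon_bins) > length(v)) {
      skipped <- skipped + 1L; next
    }
    body <- v[exon_bins]
    upstream <- v[up]; downstream <- v[down]
    if (minus) { body <- rev(body); upstream <- rev(upstream); downstream <- rev(downstream) }
    body <- rescale_vector(body, body_bins)
    rows[[length(rows) + 1L]] <- c(upstream, body, downstream)
  }
  if (skipped > 0)
    warning(sprintf("%d gene(s) skipped (no exonic bins or out of bounds)", skipped),
            call. = FALSE)
  if (length(rows) == 0) stopf("no usable genes")
  m <- do.call(rbind, rows)
  positions <- c(seq(-flank, -bs, by = bs), seq_len(body_bins),
                 seq(bs, flank, by = bs))
  new_pileup_profile(m, positions, stat, skipped)
}

# Linear rescaling of a vector to n columns: sample the piecewise-linear
# interpolant of the bin values at n evenly spaced metagene coordinates.
# Identity when length(x) == n.
rescale_vector <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = n))$y
}
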