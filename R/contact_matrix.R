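#' Binned cis contact matrix for one chromosome
#'
#' A dense symmetric matrix of observed (or balanced) contact counts at a
#' fixed bin size, the container the aggregate pile-up analyses operate on.
#'
#' @param matrix square numeric matrix of non-negative contact values.
#' @param bin_size bin width in bp (the analyses conventionally use 5 kb).
#' @param chrom chromosome name.
#' @param balanced logical flag recording whether the values were balanced
#'   upstream; purely informational, no balancing is performed here.
#' @param tol symmetry tolerance (relative).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(matrix, bin_size, chrom, balanced = FALSE,
                           tol = 1e-8) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix), bin_size > 0)
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stopf("contact matrix must be finite and non-negative")
  if (max(abs(matrix - t(matrix))) > tol * max(1, max(abs(matrix))))
    stopf("contact matrix is not symmetric")
  structure(list(matrix = matrix, bin_size = as.integer(bin_size),
                 chrom = as.character(chrom), balanced = isTRUE(balanced)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d x %d bins of %d bp (%s)\n",
              x$chrom, nrow(x$matrix), ncol(x$matrix), x$bin_size,
              if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' Read contact matrices from triplet text
#'
#' Format: tab-separated `chrom  bin_i  bin_j  value` with 0-based bin
#' indices and only the upper triangle (`bin_i <= bin_j`) stored; the matrix
#' is mirrored on load.
#'
#' @param path triplet file.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths (fixes the matrix
#'   dimension per chromosome).
#' @param balanced see [contact_matrix()].
#' @return Named list of [contact_matrix()] objects, one per chromosome.
#' @export
read_contact_matrices <- function(path, bin_size, chrom_sizes,
                                  balanced = FALSE) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "bin_i", "bin_j", "value"))
  out <- lapply(names(chrom_sizes), function(ch) {
    n <- n_bins(chrom_sizes[[ch]], bin_size)
    m <- base::matrix(0, n, n)
    sel <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sel)) {
      if (any(sel$bin_i < 0 | sel$bin_i >= n | sel$bin_j < 0 | sel$bin_j >= n))
        stopf("bin index out of range on chromosome '%s'", ch)
      i <- sel$bin_i + 1L; j <- sel$bin_j + 1L
      m[cbind(i, j)] <- sel$value
      m[cbind(j, i)] <- sel$value
    }
    contact_matrix(m, bin_size, ch, balanced)
  })
  stats::setNames(out, names(chrom_sizes))
}

#' Write contact matrices as triplet text
#'
#' Only non-zero upper-triangle entries are written.
#'
#' @param matrices a [contact_matrix()] or named list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_matrices <- function(matrices, path) {
  if (inherits(matrices, "contact_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(cm) {
    idx <- which(upper.tri(cm$matrix, diag = TRUE) & cm$matrix != 0,
                 arr.ind = TRUE)
    data.frame(chrom = cm$chrom, bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
               value = cm$matrix[idx])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$bin_i, df$bin_j), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
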