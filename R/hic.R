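#' Configuration for average-loop pile-ups
#'
#' Defaults follow the conventional aggregate-peak-analysis setup on 5 kb
#' matrices: a +/-100 kb pad around the loop pixel, ten randomly shifted
#' control regions for local-background normalisation, and the central
#' 3x3-pixel mean as the loop-strength statistic.
#'
#' @param pad half-window around the loop pixel in bp; must be a multiple
#'   of the matrix bin size.
#' @param n_controls shifted control replicates per pair (0 disables
#'   background normalisation).
#' @param center_size odd side length of the central block averaged for
#'   loop strength.
#' @param max_separation maximum anchor separation in bp considered a loop
#'   (default 1 Mb).
#' @param seed integer seed for the control shifts.
#' @return A `loop_pileup_config` list.
#' @export
loop_pileup_config <- function(pad = 100e3, n_controls = 10, center_size = 3,
                               max_separation = 1e6, seed = 1L) {
  stopifnot(pad > 0, n_controls >= 0, center_size %% 2 == 1,
            max_separation > 0)
  structure(list(pad = pad, n_controls = as.integer(n_controls),
                 center_size = as.integer(center_size),
                 max_separation = max_separation, seed = as.integer(seed)),
            class = "loop_pileup_config")
}

#' Configuration for rescaled local contact-domain pile-ups
#'
#' @param rescale_size odd pixel side of the rescaled window (default 99).
#' @param n_controls shifted control replicates (default 10).
#' @param min_anchor_distance only peak-feature pairs farther apart than
#'   this (bp) form a domain region (default 25 kb).
#' @param seed integer seed for the control shifts.
#' @return A `domain_pileup_config` list.
#' @export
domain_pileup_config <- function(rescale_size = 99, n_controls = 10,
                                 min_anchor_distance = 25e3, seed = 1L) {
  stopifnot(rescale_size %% 2 == 1, rescale_size >= 3, n_controls >= 0)
  structure(list(rescale_size = as.integer(rescale_size),
                 n_controls = as.integer(n_controls),
                 min_anchor_distance = min_anchor_distance,
                 seed = as.integer(seed)),
            class = "domain_pileup_config")
}

#' All pairwise cis anchor pairs under a separation cap
#'
#' Anchors are collapsed to interval midpoints; every cross-set same-
#' chromosome pair with separation in `(0, max_separation)` is emitted.
#' When `bin_size` is given, pairs landing in the same bin pair are
#' de-duplicated.
#'
#' @param anchors_a,anchors_b `GRanges` site sets.
#' @param max_separation maximum separation in bp (default 1 Mb).
#' @param bin_size optional bin size used to remove duplicate bin pairs.
#' @return data.frame with `chrom`, `pos_a`, `pos_b` (`pos_a < pos_b`) and
#'   `separation`.
#' @export
make_loop_pairs <- function(anchors_a, anchors_b, max_separation = 1e6,
                            bin_size = NULL) {
  stopifnot(length(anchors_a) > 0, length(anchors_b) > 0)
  ca <- as.character(GenomicRanges::seqnames(anchors_a))
  cb <- as.character(GenomicRanges::seqnames(anchors_b))
  ma <- site_anchors(anchors_a); mb <- site_anchors(anchors_b)
  idx <- expand.grid(i = seq_along(ma), j = seq_along(mb))
  same <- ca[idx$i] == cb[idx$j]
  idx <- idx[same, , drop = FALSE]
  pos_a <- pmin(ma[idx$i], mb[idx$j])
  pos_b <- pmax(ma[idx$i], mb[idx$j])
  sep <- pos_b - pos_a
  keep <- sep > 0 & sep < max_separation
  out <- data.frame(chrom = ca[idx$i], pos_a = pos_a, pos_b = pos_b,
                    separation = sep)[keep, , drop = FALSE]
  if (!is.null(bin_size)) {
    key <- paste(out$chrom, out$pos_a %/% bin_size, out$pos_b %/% bin_size)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  if (nrow(out) == 0) stopf("no pairs under max separation")
  rownames(out) <- NULL
  out
}

#' On-diagonal regions between features and their nearest distal peak
#'
#' For each feature (TSS or enhancer midpoint) the nearest same-chromosome
#' peak farther than `min_distance` is located (ties broken toward the
#' smaller coordinate) and the region spanning the two midpoints is
#' emitted.  Features with no qualifying peak are skipped with a logged
#' count.
#'
#' @param features,peaks `GRanges` site sets.
#' @param min_distance minimum midpoint distance in bp (default 25 kb).
#' @return data.frame with `chrom`, `start`, `end` (0-based bp, midpoint
#'   to midpoint).
#' @export
make_domain_regions <- function(features, peaks, min_distance = 25e3) {
  stopifnot(length(features) > 0, length(peaks) > 0)
  fc <- as.character(GenomicRanges::seqnames(features))
  pc <- as.character(GenomicRanges::seqnames(peaks))
  fm <- site_anchors(features); pm <- site_anchors(peaks)
  rows <- list(); skipped <- 0L
  for (i in seq_along(fm)) {
    cand <- which(pc == fc[i] & abs(pm - fm[i]) > min_distance)
    if (length(cand) == 0) { skipped <- skipped + 1L; next }
    d <- abs(pm[cand] - fm[i])
    best <- cand[order(d, pm[cand])][1]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = fc[i], start = min(fm[i], pm[best]), end = max(fm[i], pm[best]))
  }
  if (skipped > 0) msg(skipped, " feature(s) with no qualifying peak skipped")
  if (length(rows) == 0) stopf("no feature has a qualifying peak")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Randomly shifted control pairs
#'
#' Generates `n` pairs with the anchor separation of `pair` preserved
#' exactly: both anchors are moved by one shared uniform offset per
#' replicate, constrained so the padded window stays inside the chromosome.
#' Draws come from the current RNG stream; callers seed it (the pile-up
#' functions do so from their config).
#'
#' @param pair one-row data.frame with `pos_a` and `pos_b` (bp).
#' @param n number of control replicates.
#' @param chrom_length chromosome length in bp.
#' @param pad pile-up half-window in bp.
#' @return data.frame of `n` shifted pairs (0 rows, with a warning, when
#'   the chromosome leaves no room to shift).
#' @export
shifted_controls <- function(pair, n, chrom_length, pad) {
  if (n == 0) return(data.frame(pos_a = numeric(0), pos_b = numeric(0)))
  lo <- pad - pair$pos_a                      # most negative allowed shift
  hi <- chrom_length - pad - pair$pos_b       # most positive allowed shift
  if (hi <= lo) {
    warning("chromosome too short for any control shift", call. = FALSE)
    return(data.frame(pos_a = numeric(0), pos_b = numeric(0)))
  }
  offs <- runif(n, lo, hi)
  data.frame(pos_a = pair$pos_a + offs, pos_b = pair$pos_b + offs)
}

extract_window <- function(m, ci, cj, k) {
  n <- nrow(m)
  if (ci - k < 1L || ci + k > n || cj - k < 1L || cj + k > n) return(NULL)
  m[(ci - k):(ci + k), (cj - k):(cj + k), drop = FALSE]
}

#' Average-loop (aggregate peak) pile-up
#'
#' Extracts the `(2 pad / bin + 1)`-pixel square submatrix centred on every
#' anchor-pair pixel, averages them, and normalises by the mean of randomly
#' shifted control windows with the same separations, cancelling the
#' distance-decay background.  The loop strength is the mean of the central
#' `center_size x center_size` block of the normalised pile-up.
#'
#' @param matrices named list of [contact_matrix()] objects, keyed by
#'   chromosome.
#' @param pairs data.frame of anchor pairs (see [make_loop_pairs()]).
#' @param config a [loop_pileup_config()].
#' @return A `pileup_result`: list with `raw`, `control`, `normalized`,
#'   `n_pairs_used`, `loop_strength` and `normalized_by`.
#' @export
average_loop <- function(matrices, pairs, config = loop_pileup_config()) {
  stopifnot(inherits(config, "loop_pileup_config"), nrow(pairs) > 0)
  bs <- unique(vapply(matrices, function(x) x$bin_size, integer(1)))
  if (length(bs) != 1) stopf("matrices have mixed bin sizes")
  if (config$pad %% bs != 0) stopf("pad must be a multiple of the bin size")
  k <- as.integer(config$pad %/% bs)
  pairs <- pairs[pairs$pos_b - pairs$pos_a < config$max_separation, ,
                 drop = FALSE]
  with_seed(config$seed, {
    raw_sum <- NULL; ctrl_sum <- NULL
    n_used <- 0L; n_ctrl_pairs <- 0L
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, ]
      cm <- matrices[[p$chrom]]
      if (is.null(cm)) next
      m <- cm$matrix
      ci <- as.integer(p$pos_a %/% bs) + 1L
      cj <- as.integer(p$pos_b %/% bs) + 1L
      w <- extract_window(m, ci, cj, k)
      if (is.null(w)) next
      n_used <- n_used + 1L
      raw_sum <- if (is.null(raw_sum)) w else raw_sum + w
      if (config$n_controls > 0) {
        chrom_len <- nrow(m) * bs
        ctl <- shifted_controls(p, config$n_controls, chrom_len, config$pad)
        if (nrow(ctl)) {
          cw_sum <- NULL; cw_n <- 0L
          for (q in seq_len(nrow(ctl))) {
            wi <- as.integer(ctl$pos_a[q] %/% bs) + 1L
            wj <- as.integer(ctl$pos_b[q] %/% bs) + 1L
            cw <- extract_window(m, wi, wj, k)
            if (is.null(cw)) next
            cw_sum <- if (is.null(cw_sum)) cw else cw_sum + cw
            cw_n <- cw_n + 1L
          }
          if (cw_n > 0) {
            ctrl_sum <- if (is.null(ctrl_sum)) cw_sum / cw_n
                        else ctrl_sum + cw_sum / cw_n
            n_ctrl_pairs <- n_ctrl_pairs + 1L
          }
        }
      }
    }
    if (n_used == 0L) stopf("no usable pairs (padded windows leave the matrix)")
    raw <- raw_sum / n_used
    if (config$n_controls > 0 && n_ctrl_pairs > 0) {
      control <- ctrl_sum / n_ctrl_pairs
      normalized <- raw / control
      normalized_by <- "shifted_controls"
    } else {
      if (config$n_controls > 0)
        msg("no valid control windows; reporting unnormalized pile-up")
      control <- base::matrix(NA_real_, nrow(raw), ncol(raw))
      normalized <- raw
      normalized_by <- "none"
    }
    new_pileup_result(raw, control, normalized, n_used,
                      loop_strength(normalized, config$center_size),
                      normalized_by)
  })
}

new_pileup_result <- function(raw, control, normalized, n_pairs_used,
                              loop_strength = NULL, normalized_by) {
  structure(list(raw = raw, control = control, normalized = normalized,
                 n_pairs_used = n_pairs_used, loop_strength = loop_strength,
                 normalized_by = normalized_by),
            class = "pileup_result")
}

#' @export
print.pileup_result <- function(x, ...) {
  cat(sprintf("<pileup_result> %d x %d pixels from %d pairs/regions",
              nrow(x$normalized), ncol(x$normalized), x$n_pairs_used))
  if (!is.null(x$loop_strength))
    cat(sprintf("; loop strength %.3f", x$loop_strength))
  cat("\n")
  invisible(x)
}

#' Rescaled local contact-domain pile-up
#'
#' Each region's on-diagonal square window (the region plus one region
#' length of pad on either side, so the region occupies the central third)
#' is extracted and rescaled to `rescale_size` pixels (block mean when
#' shrinking, bilinear when enlarging; exact when sizes already match),
#' then averaged over regions and normalised by randomly shifted
#' equally-sized local windows.
#'
#' @inheritParams average_loop
#' @param regions data.frame with `chrom`, `start`, `end` in bp (see
#'   [make_domain_regions()]).
#' @param config a [domain_pileup_config()].
#' @return A `pileup_result` without a loop strength.
#' @export
rescaled_local_pileup <- function(matrices, regions,
                                  config = domain_pileup_config()) {
  stopifnot(inherits(config, "domain_pileup_config"), nrow(regions) > 0)
  bs <- unique(vapply(matrices, function(x) x$bin_size, integer(1)))
  if (length(bs) != 1) stopf("matrices have mixed bin sizes")
  with_seed(config$seed, {
    raw_sum <- NULL; ctrl_sum <- NULL
    n_used <- 0L; n_ctrl <- 0L; skipped <- 0L
    for (r in seq_len(nrow(regions))) {
      reg <- regions[r, ]
      cm <- matrices[[reg$chrom]]
      if (is.null(cm)) { skipped <- skipped + 1L; next }
      m <- cm$matrix; n <- nrow(m)
      b0 <- as.integer(reg$start %/% bs) + 1L
      b1 <- as.integer((reg$end - 1) %/% bs) + 1L
      if (b1 <= b0) { skipped <- skipped + 1L; next }
      len <- b1 - b0 + 1L
      lo <- b0 - len; hi <- b1 + len
      if (lo < 1L || hi > n) { skipped <- skipped + 1L; next }
      w <- rescale_matrix(m[lo:hi, lo:hi], config$rescale_size)
      raw_sum <- if (is.null(raw_sum)) w else raw_sum + w
      n_used <- n_used + 1L
      if (config$n_controls > 0) {
        span <- hi - lo + 1L
        room <- n - span
        if (room >= 1L) {
          cw_sum <- NULL; cw_n <- 0L
          starts <- 1L + floor(runif(config$n_controls, 0, room + 1))
          for (s in starts) {
            cw <- rescale_matrix(m[s:(s + span - 1L), s:(s + span - 1L)],
                                 config$rescale_size)
            cw_sum <- if (is.null(cw_sum)) cw else cw_sum + cw
            cw_n <- cw_n + 1L
          }
          ctrl_sum <- if (is.null(ctrl_sum)) cw_sum / cw_n
                      else ctrl_sum + cw_sum / cw_n
          n_ctrl <- n_ctrl + 1L
        }
      }
    }
    if (skipped > 0)
      warning(sprintf("%d region(s) skipped (out of bounds after padding)",
                      skipped), call. = FALSE)
    if (n_used == 0L) stopf("no usable regions")
    raw <- raw_sum / n_used
    if (config$n_controls > 0 && n_ctrl > 0) {
      control <- ctrl_sum / n_ctrl
      normalized <- raw / control
      normalized_by <- "shifted_controls"
    } else {
      control <- base::matrix(NA_real_, nrow(raw), ncol(raw))
      normalized <- raw
      normalized_by <- "none"
    }
    new_pileup_result(raw, control, normalized, n_used, NULL, normalized_by)
  })
}

#' Loop strength of a normalised pile-up
#'
#' Arithmetic mean of the centred `center_size x center_size` block; the
#' enrichment of contacts at the loop pixel over local background.
#'
#' @param normalized square odd-sided numeric matrix.
#' @param center_size odd block side, at most the matrix side (default 3).
#' @return A single number.
#' @export
loop_strength <- function(normalized, center_size = 3) {
  stopifnot(is.matrix(normalized), nrow(normalized) == ncol(normalized))
  n <- nrow(normalized)
  if (n %% 2 == 0) stopf("matrix side must be odd (no unique centre)")
  stopifnot(center_size %% 2 == 1, center_size <= n)
  c0 <- (n + 1L) %/% 2L
  h <- (center_size - 1L) %/% 2L
  mean(normalized[(c0 - h):(c0 + h), (c0 - h):(c0 + h)])
}

# Resample a square matrix to size x size: area-preserving block mean when
# shrinking, bilinear interpolation when enlarging; identity when equal.
rescale_matrix <- function(m, size) {
  n <- nrow(m)
  if (n == size) return(m)
  if (n > size) {
    grp <- floor((seq_len(n) - 1L) * size / n) + 1L
    cnt <- as.vector(table(grp))
    out <- t(rowsum(t(rowsum(m, grp) / cnt), grp) / cnt)
    dimnames(out) <- NULL
    out
  } else {
    xo <- seq(1, n, length.out = size)
    rows <- t(apply(m, 1L, function(v) approx(seq_len(n), v, xout = xo)$y))
    apply(rows, 2L, function(v) approx(seq_len(n), v, xout = xo)$y)
  }
}

#' Write a pile-up result to TSV plus a JSON sidecar
#'
#' @param result a `pileup_result`.
#' @param prefix path prefix; writes `<prefix>.normalized.tsv`,
#'   `<prefix>.raw.tsv` and `<prefix>.json`.
#' @return The JSON path, invisibly.
#' @export
write_pileup_result <- function(result, prefix) {
  write.table(result$normalized, paste0(prefix, ".normalized.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(result$raw, paste0(prefix, ".raw.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(n_pairs_used = result$n_pairs_used,
               loop_strength = result$loop_strength,
               normalized_by = result$normalized_by)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(paste0(prefix, ".json"))
}
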