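#' Simulate a proximity-labelling count table with known partners
#'
#' Background proteins draw Poisson(`background_mean`) peptide counts in
#' all six conditions; true partners draw
#' Poisson(`background_mean * bait_factor`) in the four bait conditions and
#' background counts in the enzyme-only controls.  Defaults mirror the
#' published tables' regime: background counts of 0-3 (mean 1) against
#' partner bait counts around 20 (twenty-fold labelling enrichment).
#'
#' @param n_background number of background proteins (default 480).
#' @param n_partners number of true partners (default 20).
#' @param background_mean Poisson mean of background counts (default 1).
#' @param bait_factor multiplicative labelling enrichment of partners in
#'   bait conditions (default 20; must be > 1).
#' @param technique labelling enzyme recorded on the table.
#' @param seed integer seed.
#' @return List with `table` (a [count_table()], all rows nuclear-flagged)
#'   and `truth` (logical vector, `TRUE` for planted partners).
#' @export
simulate_count_table <- function(n_background = 480, n_partners = 20,
                                 background_mean = 1, bait_factor = 20,
                                 technique = "BIOID2", seed = 1L) {
  stopifnot(n_background >= 0, n_partners >= 0, background_mean > 0,
            bait_factor > 1)
  n <- n_background + n_partners
  truth <- c(rep(TRUE, n_partners), rep(FALSE, n_background))
  with_seed(seed, {
    bait_mean <- ifelse(truth, background_mean * bait_factor, background_mean)
    df <- data.frame(
      gene = sprintf("%s%03d", ifelse(truth, "partner", "bg"), seq_len(n)),
      protein_id = sprintf("SIM%05d", seq_len(n)),
      bait1_sham = rpois(n, bait_mean), bait1_20E = rpois(n, bait_mean),
      bait2_sham = rpois(n, bait_mean), bait2_20E = rpois(n, bait_mean),
      ctrl_sham = rpois(n, background_mean),
      ctrl_20E = rpois(n, background_mean),
      is_nuclear = TRUE)
    list(table = count_table(df, technique), truth = truth)
  })
}

#' Simulate ChIP and input coverage tracks with planted peaks
#'
#' The input track is Poisson noise around a flat `background_level`
#' reads per bin.  The ChIP track adds a Gaussian bump of amplitude
#' `peak_height * background_level` (sd `peak_sd` bp) at each of `n_sites`
#' uniformly placed sites, so the expected central ChIP/input enrichment is
#' `1 + peak_height`.  Sites are kept `2 * peak_sd + flank`-safe from the
#' chromosome ends.
#'
#' @param chrom_sizes named vector of chromosome lengths (default one 2 Mb
#'   chromosome).
#' @param n_sites number of planted sites (default 200).
#' @param peak_height bump amplitude as a multiple of the background
#'   (default 4, i.e. five-fold central enrichment); 0 plants nothing.
#' @param peak_sd Gaussian peak standard deviation in bp (default 150).
#' @param background_level expected background reads per bin (default 50).
#' @param bin_size bin width in bp (default 50).
#' @param margin bp kept free of sites at each chromosome end (default
#'   10 kb).
#' @param seed integer seed.
#' @return List with `chip` and `input` [coverage_track()]s and `sites`
#'   (the planted site set as a `GRanges`, summit at the bump centre).
#' @export
simulate_chip_tracks <- function(chrom_sizes = c(chrSim = 2e6), n_sites = 200,
                                 peak_height = 4, peak_sd = 150,
                                 background_level = 50, bin_size = 50,
                                 margin = 10e3, seed = 1L) {
  stopifnot(n_sites >= 0, peak_height >= 0, peak_sd > 0,
            background_level > 0, all(chrom_sizes > 2 * margin))
  with_seed(seed, {
    chip <- list(); input <- list(); site_rows <- list()
    probs <- chrom_sizes / sum(chrom_sizes)
    site_chrom <- if (n_sites > 0)
      sample(names(chrom_sizes), n_sites, replace = TRUE, prob = probs)
      else character(0)
    for (ch in names(chrom_sizes)) {
      nb <- n_bins(chrom_sizes[[ch]], bin_size)
      centers <- (seq_len(nb) - 0.5) * bin_size
      lambda_in <- rep(background_level, nb)
      bump <- numeric(nb)
      pos <- round(runif(sum(site_chrom == ch), margin,
                         chrom_sizes[[ch]] - margin))
      for (p in pos)
        bump <- bump + exp(-((centers - p)^2) / (2 * peak_sd^2))
      lambda_chip <- lambda_in + peak_height * background_level * bump
      input[[ch]] <- as.numeric(rpois(nb, lambda_in))
      chip[[ch]] <- as.numeric(rpois(nb, lambda_chip))
      if (length(pos))
        site_rows[[ch]] <- data.frame(chrom = ch, pos = pos)
    }
    sites <- if (length(site_rows)) {
      df <- do.call(rbind, site_rows)
      site_set(df$chrom, df$pos - 250, df$pos + 250, summit = df$pos,
               name = "planted")
    } else GenomicRanges::GRanges()
    list(chip = coverage_track(chip, bin_size, chrom_sizes),
         input = coverage_track(input, bin_size, chrom_sizes),
         sites = sites)
  })
}

#' Simulate a cis contact matrix with planted loops and domains
#'
#' The expected contact count at bins `(i, j)` follows a power-law distance
#' decay `scale * (|i - j| + 1)^-decay_exponent`, multiplied by
#' `loop_factor` in the one-pixel neighbourhood of each planted anchor-pair
#' pixel and by `domain_factor` inside each planted on-diagonal domain
#' square.  Values are realised with mean-preserving multiplicative
#' log-normal noise and symmetrised.
#'
#' @param chrom_length chromosome length in bp (default 5 Mb).
#' @param bin_size bin width in bp (default 5 kb).
#' @param decay_exponent power-law exponent (> 0; default 1, typical of
#'   fly chromatin at sub-Mb separations).
#' @param scale expected count at the diagonal (default 100).
#' @param loop_anchors optional data.frame with `pos_a`, `pos_b` (bp) of
#'   planted loops.
#' @param loop_factor contact enrichment at planted loop pixels (>= 1).
#' @param domain_regions optional data.frame with `start`, `end` (bp) of
#'   planted domains.
#' @param domain_factor contact enrichment inside planted domains (>= 1).
#' @param noise_sd log-normal sdlog of the multiplicative noise (0 for a
#'   noise-free matrix; default 0.3).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return A [contact_matrix()].
#' @export
simulate_contact_matrix <- function(chrom_length = 5e6, bin_size = 5e3,
                                    decay_exponent = 1, scale = 100,
                                    loop_anchors = NULL, loop_factor = 1,
                                    domain_regions = NULL, domain_factor = 1,
                                    noise_sd = 0.3, chrom = "chrSim",
                                    seed = 1L) {
  stopifnot(decay_exponent > 0, loop_factor >= 1, domain_factor >= 1,
            noise_sd >= 0, scale > 0)
  n <- n_bins(chrom_length, bin_size)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- scale * (d + 1)^(-decay_exponent)
  if (!is.null(loop_anchors) && nrow(loop_anchors) > 0 && loop_factor > 1) {
    for (r in seq_len(nrow(loop_anchors))) {
      i <- as.integer(loop_anchors$pos_a[r] %/% bin_size) + 1L
      j <- as.integer(loop_anchors$pos_b[r] %/% bin_size) + 1L
      if (max(i, j) > n || min(i, j) < 1) stopf("loop anchor outside chromosome")
      ri <- pmax(1L, i - 1L):pmin(n, i + 1L)
      rj <- pmax(1L, j - 1L):pmin(n, j + 1L)
      expected[ri, rj] <- expected[ri, rj] * loop_factor
      expected[rj, ri] <- expected[rj, ri] * loop_factor
    }
  }
  if (!is.null(domain_regions) && nrow(domain_regions) > 0 &&
      domain_factor > 1) {
    for (r in seq_len(nrow(domain_regions))) {
      b0 <- as.integer(domain_regions$start[r] %/% bin_size) + 1L
      b1 <- as.integer((domain_regions$end[r] - 1) %/% bin_size) + 1L
      if (b1 > n || b0 < 1) stopf("domain outside chromosome")
      expected[b0:b1, b0:b1] <- expected[b0:b1, b0:b1] * domain_factor
    }
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      noise <- base::matrix(rlnorm(n * n, meanlog = -noise_sd^2 / 2,
                                   sdlog = noise_sd), n, n)
      values <- expected * noise
    } else values <- expected
    upper <- upper.tri(values)
    values[upper] <- t(values)[upper]   # mirror lower triangle: exact symmetry
    contact_matrix(values, bin_size, chrom)
  })
}
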