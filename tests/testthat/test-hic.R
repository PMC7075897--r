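test_that("loop pairs enumerate cross-set cis contacts under the cap", {
  a1 <- site_set("chr2L", 100e3, 101e3)
  b1 <- site_set("chr2L", 150e3, 151e3)
  p <- make_loop_pairs(a1, b1, max_separation = 1e6)
  expect_equal(nrow(p), 1)
  expect_equal(p$separation, 50e3)

  b2 <- site_set("chr3R", 150e3, 151e3)
  expect_error(make_loop_pairs(a1, b2), "no pairs")

  set.seed(41)
  pa <- sort(sample(seq(0, 3e6, by = 1e3), 20))
  pb <- sort(sample(seq(0, 3e6, by = 1e3), 20))
  A <- site_set("chr2L", pa, pa + 1000)
  B <- site_set("chr2L", pb, pb + 1000)
  got <- make_loop_pairs(A, B, max_separation = 1e6)
  # brute-force enumeration over midpoints
  want <- 0
  for (i in 1:20) for (j in 1:20) {
    sep <- abs((pa[i] + 500) - (pb[j] + 500))
    if (sep > 0 && sep < 1e6) want <- want + 1
  }
  expect_equal(nrow(got), want)
  expect_true(all(got$pos_a < got$pos_b))
  expect_true(all(got$separation < 1e6 & got$separation > 0))
})

test_that("duplicate bin pairs are collapsed when a bin size is given", {
  a <- site_set("chr2L", c(100e3, 100.4e3), c(101e3, 101.4e3))
  b <- site_set("chr2L", 300e3, 301e3)
  expect_equal(nrow(make_loop_pairs(a, b, 1e6)), 2)
  expect_equal(nrow(make_loop_pairs(a, b, 1e6, bin_size = 5000)), 1)
})

test_that("domain regions join features to their nearest distal peak", {
  f <- site_set("chr2L", 500e3, 500e3 + 1)
  pk <- site_set("chr2L", c(510e3, 560e3), c(510e3 + 1, 560e3 + 1))
  # the 10 kb peak violates the minimum distance; the 60 kb one is used
  r <- make_domain_regions(f, pk, min_distance = 25e3)
  expect_equal(r$end - r$start, 60e3)

  pk2 <- site_set("chr3R", 560e3, 560e3 + 1)
  expect_error(make_domain_regions(f, pk2), "no feature")

  set.seed(42)
  fpos <- sample(seq(100e3, 2.9e6, by = 1e3), 30)
  ppos <- sample(seq(100e3, 2.9e6, by = 1e3), 30)
  F <- site_set("chr2L", fpos, fpos + 1)
  P <- site_set("chr2L", ppos, ppos + 1)
  got <- make_domain_regions(F, P, min_distance = 25e3)
  # exhaustive nearest-qualifying search per feature
  k <- 0
  for (i in seq_along(fpos)) {
    fm <- fpos[i] + 0.5
    d <- abs(ppos + 0.5 - fm)
    cand <- which(d > 25e3)
    if (length(cand) == 0) next
    k <- k + 1
    best <- cand[order(d[cand], ppos[cand] + 0.5)][1]
    expect_equal(unname(got$end[k] - got$start[k]), unname(d[best]))
  }
  expect_equal(nrow(got), k)
})

test_that("shifted controls preserve separation and are seed-deterministic", {
  pair <- data.frame(pos_a = 1e6, pos_b = 1.3e6)
  expect_equal(nrow(shifted_controls(pair, 0, 5e6, 1e5)), 0)
  set.seed(50)
  ctl <- shifted_controls(pair, 25, 5e6, 1e5)
  expect_equal(ctl$pos_b - ctl$pos_a, rep(0.3e6, 25))
  expect_true(all(ctl$pos_a - 1e5 >= 0 & ctl$pos_b + 1e5 <= 5e6))
  set.seed(50)
  ctl2 <- shifted_controls(pair, 25, 5e6, 1e5)
  expect_identical(ctl, ctl2)
  expect_warning(shifted_controls(pair, 5, 4e5, 1e5), "too short")
})

test_that("average loop equals naive per-pair extraction on small matrices", {
  set.seed(51)
  for (npairs in c(1, 3, 5)) {
    n <- 60
    m <- matrix(rpois(n * n, 5), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    cm <- contact_matrix(m, 5000, "chrT")
    k <- 3   # 15 kb pad on 5 kb bins
    ci <- sample(10:25, npairs); cj <- ci + sample(10:25, npairs)
    pairs <- data.frame(chrom = "chrT", pos_a = (ci - 1) * 5000 + 100,
                        pos_b = (cj - 1) * 5000 + 100)
    res <- average_loop(list(chrT = cm), pairs,
                        loop_pileup_config(pad = 15e3, n_controls = 0,
                                           max_separation = 1e9, seed = 1))
    # naive oracle: extract each 7x7 window by direct indexing and average
    acc <- matrix(0, 7, 7)
    for (q in seq_len(npairs))
      acc <- acc + m[(ci[q] - k):(ci[q] + k), (cj[q] - k):(cj[q] + k)]
    expect_identical(res$raw, acc / npairs)
    expect_equal(res$n_pairs_used, npairs)
    # with no controls the pile-up is reported unnormalised
    expect_identical(res$normalized, res$raw)
    expect_equal(res$normalized_by, "none")
  }
})

test_that("single pair on a tiny matrix reproduces the indexed submatrix", {
  m <- matrix(as.numeric(1:81), 9, 9)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- contact_matrix(m, 1000, "chrT")
  pairs <- data.frame(chrom = "chrT", pos_a = 3500, pos_b = 5500) # bins 4, 6
  res <- average_loop(list(chrT = cm), pairs,
                      loop_pileup_config(pad = 3000, n_controls = 0,
                                         max_separation = 1e9, seed = 1))
  expect_identical(res$raw, m[1:7, 3:9])
})

test_that("loop strength is the centre-block mean", {
  expect_equal(loop_strength(matrix(1, 7, 7)), 1)
  m5 <- matrix(0, 5, 5); m5[2:4, 2:4] <- 2
  expect_equal(loop_strength(m5, 3), 2)
  set.seed(52)
  m41 <- matrix(runif(41 * 41), 41, 41)
  expect_equal(loop_strength(m41, 3), mean(m41[20:22, 20:22]))
  expect_equal(loop_strength(m41, 5), mean(m41[19:23, 19:23]))
  expect_error(loop_strength(matrix(1, 6, 6)), "odd")
})

test_that("constant matrices normalise to exactly 1", {
  n <- 100
  cm <- contact_matrix(matrix(7, n, n), 5000, "chrT")
  pairs <- data.frame(chrom = "chrT",
                      pos_a = c(150e3, 200e3), pos_b = c(250e3, 320e3))
  res <- average_loop(list(chrT = cm), pairs,
                      loop_pileup_config(pad = 50e3, n_controls = 10, seed = 2))
  expect_equal(res$normalized, matrix(1, 21, 21))
  expect_equal(res$loop_strength, 1)

  dres <- rescaled_local_pileup(
    list(chrT = cm), data.frame(chrom = "chrT", start = 200e3, end = 280e3),
    domain_pileup_config(rescale_size = 33, n_controls = 5, seed = 3))
  expect_equal(dres$normalized, matrix(1, 33, 33))
  expect_null(dres$loop_strength)
})

test_that("pairs mirrored across the diagonal give the transposed pile-up", {
  set.seed(53)
  cm <- simulate_contact_matrix(chrom_length = 1e6, bin_size = 5e3,
                                noise_sd = 0.2, seed = 53)
  p <- data.frame(chrom = "chrSim", pos_a = 300e3, pos_b = 600e3)
  cfg <- loop_pileup_config(pad = 50e3, n_controls = 0, seed = 4)
  r1 <- average_loop(list(chrSim = cm), p, cfg)
  # swapped anchor roles read the mirrored window below the diagonal,
  # which on a symmetric matrix is exactly the transpose
  p2 <- data.frame(chrom = "chrSim", pos_a = 600e3, pos_b = 300e3)
  r2 <- average_loop(list(chrSim = cm), p2, cfg)
  expect_equal(r1$raw, t(r2$raw))
})

test_that("identical seeds give bit-identical pile-up results", {
  an <- plant_loop_grid(3e6, 15, seed = 60)
  cm <- simulate_contact_matrix(chrom_length = 3e6, loop_anchors = an,
                                loop_factor = 2, seed = 60)
  cfg <- loop_pileup_config(pad = 50e3, n_controls = 5, seed = 61)
  r1 <- average_loop(list(chrSim = cm), an, cfg)
  r2 <- average_loop(list(chrSim = cm), an, cfg)
  expect_identical(r1, r2)
})

test_that("matrix rescaling is block-mean down, bilinear up, identity at size", {
  m <- decay_matrix_oracle(12)
  cm <- contact_matrix(m, 1000, "chrT")
  # a region exactly rescale_size bins long extracts without resampling:
  # region bins 5..7 (3 bins), pad 3 each side -> 9x9 window, rescale 9
  reg <- data.frame(chrom = "chrT", start = 4000, end = 7000)
  res <- rescaled_local_pileup(list(chrT = cm), reg,
                               domain_pileup_config(rescale_size = 9,
                                                    n_controls = 0, seed = 1))
  expect_identical(res$raw, m[2:10, 2:10])

  # block-mean downscale by an integer factor: 9x9 -> 3x3 window means
  res3 <- rescaled_local_pileup(list(chrT = cm), reg,
                                domain_pileup_config(rescale_size = 3,
                                                     n_controls = 0, seed = 1))
  w <- m[2:10, 2:10]
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    want[i, j] <- mean(w[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])
  expect_equal(res3$raw, want)
})

test_that("planted on-diagonal domains enrich the pile-up centre", {
  regs <- data.frame(chrom = "chrSim", start = c(1e6, 2e6, 3e6),
                     end = c(1.2e6, 2.25e6, 3.15e6))
  cm <- simulate_contact_matrix(domain_regions = regs, domain_factor = 3,
                                noise_sd = 0.2, seed = 70)
  res <- rescaled_local_pileup(list(chrSim = cm), regs,
                               domain_pileup_config(rescale_size = 99,
                                                    n_controls = 10, seed = 71))
  centre <- res$normalized[45:55, 45:55]
  corners <- c(res$normalized[1:10, 90:99], res$normalized[90:99, 1:10])
  expect_gt(mean(centre), 2)
  expect_lt(mean(corners), 1.5)
  expect_gt(mean(centre), mean(corners) * 1.5)
})
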