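test_that("count tables load, validate and round-trip through TSV", {
  tab <- read_bioid2_fixture()
  expect_s3_class(tab, "count_table")
  expect_identical(attr(tab, "technique"), "BIOID2")
  cp <- tab[tab$gene == "CP190", ]
  expect_identical(
    as.integer(cp[, count_conditions()]),
    c(15L, 12L, 9L, 4L, 0L, 0L))

  # empty table with a valid header
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(c("gene", "protein_id", count_conditions()),
                   collapse = "\t"), f)
  empty <- read_count_table(f, "BIOID2")
  expect_equal(nrow(empty), 0)

  # synthetic round-trip
  tiny <- count_table(data.frame(
    gene = c("a", "b", "c"), protein_id = c("P1", "P2", "P3"),
    bait1_sham = c(3L, 0L, 12L), bait1_20E = c(5L, 1L, 9L),
    bait2_sham = c(0L, 2L, 30L), bait2_20E = c(1L, 0L, 25L),
    ctrl_sham = c(0L, 0L, 2L), ctrl_20E = c(1L, 0L, 0L)), "APEX2")
  write_count_table(tiny, f)
  back <- read_count_table(f, "APEX2")
  expect_equal(as.data.frame(back)[, c("gene", "protein_id", count_conditions())],
               as.data.frame(tiny)[, c("gene", "protein_id", count_conditions())])

  # malformed inputs
  writeLines(c("gene\tprotein_id\tbait1_sham", "x\tP\t3"), f)
  expect_error(read_count_table(f, "BIOID2"), "bait1_20E")
  writeLines(c(paste(c("gene", "protein_id", count_conditions()),
                     collapse = "\t"),
               paste(c("x", "P", "-1", "2", "3", "4", "0", "0"),
                     collapse = "\t")), f)
  expect_error(read_count_table(f, "BIOID2"), "row 1")
  # unknown extra columns are dropped with a warning
  writeLines(c(paste(c("gene", "protein_id", count_conditions(), "score"),
                     collapse = "\t"),
               paste(c("x", "P", "1", "2", "3", "4", "0", "0", "99"),
                     collapse = "\t")), f)
  expect_warning(tab2 <- read_count_table(f, "BIOID2"), "score")
  expect_null(tab2$score)
})

test_that("max_bait_count takes the best bait condition, controls excluded", {
  t1 <- read_bioid2_fixture()
  t2 <- read_apex2_fixture()
  expect_equal(max_bait_count(t1)[t1$gene == "CP190"], 15L)
  expect_equal(max_bait_count(t2)[t2$gene == "CP190"], 27L)
  zero <- count_table(data.frame(
    gene = "z", protein_id = "Z", bait1_sham = 0L, bait1_20E = 0L,
    bait2_sham = 0L, bait2_20E = 0L, ctrl_sham = 9L, ctrl_20E = 9L),
    "BIOID2")
  expect_equal(max_bait_count(zero), 0L)
})

test_that("control_enrichment matches direct ratios and handles sentinels", {
  t2 <- read_apex2_fixture()
  # direct division of the printed APEX2 CP190 counts: 27 / max(10, 5)
  expect_equal(control_enrichment(t2, pseudocount = 0)[t2$gene == "CP190"],
               27 / 10)
  mk <- function(baits, ctrls) count_table(data.frame(
    gene = "g", protein_id = "P",
    bait1_sham = baits[1], bait1_20E = baits[2],
    bait2_sham = baits[3], bait2_20E = baits[4],
    ctrl_sham = ctrls[1], ctrl_20E = ctrls[2]), "BIOID2")
  expect_equal(control_enrichment(mk(c(7, 7, 7, 7), c(7, 7)), 0), 1)
  expect_equal(control_enrichment(mk(c(8, 0, 0, 0), c(0, 0)), 1), 8)
  expect_identical(control_enrichment(mk(c(8, 0, 0, 0), c(0, 0)), 0), Inf)
  expect_identical(control_enrichment(mk(c(0, 0, 0, 0), c(0, 0)), 0), 0)
  # per-condition variant compares each arm to its own treatment control
  pc <- control_enrichment(mk(c(9, 2, 1, 2), c(3, 1)), 0,
                           per_condition = TRUE)
  expect_equal(pc, max(9 / 3, 2 / 1, 1 / 3, 2 / 1))
})

test_that("pseudocount only ever shrinks enrichment", {
  set.seed(42)
  tab <- random_count_table(200)
  e0 <- control_enrichment(tab, 0)
  e1 <- control_enrichment(tab, 1)
  e3 <- control_enrichment(tab, 3)
  expect_true(all(e1 <= e0))
  expect_true(all(e3 <= e1))
})

test_that("select_candidates agrees with a per-record brute-force oracle", {
  set.seed(7)
  tab <- random_count_table(1000)
  for (pc in c(0, 1)) for (mp in c(5, 10, 20)) {
    got <- select_candidates(tab, filter_config("BIOID2", min_peptides = mp,
                                                pseudocount = pc))
    want <- brute_force_select(tab, mp, 2.5, pc, require_nuclear = TRUE)
    expect_identical(got$protein_id, want)
  }
  # strict comparison flag
  gotS <- select_candidates(tab, filter_config("BIOID2", pseudocount = 1,
                                               strict_enrichment = TRUE))
  wantS <- brute_force_select(tab, 10, 2.5, 1, TRUE, strict = TRUE)
  expect_identical(gotS$protein_id, wantS)
})

test_that("raising either threshold never adds a candidate", {
  set.seed(11)
  for (rep in 1:5) {
    tab <- random_count_table(150)
    base <- select_candidates(tab, filter_config("BIOID2", min_peptides = 8,
                                                 min_enrichment = 2))
    for (cfg in list(filter_config("BIOID2", min_peptides = 15,
                                   min_enrichment = 2),
                     filter_config("BIOID2", min_peptides = 8,
                                   min_enrichment = 4))) {
      expect_true(all(select_candidates(tab, cfg)$protein_id %in%
                        base$protein_id))
    }
  }
})

test_that("selection preserves input order and reports computed columns", {
  tab <- read_bioid2_fixture()
  sel <- select_candidates(tab, filter_config("BIOID2", pseudocount = 0))
  expect_identical(sel$gene, tab$gene[tab$gene %in% sel$gene])
  expect_equal(sel$max_bait_count,
               max_bait_count(tab)[tab$gene %in% sel$gene])
  expect_true(all(c("max_bait_count", "control_enrichment") %in% names(sel)))
})

test_that("require_nuclear demands an annotation and filters on it", {
  tab <- read_count_table(ext_file("bioid2_partners.tsv"), "BIOID2")
  expect_error(select_candidates(tab, filter_config("BIOID2")),
               "nuclear annotation")
  tab2 <- read_count_table(ext_file("bioid2_partners.tsv"), "BIOID2",
                           nuclear_ids = c("Q24478"))
  sel <- select_candidates(tab2, filter_config("BIOID2", pseudocount = 0))
  expect_identical(sel$gene, "CP190")
})

test_that("top3 fold change averages the three largest areas", {
  same <- top3_fold_change(c(4, 5, 6, 7), c(7, 6, 5, 4))
  expect_equal(same$fold_change, 1)
  expect_false(same$changed)

  up <- top3_fold_change(c(10, 10, 10, 1), c(30, 30, 30), pseudo_area = 0)
  expect_equal(up$top3_area_sham, 10)
  expect_equal(up$top3_area_20E, 30)
  expect_equal(up$fold_change, 3)
  expect_true(up$changed)

  # fewer than three peptides: all areas averaged
  short <- top3_fold_change(c(2), c(4, 8))
  expect_equal(short$fold_change, 6 / 2)

  degenerate <- top3_fold_change(0, 0, pseudo_area = 0)
  expect_false(degenerate$quantifiable)
  expect_true(is.na(degenerate$fold_change))

  # a two-fold shift is within-noise by default, beyond it is a change
  expect_false(top3_fold_change(c(10, 10, 10), c(20, 20, 20))$changed)
  expect_true(top3_fold_change(c(10, 10, 10), c(21, 21, 21))$changed)
  expect_true(top3_fold_change(c(21, 21, 21), c(10, 10, 10))$changed)
})
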