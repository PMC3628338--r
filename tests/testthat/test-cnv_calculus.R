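test_that("length filtering is strict, matching 'larger than'", {
  cat1 <- cnv_catalog(c("a", "b", "c"), "chr1",
                      c(0L, 1000L, 10000L), c(500L, 1600L, 35000L), "gain")
  expect_equal(filter_by_length(cat1, 500)$cnv_id, c("b", "c"))  # 500 excluded
  expect_equal(filter_by_length(cat1, 20000)$cnv_id, "c")
  expect_equal(filter_by_length(cat1, 25000)$cnv_id, character(0))  # strict
  expect_equal(nrow(filter_by_length(cat1, 0)), 3)
})

test_that("locus overlap uses half-open semantics", {
  cat1 <- cnv_catalog(c("touch", "in", "other"), c("chr1", "chr1", "chr2"),
                      c(0L, 150L, 150L), c(100L, 250L, 250L), "loss")
  ov <- locus_overlap(cat1, "chr1", 100, 300)
  expect_equal(ov$n_in, 1)          # the CNV ending at 100 does not overlap
  expect_equal(ov$n_total, 3)
  whole <- locus_overlap(cat1[cat1$chrom == "chr1", ], "chr1", 0, 1e9)
  expect_equal(whole$fraction, 1)
  expect_error(locus_overlap(cat1[0, ], "chr1", 0, 1), "empty")
})

test_that("polymorphism classification is strict at the frequency threshold", {
  cat1 <- cnv_catalog(paste0("c", 1:4), "chr1", (0:3) * 1000L,
                      (0:3) * 1000L + 500L, "gain",
                      freq = list(c(CEU = 0.05, YRI = 0),
                                  c(CEU = 0.01, YRI = 0.01),
                                  c(ASN = 0.8),
                                  numeric(0)))
  poly <- classify_polymorphisms(cat1, 0.01)
  expect_true(poly[["c1"]])
  expect_false(poly[["c2"]])   # exactly at threshold -> not a polymorphism
  expect_true(poly[["c3"]])
  expect_true(is.na(poly[["c4"]]))  # unknown, never FALSE
})

test_that("gene copy numbers follow the signed event calculus", {
  cat22 <- psg_two_cnv_catalog()
  baseline <- psg_baseline()
  # homozygous loss at the 5-gene CNV: 22 - 2*5 = 12
  prof_min <- gene_copy_number(c(CNVR7658.2 = 2, CNVR7658.5 = 0), cat22,
                               baseline)
  expect_equal(unname(attr(prof_min, "total")), 12)
  expect_equal(unname(prof_min["PSG1", 1]), 0)
  expect_equal(unname(prof_min["PSG2", 1]), 2)
  # homozygous gain at the 4-gene CNV: 22 + 2*4 = 30
  prof_max <- gene_copy_number(c(CNVR7658.2 = 0, CNVR7658.5 = 2), cat22,
                               baseline)
  expect_equal(unname(attr(prof_max, "total")), 30)
  # no events: the baseline 22 exactly
  prof0 <- gene_copy_number(c(CNVR7658.2 = 0, CNVR7658.5 = 0), cat22,
                            baseline)
  expect_equal(unname(attr(prof0, "total")), 22)
  expect_equal(unname(prof0[, 1]), unname(baseline[rownames(prof0)]))
})

test_that("copy numbers floor at zero with a warning", {
  cat1 <- cnv_catalog(c("l1", "l2"), "chr1", c(0L, 2000L), c(1000L, 3000L),
                      "loss", genes = list("G1", "G1"))
  expect_warning(
    prof <- gene_copy_number(c(l1 = 2, l2 = 2), cat1,
                             c(G1 = 2L)),
    "floored")
  expect_equal(unname(prof["G1", 1]), 0)
})

test_that("'both'-type CNVs cannot be genotyped without a direction", {
  cat1 <- cnv_catalog("b1", "chr1", 0L, 1000L, "both", genes = list("G1"))
  expect_error(gene_copy_number(c(b1 = 1), cat1, c(G1 = 2L)), "'both'")
})

test_that("copy-number range matches exhaustive enumeration", {
  cat22 <- psg_two_cnv_catalog()
  baseline <- psg_baseline()
  expect_equal(copy_number_range(cat22, baseline), c(min = 12, max = 30))
  expect_equal(copy_number_range(cat22[0, ], baseline), c(min = 22, max = 22))

  # 3 non-overlapping loss CNVs of 1 gene each: min = baseline - 6
  cat3 <- cnv_catalog(paste0("l", 1:3), "chr1", (0:2) * 2000L,
                      (0:2) * 2000L + 1000L, "loss",
                      genes = list("G1", "G2", "G3"))
  b3 <- c(G1 = 2L, G2 = 2L, G3 = 2L)
  expect_equal(copy_number_range(cat3, b3),
               copy_range_oracle(cat3$genes, cat3$cnv_type, b3))
  expect_equal(unname(copy_number_range(cat3, b3)["min"]), 0)

  # overlapping gene sets (where greedy per-CNV bounds go wrong)
  cat_ov <- cnv_catalog(c("lossA", "gainA"), "chr1", c(0L, 5000L),
                        c(4000L, 9000L), c("loss", "gain"),
                        genes = list(c("G1", "G2"), c("G2", "G3")))
  b_ov <- c(G1 = 2L, G2 = 2L, G3 = 2L)
  expect_equal(copy_number_range(cat_ov, b_ov),
               copy_range_oracle(cat_ov$genes, cat_ov$cnv_type, b_ov))
})

test_that("enumeration min/max bracket sampled copy-number profiles", {
  cat22 <- psg_two_cnv_catalog()
  baseline <- psg_baseline()
  rng <- copy_number_range(cat22, baseline)
  gts <- simulate_cnv_genotypes(cat22, 10000, "CEU", seed = 31)
  prof <- suppressWarnings(gene_copy_number(gts, cat22, baseline))
  totals <- attr(prof, "total")
  expect_gte(min(totals), rng["min"])
  expect_lte(max(totals), rng["max"])
})

test_that("population differentiation flags private and shared CNVs", {
  cat1 <- cnv_catalog(paste0("c", 1:3), "chr1", (0:2) * 1000L,
                      (0:2) * 1000L + 500L, "gain",
                      freq = list(c(CEU = 0.05, YRI = 0),
                                  c(YRI = 0.15, CEU = 0),
                                  c(CEU = 0.1, YRI = 0.1)))
  tab <- cnv_population_differentiation(cat1)
  expect_equal(tab$status[tab$cnv_id == "c1"], "private")
  expect_equal(tab$private_to[tab$cnv_id == "c1"], "CEU")
  expect_equal(tab$private_to[tab$cnv_id == "c2"], "YRI")
  expect_equal(tab$status[tab$cnv_id == "c3"], "shared")
  expect_equal(tab$cnv_id[1], "c2")  # sorted by max frequency
  single <- cnv_catalog("x", "chr1", 0L, 100L, "gain",
                        freq = list(c(CEU = 0.5)))
  expect_error(cnv_population_differentiation(single), "two populations")
})

test_that("catalog summaries count thresholded records and locus overlap", {
  # synthetic chromosome-wide catalog: 387 records > 500 bp, 46 > 20 kb,
  # 8 of the long ones inside the locus
  set.seed(17)
  n_short <- 341; n_long <- 46
  starts <- c(sample.int(4e7, n_short), sample.int(4e7, n_long - 8),
              seq(47610000, 48400000, length.out = 8))
  lens <- c(sample(501:20000, n_short, replace = TRUE),
            sample(20001:379000, n_long, replace = TRUE))
  cat_chr <- cnv_catalog(sprintf("cnv%03d", seq_along(starts)), "chr19",
                         as.integer(starts), as.integer(starts + lens),
                         "gain")
  s <- cnv_summary(cat_chr, c(500, 20000),
                   locus = list(chrom = "chr19", start = 47600000,
                                end = 48500000))
  expect_equal(unname(s$n_over_length[">500bp"]), 387)
  expect_equal(unname(s$n_over_length[">20000bp"]), 46)
  expect_equal(s$locus$n_in, 8)
  expect_equal(s$locus$fraction, 8 / 46, tolerance = 1e-12)
  expect_equal(sum(s$size_histogram$count), 387)
})
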