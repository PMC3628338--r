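test_that("theta is 1 for populations fixed for opposite alleles", {
  panel <- panel_from_vector(c(rep(2, 50), rep(0, 50)),
                             rep(c("p1", "p2"), each = 50))
  expect_equal(weir_cockerham_fst(panel, "snp1"), 1)
})

test_that("theta matches the independent ANOVA variance-components oracle", {
  # hand-sized table: 2 populations x 4 individuals
  g <- c(0, 1, 2, 1, 0, 0, 1, 0)
  pops <- rep(c("p1", "p2"), each = 4)
  panel <- panel_from_vector(g, pops)
  expect_equal(weir_cockerham_fst(panel, "snp1"), wc_oracle_anova(g, pops),
               tolerance = 1e-12)

  # randomized tables, uneven sizes, three populations, missing data
  set.seed(42)
  for (i in 1:25) {
    sizes <- sample(3:8, 3, replace = TRUE)
    pops <- rep(paste0("p", 1:3), sizes)
    g <- rbinom(sum(sizes), 2, runif(1, 0.15, 0.85))
    if (i %% 3 == 0) g[sample(length(g), 1)] <- NA
    if (length(unique(na.omit(g))) == 1) next  # skip monomorphic draws
    panel <- panel_from_vector(g, pops)
    got <- weir_cockerham_fst(panel, "snp1")
    want <- wc_oracle_anova(g, pops)
    if (is.na(got)) expect_true(is.na(want) || !is.finite(want))
    else expect_equal(got, want, tolerance = 1e-10, info = paste("case", i))
  }
})

test_that("theta is undefined (not 0) for monomorphic or 1-population SNPs", {
  panel <- panel_from_vector(rep(0, 20), rep(c("p1", "p2"), each = 10))
  expect_true(is.na(weir_cockerham_fst(panel, "snp1")))
  g <- matrix(c(rep(1, 10), rep(NA, 10)), 1,
              dimnames = list("s", sprintf("i%02d", 1:20)))
  panel2 <- panel_from_matrix(g, rep(c("p1", "p2"), each = 10))
  scan <- fst_scan(panel2)
  expect_true(is.na(scan$theta))
  expect_false(scan$defined)
})

test_that("theta is invariant to allele-label swap and population relabeling", {
  set.seed(7)
  g <- rbinom(30, 2, 0.4)
  pops <- rep(c("a", "b", "c"), each = 10)
  t0 <- weir_cockerham_fst(panel_from_vector(g, pops), "snp1")
  t_swap <- weir_cockerham_fst(panel_from_vector(2 - g, pops), "snp1")
  t_rel <- weir_cockerham_fst(panel_from_vector(g, c(b = "z", a = "y",
                                                     c = "x")[pops]), "snp1")
  expect_equal(t_swap, t0, tolerance = 1e-12)
  expect_equal(t_rel, t0, tolerance = 1e-12)
})

test_that("percentile brackets count, promote ties, and stay monotone", {
  # distinct values: exact bracket counts from a sort-based oracle
  set.seed(1)
  th <- sample(seq(0.001, 1, length.out = 1000))
  scan <- structure(data.frame(snp_id = paste0("s", 1:1000), theta = th,
                               n_pops = 3, defined = TRUE),
                    class = c("fst_scan", "data.frame"))
  ranked <- rank_brackets(scan, c(15, 10, 5, 1))
  expect_equal(sum(ranked$top_15), 150)
  expect_equal(sum(ranked$top_10), 100)
  expect_equal(sum(ranked$top_5), 50)
  expect_equal(sum(ranked$top_1), 10)
  oracle_top <- function(q) paste0("s", order(th, decreasing = TRUE)[
    seq_len(floor(1000 * q / 100))])
  expect_setequal(ranked$snp_id[ranked$top_5], oracle_top(5))

  # all-equal thetas: ties promoted into every bracket
  scan_eq <- scan
  scan_eq$theta <- 0.5
  ranked_eq <- rank_brackets(scan_eq)
  expect_true(all(ranked_eq$top_1))

  # random theta vectors: monotone nesting of brackets
  for (i in 1:10) {
    scan$theta <- round(rnorm(1000), i %% 3)  # induce ties
    r <- rank_brackets(scan)
    expect_true(all(r$top_1 <= r$top_5))
    expect_true(all(r$top_5 <= r$top_10))
    expect_true(all(r$top_10 <= r$top_15))
  }
  expect_error(rank_brackets(scan[0, ]), "empty")
})

test_that("undefined thetas are excluded from the ranking universe", {
  scan <- structure(data.frame(snp_id = paste0("s", 1:10),
                               theta = c(seq(0.1, 0.9, length.out = 9), NA),
                               n_pops = 3,
                               defined = c(rep(TRUE, 9), FALSE)),
                    class = c("fst_scan", "data.frame"))
  ranked <- rank_brackets(scan, 15)
  expect_true(is.na(ranked$top_15[10]))
  expect_equal(sum(ranked$top_15, na.rm = TRUE), 1)  # floor(9 * 0.15) = 1
})

test_that("family enrichment reproduces printed bracket ratios from counts", {
  tab <- fixture_from_counts(1327, 43, 25, 7)
  fam_map <- setNames(ifelse(tab$group == "family", "CEACAM/PSG",
                             "conserved"), tab$gene_id)
  enr <- family_enrichment(setNames(tab$flag, tab$gene_id), fam_map,
                           "conserved")
  expect_equal(enr$ratio[enr$family == "conserved"], 43 / 1327)  # 3.2%
  expect_equal(enr$ratio[enr$family == "CEACAM/PSG"], 7 / 25)    # 28.0%
  expect_lt(enr$p_value[enr$family == "CEACAM/PSG"], 0.01)

  # chi-squared equals the direct 2x2 computation without Yates correction
  direct <- suppressWarnings(chisq.test(rbind(c(7, 18), c(43, 1284)),
                                        correct = FALSE))
  expect_equal(enr$chisq[enr$family == "CEACAM/PSG"],
               unname(direct$statistic))

  # pooled progressive families: 9/36 = 25.0%
  tab2 <- fixture_from_counts(1327, 43, 36, 9)
  fmap2 <- setNames(ifelse(tab2$group == "family", "OR", "conserved"),
                    tab2$gene_id)
  enr2 <- family_enrichment(setNames(tab2$flag, tab2$gene_id), fmap2,
                            "conserved", pooled = list(progressive = "OR"))
  expect_equal(enr2$ratio[enr2$family == "progressive"], 0.25)
})

test_that("zero hits everywhere gives ratio 0 and p = 1 by convention", {
  tab <- fixture_from_counts(10, 0, 5, 0)
  fam_map <- setNames(ifelse(tab$group == "family", "F", "conserved"),
                      tab$gene_id)
  enr <- family_enrichment(setNames(tab$flag, tab$gene_id), fam_map,
                           "conserved")
  expect_equal(enr$ratio, c(0, 0))
  expect_equal(enr$p_value[enr$family == "F"], 1)
})

test_that("SNP-density contrast reproduces printed fractions and tests", {
  tab <- fixture_from_counts(1363, 113, 25, 10)
  counts <- data.frame(gene_id = tab$gene_id,
                       family = ifelse(tab$group == "family", "FAM", "BG"),
                       n_syn = 0L, n_nonsyn = as.integer(tab$flag))
  dens <- snp_density(counts, "FAM", "BG")
  g <- dens$groups
  expect_equal(g$fraction_with_nonsyn[g$group == "conserved"], 113 / 1363,
               tolerance = 1e-12)  # 8.29%
  expect_equal(g$fraction_with_nonsyn[g$group == "family"], 0.40)
  expect_lt(dens$chisq_fraction["p"], 0.01)

  # all-zero counts: means 0 with p = 1
  zero <- counts
  zero$n_nonsyn <- 0L
  d0 <- snp_density(zero, "FAM", "BG")
  expect_equal(d0$groups$mean_nonsyn, c(0, 0))
  expect_equal(unname(d0$welch_nonsyn["p"]), 1)
  expect_equal(unname(d0$chisq_fraction["p"]), 1)
})

test_that("SEM matches sd/sqrt(n) and Welch test matches t.test directly", {
  set.seed(3)
  counts <- data.frame(gene_id = paste0("g", 1:60),
                       family = rep(c("FAM", "BG"), c(20, 40)),
                       n_syn = rpois(60, 3),
                       n_nonsyn = rpois(60, rep(c(8, 4), c(20, 40))))
  dens <- snp_density(counts, "FAM", "BG")
  fam <- counts$n_nonsyn[counts$family == "FAM"]
  expect_equal(dens$groups$sem_nonsyn[dens$groups$group == "family"],
               sd(fam) / sqrt(20))
  tt <- t.test(fam, counts$n_nonsyn[counts$family == "BG"])
  expect_equal(unname(dens$welch_nonsyn["p"]), tt$p.value)
})

test_that("a 2x family nonsynonymous rate is detected with high power", {
  hits <- vapply(1:100, function(s) {
    cfg <- simulation_config(seed = s, n_snps = 3000, n_genes = 200,
                             family_fraction = 0.2,
                             nonsyn_rate_family = 7.6,
                             nonsyn_rate_background = 3.8)
    panel <- simulate_genotype_panel(cfg)
    dens <- snp_density(per_gene_snp_counts(panel), "FAM", "BG")
    dens$welch_nonsyn["p"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
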