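# Independent oracles and small builders shared across test files.

# Weir-Cockerham theta via nested ANOVA mean squares on allele indicators:
# alleles within individuals within populations, fitted with lm(). This is an
# algebraically independent route to the same estimator as the closed-form
# a/b/c components in the package.
wc_oracle_anova <- function(genotypes, populations) {
  keep <- !is.na(genotypes)
  g <- genotypes[keep]
  pop <- populations[keep]
  n_i <- table(pop)
  r <- length(n_i)
  n_tot <- sum(n_i)
  ind <- factor(seq_along(g))
  x <- c(rbind(as.integer(g >= 1), as.integer(g == 2)))  # 2 alleles per ind
  pop2 <- factor(rep(pop, each = 2))
  ind2 <- rep(ind, each = 2)
  av <- stats::anova(stats::lm(x ~ pop2 + pop2:ind2))
  ms <- av$`Mean Sq`
  names(ms) <- rownames(av)
  ms_p <- ms[["pop2"]]
  ms_i <- ms[["pop2:ind2"]]
  ms_g <- av["Residuals", "Mean Sq"]
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  sig_g <- ms_g
  sig_i <- (ms_i - ms_g) / 2
  sig_p <- (ms_p - ms_i) / (2 * nc)
  sig_p / (sig_p + sig_i + sig_g)
}

# One-SNP genotype panel from a genotype vector and population labels.
panel_from_vector <- function(g, pops, snp_id = "snp1") {
  inds <- sprintf("ind%03d", seq_along(g))
  m <- matrix(as.integer(g), nrow = 1,
              dimnames = list(snp_id, inds))
  genotype_panel(m, stats::setNames(pops, inds))
}

# Multi-SNP panel from a SNP x individual matrix.
panel_from_matrix <- function(g, pops, snps = NULL) {
  if (is.null(rownames(g))) rownames(g) <- sprintf("snp%04d", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- sprintf("ind%03d", seq_len(ncol(g)))
  genotype_panel(g, stats::setNames(pops, colnames(g)), snps)
}

# Genotype pair encoding known haplotype counts with unambiguous phase
# (homozygote-only pairing, so genotype data determine haplotypes exactly).
genotypes_from_haplotype_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  stopifnot(n_AB %% 2 == 0, n_Ab %% 2 == 0, n_aB %% 2 == 0, n_ab %% 2 == 0)
  ga <- c(rep(2L, n_AB / 2), rep(2L, n_Ab / 2), rep(0L, n_aB / 2),
          rep(0L, n_ab / 2))
  gb <- c(rep(2L, n_AB / 2), rep(0L, n_Ab / 2), rep(2L, n_aB / 2),
          rep(0L, n_ab / 2))
  list(ga = ga, gb = gb)
}

# Closed-form r^2 from phased haplotype counts.
r2_from_haplotype_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  pAB <- n_AB / n
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Exhaustive CNV copy-number enumeration, coded independently of the package
# (explicit per-genotype loops over a list-of-vectors representation).
copy_range_oracle <- function(cnv_genes, cnv_types, baseline) {
  k <- length(cnv_genes)
  combos <- expand.grid(rep(list(0:2), k))
  totals <- apply(combos, 1, function(gt) {
    copies <- baseline
    for (i in seq_len(k)) {
      s <- if (cnv_types[i] == "gain") 1 else -1
      for (g in cnv_genes[[i]]) copies[g] <- copies[g] + s * gt[i]
    }
    sum(pmax(copies, 0))
  })
  c(min = min(totals), max = max(totals))
}

demo_cnv_path <- function() {
  system.file("extdata", "psg_cnv_catalog_synthetic.tsv", package = "famdiv")
}

# The two printed PSG-locus CNVs used in worked examples: a loss spanning
# PSG1/6/7/10/11 and a gain spanning PSG2/4/5/9, on an 11-gene diploid
# baseline (family total 22).
psg_two_cnv_catalog <- function() {
  cnv_catalog(cnv_id = c("CNVR7658.2", "CNVR7658.5"),
              chrom = "chr19",
              start = c(47600000L, 47990000L),
              end = c(47838000L, 48242000L),
              cnv_type = c("loss", "gain"),
              freq = list(c(CEU = 0.10), c(CEU = 0.10)),
              genes = list(c("PSG1", "PSG6", "PSG7", "PSG10", "PSG11"),
                           c("PSG2", "PSG4", "PSG5", "PSG9")))
}

psg_baseline <- function() {
  stats::setNames(rep(2L, 11), paste0("PSG", c(1:9, 10, 11)))
}
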