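#' Per-SNP Weir–Cockerham F_ST scan
#'
#' Computes the Weir & Cockerham (1984) unbiased estimator theta for every
#' SNP of a panel, from per-population allele frequencies, sample sizes and
#' observed heterozygosities via the standard a/b/c variance components
#' (theta = a / (a + b + c)). Missing genotypes are dropped per population;
#' populations left with no data at a SNP drop out of that SNP's estimate.
#' Theta may be negative at weakly differentiated SNPs (the price of
#' small-sample unbiasedness). SNPs that are monomorphic across the retained
#' populations, or that retain fewer than two informative populations, are
#' undefined (`NA`) and excluded from downstream ranking.
#'
#' @param panel a [genotype_panel].
#' @return A `data.frame` of class `fst_scan` with columns `snp_id`, `theta`,
#'   `n_pops` (informative populations) and `defined`.
#' @examples
#' panel <- simulate_genotype_panel(simulation_config(seed = 1, n_snps = 100))
#' scan <- fst_scan(panel)
#' summary(scan)
#' @export
fst_scan <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  pops <- unique(panel$populations)
  nsnp <- nrow(g)
  r_tot <- length(pops)
  n_i <- p_i <- h_i <- matrix(0, nsnp, r_tot)
  for (k in seq_len(r_tot)) {
    sub <- g[, panel$populations == pops[k], drop = FALSE]
    n_i[, k] <- rowSums(!is.na(sub))
    p_i[, k] <- rowSums(sub, na.rm = TRUE) / (2 * pmax(n_i[, k], 1))
    h_i[, k] <- rowSums(sub == 1, na.rm = TRUE) / pmax(n_i[, k], 1)
  }
  theta <- wc_theta(n_i, p_i, h_i)
  out <- data.frame(snp_id = rownames(g), theta = theta$theta,
                    n_pops = theta$r, defined = !is.na(theta$theta),
                    stringsAsFactors = FALSE)
  class(out) <- c("fst_scan", "data.frame")
  out
}

# Vectorised a/b/c variance components; n_i, p_i, h_i are SNP x population
# matrices (n_i = 0 marks an uninformative population at that SNP).
wc_components <- function(n_i, p_i, h_i) {
  inform <- n_i > 0
  r <- rowSums(inform)
  n_i[!inform] <- 0; p_i[!inform] <- 0; h_i[!inform] <- 0
  nsum <- rowSums(n_i)
  nbar <- nsum / pmax(r, 1)
  p_bar <- rowSums(n_i * p_i) / pmax(nsum, 1)
  h_bar <- rowSums(n_i * h_i) / pmax(nsum, 1)
  s2 <- rowSums(n_i * (p_i - p_bar)^2) / pmax((r - 1) * nbar, 1e-300)
  nc <- (nsum - rowSums(n_i^2) / pmax(nsum, 1)) / pmax(r - 1, 1e-300)
  a <- (nbar / nc) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * nbar - 1) / (4 * nbar))
  cc <- h_bar / 2
  defined <- r >= 2 & p_bar > 0 & p_bar < 1 & nbar > 1 &
    is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = a, b = b, c = cc, r = r, defined = defined)
}

wc_theta <- function(n_i, p_i, h_i) {
  comp <- wc_components(n_i, p_i, h_i)
  theta <- comp$a / (comp$a + comp$b + comp$c)
  theta[!comp$defined | !is.finite(theta)] <- NA_real_
  list(theta = theta, r = comp$r)
}

#' Multi-locus Weir–Cockerham F_ST (ratio of sums)
#'
#' The standard aggregate Weir & Cockerham estimator over a SNP set:
#' `sum(a) / sum(a + b + c)` across loci. Unlike the mean of per-SNP ratio
#' estimates — which carries a systematic downward Jensen bias that grows
#' with F — the ratio of sums is consistent for the differentiation
#' parameter and is the quantity to use for genome- or panel-wide summaries
#' and for checking generator calibration.
#'
#' @param panel a [genotype_panel].
#' @return A single theta estimate over all SNPs with defined components.
#' @export
fst_global <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  pops <- unique(panel$populations)
  nsnp <- nrow(g)
  r_tot <- length(pops)
  n_i <- p_i <- h_i <- matrix(0, nsnp, r_tot)
  for (k in seq_len(r_tot)) {
    sub <- g[, panel$populations == pops[k], drop = FALSE]
    n_i[, k] <- rowSums(!is.na(sub))
    p_i[, k] <- rowSums(sub, na.rm = TRUE) / (2 * pmax(n_i[, k], 1))
    h_i[, k] <- rowSums(sub == 1, na.rm = TRUE) / pmax(n_i[, k], 1)
  }
  comp <- wc_components(n_i, p_i, h_i)
  ok <- comp$defined
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' Weir–Cockerham theta for a single SNP
#'
#' Convenience wrapper around [fst_scan()] for one SNP.
#'
#' @param panel a [genotype_panel].
#' @param snp SNP identifier.
#' @return Numeric theta (may be negative; `NA` if undefined).
#' @export
weir_cockerham_fst <- function(panel, snp) {
  scan <- fst_scan(panel)
  i <- match(snp, scan$snp_id)
  if (is.na(i)) stop_famdiv("unknown SNP: ", snp)
  scan$theta[i]
}

#' @export
summary.fst_scan <- function(object, brackets = c(15, 10, 5, 1), ...) {
  def <- object$theta[object$defined]
  cat(sprintf("<fst_scan> %d SNPs (%d defined)\n", nrow(object), length(def)))
  if (length(def)) {
    cat(sprintf("  theta: mean %.4f, median %.4f, range [%.4f, %.4f]\n",
                mean(def), stats::median(def), min(def), max(def)))
    if ("percentile_rank" %in% names(object)) {
      for (b in brackets) {
        col <- bracket_col(b)
        if (col %in% names(object))
          cat(sprintf("  top %g%%: %d SNPs\n", b, sum(object[[col]],
                                                      na.rm = TRUE)))
      }
    }
  }
  invisible(object)
}

#' @export
print.fst_scan <- function(x, ...) {
  summary.fst_scan(x)
  invisible(x)
}

bracket_col <- function(b) sprintf("top_%g", b)

#' Empirical percentile brackets over an F_ST scan
#'
#' Ranks defined theta values over the analysed SNP set (the ranking
#' universe: by design, all SNPs supplied in the run) and flags membership of
#' the upper percentile brackets. A bracket of q% flags the
#' `floor(n * q / 100)` largest theta values; ties with the cut value are
#' promoted into the better bracket, so flags are monotone (top-1 implies
#' top-5 implies top-10 implies top-15).
#'
#' @param scan an `fst_scan` table.
#' @param brackets numeric percent vector (default `c(15, 10, 5, 1)`).
#' @return The scan with added `percentile_rank` (share of defined SNPs with
#'   theta <= this SNP's theta, in 0–100) and one logical `top_<q>` column per
#'   bracket.
#' @export
rank_brackets <- function(scan, brackets = c(15, 10, 5, 1)) {
  if (nrow(scan) == 0) stop_famdiv("empty F_ST result set")
  def <- which(scan$defined & !is.na(scan$theta))
  if (!length(def)) stop_famdiv("no defined theta values to rank")
  th <- scan$theta[def]
  n <- length(th)
  scan$percentile_rank <- NA_real_
  scan$percentile_rank[def] <- 100 * rank(th, ties.method = "max") / n
  sorted <- sort(th, decreasing = TRUE)
  for (b in sort(brackets, decreasing = TRUE)) {
    k <- floor(n * b / 100)
    col <- bracket_col(b)
    scan[[col]] <- NA
    scan[[col]][def] <- if (k >= 1) th >= sorted[k] else FALSE
  }
  class(scan) <- c("fst_scan", "data.frame")
  scan
}

#' Gene-family enrichment of flagged genes
#'
#' Given a per-gene flag (e.g. "carries at least one nonsynonymous SNP in the
#' top-15% F_ST bracket"), compares each gene family's flagged fraction with
#' the conserved-gene background by a 2x2 chi-squared test (Yates correction
#' off, matching the usual large-sample contingency contrast).
#'
#' @param gene_flags named logical vector (names = gene ids) or `data.frame`
#'   with columns `gene_id`, `flag`.
#' @param family_map named character vector gene_id -> family; every flagged
#'   gene must be assigned.
#' @param conserved_group character vector of family labels forming the
#'   background group.
#' @param pooled optional named list of family-label groups to report as
#'   additional pooled rows (e.g. all progressive families together).
#' @return `data.frame` of class `family_enrichment`: one row per family (and
#'   pooled group) with `n_genes`, `n_hit`, `ratio`, and `chisq`/`p_value`
#'   against the conserved group (the conserved row carries `NA` tests).
#' @examples
#' tab <- fixture_from_counts(1327, 43, 25, 7)
#' fam <- setNames(ifelse(tab$group == "family", "CEACAM/PSG", "conserved"),
#'                 tab$gene_id)
#' family_enrichment(setNames(tab$flag, tab$gene_id), fam, "conserved")
#' @export
family_enrichment <- function(gene_flags, family_map, conserved_group,
                              pooled = NULL) {
  if (is.data.frame(gene_flags))
    gene_flags <- stats::setNames(gene_flags$flag, gene_flags$gene_id)
  if (!length(conserved_group)) stop_famdiv("conserved group is empty")
  if (!all(names(gene_flags) %in% names(family_map)))
    stop_famdiv("gene(s) without family assignment: ",
                paste(utils::head(setdiff(names(gene_flags),
                                          names(family_map))), collapse = ", "))
  fam <- family_map[names(gene_flags)]
  families <- unique(fam)
  groups <- c(list(conserved = intersect(families, conserved_group)),
              stats::setNames(as.list(setdiff(families, conserved_group)),
                              setdiff(families, conserved_group)),
              pooled)
  if (!length(groups$conserved))
    stop_famdiv("no genes belong to the conserved group")
  cons_genes <- gene_flags[fam %in% conserved_group]
  rows <- lapply(names(groups), function(gname) {
    genes <- gene_flags[fam %in% groups[[gname]]]
    if (!length(genes)) stop_famdiv("family with 0 genes: ", gname)
    n <- length(genes); hit <- sum(genes)
    if (gname == "conserved") {
      chisq <- NA_real_; p <- NA_real_
    } else if (hit == 0 && sum(cons_genes) == 0) {
      chisq <- 0; p <- 1  # no flagged genes anywhere: no evidence, p = 1
    } else {
      tab <- rbind(c(hit, n - hit),
                   c(sum(cons_genes), length(cons_genes) - sum(cons_genes)))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chisq <- unname(ct$statistic); p <- ct$p.value
    }
    data.frame(family = gname, n_genes = n, n_hit = hit, ratio = hit / n,
               chisq = chisq, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("family_enrichment", "data.frame")
  out
}

#' @export
print.family_enrichment <- function(x, digits = 3, ...) {
  cat("<family_enrichment> flagged-gene fractions vs conserved background\n")
  df <- as.data.frame(x)
  df$ratio <- sprintf("%.1f%%", 100 * df$ratio)
  df$chisq <- ifelse(is.na(df$chisq), "", sprintf("%.2f", df$chisq))
  df$p_value <- ifelse(is.na(df$p_value), "", format.pval(df$p_value,
                                                          digits = digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Per-gene synonymous/nonsynonymous SNP counts from a panel
#'
#' Tallies the panel's SNP annotations into one row per annotated gene.
#'
#' @param panel a [genotype_panel] whose SNP annotations carry `gene_id` and
#'   `consequence` (a `gene_family` column, when present, is carried through).
#' @return `data.frame` with columns `gene_id`, `family` (`NA` if
#'   unannotated), `n_syn`, `n_nonsyn`.
#' @export
per_gene_snp_counts <- function(panel) {
  s <- panel$snps[!is.na(panel$snps$gene_id), ]
  genes <- unique(s$gene_id)
  fam <- if ("gene_family" %in% names(s))
    s$gene_family[match(genes, s$gene_id)] else rep(NA_character_,
                                                    length(genes))
  data.frame(
    gene_id = genes,
    family = fam,
    n_syn = vapply(genes, function(g)
      sum(s$gene_id == g & s$consequence == "synonymous"), integer(1)),
    n_nonsyn = vapply(genes, function(g)
      sum(s$gene_id == g & s$consequence == "nonsynonymous"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Synonymous/nonsynonymous SNP-density contrast between gene groups
#'
#' Summarises per-gene SNP counts as group means with standard errors
#' (SEM = sd / sqrt(n)), compares group means by Welch's two-sample t-test,
#' and compares the fractions of genes carrying at least one nonsynonymous
#' SNP by a 2x2 chi-squared test.
#'
#' @param counts per-gene count table with columns `gene_id`, `family`,
#'   `n_syn`, `n_nonsyn` (see [per_gene_snp_counts()]).
#' @param family family label of the focal group.
#' @param conserved_group family label(s) of the background group.
#' @return A list of class `density_summary` with a per-group summary table
#'   (`groups`) and the test results (`welch_nonsyn`, `welch_syn`,
#'   `chisq_fraction`).
#' @export
snp_density <- function(counts, family, conserved_group) {
  grp <- ifelse(counts$family %in% family, "family",
                ifelse(counts$family %in% conserved_group, "conserved", NA))
  counts <- counts[!is.na(grp), ]; grp <- grp[!is.na(grp)]
  if (!any(grp == "family") || !any(grp == "conserved"))
    stop_famdiv("both the family and the conserved group must be non-empty")
  sem <- function(x) if (length(x) < 2) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  summarise <- function(which) {
    x <- counts[grp == which, ]
    data.frame(group = which, n_genes = nrow(x),
               mean_nonsyn = mean(x$n_nonsyn), sem_nonsyn = sem(x$n_nonsyn),
               mean_syn = mean(x$n_syn), sem_syn = sem(x$n_syn),
               fraction_with_nonsyn = mean(x$n_nonsyn > 0),
               stringsAsFactors = FALSE)
  }
  groups <- rbind(summarise("conserved"), summarise("family"))
  if (any(groups$n_genes < 2))
    warning("group with < 2 genes: SEM undefined", call. = FALSE)
  welch <- function(col) {
    a <- counts[[col]][grp == "family"]; b <- counts[[col]][grp == "conserved"]
    if (stats::var(a) + stats::var(b) == 0)
      return(list(statistic = 0, p.value = 1))
    stats::t.test(a, b)
  }
  wn <- welch("n_nonsyn"); ws <- welch("n_syn")
  hits <- c(sum(counts$n_nonsyn[grp == "family"] > 0),
            sum(counts$n_nonsyn[grp == "conserved"] > 0))
  tot <- c(sum(grp == "family"), sum(grp == "conserved"))
  chisq <- if (sum(hits) == 0) list(statistic = 0, p.value = 1) else
    suppressWarnings(stats::chisq.test(rbind(hits, tot - hits),
                                       correct = FALSE))
  structure(list(groups = groups,
                 welch_nonsyn = c(t = unname(wn$statistic),
                                  p = wn$p.value),
                 welch_syn = c(t = unname(ws$statistic), p = ws$p.value),
                 chisq_fraction = c(chisq = unname(chisq$statistic),
                                    p = chisq$p.value)),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat("<density_summary> per-gene SNP counts by group\n")
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf(
      "  %-9s n=%4d  nonsyn %.2f+-%.2f  syn %.2f+-%.2f  with nonsyn %.1f%%\n",
      g$group[i], g$n_genes[i], g$mean_nonsyn[i], g$sem_nonsyn[i],
      g$mean_syn[i], g$sem_syn[i], 100 * g$fraction_with_nonsyn[i]))
  cat(sprintf("  Welch t (nonsyn): p = %.3g; Welch t (syn): p = %.3g\n",
              x$welch_nonsyn["p"], x$welch_syn["p"]))
  cat(sprintf("  chi-squared (fraction with nonsyn): p = %.3g\n",
              x$chisq_fraction["p"]))
  invisible(x)
}
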