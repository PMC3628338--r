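#' Simulation configuration for synthetic genotype panels
#'
#' Bundles and validates the parameters of the Balding–Nichols panel
#' generator. The defaults describe the study conditions the analyses assume:
#' three continental-scale populations of HapMap-II size (60 unrelated
#' individuals each), a moderate genome-wide differentiation of F_ST = 0.10,
#' ancestral allele frequencies uniform on (0.05, 0.95) (common SNPs, as in a
#' genotyping-array panel), and per-gene SNP counts matching the chromosome-19
#' coding-SNP densities observed for the CEACAM/PSG family (nonsynonymous
#' mean 8.3 per family gene vs 3.8 per background gene; synonymous 4.2 vs
#' 3.6).
#'
#' @param seed master seed; every generator derives its own sub-stream from
#'   it.
#' @param n_populations,n_per_pop,n_snps panel dimensions.
#' @param target_fst Balding–Nichols F, in the open interval (0, 1).
#' @param ancestral_freq_law either `list(dist = "uniform", min, max)` or
#'   `list(dist = "beta", a, b)`.
#' @param n_genes number of genes SNPs are assigned to.
#' @param family_fraction fraction of genes belonging to the focal family.
#' @param nonsyn_rate_family,nonsyn_rate_background Poisson means of the
#'   per-gene nonsynonymous SNP count.
#' @param syn_rate_family,syn_rate_background Poisson means of the per-gene
#'   synonymous SNP count.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_populations = 3, n_per_pop = 60,
                              n_snps = 1000, target_fst = 0.10,
                              ancestral_freq_law = list(dist = "uniform",
                                                        min = 0.05,
                                                        max = 0.95),
                              n_genes = 50, family_fraction = 0.1,
                              nonsyn_rate_family = 8.3,
                              nonsyn_rate_background = 3.8,
                              syn_rate_family = 4.2,
                              syn_rate_background = 3.6) {
  cfg <- list(seed = seed, n_populations = n_populations,
              n_per_pop = n_per_pop, n_snps = n_snps, target_fst = target_fst,
              ancestral_freq_law = ancestral_freq_law, n_genes = n_genes,
              family_fraction = family_fraction,
              nonsyn_rate_family = nonsyn_rate_family,
              nonsyn_rate_background = nonsyn_rate_background,
              syn_rate_family = syn_rate_family,
              syn_rate_background = syn_rate_background)
  for (f in c("n_populations", "n_per_pop", "n_snps", "n_genes"))
    if (!is_count(cfg[[f]])) stop_famdiv(f, " must be a positive integer")
  if (!is.numeric(target_fst) || target_fst <= 0 || target_fst >= 1)
    stop_famdiv("target_fst must lie in the open interval (0, 1)")
  rates <- c(nonsyn_rate_family, nonsyn_rate_background,
             syn_rate_family, syn_rate_background)
  if (any(rates < 0)) stop_famdiv("SNP rates must be >= 0")
  if (family_fraction < 0 || family_fraction > 1)
    stop_famdiv("family_fraction must lie in [0, 1]")
  if (!ancestral_freq_law$dist %in% c("uniform", "beta"))
    stop_famdiv("ancestral_freq_law$dist must be 'uniform' or 'beta'")
  class(cfg) <- "simulation_config"
  cfg
}

draw_ancestral_freq <- function(law, n) {
  switch(law$dist,
         uniform = stats::runif(n, law$min %||% 0.05, law$max %||% 0.95),
         beta = stats::rbeta(n, law$a, law$b))
}

#' Simulate a multi-population genotype panel (Balding–Nichols model)
#'
#' For each SNP an ancestral frequency `p` is drawn from the configured law;
#' each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = target_fst`, so that
#' `Var(p_k) = F p (1 - p)`; diploid genotypes are then Binomial(2, p_k).
#' SNPs are laid out in order along one chromosome and assigned to genes:
#' per-gene synonymous and nonsynonymous SNP counts are Poisson with
#' family-specific means, and any remaining SNPs are intergenic
#' (`gene_id = NA`, consequence `"other"`). The generator is bit-reproducible
#' from `config$seed` and leaves the caller's RNG state untouched.
#'
#' @param config a [simulation_config].
#' @return A [genotype_panel]. Population labels are `pop1`, `pop2`, ...;
#'   per-SNP true ancestral frequencies are kept in the annotation column
#'   `true_p` for calibration checks.
#' @examples
#' panel <- simulate_genotype_panel(simulation_config(seed = 7, n_snps = 200))
#' panel
#' @export
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(sub_seed(config$seed, 1), {
    n_pop <- config$n_populations
    n_ind <- n_pop * config$n_per_pop
    n_snp <- config$n_snps
    f <- config$target_fst
    p <- draw_ancestral_freq(config$ancestral_freq_law, n_snp)
    g <- matrix(NA_integer_, n_snp, n_ind)
    for (k in seq_len(n_pop)) {
      pk <- stats::rbeta(n_snp, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      cols <- ((k - 1) * config$n_per_pop + 1):(k * config$n_per_pop)
      g[, cols] <- stats::rbinom(n_snp * config$n_per_pop, 2, pk)
    }
    inds <- sprintf("pop%d_ind%03d", rep(seq_len(n_pop),
                                         each = config$n_per_pop),
                    rep(seq_len(config$n_per_pop), n_pop))
    colnames(g) <- inds
    rownames(g) <- sprintf("snp%05d", seq_len(n_snp))
    pops <- stats::setNames(sprintf("pop%d", rep(seq_len(n_pop),
                                                 each = config$n_per_pop)),
                            inds)

    # gene landscape of the SNP annotations
    n_fam <- round(config$family_fraction * config$n_genes)
    gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
    is_fam <- seq_len(config$n_genes) <= n_fam
    nonsyn <- stats::rpois(config$n_genes,
                           ifelse(is_fam, config$nonsyn_rate_family,
                                  config$nonsyn_rate_background))
    syn <- stats::rpois(config$n_genes,
                        ifelse(is_fam, config$syn_rate_family,
                               config$syn_rate_background))
    gene_of <- rep(NA_character_, n_snp)
    csq <- rep("other", n_snp)
    assign <- rep(gene_ids, times = nonsyn + syn)
    types <- unlist(mapply(function(ns, s) c(rep("nonsynonymous", ns),
                                             rep("synonymous", s)),
                           nonsyn, syn, SIMPLIFY = FALSE))
    n_assign <- min(length(assign), n_snp)
    if (length(assign) > n_snp)
      warning("n_snps (", n_snp, ") smaller than the drawn per-gene SNP ",
              "total (", length(assign), "); gene assignments truncated",
              call. = FALSE)
    if (n_assign > 0) {
      gene_of[seq_len(n_assign)] <- assign[seq_len(n_assign)]
      csq[seq_len(n_assign)] <- types[seq_len(n_assign)]
    }
    snps <- data.frame(snp_id = rownames(g), chrom = "chrSim",
                       pos = seq_len(n_snp) * 1000L, gene_id = gene_of,
                       consequence = csq,
                       ancestral_is_ref = TRUE,
                       stringsAsFactors = FALSE)
    snps$true_p <- p
    snps$gene_family <- ifelse(is.na(gene_of), NA_character_,
                               ifelse(gene_of %in% gene_ids[is_fam],
                                      "FAM", "BG"))
    genotype_panel(g, pops, snps)
  })
}

#' Simulate a marker-anchored gene landscape with known duplication history
#'
#' Builds a reference species and one query species whose chromosomes mirror
#' marker-gene blocks of the reference, emulating the marker-flanked layout of
#' duplicated gene-family loci. Three block archetypes are generated, each on
#' its own chromosome pair:
#'
#' * *tandem blocks* — one query chromosome carrying the marker set plus an
#'   array of `tandem_size` family genes at neighbouring positions;
#' * *WGD blocks* — two query chromosome fragments each carrying a copy of the
#'   same reference marker set (duplicated marker orthologs, as for
#'   TOMM40a/TOMM40b in teleosts) plus one family gene per fragment;
#' * *singleton blocks* — one query chromosome with the markers and a single
#'   family gene.
#'
#' @param n_markers markers per block (>= 3).
#' @param n_tandem_arrays,n_wgd_blocks,n_singleton_blocks number of blocks of
#'   each archetype.
#' @param tandem_size family genes per tandem array (>= 2).
#' @param seed RNG seed (positions are jittered).
#' @param chrom_length chromosome length in bp; an error is raised if the
#'   layout cannot fit.
#' @param marker_spacing mean distance between adjacent markers (bp).
#' @param tandem_gap_bp gap between adjacent genes of a tandem array (bp).
#' @return A list with elements `annotations` (a [gene_annotation] covering
#'   both species), `marker_orthology` (data.frame `ref_id`, `query_id`), and
#'   `truth` (data.frame `gene_id`, `label` with the true duplication class of
#'   every query family gene).
#' @export
simulate_gene_landscape <- function(n_markers = 4, n_tandem_arrays = 1,
                                    n_wgd_blocks = 1, n_singleton_blocks = 1,
                                    tandem_size = 3, seed = 1,
                                    chrom_length = 5e7,
                                    marker_spacing = 400000,
                                    tandem_gap_bp = 50000) {
  if (n_markers < 3) stop_famdiv("n_markers must be >= 3 per block")
  if (tandem_size < 2) stop_famdiv("tandem_size must be >= 2")
  n_blocks <- n_tandem_arrays + n_wgd_blocks + n_singleton_blocks
  if (n_blocks < 1) stop_famdiv("at least one block is required")
  span <- (n_markers + tandem_size + 2) * (marker_spacing + 20000)
  if (span > chrom_length)
    stop_famdiv("infeasible layout: block span ", span,
                " bp exceeds chromosome length ", chrom_length, " bp")
  local_seed(sub_seed(seed, 2), {
    gene_len <- 10000
    ann <- list(); orth <- list(); truth <- list()
    types <- c(rep("tandem", n_tandem_arrays), rep("wgd", n_wgd_blocks),
               rep("singleton", n_singleton_blocks))
    for (b in seq_len(n_blocks)) {
      type <- types[b]
      mk_ids <- sprintf("M%d_%d", b, seq_len(n_markers))
      # reference chromosome: markers only
      pos <- cumsum(c(1e6, stats::runif(n_markers - 1, 0.6, 1.4) *
                        marker_spacing))
      ann[[length(ann) + 1]] <- data.frame(
        gene_id = mk_ids, species = "ref", chrom = sprintf("r_chr%d", b),
        start = as.integer(pos), end = as.integer(pos + gene_len),
        strand = ".", role = "marker", family = NA_character_,
        stringsAsFactors = FALSE)
      # query fragments: markers mirrored, family genes between markers 1-2
      n_frag <- if (type == "wgd") 2 else 1
      for (fg in seq_len(n_frag)) {
        suffix <- if (n_frag == 2) letters[fg] else ""
        qchrom <- sprintf("q_chr%d%s", b, suffix)
        qmk <- sprintf("%s_q%s", mk_ids, suffix)
        n_fam_here <- switch(type, tandem = tandem_size, wgd = 1,
                             singleton = 1)
        fam_ids <- sprintf("FAMG_b%d%s_%d", b, suffix, seq_len(n_fam_here))
        # family genes sit between the first two markers
        fam_start <- 1e6 + gene_len + 30000 +
          cumsum(c(0, rep(gene_len + tandem_gap_bp, n_fam_here - 1)))
        shift <- fam_start[n_fam_here] + gene_len + 30000 - 1e6
        qpos <- c(1e6, pos[-1] + shift)
        if (max(qpos) + gene_len > chrom_length)
          stop_famdiv("infeasible layout: genes exceed chromosome length")
        ann[[length(ann) + 1]] <- data.frame(
          gene_id = c(qmk, fam_ids), species = "query", chrom = qchrom,
          start = as.integer(c(qpos, fam_start)),
          end = as.integer(c(qpos, fam_start) + gene_len),
          strand = ".", role = c(rep("marker", n_markers),
                                 rep("family", n_fam_here)),
          family = c(rep(NA_character_, n_markers),
                     rep("FAM", n_fam_here)),
          stringsAsFactors = FALSE)
        orth[[length(orth) + 1]] <- data.frame(ref_id = mk_ids,
                                               query_id = qmk,
                                               stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          gene_id = fam_ids,
          label = switch(type, tandem = "tandem",
                         wgd = "wgd_coortholog", singleton = "singleton"),
          stringsAsFactors = FALSE)
      }
    }
    ann <- validate_gene_annotation(do.call(rbind, ann))
    list(annotations = ann,
         marker_orthology = do.call(rbind, orth),
         truth = do.call(rbind, truth))
  })
}

#' Simulate per-individual CNV genotypes
#'
#' Each CNV's event allele is sampled per haplotype at the record's frequency
#' for the requested population and combined under Hardy–Weinberg into event
#' counts 0/1/2.
#'
#' @param cnvs a [cnv_catalog].
#' @param n_individuals number of diploid individuals.
#' @param population population label whose frequency is used; every record
#'   must carry a frequency for it.
#' @param seed RNG seed.
#' @return Integer matrix of event counts, CNVs in rows (rownames = cnv_id),
#'   individuals in columns.
#' @export
simulate_cnv_genotypes <- function(cnvs, n_individuals, population,
                                   seed = 1) {
  stopifnot(inherits(cnvs, "cnv_catalog"))
  freqs <- vapply(cnvs$freq, function(f) {
    if (!population %in% names(f))
      stop_famdiv("no frequency for population '", population, "'")
    unname(f[[population]])
  }, numeric(1))
  local_seed(sub_seed(seed, 3), {
    g <- matrix(stats::rbinom(nrow(cnvs) * n_individuals, 2, rep(freqs,
                                                                 n_individuals)),
                nrow = nrow(cnvs), ncol = n_individuals)
    rownames(g) <- cnvs$cnv_id
    colnames(g) <- sprintf("ind%05d", seq_len(n_individuals))
    g
  })
}

#' Build a deterministic per-gene flag table from printed counts
#'
#' Reconstructs the exact count structure of a published 2x2 gene-level
#' contrast (total genes and flagged genes in a background group and in a
#' family group), so that enrichment operations can be exercised against
#' printed tables.
#'
#' @param total_genes,flagged_genes background-group counts.
#' @param family_total,family_flagged family-group counts.
#' @return `data.frame` with columns `gene_id`, `group` (`"background"` /
#'   `"family"`) and logical `flag`; the first `flagged` genes of each group
#'   are flagged.
#' @examples
#' tab <- fixture_from_counts(1363, 113, 25, 10)
#' tapply(tab$flag, tab$group, mean)   # 0.0829, 0.40
#' @export
fixture_from_counts <- function(total_genes, flagged_genes, family_total,
                                family_flagged) {
  if (flagged_genes > total_genes || family_flagged > family_total)
    stop_famdiv("flagged count exceeds total count")
  data.frame(
    gene_id = c(sprintf("bg%04d", seq_len(total_genes)),
                sprintf("fam%04d", seq_len(family_total))),
    group = c(rep("background", total_genes), rep("family", family_total)),
    flag = c(seq_len(total_genes) <= flagged_genes,
             seq_len(family_total) <= family_flagged),
    stringsAsFactors = FALSE)
}
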