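#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or an equivalent list), checks every field,
#' and returns a normalised `run_config`. Validation is collect-all: every
#' problem found is reported in a single error message rather than one at a
#' time. Unknown keys are errors (they usually mean a typo); a missing seed
#' is defaulted to 1 with a warning.
#'
#' Recognised top-level keys: `seed`, `output_dir`, `stages` (subset of
#' `simulate`, `synteny`, `fst`, `enrich`, `density`, `ld`, `cnv`),
#' `thresholds` (`tandem_gap`, `min_markers`, `max_gap`, `ld_r2`, `brackets`,
#' `cnv_min_len`, `freq_threshold`, `locus`), `simulate` (arguments of
#' [simulation_config()] plus `landscape` and `cnv` sub-blocks), `paths`
#' (`annotations`, `orthology`, `genotypes`, `pop_manifest`, `cnv_catalog`,
#' `baseline`), `family` and `conserved`.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return A `run_config` list.
#' @export
validate_config <- function(config) {
  config_dir <- NULL
  if (is.character(config)) {
    if (!file.exists(config)) stop_famdiv("no such config file: ", config)
    config_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  # resolve relative input paths against the config file's directory
  if (!is.null(config_dir) && !is.null(config$paths)) {
    config$paths <- lapply(config$paths, function(p) {
      if (!file.exists(p) && file.exists(file.path(config_dir, p)))
        file.path(config_dir, p) else p
    })
  }
  errors <- character(0)
  note <- function(...) errors <<- c(errors, paste0(...))

  known <- c("seed", "output_dir", "stages", "thresholds", "simulate",
             "paths", "family", "conserved")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) note("unknown key(s): ", paste(unknown, collapse = ", "))

  all_stages <- c("simulate", "synteny", "fst", "enrich", "density", "ld",
                  "cnv")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) note("unknown stage(s): ", paste(bad, collapse = ", "))

  if (is.null(config$seed)) {
    warning("no seed in config; defaulting to 1", call. = FALSE)
    config$seed <- 1
  } else if (!is.numeric(config$seed)) note("seed must be numeric")

  th_known <- c("tandem_gap", "min_markers", "max_gap", "ld_r2", "brackets",
                "cnv_min_len", "freq_threshold", "locus")
  th <- config$thresholds %||% list()
  unknown_th <- setdiff(names(th), th_known)
  if (length(unknown_th))
    note("unknown threshold key(s): ", paste(unknown_th, collapse = ", "))
  defaults <- list(tandem_gap = 5e5, min_markers = 2, max_gap = 2e6,
                   ld_r2 = 0.8, brackets = c(15, 10, 5, 1),
                   cnv_min_len = 500, freq_threshold = 0.01, locus = NULL)
  th <- utils::modifyList(defaults, th[intersect(names(th), th_known)])
  if (th$ld_r2 <= 0 || th$ld_r2 > 1) note("threshold ld_r2 out of range (0, 1]")
  if (th$freq_threshold < 0 || th$freq_threshold >= 1)
    note("threshold freq_threshold out of range [0, 1)")
  if (any(th$brackets <= 0 | th$brackets > 100))
    note("threshold brackets must lie in (0, 100]")
  if (th$min_markers < 1) note("threshold min_markers must be >= 1")

  paths <- config$paths %||% list()
  path_known <- c("annotations", "orthology", "genotypes", "pop_manifest",
                  "cnv_catalog", "baseline")
  unknown_p <- setdiff(names(paths), path_known)
  if (length(unknown_p))
    note("unknown path key(s): ", paste(unknown_p, collapse = ", "))

  # validate-first: every enabled stage must have resolvable inputs
  need_path <- function(stage, keys) {
    if (!stage %in% stages) return()
    if ("simulate" %in% stages) return()  # simulate provides them
    for (k in keys) {
      if (is.null(paths[[k]]))
        note("stage '", stage, "' needs paths$", k,
             " when the simulate stage is disabled")
      else if (!file.exists(paths[[k]]))
        note("stage '", stage, "': no such file: ", paths[[k]])
    }
  }
  need_path("synteny", c("annotations", "orthology"))
  for (s in c("fst", "enrich", "density", "ld"))
    need_path(s, c("genotypes", "pop_manifest"))
  if ("cnv" %in% stages && is.null(paths$cnv_catalog))
    note("stage 'cnv' needs paths$cnv_catalog")
  else if ("cnv" %in% stages && !file.exists(paths$cnv_catalog))
    note("stage 'cnv': no such file: ", paths$cnv_catalog)

  if (length(errors))
    stop_famdiv("invalid configuration:\n  - ",
                paste(errors, collapse = "\n  - "))

  structure(list(seed = config$seed,
                 output_dir = config$output_dir %||% "famdiv_out",
                 stages = stages, thresholds = th,
                 simulate = config$simulate %||% list(),
                 paths = paths,
                 family = config$family %||% "FAM",
                 conserved = config$conserved %||% "BG"),
            class = "run_config")
}

stage_sidecar <- function(dir, stage, params, inputs = character(0)) {
  meta <- list(stage = stage, parameters = params,
               package = paste0("famdiv ",
                                as.character(utils::packageVersion("famdiv"))),
               inputs = as.list(tools::md5sum(inputs)))
  names(meta$inputs) <- basename(inputs)
  jsonlite::write_json(meta, file.path(dir, paste0(stage, ".meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate, synteny, fst, enrich, density, ld, cnv), writing each stage's
#' TSV outputs plus a JSON metadata sidecar (parameters, seed, package
#' version, input checksums) into `output_dir`, and finally a Markdown report
#' whose every number is read back from a stage output. Identical
#' configuration and seed yield byte-identical output trees.
#'
#' @param config a `run_config` from [validate_config()] (or a path/list,
#'   validated on the fly).
#' @return Invisibly, the character vector of files written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  th <- config$thresholds
  written <- character(0)
  emit <- function(df, f) {
    write_tsv(df, out(f)); written <<- c(written, out(f))
  }
  message("famdiv pipeline: stages [", paste(config$stages, collapse = ", "),
          "], seed ", config$seed)

  panel <- NULL; ann <- NULL; orth <- NULL; truth <- NULL; cnvs <- NULL
  baseline <- NULL

  # ---- simulate ----
  if ("simulate" %in% config$stages) {
    sim <- config$simulate
    cfg_args <- sim[intersect(names(sim),
                              names(formals(simulation_config)))]
    cfg_args$seed <- config$seed
    scfg <- do.call(simulation_config, cfg_args)
    panel <- simulate_genotype_panel(scfg)
    write_genotypes(panel, out("genotypes.tsv"), "tsv",
                    manifest_path = out("pop_manifest.tsv"))
    ls_args <- sim$landscape %||% list()
    ls_args$seed <- config$seed
    land <- do.call(simulate_gene_landscape, ls_args)
    ann <- land$annotations; orth <- land$marker_orthology
    truth <- land$truth
    write_gene_annotations(ann, out("annotations.bed"), "bed")
    emit(orth, "marker_orthology.tsv")
    emit(truth, "landscape_truth.tsv")
    written <- c(written, out("genotypes.tsv"), out("pop_manifest.tsv"),
                 out("annotations.bed"))
    stage_sidecar(config$output_dir, "simulate",
                  list(config = unclass(scfg), landscape = ls_args))
    message("  simulate: ", nrow(panel$genotypes), " SNPs, ",
            ncol(panel$genotypes), " individuals; landscape with ",
            nrow(truth), " family genes")
  } else {
    p <- config$paths
    if (!is.null(p$genotypes))
      panel <- read_genotypes(p$genotypes, p$pop_manifest, "tsv")
    if (!is.null(p$annotations))
      ann <- read_gene_annotations(p$annotations, "bed")
    if (!is.null(p$orthology))
      orth <- utils::read.table(p$orthology, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  if (!is.null(config$paths$cnv_catalog))
    cnvs <- read_cnv_catalog(config$paths$cnv_catalog)
  if (!is.null(config$paths$baseline)) {
    b <- utils::read.table(config$paths$baseline, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    baseline <- stats::setNames(as.integer(b$copies), b$gene_id)
  }

  # ---- synteny ----
  calls <- NULL; inv <- NULL
  if ("synteny" %in% config$stages) {
    species <- unique(ann$species)
    if (length(species) < 2)
      stop_famdiv("synteny stage needs annotations for two species")
    ref <- ann[ann$species == species[1], ]
    query <- ann[ann$species == species[2], ]
    blocks <- find_blocks(ref, query, orth, th$min_markers, th$max_gap)
    fam_genes <- query[query$role == "family", ]
    calls <- classify_duplicates(fam_genes, blocks, th$tandem_gap,
                                 th$min_markers)
    family_label <- stats::na.omit(unique(fam_genes$family))[1]
    inv <- inventory(ann, family_label)
    emit(as.data.frame(blocks), "synteny_blocks.tsv")
    emit(as.data.frame(calls), "duplication_calls.tsv")
    emit(inv, "inventory.tsv")
    stage_sidecar(config$output_dir, "synteny",
                  list(tandem_gap = th$tandem_gap,
                       min_markers = th$min_markers, max_gap = th$max_gap))
    message("  synteny: ", nrow(blocks), " blocks, ", nrow(calls), " calls")
  }

  # ---- fst ----
  scan <- NULL
  if ("fst" %in% config$stages) {
    scan <- rank_brackets(fst_scan(panel), th$brackets)
    emit(scan, "fst.tsv")
    stage_sidecar(config$output_dir, "fst",
                  list(estimator = "Weir-Cockerham 1984 theta (a/(a+b+c))",
                       brackets = th$brackets,
                       tie_rule = "ties promoted to the better bracket",
                       seed = config$seed))
    message("  fst: ", sum(scan$defined), "/", nrow(scan),
            " SNPs with defined theta; mean ",
            signif(mean(scan$theta[scan$defined]), 3))
  }

  # ---- enrich ----
  enr_tables <- NULL
  if ("enrich" %in% config$stages) {
    s <- panel$snps
    fam_map <- stats::setNames(s$gene_family, s$gene_id)[!is.na(s$gene_id)]
    fam_map <- fam_map[!duplicated(names(fam_map))]
    genes <- names(fam_map)
    enr_tables <- do.call(rbind, lapply(th$brackets, function(b) {
      col <- bracket_col(b)
      hit_snp <- !is.na(scan[[col]]) & scan[[col]] &
        s$consequence == "nonsynonymous" & !is.na(s$gene_id)
      flags <- stats::setNames(genes %in% s$gene_id[hit_snp], genes)
      e <- family_enrichment(flags, fam_map, config$conserved)
      cbind(bracket = b, as.data.frame(e))
    }))
    emit(enr_tables, "family_enrichment.tsv")
    stage_sidecar(config$output_dir, "enrich",
                  list(brackets = th$brackets, conserved = config$conserved))
    message("  enrich: ", length(genes), " genes over ",
            length(th$brackets), " brackets")
  }

  # ---- density ----
  dens <- NULL
  if ("density" %in% config$stages) {
    counts <- per_gene_snp_counts(panel)
    dens <- snp_density(counts, config$family, config$conserved)
    tab <- dens$groups
    tab$welch_nonsyn_p <- dens$welch_nonsyn["p"]
    tab$chisq_fraction_p <- dens$chisq_fraction["p"]
    emit(tab, "snp_density.tsv")
    stage_sidecar(config$output_dir, "density",
                  list(family = config$family, conserved = config$conserved,
                       tests = c("Welch t", "chi-squared")))
    message("  density: family mean nonsyn ",
            signif(tab$mean_nonsyn[tab$group == "family"], 3),
            " vs conserved ",
            signif(tab$mean_nonsyn[tab$group == "conserved"], 3))
  }

  # ---- ld ----
  if ("ld" %in% config$stages) {
    n_ld <- min(nrow(panel$genotypes),
                config$simulate$ld_snps %||% 15)
    snps <- panel$snps$snp_id[seq_len(n_ld)]
    r2 <- ld_matrix(panel, snps)
    blocks_ld <- ld_blocks(r2, th$ld_r2)
    emit(data.frame(snp = snps, as.data.frame(round(r2, 6))), "ld_r2.tsv")
    emit(blocks_ld, "ld_blocks.tsv")
    stage_sidecar(config$output_dir, "ld",
                  list(threshold = th$ld_r2, n_snps = n_ld,
                       method = "EM haplotype frequencies"))
    message("  ld: ", nrow(blocks_ld), " block(s) at r2 >= ", th$ld_r2)
  }

  # ---- cnv ----
  cnv_sum <- NULL; cn_range <- NULL
  if ("cnv" %in% config$stages) {
    locus <- th$locus
    cnv_sum <- cnv_summary(cnvs, c(th$cnv_min_len, 20000),
                           locus = locus)
    poly <- classify_polymorphisms(cnvs, th$freq_threshold)
    popdiff <- cnv_population_differentiation(cnvs)
    directional <- cnvs[cnvs$cnv_type %in% c("gain", "loss") &
                          lengths(cnvs$genes) > 0, ]
    class(directional) <- c("cnv_catalog", "data.frame")
    if (is.null(baseline)) {
      genes <- sort(unique(unlist(directional$genes)))
      baseline <- stats::setNames(rep(2L, length(genes)), genes)
    }
    cn_range <- copy_number_range(directional, baseline)
    emit(data.frame(metric = c("n_total", names(cnv_sum$n_over_length),
                               "locus_n_in", "locus_fraction",
                               "copy_min", "copy_max", "copy_baseline"),
                    value = c(cnv_sum$n_total, cnv_sum$n_over_length,
                              if (is.null(cnv_sum$locus)) c(NA, NA)
                              else c(cnv_sum$locus$n_in,
                                     cnv_sum$locus$fraction),
                              cn_range["min"], cn_range["max"],
                              sum(baseline))),
         "cnv_summary.tsv")
    emit(data.frame(cnv_id = names(poly), polymorphism = unname(poly)),
         "cnv_polymorphisms.tsv")
    emit(popdiff, "cnv_popdiff.tsv")
    emit(cnv_sum$size_histogram, "cnv_size_histogram.tsv")
    if ("simulate" %in% config$stages) {
      sim_cnv <- config$simulate$cnv %||% list()
      pop <- sim_cnv$population %||%
        names(cnvs$freq[[which.max(lengths(cnvs$freq))]])[1]
      gts <- simulate_cnv_genotypes(directional,
                                    sim_cnv$n_individuals %||% 100,
                                    pop, seed = config$seed)
      prof <- suppressWarnings(gene_copy_number(gts, directional, baseline))
      emit(data.frame(individual = colnames(prof),
                      family_total = attr(prof, "total")),
           "copy_number_totals.tsv")
    }
    stage_sidecar(config$output_dir, "cnv",
                  list(min_len = th$cnv_min_len,
                       freq_threshold = th$freq_threshold, locus = locus),
                  inputs = config$paths$cnv_catalog %||% character(0))
    message("  cnv: ", nrow(cnvs), " records; family copy range ",
            cn_range["min"], "-", cn_range["max"])
  }

  write_report(config, out("report.md"), calls, inv, scan, enr_tables, dens,
               cnv_sum, cn_range)
  written <- c(written, out("report.md"))
  invisible(sort(unique(written)))
}

write_report <- function(config, path, calls, inv, scan, enr, dens, cnv_sum,
                        cn_range) {
  lines <- c("# famdiv pipeline report", "",
             paste0("Seed: ", config$seed),
             paste0("Stages: ", paste(config$stages, collapse = ", ")), "")
  if (!is.null(inv)) {
    lines <- c(lines, "## Gene-family inventory", "",
               paste0("- ", inv$species, ": ", inv$n_genes, " family genes"),
               "")
  }
  if (!is.null(calls)) {
    tc <- table(calls$label)
    lines <- c(lines, "## Duplication calls", "",
               paste0("- ", names(tc), ": ", as.integer(tc)), "")
  }
  if (!is.null(scan)) {
    def <- scan$theta[scan$defined]
    lines <- c(lines, "## F_ST scan", "",
               sprintf("- %d/%d SNPs defined; mean theta %.4f",
                       sum(scan$defined), nrow(scan), mean(def)), "")
  }
  if (!is.null(dens)) {
    g <- dens$groups
    lines <- c(lines, "## SNP density (per-gene means +- SEM)", "",
               sprintf("- %s: nonsyn %.2f+-%.2f, syn %.2f+-%.2f (n=%d, %.1f%% with nonsyn)",
                       g$group, g$mean_nonsyn, g$sem_nonsyn, g$mean_syn,
                       g$sem_syn, g$n_genes, 100 * g$fraction_with_nonsyn),
               sprintf("- Welch t-test (nonsyn): p = %.3g",
                       dens$welch_nonsyn["p"]), "")
  }
  if (!is.null(enr)) {
    lines <- c(lines, "## High-F_ST nonsynonymous gene-family enrichment", "",
               sprintf("- top %g%% bracket, %s: %d/%d genes (%.1f%%)",
                       enr$bracket, enr$family, enr$n_hit, enr$n_genes,
                       100 * enr$ratio), "")
  }
  if (!is.null(cnv_sum)) {
    lines <- c(lines, "## CNV summary", "",
               sprintf("- records over length cuts: %s",
                       paste(names(cnv_sum$n_over_length),
                             cnv_sum$n_over_length, collapse = ", ")),
               if (!is.null(cnv_sum$locus))
                 sprintf("- locus overlap: %d/%d (%.1f%%)",
                         cnv_sum$locus$n_in, cnv_sum$locus$n_total,
                         100 * cnv_sum$locus$fraction),
               if (!is.null(cn_range))
                 sprintf("- attainable family copy-number range: %d-%d",
                         cn_range["min"], cn_range["max"]),
               "")
  }
  writeLines(lines, path)
}
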