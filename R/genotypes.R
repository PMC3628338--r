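#' Construct a validated genotype panel
#'
#' Diploid SNP genotypes for individuals grouped into populations, the input
#' to the F_ST scan and LD machinery. Genotypes are counts of the non-reference
#' allele (0/1/2, `NA` for missing); ancestral/derived polarity, when known,
#' travels as the per-SNP `ancestral_is_ref` flag rather than by recoding the
#' counts.
#'
#' @param genotypes integer matrix, SNPs in rows (rownames = SNP ids),
#'   individuals in columns (colnames = individual ids), values in
#'   `{0, 1, 2, NA}`.
#' @param populations named character vector mapping every individual (names)
#'   to its population label.
#' @param snps optional per-SNP annotation `data.frame` with columns
#'   `snp_id`, `chrom`, `pos`, `gene_id` (`NA` for intergenic), `consequence`
#'   (`"synonymous"`, `"nonsynonymous"` or `"other"`) and `ancestral_is_ref`
#'   (logical, `NA` if unpolarised). Defaults to a skeleton built from the
#'   rownames.
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `populations` and `snps` (which gains a `missingness`
#'   column, the per-SNP fraction of missing genotypes).
#' @export
genotype_panel <- function(genotypes, populations, snps = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop_famdiv("genotype matrix needs SNP rownames and individual colnames")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2))
    stop_famdiv("genotypes must be allele counts in {0, 1, 2} or NA")
  inds <- colnames(genotypes)
  if (!all(inds %in% names(populations)))
    stop_famdiv("individual(s) without a population label: ",
                paste(setdiff(inds, names(populations)), collapse = ", "))
  populations <- populations[inds]
  if (any(table(populations) < 1))
    stop_famdiv("every population must contain at least one individual")
  if (is.null(snps)) {
    snps <- data.frame(snp_id = rownames(genotypes), chrom = NA_character_,
                       pos = NA_integer_, gene_id = NA_character_,
                       consequence = "other", ancestral_is_ref = NA,
                       stringsAsFactors = FALSE)
  }
  snps <- as.data.frame(snps)
  if (!identical(as.character(snps$snp_id), rownames(genotypes)))
    stop_famdiv("snp annotation order must match genotype matrix rows")
  if (!all(snps$consequence %in% c("synonymous", "nonsynonymous", "other")))
    stop_famdiv("consequence must be synonymous/nonsynonymous/other")
  snps$missingness <- rowMeans(is.na(genotypes))
  structure(list(genotypes = genotypes, populations = populations,
                 snps = snps),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  pt <- table(x$populations)
  cat(sprintf("<genotype_panel> %d SNPs x %d individuals\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat("  populations:", paste(names(pt), pt, sep = "=", collapse = " "), "\n")
  cat(sprintf("  missingness: %.3f (mean per-SNP fraction)\n",
              mean(x$snps$missingness)))
  ct <- table(x$snps$consequence)
  cat("  consequences:", paste(names(ct), ct, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a genotype panel from VCF or the TSV dialect
#'
#' VCF input uses the GT field only (parsed with \pkg{vcfR}); `GENE=`, `CSQ=`
#' and `AA=` INFO keys, when present, populate the per-SNP gene, consequence
#' and ancestral-allele annotations. Sites must be biallelic: multiallelic
#' records are split into one pseudo-biallelic row per alternate allele when
#' `split_multiallelic = TRUE` and rejected otherwise. The TSV dialect has
#' header columns `snp_id chrom pos gene_id consequence ancestral_is_ref`
#' followed by one column per individual holding 0/1/2/NA.
#'
#' @param path genotype file.
#' @param pop_manifest TSV with header `individual<TAB>population`; every
#'   individual in the genotype file must appear in it.
#' @param format `"vcf"` or `"tsv"`.
#' @param split_multiallelic split multiallelic VCF records instead of
#'   erroring.
#' @return A [genotype_panel].
#' @export
read_genotypes <- function(path, pop_manifest, format = c("vcf", "tsv"),
                           split_multiallelic = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_famdiv("no such file: ", path)
  man <- utils::read.table(pop_manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(man)))
    stop_famdiv("population manifest needs 'individual' and 'population' columns")
  pops <- stats::setNames(as.character(man$population),
                          as.character(man$individual))
  if (format == "tsv") read_genotypes_tsv(path, pops)
  else read_genotypes_vcf(path, pops, split_multiallelic)
}

read_genotypes_tsv <- function(path, pops) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."))
  meta_cols <- c("snp_id", "chrom", "pos", "gene_id", "consequence",
                 "ancestral_is_ref")
  if (!all(meta_cols %in% names(df)))
    stop_famdiv("genotype TSV must carry columns: ",
                paste(meta_cols, collapse = ", "))
  inds <- setdiff(names(df), meta_cols)
  g <- as.matrix(df[, inds, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df$snp_id
  snps <- df[, meta_cols]
  snps$ancestral_is_ref <- as.logical(snps$ancestral_is_ref)
  rownames(snps) <- NULL
  missing_pop <- setdiff(inds, names(pops))
  if (length(missing_pop))
    stop_famdiv("individual(s) missing from population manifest: ",
                paste(missing_pop, collapse = ", "))
  genotype_panel(g, pops, snps)
}

read_genotypes_vcf <- function(path, pops, split_multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  inds <- colnames(gt)
  missing_pop <- setdiff(inds, names(pops))
  if (length(missing_pop))
    stop_famdiv("individual(s) missing from population manifest: ",
                paste(missing_pop, collapse = ", "))
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  info <- vcfR::getINFO(v)
  multi <- grepl(",", fix$ALT)
  if (any(multi) && !split_multiallelic)
    stop_famdiv("non-biallelic record(s) at ",
                paste(fix$CHROM[multi], fix$POS[multi], sep = ":",
                      collapse = ", "),
                " (set split_multiallelic = TRUE to split)")
  count_allele <- function(gt_row, allele) {
    a <- strsplit(gsub("\\|", "/", gt_row), "/")
    vapply(a, function(x) {
      if (length(x) < 2 || any(x == ".")) return(NA_integer_)
      sum(x == as.character(allele))
    }, integer(1))
  }
  rows <- list(); ann <- list(); k <- 0
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    for (j in seq_along(alts)) {
      k <- k + 1
      id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i]
            else paste0(fix$CHROM[i], ":", fix$POS[i])
      if (length(alts) > 1) id <- paste0(id, "_alt", j)
      rows[[k]] <- count_allele(gt[i, ], j)
      csq <- info_field(info[i], "CSQ")
      aa <- info_field(info[i], "AA")
      ann[[k]] <- data.frame(
        snp_id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        gene_id = info_field(info[i], "GENE"),
        consequence = if (is.na(csq)) "other" else csq,
        ancestral_is_ref = if (is.na(aa) || aa == ".") NA
                           else identical(aa, fix$REF[i]),
        stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, rows)
  snps <- do.call(rbind, ann)
  rownames(g) <- snps$snp_id
  colnames(g) <- inds
  genotype_panel(g, pops, snps)
}

#' Write a genotype panel to the TSV dialect or a minimal VCF
#'
#' The TSV writer is the exact inverse of the TSV reader. The VCF writer emits
#' a minimal VCF 4.2 with GT-only genotypes and `GENE`/`CSQ`/`AA` INFO keys;
#' because the panel stores allele counts rather than nucleotides, placeholder
#' REF/ALT bases (`A`/`G`) are written, which round-trips every field the
#' panel carries.
#'
#' @param panel a [genotype_panel].
#' @param path output genotype file.
#' @param format `"tsv"` or `"vcf"`.
#' @param manifest_path optional path; when given, the population manifest TSV
#'   is written alongside.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "vcf"),
                            manifest_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(manifest_path)) {
    write_tsv(data.frame(individual = names(panel$populations),
                         population = unname(panel$populations)),
              manifest_path)
  }
  if (format == "tsv") {
    meta <- panel$snps[, c("snp_id", "chrom", "pos", "gene_id",
                           "consequence", "ancestral_is_ref")]
    write_tsv(cbind(meta, as.data.frame(panel$genotypes)), path)
    return(invisible(path))
  }
  s <- panel$snps
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(panel$genotypes), ncol(panel$genotypes))
  ok <- !is.na(panel$genotypes)
  gt[ok] <- gt_code[as.character(panel$genotypes[ok])]
  info <- sprintf("%s%sAA=%s",
                  ifelse(is.na(s$gene_id), "", paste0("GENE=", s$gene_id, ";")),
                  paste0("CSQ=", s$consequence, ";"),
                  ifelse(is.na(s$ancestral_is_ref), ".",
                         ifelse(s$ancestral_is_ref, "A", "G")))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
              "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(panel$genotypes)),
                    collapse = "\t"))
  body <- paste(ifelse(is.na(s$chrom), "chrUn", s$chrom),
                ifelse(is.na(s$pos), seq_len(nrow(s)), s$pos),
                s$snp_id, "A", "G", ".", "PASS", info, "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
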