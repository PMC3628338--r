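#' Construct a validated gene-annotation table
#'
#' The central gene container used by the synteny and simulation modules: one
#' row per gene locus, with 0-based half-open coordinates regardless of the
#' file dialect the record came from. `role` separates the gene family under
#' study (`"family"`) from the single-copy marker genes that anchor syntenic
#' blocks (`"marker"`, e.g. TGFB1, ATP1A3, TOMM40) and everything else
#' (`"other"`).
#'
#' @param gene_id character vector of gene identifiers.
#' @param species character vector (recycled) naming the source genome.
#' @param chrom character vector of chromosome/contig names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand `"+"`, `"-"` or `"."` (recycled; strand is carried but never
#'   used by overlap computations).
#' @param role one of `"family"`, `"marker"`, `"other"` per gene (recycled).
#' @param family optional family label (e.g. `"CEACAM/PSG"`); `NA` for genes
#'   outside any annotated family.
#' @return A `data.frame` of class `gene_annotation` with the columns above.
#' @examples
#' gene_annotation("PSG1", "human", "chr19", 47600000, 47620000,
#'                 role = "family", family = "CEACAM/PSG")
#' @export
gene_annotation <- function(gene_id, species = "unspecified", chrom, start,
                            end, strand = ".", role = "other", family = NA) {
  n <- length(gene_id)
  ann <- data.frame(
    gene_id = as.character(gene_id),
    species = rep_len(as.character(species), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    role = rep_len(as.character(role), n),
    family = rep_len(as.character(family), n),
    stringsAsFactors = FALSE
  )
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  if (any(is.na(ann$start)) || any(is.na(ann$end)))
    stop_famdiv("gene annotation has non-integer coordinates")
  if (any(ann$start < 0))
    stop_famdiv("gene annotation has negative start coordinates")
  bad <- which(ann$end <= ann$start)
  if (length(bad))
    stop_famdiv("gene annotation has end <= start for gene(s): ",
                paste(ann$gene_id[bad], collapse = ", "))
  if (!all(ann$strand %in% c("+", "-", ".")))
    stop_famdiv("strand must be one of '+', '-', '.'")
  if (!all(ann$role %in% c("family", "marker", "other")))
    stop_famdiv("role must be one of 'family', 'marker', 'other'")
  key <- paste(ann$gene_id, ann$species)
  if (anyDuplicated(key))
    stop_famdiv("duplicate (gene_id, species): ",
                paste(unique(key[duplicated(key)]), collapse = ", "))
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d loci, %d species, %d chromosome(s)\n",
              nrow(x), length(unique(x$species)), length(unique(x$chrom))))
  rc <- table(x$role)
  cat("  roles:", paste(names(rc), rc, sep = "=", collapse = " "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read gene annotations from BED or GFF3
#'
#' BED input is the tab/space-separated extended dialect
#' `chrom start end gene_id [score strand species role family]` (0-based
#' half-open, extra columns optional). GFF3 input (1-based closed, converted
#' to the internal 0-based half-open convention on read) is parsed with
#' \pkg{rtracklayer}; `species`, `role` and `family` are taken from the
#' attribute column when present.
#'
#' @param path path to the annotation file.
#' @param format `"bed"` or `"gff"`.
#' @param species default species label applied to records that do not carry
#'   their own.
#' @return A [gene_annotation] table.
#' @seealso [write_gene_annotations()]
#' @export
read_gene_annotations <- function(path, format = c("bed", "gff"),
                                  species = "unspecified") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_famdiv("no such file: ", path)
  if (format == "bed") read_annotations_bed(path, species)
  else read_annotations_gff(path, species)
}

read_annotations_bed <- function(path, species) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- lapply(seq_along(idx), function(i) {
    ln <- idx[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 4)
      stop_famdiv("malformed BED line ", ln, ": fewer than 4 fields")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      stop_famdiv("malformed BED line ", ln, ": non-integer coordinates")
    if (e <= s)
      stop_famdiv("malformed BED line ", ln, ": end <= start")
    data.frame(gene_id = f[4], species = if (length(f) >= 7) f[7] else species,
               chrom = f[1], start = s, end = e,
               strand = if (length(f) >= 6) f[6] else ".",
               role = if (length(f) >= 8) f[8] else "other",
               family = if (length(f) >= 9 && f[9] != ".") f[9] else NA_character_,
               stringsAsFactors = FALSE)
  })
  validate_gene_annotation(do.call(rbind, rows))
}

read_annotations_gff <- function(path, species) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  get_attr <- function(name, default) {
    if (name %in% names(df)) {
      v <- as.character(df[[name]])
      ifelse(is.na(v) | v == "", default, v)
    } else rep(default, nrow(df))
  }
  ann <- data.frame(
    gene_id = get_attr("ID", NA_character_),
    species = get_attr("species", species),
    chrom = as.character(df$seqnames),
    start = df$start - 1L,          # GFF 1-based closed -> 0-based half-open
    end = df$end,
    strand = ifelse(as.character(df$strand) == "*", ".",
                    as.character(df$strand)),
    role = get_attr("role", "other"),
    family = get_attr("family", NA_character_),
    stringsAsFactors = FALSE
  )
  if (any(is.na(ann$gene_id)))
    stop_famdiv("GFF record(s) without an ID attribute in ", path)
  validate_gene_annotation(ann)
}

#' Write gene annotations to BED or GFF3
#'
#' Inverse of [read_gene_annotations()]: a write/read round trip reproduces
#' the annotation table exactly, including the GFF3 1-based-closed to
#' 0-based-half-open coordinate conversion (an involution).
#'
#' @param ann a [gene_annotation] table.
#' @param path output path.
#' @param format `"bed"` or `"gff"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(ann, path, format = c("bed", "gff")) {
  format <- match.arg(format)
  ann <- validate_gene_annotation(as.data.frame(ann))
  if (format == "bed") {
    fam <- ifelse(is.na(ann$family), ".", ann$family)
    lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s\t%s\t%s\t%s",
                     ann$chrom, ann$start, ann$end, ann$gene_id,
                     ann$strand, ann$species, ann$role, fam)
  } else {
    attrs <- sprintf("ID=%s;species=%s;role=%s%s",
                     ann$gene_id, ann$species, ann$role,
                     ifelse(is.na(ann$family), "",
                            paste0(";family=", ann$family)))
    lines <- c("##gff-version 3",
               sprintf("%s\tfamdiv\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       ann$chrom, ann$start + 1L, ann$end, ann$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
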