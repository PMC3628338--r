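#' Construct a validated CNV catalog
#'
#' A catalog of copy-number-variable regions, BED-like with 0-based half-open
#' coordinates, each carrying an event type (`gain`, `loss` or `both`),
#' per-population frequencies, and the identifiers of the genes the region
#' overlaps.
#'
#' @param cnv_id character vector of CNV region identifiers.
#' @param chrom,start,end interval columns (0-based half-open,
#'   `end - start > 0`).
#' @param cnv_type `"gain"`, `"loss"` or `"both"` per record.
#' @param freq list of named numeric vectors (population -> frequency in
#'   `[0, 1]`); an empty vector means no frequency information.
#' @param genes list of character vectors of overlapped gene ids (may be
#'   empty).
#' @return A `data.frame` of class `cnv_catalog` with list columns `freq` and
#'   `genes`.
#' @examples
#' cnv_catalog("CNVR7658.2", "chr19", 47600000, 47838000, "loss",
#'             freq = list(c(CEU = 0.24)),
#'             genes = list(c("PSG1", "PSG6", "PSG7", "PSG10", "PSG11")))
#' @export
cnv_catalog <- function(cnv_id, chrom, start, end, cnv_type,
                        freq = NULL, genes = NULL) {
  n <- length(cnv_id)
  if (is.null(freq)) freq <- rep(list(numeric(0)), n)
  if (is.null(genes)) genes <- rep(list(character(0)), n)
  cat_df <- data.frame(cnv_id = as.character(cnv_id),
                       chrom = rep_len(as.character(chrom), n),
                       start = as.integer(start), end = as.integer(end),
                       cnv_type = rep_len(as.character(cnv_type), n),
                       stringsAsFactors = FALSE)
  cat_df$freq <- lapply(freq, function(f) {
    f <- unlist(f)
    if (is.null(f)) numeric(0) else f
  })
  cat_df$genes <- lapply(genes, as.character)
  validate_cnv_catalog(cat_df)
}

validate_cnv_catalog <- function(x) {
  if (any(x$end - x$start <= 0))
    stop_famdiv("CNV record(s) with non-positive length: ",
                paste(x$cnv_id[x$end - x$start <= 0], collapse = ", "))
  if (!all(x$cnv_type %in% c("gain", "loss", "both")))
    stop_famdiv("cnv_type must be gain/loss/both")
  for (i in seq_len(nrow(x))) {
    f <- x$freq[[i]]
    if (length(f) && (any(f < 0) || any(f > 1)))
      stop_famdiv("frequency outside [0, 1] for ", x$cnv_id[i])
    if (length(f) && is.null(names(f)))
      stop_famdiv("frequencies must be named by population for ", x$cnv_id[i])
  }
  if (anyDuplicated(x$cnv_id))
    stop_famdiv("duplicate cnv_id: ",
                paste(unique(x$cnv_id[duplicated(x$cnv_id)]), collapse = ", "))
  class(x) <- c("cnv_catalog", "data.frame")
  x
}

#' @export
print.cnv_catalog <- function(x, ...) {
  len <- x$end - x$start
  cat(sprintf("<cnv_catalog> %d records, lengths %s-%s bp\n", nrow(x),
              format(min(len), big.mark = ","),
              format(max(len), big.mark = ",")))
  tt <- table(x$cnv_type)
  cat("  types:", paste(names(tt), tt, sep = "=", collapse = " "), "\n")
  pops <- unique(unlist(lapply(x$freq, names)))
  if (length(pops)) cat("  populations:", paste(pops, collapse = ", "), "\n")
  invisible(x)
}

#' Read a CNV catalog from its TSV representation
#'
#' One record per row:
#' `chrom start end cnv_id cnv_type freqs genes`, where `freqs` is a
#' comma-separated list of `population:frequency` pairs and `genes` a
#' comma-separated gene list (`.` for none in either field).
#'
#' @param path catalog file.
#' @return A [cnv_catalog].
#' @export
read_cnv_catalog <- function(path) {
  if (!file.exists(path)) stop_famdiv("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- lapply(seq_along(keep), function(i) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 5)
      stop_famdiv("malformed CNV line ", ln, ": fewer than 5 fields")
    freqs <- numeric(0)
    if (length(f) >= 6 && f[6] != ".") {
      parts <- strsplit(strsplit(f[6], ",")[[1]], ":")
      if (any(lengths(parts) != 2))
        stop_famdiv("malformed CNV line ", ln, ": bad frequency field")
      freqs <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                               vapply(parts, `[`, "", 1))
      if (any(is.na(freqs)) || any(freqs < 0) || any(freqs > 1))
        stop_famdiv("malformed CNV line ", ln, ": frequency outside [0, 1]")
    }
    genes <- if (length(f) >= 7 && f[7] != ".")
      strsplit(f[7], ",")[[1]] else character(0)
    list(chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
         cnv_id = f[4], cnv_type = f[5], freq = freqs, genes = genes)
  })
  cnv_catalog(cnv_id = vapply(rows, `[[`, "", "cnv_id"),
              chrom = vapply(rows, `[[`, "", "chrom"),
              start = vapply(rows, `[[`, 0L, "start"),
              end = vapply(rows, `[[`, 0L, "end"),
              cnv_type = vapply(rows, `[[`, "", "cnv_type"),
              freq = lapply(rows, `[[`, "freq"),
              genes = lapply(rows, `[[`, "genes"))
}

#' Write a CNV catalog
#'
#' Inverse of [read_cnv_catalog()].
#'
#' @param x a [cnv_catalog].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cnv_catalog <- function(x, path) {
  x <- validate_cnv_catalog(as.data.frame(x))
  fr <- vapply(x$freq, function(f) {
    if (!length(f)) "." else paste(names(f), f, sep = ":", collapse = ",")
  }, character(1))
  gn <- vapply(x$genes, function(g) {
    if (!length(g)) "." else paste(g, collapse = ",")
  }, character(1))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     x$chrom, x$start, x$end, x$cnv_id, x$cnv_type, fr, gn),
             path)
  invisible(path)
}
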