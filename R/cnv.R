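#' Filter CNV records by length
#'
#' Keeps records strictly longer than `min_len` (matching "larger than"
#' wording: a record of exactly `min_len` bp is excluded).
#'
#' @param cnvs a [cnv_catalog].
#' @param min_len length threshold in bp.
#' @return The filtered [cnv_catalog].
#' @export
filter_by_length <- function(cnvs, min_len) {
  keep <- (cnvs$end - cnvs$start) > min_len
  out <- cnvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_catalog", "data.frame")
  out
}

#' Fraction of CNVs overlapping a locus
#'
#' Overlap means sharing at least one base under half-open interval
#' semantics: a CNV ending exactly at the locus start does not overlap.
#'
#' @param cnvs a [cnv_catalog].
#' @param chrom,start,end the locus (0-based half-open).
#' @return List with `n_in`, `n_total` and `fraction`.
#' @examples
#' # 8 of 46 long CNVs at a locus -> fraction 0.174
#' @export
locus_overlap <- function(cnvs, chrom, start, end) {
  if (nrow(cnvs) == 0) stop_famdiv("empty CNV catalog")
  hit <- cnvs$chrom == chrom & overlap_bp(cnvs$start, cnvs$end, start, end) > 0
  list(n_in = sum(hit), n_total = nrow(cnvs),
       fraction = sum(hit) / nrow(cnvs))
}

#' Distinguish copy-number polymorphisms from rare CNVs
#'
#' A CNV is a copy-number polymorphism when its frequency exceeds the
#' threshold (strictly) in at least one population. Records without any
#' frequency information are flagged unknown (`NA`), never `FALSE`.
#'
#' @param cnvs a [cnv_catalog].
#' @param freq_threshold frequency cut (default 0.01, i.e. the conventional
#'   1% polymorphism criterion).
#' @return Named logical vector (cnv_id -> polymorphism status, `NA` if
#'   unknown).
#' @export
classify_polymorphisms <- function(cnvs, freq_threshold = 0.01) {
  out <- vapply(cnvs$freq, function(f) {
    if (!length(f)) NA else max(f) > freq_threshold
  }, logical(1))
  stats::setNames(out, cnvs$cnv_id)
}

#' Per-individual gene copy numbers implied by CNV genotypes
#'
#' Starting from a diploid baseline, each loss event removes and each gain
#' event adds one copy of every gene the CNV overlaps, so an individual
#' homozygous for a loss spanning five genes loses ten gene copies. Copy
#' numbers are floored at zero (with a warning) since an individual cannot
#' carry negative copies.
#'
#' @param cnv_genotypes integer matrix of event counts (0/1/2), CNVs in rows
#'   (rownames = cnv_id), individuals in columns — or a named vector for a
#'   single individual.
#' @param cnvs the [cnv_catalog] the genotypes refer to; every genotyped CNV
#'   must be of type `gain` or `loss` (`both` records need a per-individual
#'   direction and are rejected).
#' @param baseline named integer vector gene_id -> baseline copy number;
#'   default 2 for every gene overlapped by the catalog.
#' @return Object of class `copy_number_profile`: a gene x individual integer
#'   matrix of copy numbers, with the per-individual family totals in
#'   attribute `total` and the inputs in attributes `baseline` and
#'   `genotypes`.
#' @examples
#' cat22 <- cnv_catalog(c("loss1", "gain1"), "chr19",
#'                      c(47600000, 47800000), c(47838000, 48052000),
#'                      c("loss", "gain"),
#'                      genes = list(c("PSG1", "PSG6", "PSG7", "PSG10", "PSG11"),
#'                                   c("PSG2", "PSG4", "PSG5", "PSG9")))
#' baseline <- setNames(rep(2L, 11), paste0("PSG", c(1:9, 10, 11)))
#' prof <- gene_copy_number(c(loss1 = 2, gain1 = 0), cat22, baseline)
#' attr(prof, "total")  # 12
#' @export
gene_copy_number <- function(cnv_genotypes, cnvs, baseline = NULL) {
  if (is.null(dim(cnv_genotypes)))
    cnv_genotypes <- matrix(cnv_genotypes, ncol = 1,
                            dimnames = list(names(cnv_genotypes), "ind1"))
  ids <- rownames(cnv_genotypes)
  if (is.null(ids) || !all(ids %in% cnvs$cnv_id))
    stop_famdiv("genotyped CNV(s) absent from the catalog: ",
                paste(setdiff(ids, cnvs$cnv_id), collapse = ", "))
  if (!all(cnv_genotypes %in% 0:2))
    stop_famdiv("CNV genotypes must be event counts in {0, 1, 2}")
  rows <- match(ids, cnvs$cnv_id)
  types <- cnvs$cnv_type[rows]
  if (any(types == "both"))
    stop_famdiv("cnv_type 'both' needs a per-individual direction; ",
                "split the record into gain and loss components")
  genes <- if (is.null(baseline))
    sort(unique(unlist(cnvs$genes[rows]))) else names(baseline)
  if (is.null(baseline))
    baseline <- stats::setNames(rep(2L, length(genes)), genes)
  # membership matrix: genes x CNVs
  mem <- vapply(rows, function(r) as.integer(genes %in% cnvs$genes[[r]]),
                integer(length(genes)))
  mem <- matrix(mem, nrow = length(genes))
  sign <- ifelse(types == "gain", 1L, -1L)
  delta <- mem %*% (sign * cnv_genotypes)
  copies <- matrix(baseline[genes], length(genes), ncol(cnv_genotypes)) + delta
  if (any(copies < 0)) {
    warning("copy number floored at 0 for ",
            sum(copies < 0), " gene-individual combination(s)", call. = FALSE)
    copies[copies < 0] <- 0
  }
  dimnames(copies) <- list(genes, colnames(cnv_genotypes))
  structure(copies, class = "copy_number_profile",
            total = colSums(copies), baseline = baseline,
            genotypes = cnv_genotypes)
}

#' @export
print.copy_number_profile <- function(x, ...) {
  tot <- attr(x, "total")
  cat(sprintf("<copy_number_profile> %d genes x %d individual(s)\n",
              nrow(x), ncol(x)))
  cat(sprintf("  baseline family total: %d\n", sum(attr(x, "baseline"))))
  if (length(tot) <= 8) {
    cat("  family totals:", paste(names(tot), tot, sep = "=",
                                  collapse = " "), "\n")
  } else {
    cat(sprintf("  family totals: range %d-%d, median %s\n", min(tot),
                max(tot), format(stats::median(tot))))
  }
  invisible(x)
}

#' Attainable family copy-number range over all CNV genotype combinations
#'
#' Enumerates every combination of event counts (0/1/2 per CNV; `3^k`
#' combinations) and reports the minimum and maximum family copy-number total
#' after per-gene flooring at zero. Exhaustive enumeration is exact in the
#' presence of CNVs that overlap shared genes, where per-CNV greedy bounds
#' are wrong; it is capped at 12 CNVs.
#'
#' @param cnvs a [cnv_catalog] restricted to the family of interest (types
#'   `gain`/`loss`).
#' @param baseline named integer vector gene_id -> baseline copies.
#' @return `c(min = , max = )` family copy-number totals.
#' @export
copy_number_range <- function(cnvs, baseline) {
  k <- nrow(cnvs)
  if (k == 0) {
    tot <- sum(baseline)
    return(c(min = tot, max = tot))
  }
  if (k > 12)
    stop_famdiv("exhaustive enumeration capped at 12 CNVs (got ", k, ")")
  combos <- as.matrix(expand.grid(rep(list(0:2), k)))
  gt <- t(combos)
  rownames(gt) <- cnvs$cnv_id
  colnames(gt) <- sprintf("c%d", seq_len(ncol(gt)))
  prof <- suppressWarnings(gene_copy_number(gt, cnvs, baseline))
  tot <- attr(prof, "total")
  c(min = unname(min(tot)), max = unname(max(tot)))
}

#' Population differentiation of CNV frequencies
#'
#' Tabulates per-population frequencies and flags each CNV as private to a
#' single population (frequency > 0 in exactly one) or shared. Requires
#' frequencies for at least two populations across the catalog.
#'
#' @param cnvs a [cnv_catalog].
#' @return `data.frame` sorted by decreasing maximum frequency with columns
#'   `cnv_id`, one `freq_<pop>` column per population, `max_freq`, `status`
#'   (`"private"`/`"shared"`/`"absent"`) and `private_to`.
#' @export
cnv_population_differentiation <- function(cnvs) {
  pops <- sort(unique(unlist(lapply(cnvs$freq, names))))
  if (length(pops) < 2)
    stop_famdiv("frequencies for at least two populations are required")
  fr <- t(vapply(cnvs$freq, function(f) {
    out <- stats::setNames(rep(0, length(pops)), pops)
    out[names(f)] <- f
    out
  }, numeric(length(pops))))
  n_pos <- rowSums(fr > 0)
  status <- ifelse(n_pos == 0, "absent", ifelse(n_pos == 1, "private",
                                                "shared"))
  private_to <- ifelse(status == "private",
                       pops[apply(fr, 1, which.max)], NA_character_)
  out <- data.frame(cnv_id = cnvs$cnv_id, fr, max_freq = apply(fr, 1, max),
                    status = status, private_to = private_to,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(pops) + 1] <- paste0("freq_", pops)
  out <- out[order(-out$max_freq), ]
  rownames(out) <- NULL
  out
}

#' Length and locus summary of a CNV catalog
#'
#' Counts records above each length threshold, bins record lengths into a
#' size histogram, and (optionally) reports the locus-overlap fraction among
#' the records above the largest threshold.
#'
#' @param cnvs a [cnv_catalog].
#' @param length_thresholds strict length cuts in bp (default 500 and
#'   20,000).
#' @param locus optional `list(chrom =, start =, end =)` for the overlap
#'   fraction.
#' @param bin_width histogram bin width in bp (default 20 kb).
#' @return List of class `cnv_summary` with `n_total`, `n_over_length`,
#'   `locus` (or `NULL`) and `size_histogram`.
#' @export
cnv_summary <- function(cnvs, length_thresholds = c(500, 20000),
                        locus = NULL, bin_width = 20000) {
  len <- cnvs$end - cnvs$start
  n_over <- vapply(length_thresholds, function(th) sum(len > th), integer(1))
  names(n_over) <- paste0(">", length_thresholds, "bp")
  loc <- NULL
  if (!is.null(locus)) {
    big <- filter_by_length(cnvs, max(length_thresholds))
    loc <- locus_overlap(big, locus$chrom, locus$start, locus$end)
  }
  breaks <- seq(0, max(len) + bin_width, by = bin_width)
  h <- hist(len, breaks = breaks, plot = FALSE)
  structure(list(n_total = nrow(cnvs), n_over_length = n_over, locus = loc,
                 size_histogram = data.frame(bin_start = h$breaks[-length(h$breaks)],
                                             bin_end = h$breaks[-1],
                                             count = h$counts)),
            class = "cnv_summary")
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat(sprintf("<cnv_summary> %d records\n", x$n_total))
  cat("  over length:", paste(names(x$n_over_length), x$n_over_length,
                              sep = " ", collapse = ", "), "\n")
  if (!is.null(x$locus))
    cat(sprintf("  locus overlap: %d/%d (%.1f%%)\n", x$locus$n_in,
                x$locus$n_total, 100 * x$locus$fraction))
  invisible(x)
}
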