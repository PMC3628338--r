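#' Two-locus r^2 from unphased diploid genotypes (EM haplotype frequencies)
#'
#' Estimates the four haplotype frequencies of a SNP pair by maximum
#' likelihood: all genotype combinations determine their haplotypes except
#' the double heterozygote, whose cis/trans split is resolved iteratively by
#' expectation-maximisation (tolerance 1e-10 on the frequency change, at most
#' 1000 iterations). Individuals missing either genotype are excluded
#' pairwise. `r^2 = D^2 / (pA(1-pA) pB(1-pB))`, clamped into `[0, 1]`; pairs
#' whose denominator vanishes (monomorphic after deletion) are undefined.
#'
#' @param panel a [genotype_panel].
#' @param snp_a,snp_b SNP identifiers.
#' @return `r^2` in `[0, 1]`, or `NA` if undefined.
#' @export
ld_r2 <- function(panel, snp_a, snp_b) {
  g <- panel$genotypes
  ia <- match(snp_a, rownames(g)); ib <- match(snp_b, rownames(g))
  if (is.na(ia) || is.na(ib)) stop_famdiv("unknown SNP id")
  ld_r2_vec(g[ia, ], g[ib, ])
}

ld_r2_vec <- function(ga, gb, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  if (n == 0) return(NA_real_)
  # haplotype counts fixed by unambiguous genotype pairs; alleles A/a at the
  # first locus are alt/ref, B/b at the second
  n_ab <- function(a, b) sum(ga == a & gb == b)
  d <- n_ab(1, 1)                      # double heterozygotes
  c_AB <- 2 * n_ab(2, 2) + n_ab(2, 1) + n_ab(1, 2)
  c_Ab <- 2 * n_ab(2, 0) + n_ab(2, 1) + n_ab(1, 0)
  c_aB <- 2 * n_ab(0, 2) + n_ab(0, 1) + n_ab(1, 2)
  c_ab <- 2 * n_ab(0, 0) + n_ab(0, 1) + n_ab(1, 0)
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom < 1e-12) return(NA_real_)
  # EM over the cis/trans split of the double heterozygotes
  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  total <- 2 * n
  for (iter in seq_len(max_iter)) {
    cis <- h["AB"] * h["ab"]
    trans <- h["Ab"] * h["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    h_new <- c(c_AB + d * w, c_Ab + d * (1 - w),
               c_aB + d * (1 - w), c_ab + d * w) / total
    names(h_new) <- names(h)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
    if (iter == max_iter)
      stop_famdiv("EM did not converge within ", max_iter, " iterations")
  }
  D <- h[["AB"]] - (h[["AB"]] + h[["Ab"]]) * (h[["AB"]] + h[["aB"]])
  r2 <- D^2 / denom
  min(max(r2, 0), 1)
}

#' Pairwise r^2 matrix over position-ordered SNPs
#'
#' @param panel a [genotype_panel].
#' @param snps SNP ids to include (default: all, in panel order).
#' @return Symmetric matrix of [ld_r2()] values with unit diagonal and a
#'   `pos` attribute carrying the SNP positions (used by [ld_blocks()] to
#'   verify ordering).
#' @export
ld_matrix <- function(panel, snps = NULL) {
  if (is.null(snps)) snps <- panel$snps$snp_id
  idx <- match(snps, rownames(panel$genotypes))
  if (any(is.na(idx))) stop_famdiv("unknown SNP id(s)")
  m <- length(idx)
  r2 <- diag(1, m)
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      r2[i, j] <- r2[j, i] <- ld_r2_vec(panel$genotypes[idx[i], ],
                                        panel$genotypes[idx[j], ])
  dimnames(r2) <- list(snps, snps)
  attr(r2, "pos") <- panel$snps$pos[match(snps, panel$snps$snp_id)]
  r2
}

#' LD blocks as maximal adjacency chains above an r^2 threshold
#'
#' A block is a maximal run of consecutive (position-ordered) SNPs in which
#' every adjacent pair has `r^2 >= threshold`; a single SNP forms no block.
#' This adjacency-chain rule operationalises an r^2-threshold block
#' definition directly (it is deliberately simpler than confidence-interval
#' block algorithms).
#'
#' @param r2_matrix square r^2 matrix over position-ordered SNPs, as from
#'   [ld_matrix()]. If a `pos` attribute is present it must be
#'   non-decreasing; otherwise the matrix order is trusted.
#' @param threshold block threshold (default 0.8).
#' @return `data.frame` with one row per block: first/last SNP index and id,
#'   and `n_snps`.
#' @export
ld_blocks <- function(r2_matrix, threshold = 0.8) {
  m <- nrow(r2_matrix)
  if (m != ncol(r2_matrix)) stop_famdiv("r2 matrix must be square")
  pos <- attr(r2_matrix, "pos")
  if (!is.null(pos) && !all(is.na(pos)) && is.unsorted(pos, na.rm = TRUE))
    stop_famdiv("SNPs must be position-ordered")
  ids <- rownames(r2_matrix) %||% as.character(seq_len(m))
  if (m < 2)
    return(data.frame(from = integer(0), to = integer(0),
                      from_snp = character(0), to_snp = character(0),
                      n_snps = integer(0)))
  adj <- r2_matrix[cbind(seq_len(m - 1), seq(2, m))]
  linked <- !is.na(adj) & adj >= threshold
  runs <- rle(linked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  data.frame(from = starts[keep], to = ends[keep] + 1L,
             from_snp = ids[starts[keep]], to_snp = ids[ends[keep] + 1L],
             n_snps = ends[keep] + 1L - starts[keep] + 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}
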