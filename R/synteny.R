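#' Detect marker-anchored syntenic blocks between two species
#'
#' Greedy chaining of marker genes: query markers are sorted by position;
#' consecutive markers join one block when they lie on the same query
#' chromosome, their reference partners share a reference chromosome, and the
#' query gap does not exceed `max_gap`. Chains with fewer than `min_markers`
#' markers are discarded. A reference marker with query partners on two
#' different query chromosomes seeds two blocks sharing the same reference
#' region — the signature of a duplicated (e.g. whole-genome-duplication
#' derived) block.
#'
#' @param ref,query [gene_annotation] tables for the reference and query
#'   species (only rows whose `gene_id` appears in `marker_orthology` are
#'   used as anchors).
#' @param marker_orthology `data.frame` with columns `ref_id`, `query_id`
#'   mapping reference marker genes to query orthologs (one-to-many allowed).
#' @param min_markers minimum markers per retained block (default 2).
#' @param max_gap maximum query gap between consecutive chained markers, bp
#'   (default 2 Mb).
#' @return A `data.frame` of class `synteny_blocks`: one row per block with
#'   the covered reference/query regions (minimal intervals spanning the
#'   block's markers), marker count, and list columns `markers_ref`,
#'   `markers_query`.
#' @export
find_blocks <- function(ref, query, marker_orthology, min_markers = 2,
                        max_gap = 2e6) {
  if (is.null(marker_orthology) || nrow(marker_orthology) == 0)
    stop_famdiv("empty marker orthology set")
  qmk <- as.data.frame(query)[query$gene_id %in% marker_orthology$query_id, ]
  if (nrow(qmk) == 0) stop_famdiv("no query markers found in the annotation")
  ref_of <- stats::setNames(as.character(marker_orthology$ref_id),
                            marker_orthology$query_id)
  ref_df <- as.data.frame(ref)
  ref_row <- match(ref_of[qmk$gene_id], ref_df$gene_id)
  if (any(is.na(ref_row)))
    stop_famdiv("reference marker(s) missing from the reference annotation: ",
                paste(unique(ref_of[qmk$gene_id][is.na(ref_row)]),
                      collapse = ", "))
  qmk$ref_id <- ref_of[qmk$gene_id]
  qmk$ref_chrom <- ref_df$chrom[ref_row]
  qmk$ref_start <- ref_df$start[ref_row]
  qmk$ref_end <- ref_df$end[ref_row]
  qmk <- qmk[order(qmk$chrom, qmk$start), ]

  # chain: break on chromosome change, ref-chromosome change, or large gap
  n <- nrow(qmk)
  new_chain <- c(TRUE, (qmk$chrom[-1] != qmk$chrom[-n]) |
                   (qmk$ref_chrom[-1] != qmk$ref_chrom[-n]) |
                   (qmk$start[-1] - qmk$end[-n] > max_gap))
  chain_id <- cumsum(new_chain)
  blocks <- lapply(split(qmk, chain_id), function(ch) {
    if (nrow(ch) < min_markers) return(NULL)
    data.frame(species_a = ref_df$species[1], chrom_a = ch$ref_chrom[1],
               start_a = min(ch$ref_start), end_a = max(ch$ref_end),
               species_b = ch$species[1], chrom_b = ch$chrom[1],
               start_b = min(ch$start), end_b = max(ch$end),
               n_markers = nrow(ch),
               markers_ref = I(list(ch$ref_id)),
               markers_query = I(list(ch$gene_id)),
               stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (is.null(blocks))
    blocks <- data.frame(species_a = character(0), chrom_a = character(0),
                         start_a = integer(0), end_a = integer(0),
                         species_b = character(0), chrom_b = character(0),
                         start_b = integer(0), end_b = integer(0),
                         n_markers = integer(0),
                         markers_ref = I(list()), markers_query = I(list()))
  blocks <- cbind(block_id = sprintf("B%d", seq_len(nrow(blocks))), blocks,
                  stringsAsFactors = FALSE)
  rownames(blocks) <- NULL
  class(blocks) <- c("synteny_blocks", "data.frame")
  blocks
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d block(s)\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: %s:%d-%d <-> %s:%d-%d (%d markers)\n",
                x$block_id[i], x$chrom_a[i], x$start_a[i], x$end_a[i],
                x$chrom_b[i], x$start_b[i], x$end_b[i], x$n_markers[i]))
  invisible(x)
}

#' Classify family duplicates as tandem, WGD co-orthologs, or singletons
#'
#' Applies the synteny-based duplication rules in fixed precedence order:
#'
#' 1. family genes on the same chromosome within `tandem_gap` of another
#'    family gene (chained transitively) form one *tandem* call;
#' 2. remaining single genes (and, as evidence, tandem clusters) lying in two
#'    syntenic blocks that share reference markers but occupy different query
#'    chromosomes are paired as *wgd_coortholog* calls;
#' 3. a lone gene inside exactly one block is a *singleton*;
#' 4. a gene inside no block — or ambiguously inside several overlapping
#'    blocks — is *unresolved* (with a warning for the ambiguous case; no
#'    silent tie-break).
#'
#' @param family_genes [gene_annotation] rows of the query species' family
#'   genes.
#' @param blocks a `synteny_blocks` table from [find_blocks()].
#' @param tandem_gap maximum bp between neighbouring family genes of one
#'   tandem array (default 500 kb).
#' @param min_shared_markers reference markers two blocks must share to count
#'   as a duplicated block pair (default 2).
#' @return A `data.frame` of class `duplication_calls`: columns `call_id`,
#'   `label`, list column `gene_ids`, and `evidence`. Every family gene
#'   appears in exactly one call.
#' @export
classify_duplicates <- function(family_genes, blocks, tandem_gap = 5e5,
                                min_shared_markers = 2) {
  fam <- as.data.frame(family_genes)
  if (nrow(fam) == 0) stop_famdiv("no family genes supplied")
  fam <- fam[order(fam$chrom, fam$start), ]

  # 1. transitive tandem chaining within chromosomes
  n <- nrow(fam)
  brk <- c(TRUE, (fam$chrom[-1] != fam$chrom[-n]) |
             (fam$start[-1] - fam$end[-n] > tandem_gap))
  fam$cluster <- cumsum(brk)
  clusters <- split(fam, fam$cluster)

  # block assignment of each unit (cluster or lone gene) by query overlap
  assign_block <- function(chrom, s, e) {
    hit <- which(blocks$chrom_b == chrom &
                   overlap_bp(s, e, blocks$start_b, blocks$end_b) > 0)
    blocks$block_id[hit]
  }
  units <- lapply(clusters, function(cl) {
    list(genes = cl$gene_id, chrom = cl$chrom[1], start = min(cl$start),
         end = max(cl$end), tandem = nrow(cl) >= 2,
         blocks = assign_block(cl$chrom[1], min(cl$start), max(cl$end)))
  })

  shared_ref <- function(b1, b2) {
    i <- match(b1, blocks$block_id); j <- match(b2, blocks$block_id)
    length(intersect(blocks$markers_ref[[i]], blocks$markers_ref[[j]]))
  }

  calls <- list(); cid <- 0
  add_call <- function(label, genes, evidence) {
    cid <<- cid + 1
    calls[[cid]] <<- data.frame(call_id = sprintf("D%d", cid), label = label,
                                gene_ids = I(list(genes)),
                                evidence = evidence, stringsAsFactors = FALSE)
  }

  # pair single-gene units across duplicated blocks
  singles <- which(!vapply(units, `[[`, logical(1), "tandem"))
  paired <- rep(FALSE, length(units))
  wgd_partner_note <- rep("", length(units))
  if (length(singles) >= 2) {
    for (ii in seq_along(singles)) {
      for (jj in seq_len(ii - 1L)) {
        u <- units[[singles[ii]]]; v <- units[[singles[jj]]]
        if (length(u$blocks) != 1 || length(v$blocks) != 1) next
        if (u$chrom == v$chrom) next
        if (u$blocks == v$blocks) next
        sh <- shared_ref(u$blocks, v$blocks)
        if (sh >= min_shared_markers) {
          add_call("wgd_coortholog", c(u$genes, v$genes),
                   sprintf("blocks %s+%s share %d ref markers on distinct query chromosomes",
                           u$blocks, v$blocks, sh))
          paired[singles[ii]] <- TRUE
          paired[singles[jj]] <- TRUE
        }
      }
    }
  }

  for (k in seq_along(units)) {
    u <- units[[k]]
    if (u$tandem) {
      ev <- sprintf("%d genes chained on %s within %d bp", length(u$genes),
                    u$chrom, tandem_gap)
      # a tandem array inside a duplicated block keeps its tandem label but
      # the pairing is recorded as evidence
      dup_partners <- Filter(function(b) {
        any(vapply(blocks$block_id, function(b2)
          b2 != b && blocks$chrom_b[match(b2, blocks$block_id)] != u$chrom &&
            shared_ref(b, b2) >= min_shared_markers, logical(1)))
      }, u$blocks)
      if (length(dup_partners))
        ev <- paste0(ev, "; cluster lies in duplicated block ",
                     paste(unlist(dup_partners), collapse = ","))
      add_call("tandem", u$genes, ev)
    } else if (paired[k]) {
      next  # already emitted in a wgd_coortholog call
    } else if (length(u$blocks) > 1) {
      warning("gene ", paste(u$genes, collapse = ","),
              " overlaps several syntenic blocks; reported unresolved",
              call. = FALSE)
      add_call("unresolved", u$genes,
               sprintf("ambiguous: overlaps blocks %s",
                       paste(u$blocks, collapse = ",")))
    } else if (length(u$blocks) == 1) {
      add_call("singleton", u$genes, sprintf("inside block %s", u$blocks))
    } else {
      add_call("unresolved", u$genes, "no covering syntenic block")
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("duplication_calls", "data.frame")
  out
}

#' @export
print.duplication_calls <- function(x, ...) {
  cat(sprintf("<duplication_calls> %d call(s): %s\n", nrow(x),
              paste(names(table(x$label)), table(x$label), sep = "=",
                    collapse = " ")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s [%s] %s — %s\n", x$call_id[i], x$label[i],
                paste(x$gene_ids[[i]], collapse = ","), x$evidence[i]))
  invisible(x)
}

#' Per-gene duplication labels from a call set
#'
#' Flattens [classify_duplicates()] output to one label per gene, convenient
#' for comparing against simulated ground truth.
#'
#' @param calls a `duplication_calls` table.
#' @return Named character vector gene_id -> label.
#' @export
call_labels <- function(calls) {
  stats::setNames(rep(calls$label, lengths(calls$gene_ids)),
                  unlist(calls$gene_ids))
}

#' Per-species gene-family inventory
#'
#' Counts family members per species; species with zero members are retained
#' (absence is itself a result, as for the avian loss of the family).
#'
#' @param annotations a [gene_annotation] covering one or more species.
#' @param family family label to count.
#' @return `data.frame` with columns `species`, `n_genes`, `present`.
#' @export
inventory <- function(annotations, family) {
  ann <- as.data.frame(annotations)
  if (nrow(ann) == 0) stop_famdiv("empty annotation set")
  if (!family %in% stats::na.omit(unique(ann$family)))
    stop_famdiv("unknown family label: ", family)
  species <- unique(ann$species)
  counts <- vapply(species, function(sp)
    sum(ann$species == sp & !is.na(ann$family) & ann$family == family),
    integer(1))
  data.frame(species = species, n_genes = unname(counts),
             present = unname(counts) > 0, stringsAsFactors = FALSE)
}
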