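# A hand-laid mini-landscape mirroring the teleost situation: a reference
# chromosome of markers, a query with either one mirrored chromosome or two
# WGD-derived fragments carrying duplicated marker orthologs.
mini_landscape <- function(wgd = FALSE) {
  ref <- gene_annotation(c("TOMM40", "ATP1A3", "ZNF574"), "ref", "r1",
                         c(1e6, 2e6, 3e6), c(1e6, 2e6, 3e6) + 1e4,
                         role = "marker")
  if (!wgd) {
    query <- gene_annotation(c("TOMM40_q", "ATP1A3_q", "ZNF574_q", "CEACAMI"),
                             "query", "q1",
                             c(1e6, 2e6, 3e6, 1.5e6),
                             c(1e6, 2e6, 3e6, 1.5e6) + 1e4,
                             role = c(rep("marker", 3), "family"),
                             family = c(NA, NA, NA, "FAM"))
    orth <- data.frame(ref_id = c("TOMM40", "ATP1A3", "ZNF574"),
                       query_id = c("TOMM40_q", "ATP1A3_q", "ZNF574_q"))
  } else {
    query <- gene_annotation(
      c("TOMM40a", "ATP1A3a", "ZNF574a", "CEACAMIa",
        "TOMM40b", "ATP1A3b", "ZNF574b", "CEACAMIb"),
      "query", rep(c("q1", "q2"), each = 4),
      rep(c(1e6, 2e6, 3e6, 1.5e6), 2),
      rep(c(1e6, 2e6, 3e6, 1.5e6), 2) + 1e4,
      role = rep(c("marker", "marker", "marker", "family"), 2),
      family = rep(c(NA, NA, NA, "FAM"), 2))
    orth <- data.frame(ref_id = rep(c("TOMM40", "ATP1A3", "ZNF574"), 2),
                       query_id = c("TOMM40a", "ATP1A3a", "ZNF574a",
                                    "TOMM40b", "ATP1A3b", "ZNF574b"))
  }
  list(ref = ref, query = query, orth = orth)
}

test_that("collinear markers chain into a single block", {
  ml <- mini_landscape()
  blocks <- find_blocks(ml$ref, ml$query, ml$orth)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_markers, 3)
  expect_equal(blocks$start_b, 1e6)
  expect_equal(blocks$end_b, 3e6 + 1e4)  # minimal marker-covering interval
})

test_that("duplicated marker orthologs seed two blocks sharing the ref region", {
  ml <- mini_landscape(wgd = TRUE)
  blocks <- find_blocks(ml$ref, ml$query, ml$orth)
  expect_equal(nrow(blocks), 2)
  expect_setequal(blocks$chrom_b, c("q1", "q2"))
  expect_equal(blocks$chrom_a, rep("r1", 2))
  expect_setequal(blocks$markers_ref[[1]], blocks$markers_ref[[2]])
})

test_that("gaps above max_gap split chains that may then fail min_markers", {
  ml <- mini_landscape()
  # brute-force chaining oracle on the sorted marker positions
  chain_oracle <- function(starts, ends, max_gap, min_markers) {
    o <- order(starts)
    breaks <- which(starts[o][-1] - ends[o][-length(o)] > max_gap)
    sizes <- diff(c(0, breaks, length(starts)))
    sum(sizes >= min_markers)
  }
  qm <- ml$query[ml$query$role == "marker", ]
  for (max_gap in c(5e5, 9.9e5 + 1e4, 1.5e6, 3e6)) {
    blocks <- find_blocks(ml$ref, ml$query, ml$orth, min_markers = 2,
                          max_gap = max_gap)
    expect_equal(nrow(blocks),
                 chain_oracle(qm$start, qm$end, max_gap, 2),
                 info = paste("max_gap =", max_gap))
  }
  # every marker isolated -> all chains fail min_markers -> empty set
  expect_equal(nrow(find_blocks(ml$ref, ml$query, ml$orth, max_gap = 1e5)), 0)
  expect_error(find_blocks(ml$ref, ml$query, ml$orth[0, ]), "empty marker")
})

test_that("family genes in duplicated blocks are called WGD co-orthologs", {
  ml <- mini_landscape(wgd = TRUE)
  blocks <- find_blocks(ml$ref, ml$query, ml$orth)
  fam <- ml$query[ml$query$role == "family", ]
  calls <- classify_duplicates(fam, blocks)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$label, "wgd_coortholog")
  expect_setequal(calls$gene_ids[[1]], c("CEACAMIa", "CEACAMIb"))
})

test_that("neighbouring family genes on one chromosome are one tandem call", {
  ml <- mini_landscape()
  blocks <- find_blocks(ml$ref, ml$query, ml$orth)
  fam <- gene_annotation(c("F1", "F2", "F3"), "query", "q1",
                         c(1.5e6, 1.8e6, 2.1e6), c(1.5e6, 1.8e6, 2.1e6) + 1e4,
                         role = "family", family = "FAM")
  calls <- classify_duplicates(fam, blocks, tandem_gap = 5e5)
  expect_equal(calls$label, "tandem")
  expect_setequal(calls$gene_ids[[1]], c("F1", "F2", "F3"))
  # chaining is transitive: F1-F3 are 6e5 apart but linked through F2
  expect_gt(1.8e6 + 1e4 + 5e5, 2.1e6)
})

test_that("lone genes map to singleton or unresolved calls", {
  ml <- mini_landscape()
  blocks <- find_blocks(ml$ref, ml$query, ml$orth)
  fam <- gene_annotation(c("IN", "OUT"), "query", c("q1", "q9"),
                         c(1.5e6, 1e6), c(1.51e6, 1.01e6),
                         role = "family", family = "FAM")
  calls <- classify_duplicates(fam, blocks)
  labels <- call_labels(calls)
  expect_equal(unname(labels["IN"]), "singleton")
  expect_equal(unname(labels["OUT"]), "unresolved")
})

test_that("classification is invariant under translation and relabeling", {
  land <- simulate_gene_landscape(n_tandem_arrays = 1, n_wgd_blocks = 1,
                                  n_singleton_blocks = 1, seed = 21)
  ann <- land$annotations
  split_sp <- function(a) list(ref = a[a$species == "ref", ],
                               query = a[a$species == "query", ])
  run <- function(a) {
    sp <- split_sp(a)
    blocks <- find_blocks(sp$ref, sp$query, land$marker_orthology)
    calls <- classify_duplicates(sp$query[sp$query$role == "family", ], blocks)
    lab <- call_labels(calls)
    lab[order(names(lab))]
  }
  rebuild <- function(a) gene_annotation(a$gene_id, a$species, a$chrom,
                                         a$start, a$end, a$strand, a$role,
                                         a$family)
  base <- run(ann)
  shifted <- ann
  shifted$start <- shifted$start + 12345L
  shifted$end <- shifted$end + 12345L
  expect_identical(run(rebuild(shifted)), base)
  relabeled <- ann
  relabeled$chrom <- paste0("X", relabeled$chrom)
  expect_identical(run(rebuild(relabeled)), base)
})

test_that("every family gene lands in exactly one duplication call", {
  for (seed in 1:5) {
    land <- simulate_gene_landscape(n_tandem_arrays = 2, n_wgd_blocks = 2,
                                    n_singleton_blocks = 2, seed = seed)
    ann <- land$annotations
    ref <- ann[ann$species == "ref", ]
    query <- ann[ann$species == "query", ]
    blocks <- find_blocks(ref, query, land$marker_orthology)
    calls <- classify_duplicates(query[query$role == "family", ], blocks)
    genes <- unlist(calls$gene_ids)
    expect_equal(anyDuplicated(genes), 0)
    expect_setequal(genes, land$truth$gene_id)
  }
})

test_that("species inventories keep zero rows and reject unknown families", {
  ann <- gene_annotation(c(paste0("g", 1:25), "m1"),
                         c(rep("human", 25), "chicken"),
                         c(rep("chr19", 25), "chr1"),
                         c((1:25) * 1e5, 1e5), c((1:25) * 1e5 + 1e4, 1.1e5),
                         role = c(rep("family", 25), "marker"),
                         family = c(rep("FAM", 25), NA))
  inv <- inventory(ann, "FAM")
  expect_equal(inv$n_genes[inv$species == "human"], 25)
  expect_equal(inv$n_genes[inv$species == "chicken"], 0)  # absence retained
  expect_false(inv$present[inv$species == "chicken"])
  expect_error(inventory(ann, "NOPE"), "unknown family")
  expect_error(inventory(ann[0, ], "FAM"), "empty annotation")
})
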