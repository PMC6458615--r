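test_that("global alignment matches exhaustive and NW oracles", {
  r <- align_pair("ACDEFG", "ACDEFG")
  expect_equal(r$identity, 1.0)
  expect_equal(r$score, 6 * scoring_params()$match)
  # nucleotide-mode example against the exhaustive oracle
  sc <- scoring_params(match = 1, mismatch = -1, gap = -2)
  r <- align_pair("ACGT", "AGT", sc)
  expect_equal(r$score, 1)
  expect_equal(r$score, oracle_align_score("ACGT", "AGT", 1, -1, -2))
  # symmetry and oracle agreement on random pairs
  set.seed(3)
  for (i in 1:10) {
    a <- paste(sample(LETTERS[1:6], sample(4:12, 1), TRUE), collapse = "")
    b <- paste(sample(LETTERS[1:6], sample(4:12, 1), TRUE), collapse = "")
    ab <- align_pair(a, b, sc)$score
    expect_equal(ab, align_pair(b, a, sc)$score)
    expect_equal(ab, oracle_align_score(a, b, 1, -1, -2))
  }
  expect_error(align_pair("", "AC"), "empty")
})

test_that("aligner agrees with Biostrings on global pairwise scores", {
  set.seed(11)
  for (i in 1:8) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 55, TRUE), collapse = "")
    mine <- align_pair(a, b, scoring_params(match = 1, mismatch = -1,
                                            gap = -2))$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("reciprocal best hits connect identical genes and skip the rest", {
  prot <- list(s1 = c(gA = "MKLVNNWWAQTPLE"), s2 = c(gB = "MKLVNNWWAQTPLE"))
  e <- build_rbh_graph(prot, kmer_prefilter = 0)
  expect_equal(nrow(e), 1)
  expect_equal(e$gene1, "gA"); expect_equal(e$gene2, "gB")
  # a gene with no hit above thresholds stays isolated
  prot$s1 <- c(prot$s1, gZ = "CCCCCCCCCCHHHH")
  e2 <- build_rbh_graph(prot, kmer_prefilter = 0)
  fams <- cluster_families(e2)
  expect_equal(sum(fams$gene_id == "gZ"), 1)
  expect_equal(sum(fams$family_id == fams$family_id[fams$gene_id == "gZ"]), 1)
  # a strain with zero proteins is excluded with a warning
  expect_warning(build_rbh_graph(list(a = c(g = "MKLV"), b = character(0),
                                      c = c(h = "MKLV")), kmer_prefilter = 0),
                 "zero proteins")
})

test_that("ortholog families recover the truth on a low-divergence clade", {
  ds <- tiny_clade()
  prot <- lapply(ds$genomes, function(g) g$proteins)
  edges <- build_rbh_graph(prot)
  fams <- cluster_families(edges)
  # partition property: every gene in exactly one family
  all_genes <- unlist(lapply(ds$genomes, function(g)
    paste0(g$strain_id, "|", g$genes$gene_id)), use.names = FALSE)
  expect_setequal(paste0(fams$strain, "|", fams$gene_id), all_genes)
  expect_equal(nrow(fams), length(all_genes))
  # family count and membership match the truth exactly
  tm <- ds$truth$gene_map
  expect_equal(length(unique(fams$family_id)), length(unique(tm$family_id)))
  key <- paste(tm$strain, tm$gene_id)
  fkey <- paste(fams$strain, fams$gene_id)
  tab <- table(tm$family_id, fams$family_id[match(key, fkey)])
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("families are deterministic under input reordering", {
  ds <- tiny_clade()
  prot <- lapply(ds$genomes, function(g) g$proteins)
  shuffled <- rev(lapply(prot, function(p) p[rev(seq_along(p))]))
  f1 <- cluster_families(build_rbh_graph(prot))
  f2 <- cluster_families(build_rbh_graph(shuffled))
  o1 <- f1[order(f1$strain, f1$gene_id), ]
  o2 <- f2[order(f2$strain, f2$gene_id), ]
  expect_equal(o1$family_id, o2$family_id)
})

test_that("the k-mer prefilter is lossless on suite data", {
  ds <- tiny_clade()
  prot <- lapply(ds$genomes[1:3], function(g) g$proteins)
  with_pf <- build_rbh_graph(prot)
  without <- build_rbh_graph(prot, kmer_prefilter = 0)
  key <- function(e) sort(paste(e$strain1, e$gene1, e$strain2, e$gene2))
  expect_identical(key(with_pf), key(without))
})

test_that("single-copy core keeps exactly the one-per-genome families", {
  fams <- data.frame(
    family_id = c("F1", "F1", "F1", "F2", "F2", "F2", "F2", "F3"),
    strain = c("a", "b", "c", "a", "a", "b", "c", "a"),
    gene_id = paste0("g", 1:8))
  scc <- single_copy_core(fams, c("a", "b", "c"))
  expect_identical(scc, "F1")   # F2 has a paralog in a; F3 misses b, c
  expect_error(single_copy_core(fams, character(0)), "empty genome list")
  # synthetic clade: single-copy core equals the truth core count
  ds <- tiny_clade()
  prot <- lapply(ds$genomes, function(g) g$proteins)
  fams <- cluster_families(build_rbh_graph(prot))
  scc <- single_copy_core(fams, names(ds$genomes))
  n_core_truth <- sum(ds$truth$family_class$class == "core")
  # accessory families present once everywhere also qualify
  m <- truth_matrix(ds)
  acc_all <- sum(startsWith(rownames(m), "ACC") & rowSums(m == 1) == ncol(m))
  expect_equal(length(scc), n_core_truth + acc_all)
})
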