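test_that("center-star alignment handles the small worked cases", {
  same <- c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC")
  aln <- center_star_msa(same)
  expect_identical(unname(aln[names(same)]), unname(same))
  trio <- c(x = "ACGT", y = "AGT", z = "ACGT")
  aln <- center_star_msa(trio)
  expect_identical(attr(aln, "center"), "x")
  expect_true(all(nchar(aln) == 4))
  expect_identical(unname(aln["x"]), "ACGT")
  expect_equal(lengths(regmatches(aln["y"], gregexpr("-", aln["y"]))), 1,
               ignore_attr = TRUE)
  # alignment length >= max input length on random inputs
  set.seed(12)
  for (i in 1:5) {
    seqs <- setNames(vapply(1:4, function(j)
      random_dna(sample(20:40, 1)), ""), paste0("t", 1:4))
    a <- center_star_msa(seqs)
    expect_true(all(nchar(a) == nchar(a[1])))
    expect_gte(nchar(a[1]), max(nchar(seqs)))
  }
  expect_error(center_star_msa(character(0)), "empty")
})

test_that("SNP extraction drops gapped columns and keeps provenance", {
  aln <- list(g1 = c(t1 = "AAAT", t2 = "AATT"),
              g2 = c(t1 = "CC-G", t2 = "CCAG"))
  snps <- concat_and_extract_snps(aln)
  # one variable site in g1; the gapped g2 column is dropped even though
  # it differs between taxa
  expect_equal(ncol(snps$snps), 1)
  expect_equal(snps$provenance$gene, "g1")
  expect_equal(snps$provenance$offset, 3)
  expect_equal(snps$n_total_sites, 4 + 3)
  expect_error(concat_and_extract_snps(
    list(g1 = c(t1 = "AA", t2 = "AA"), g2 = c(t1 = "AA", tX = "AA"))),
    "taxa mismatch.*g2")
})

test_that("SNP count equals the pairwise discrepancy count on gap-free data", {
  anc <- random_dna(3000, seed = 13)
  t1 <- evolve_sequence(anc, 0.01, seed = 1)
  t2 <- evolve_sequence(anc, 0.01, seed = 2)
  aln <- list(g = c(a = t1, b = t2))   # substitution-only: already aligned
  snps <- concat_and_extract_snps(aln)
  direct <- sum(strsplit(t1, "")[[1]] != strsplit(t2, "")[[1]])
  expect_equal(ncol(snps$snps), direct)
  expect_equal(snps$n_total_sites, 3000)
})

test_that("distance models order correctly and fail when saturated", {
  snps <- structure(list(
    snps = matrix(c("A", "C", "A", "G"), 2, 2,
                  dimnames = list(c("t1", "t2"), NULL)),
    provenance = NULL, n_total_sites = 10L), class = "snp_matrix")
  p <- snp_distance_matrix(snps, "p")
  jc <- snp_distance_matrix(snps, "jc")
  poi <- snp_distance_matrix(snps, "poisson")
  expect_equal(p["t1", "t2"], 0.2)
  expect_gte(jc["t1", "t2"], p["t1", "t2"])
  expect_equal(jc["t1", "t2"], -0.75 * log(1 - 4 * 0.2 / 3))
  expect_equal(poi["t1", "t2"], -log(0.8))
  snps$n_total_sites <- 2L   # p = 1 >= 0.75
  expect_error(snp_distance_matrix(snps, "jc"), "undefined")
})

test_that("neighbor joining solves the additive four-taxon case exactly", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- nj_tree(D)
  # split AB|CD with branch lengths from ((A:1,B:2):1,(C:3,D:4))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::read.tree(
    text = "((A:1,B:2):1,C:3,D:4);")), 0, ignore_attr = TRUE)
  pat <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(pat, D, tolerance = 1e-9, ignore_attr = TRUE)
  # 3 taxa: closed-form star
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(D3)
  expect_equal(sort(t3$edge.length), c(1, 1, 3))
  # deterministic tie-break on an equidistant quartet: (A, B) joined first
  De <- matrix(1, 4, 4, dimnames = list(taxa, taxa)); diag(De) <- 0
  te <- nj_tree(De)
  sib <- ape::prop.part(te)
  expect_true(any(vapply(sib, function(s)
    setequal(te$tip.label[s], c("A", "B")) ||
      setequal(te$tip.label[s], c("C", "D")), TRUE)))
  # validation
  expect_error(nj_tree(D - 1), "negative")
  Dn <- D; Dn[1, 2] <- 4
  expect_error(nj_tree(Dn), "non-symmetric")
})

test_that("NJ recovers random additive trees and matches the ape oracle", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
    D <- ape::cophenetic.phylo(gen)
    D <- (D + t(D)) / 2
    mine <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(gen), mine), 0,
                 ignore_attr = TRUE)
    # independent implementation agrees on the topology
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ref, mine), 0, ignore_attr = TRUE)
    # additive case: branch lengths reproduce the input distances
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("bootstrap gives full support to a uniform signal", {
  # every column supports the split t1t2 | t3t4
  m <- matrix(rep(c("A", "A", "C", "C"), 30), nrow = 4,
              dimnames = list(paste0("t", 1:4), NULL))
  snps <- structure(list(snps = m, provenance = NULL, n_total_sites = 300L),
                    class = "snp_matrix")
  tr <- bootstrap_support(snps, n_reps = 50, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("the lineage bipartition is strongly supported on synthetic clades", {
  hits <- 0
  for (s in 1:5) {
    ds <- tiny_clade(seed = 200 + s)
    # align the true core families (substitution-only data)
    tm <- ds$truth$gene_map
    core <- unique(tm$family_id[startsWith(tm$family_id, "CORE")])[1:10]
    alns <- lapply(core, function(f) {
      rows <- tm[tm$family_id == f, ]
      setNames(vapply(seq_len(nrow(rows)), function(i)
        ds$genomes[[rows$strain[i]]]$cds[[rows$gene_id[i]]], ""),
        rows$strain)
    })
    names(alns) <- core
    snps <- concat_and_extract_snps(alns)
    tr <- bootstrap_support(snps, n_reps = 50, seed = s)
    keys <- panclade:::tree_split_keys(tr)
    lin <- split(names(ds$genomes), ds$config$lineage_assignment)
    want <- panclade:::canonical_split(lin[[1]], names(ds$genomes))
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (!is.na(match(want, keys)) && sup[match(want, keys)] >= 95)
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("Newick round-trips preserve topology, lengths, and supports", {
  ds <- tiny_clade()
  genomes <- names(ds$genomes)
  tm <- ds$truth$gene_map
  core <- unique(tm$family_id[startsWith(tm$family_id, "CORE")])[1:5]
  alns <- lapply(core, function(f) {
    rows <- tm[tm$family_id == f, ]
    setNames(vapply(seq_len(nrow(rows)), function(i)
      ds$genomes[[rows$strain[i]]]$cds[[rows$gene_id[i]]], ""), rows$strain)
  })
  names(alns) <- core
  tr <- bootstrap_support(concat_and_extract_snps(alns), n_reps = 20, seed = 2)
  f <- tempfile()
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_identical(sort(back$node.label), sort(tr$node.label))
  unlink(f)
})
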