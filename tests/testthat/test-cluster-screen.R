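test_that("BSR is 1 against the source genome and ~0 when absent", {
  ds <- tiny_clade()
  g1 <- ds$genomes[[1]]
  q <- g1$proteins[[5]]
  expect_equal(compute_bsr(q, g1$proteins), 1, tolerance = 1e-9)
  set.seed(15)
  alien <- paste(sample(LETTERS[1:20], 150, TRUE), collapse = "")
  expect_lt(compute_bsr(alien, g1$proteins), 0.4)
  expect_error(compute_bsr("", g1$proteins), "empty query")
})

test_that("a half-identity ortholog lands between the divergent bounds", {
  set.seed(16)
  q <- paste(sample(LETTERS[1:20], 200, TRUE), collapse = "")
  ortho <- strsplit(q, "")[[1]]
  flip <- sample(200, 100)
  ortho[flip] <- sample(LETTERS[1:20], 100, TRUE)
  ortho <- paste(ortho, collapse = "")
  bsr <- compute_bsr(q, c(g = ortho))
  expect_gt(bsr, 0.4)
  expect_lt(bsr, 0.8)
  # exact value against the plain R dynamic-programming oracle
  sc <- scoring_params()
  oracle <- max(0, oracle_nw_score(q, ortho, sc$match, sc$mismatch, sc$gap)) /
    (sc$match * nchar(q))
  expect_equal(bsr, oracle, tolerance = 1e-12)
})

test_that("cluster screening recovers the true recipients exactly", {
  ds <- tiny_clade(seed = 31, hgt_clusters = list(
    hgt_cluster_spec("lanP", n_genes = 8, gene_length = 900,
                     target_gc = 0.36,
                     recipient_genomes = c("G01", "G02", "G03"))))
  ref <- ds$genomes$G01
  tm <- ds$truth$gene_map
  hgt_genes <- tm$gene_id[tm$strain == "G01" & startsWith(tm$family_id, "HGT")]
  clusters <- list(lanP = ref$proteins[hgt_genes])
  res <- screen_clusters(clusters, ds$genomes)
  expect_equal(colnames(res$summary), names(ds$genomes))
  expect_identical(unname(res$summary["lanP", ]),
                   names(ds$genomes) %in% ds$truth$cluster_recipients$lanP)
  # recipients carry every gene verbatim: BSR 1 across the cluster
  expect_true(all(res$bsr[, c("G01", "G02", "G03")] > 0.999))
  # a cluster of core genes is present across its whole (low-divergence)
  # lineage panel
  core_genes <- tm$gene_id[tm$strain == "G01" &
                             startsWith(tm$family_id, "CORE")][1:4]
  res2 <- screen_clusters(list(core = ref$proteins[core_genes]),
                          ds$genomes[c("G01", "G02", "G03")])
  expect_true(all(res2$summary["core", ]))
  expect_warning(
    screen_clusters(list(core = ref$proteins[core_genes],
                         void = character(0)), ds$genomes[1:2]),
    "zero-gene")
})

test_that("removing one homolog flips only its cell and the call at f", {
  ds <- tiny_clade(seed = 31, hgt_clusters = list(
    hgt_cluster_spec("lanP", n_genes = 8, gene_length = 900,
                     target_gc = 0.36,
                     recipient_genomes = c("G01", "G02", "G03"))))
  tm <- ds$truth$gene_map
  hgt_g2 <- tm$gene_id[tm$strain == "G02" & startsWith(tm$family_id, "HGT")]
  panel <- ds$genomes
  panel$G02$proteins <- panel$G02$proteins[
    setdiff(names(panel$G02$proteins), hgt_g2[1])]
  ref_genes <- tm$gene_id[tm$strain == "G01" & startsWith(tm$family_id, "HGT")]
  clusters <- list(lanP = ds$genomes$G01$proteins[ref_genes])
  full <- screen_clusters(clusters, ds$genomes)
  cut <- screen_clusters(clusters, panel)
  changed <- full$calls != cut$calls
  expect_true(all(which(changed, arr.ind = TRUE)[, "col"] ==
                    which(colnames(full$calls) == "G02")))
  # 7/8 = 0.875 >= f = 0.8: the cluster call survives one missing gene
  expect_true(cut$summary["lanP", "G02"])
  # raising the presence fraction above 7/8 flips the cluster call
  strict <- screen_clusters(clusters, panel, f = 0.9)
  expect_false(strict$summary["lanP", "G02"])
})

test_that("raising the present threshold never adds present calls", {
  ds <- tiny_clade()
  tm <- ds$truth$gene_map
  genes <- tm$gene_id[tm$strain == "G01"][1:6]
  clusters <- list(c1 = ds$genomes$G01$proteins[genes])
  loose <- screen_clusters(clusters, ds$genomes, present_min = 0.6)
  strict <- screen_clusters(clusters, ds$genomes, present_min = 0.9)
  expect_true(all(sum(strict$calls == "present") <=
                    sum(loose$calls == "present")))
})

test_that("GC arithmetic: pure-GC region, worked deltas, and conservation", {
  g <- genome_record("s", c(chr = paste0(strrep("AT", 300), strrep("GC", 150))))
  rep <- gc_deviation_scan(g, data.frame(region_id = "r", contig = "chr",
                                         start = 600, end = 900),
                           window = 100)
  expect_equal(rep$region_gc, 1.0)
  # paper-style contrast: 38.6% cluster in a 46.7% genome = -8.1 points
  expect_equal(100 * (0.386 - 0.467), -8.1)
  # genome GC equals the length-weighted mean of tiling windows
  s <- random_dna(25731, seed = 17)
  tiles <- panclade:::gc_tiling(s, 10000)
  expect_equal(sum(tiles[, 1]) / sum(tiles[, 2]),
               panclade:::gc_fraction(s), tolerance = 1e-12)
  # short regions are reported but low-confidence
  rep2 <- gc_deviation_scan(g, data.frame(region_id = "tiny", contig = "chr",
                                          start = 0, end = 150), window = 100)
  expect_true(rep2$low_confidence)
  expect_error(gc_deviation_scan(g, data.frame(region_id = "oob",
                                               contig = "chr",
                                               start = 0, end = 1e6)),
               "bounds")
})

test_that("GC-shifted insertions are flagged in at least 19 of 20 seeds", {
  flags <- 0
  for (s in 1:20) {
    cfg <- clade_config(n_genomes = 2, lineage_assignment = c("P", "P"),
                        n_core = 80, n_accessory = 0, singleton_rate = 0,
                        base_gc = 0.50, seed = 400 + s,
                        hgt_clusters = list(
                          hgt_cluster_spec("h", n_genes = 10,
                                           gene_length = 1200,
                                           target_gc = 0.35,
                                           recipient_genomes = "G01")))
    ds <- simulate_clade(cfg)
    rep <- gc_deviation_scan(ds$genomes$G01)
    if (isTRUE(rep$flag[rep$region_id == "h"])) flags <- flags + 1
  }
  expect_gte(flags, 19)
})
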