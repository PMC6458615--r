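test_that("identical config and seed give byte-identical output", {
  cfg <- clade_config(n_genomes = 3, lineage_assignment = c("P", "P", "L"),
                      n_core = 10, n_accessory = 5, singleton_rate = 1,
                      seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_clade(cfg), d1)
  write_dataset(simulate_clade(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("core-only config yields exactly n_core genes per genome", {
  cfg <- clade_config(n_genomes = 4, lineage_assignment = rep("P", 4),
                      n_core = 12, n_accessory = 0, singleton_rate = 0,
                      seed = 5)
  ds <- simulate_clade(cfg)
  for (g in ds$genomes) expect_equal(nrow(g$genes), 12)
  m <- truth_matrix(ds)
  expect_equal(nrow(m), 12)                      # pan = core
  expect_true(all(m == 1))
})

test_that("observed core count on a 14-genome clade matches the truth table", {
  cfg <- clade_config(n_genomes = 14, n_core = 300, n_accessory = 100,
                      accessory_presence_prob = 0.5, singleton_rate = 3,
                      seed = 21)
  ds <- simulate_clade(cfg)
  # recount from emitted annotations: families present in every genome
  m <- presence_absence_matrix(
    do.call(rbind, lapply(ds$genomes, function(g) {
      gm <- ds$truth$gene_map
      gm[gm$strain == g$strain_id, c("family_id", "strain")]
    })), genomes = names(ds$genomes))
  observed_core <- sum(rowSums(m > 0) == 14)
  acc_all <- sum(startsWith(rownames(m), "ACC") & rowSums(m > 0) == 14)
  expect_equal(observed_core, 300 + acc_all)
  # per-genome gene counts decompose as core + accessory + singletons
  for (g in names(ds$genomes)) {
    gm <- ds$truth$gene_map
    expect_equal(nrow(ds$genomes[[g]]$genes), sum(gm$strain == g))
  }
})

test_that("Jukes-Cantor evolution matches its closed-form divergence", {
  s <- random_dna(100000, seed = 1)
  expect_identical(evolve_sequence(s, 0), s)
  out <- evolve_sequence(s, 0.1, seed = 2)
  p <- mean(strsplit(s, "")[[1]] != strsplit(out, "")[[1]])
  p_exp <- 0.75 * (1 - exp(-0.4 / 3))          # 0.09365...
  se <- sqrt(p_exp * (1 - p_exp) / 100000)
  expect_lt(abs(p - p_exp), 3 * se)
  # saturation
  sat <- evolve_sequence(s, 10, seed = 3)
  psat <- mean(strsplit(s, "")[[1]] != strsplit(sat, "")[[1]])
  expect_lt(abs(psat - 0.75), 0.02)
  expect_error(evolve_sequence(s, -0.1), "branch_length")
})

test_that("HGT insertion hits its GC target and annotation arithmetic", {
  host <- random_dna(50000, seed = 4)
  spec <- hgt_cluster_spec("lan", n_genes = 11, gene_length = 1500,
                           target_gc = 0.386, recipient_genomes = "G01")
  ins <- insert_hgt_cluster(host, spec, locus = 20000, seed = 7)
  # ~17 kb cluster: realized GC within +/- 0.01 of target
  clseq <- substring(ins$sequence, ins$cluster_start + 1, ins$cluster_end)
  expect_gte(nchar(clseq), 10000)
  gc <- panclade:::gc_fraction(clseq)
  expect_gte(gc, 0.376); expect_lte(gc, 0.396)
  # length bookkeeping: genes + spacers
  expect_equal(nchar(ins$sequence), nchar(host) + 11 * 1500 + 10 * 100)
  expect_equal(ins$cluster_end - ins$cluster_start, 11 * 1500 + 10 * 100)
  expect_equal(unname(ins$genes$end - ins$genes$start), rep(1500, 11))
  # errors
  expect_error(hgt_cluster_spec("x", n_genes = 0, recipient_genomes = "G01"),
               "n_genes")
  expect_error(insert_hgt_cluster(host, spec, locus = nchar(host) + 1),
               "out of genome bounds")
})

test_that("truth table round-trips from the emitted annotations", {
  ds <- tiny_clade()
  # every gene in the records appears exactly once in the truth map
  rec_genes <- do.call(rbind, lapply(ds$genomes, function(g)
    data.frame(strain = g$strain_id, gene_id = g$genes$gene_id)))
  tm <- ds$truth$gene_map
  expect_setequal(paste(rec_genes$strain, rec_genes$gene_id),
                  paste(tm$strain, tm$gene_id))
  expect_false(anyDuplicated(paste(tm$strain, tm$gene_id)) > 0)
  # core families present exactly once everywhere; singletons exactly once
  m <- truth_matrix(ds)
  core <- ds$truth$family_class$family_id[ds$truth$family_class$class == "core"]
  expect_true(all(m[core, ] == 1))
  sing <- ds$truth$family_class$family_id[
    ds$truth$family_class$class == "singleton"]
  if (length(sing)) expect_true(all(rowSums(m[sing, , drop = FALSE] > 0) == 1))
  # CDS in the record equals the genome substring, and proteins translate
  g <- ds$genomes[[1]]
  i <- 3
  expect_identical(unname(g$cds[i]),
                   substring(g$sequences[["chr"]], g$genes$start[i] + 1,
                             g$genes$end[i]))
  expect_identical(g$proteins, translate_cds(g$cds))
})

test_that("higher singleton rates enlarge the expected pan-genome", {
  pan_size <- function(rate, seed) {
    cfg <- clade_config(n_genomes = 4, lineage_assignment = rep("P", 4),
                        n_core = 20, n_accessory = 0, singleton_rate = rate,
                        seed = seed)
    nrow(truth_matrix(simulate_clade(cfg)))
  }
  lo <- mean(vapply(1:5, function(s) pan_size(1, s), 0))
  hi <- mean(vapply(1:5, function(s) pan_size(8, s), 0))
  expect_gt(hi, lo)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(clade_config(n_genomes = 1), "n_genomes")
  expect_error(clade_config(accessory_presence_prob = 1.4),
               "accessory_presence_prob")
  expect_error(clade_config(gene_length_range = c(100, 200)),
               "gene_length_range")
  expect_error(clade_config(singleton_rate = -1), "singleton_rate")
  expect_error(clade_config(base_gc = 0), "base_gc")
  expect_error(hgt_cluster_spec("x", 3, recipient_genomes = character(0)),
               "recipient_genomes")
})
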