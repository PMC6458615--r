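#' Run a pipeline stage
#'
#' Thin orchestration over the package's analysis functions, reading and
#' writing the standard plain-text formats (FASTA, GFF3, TSV, JSON, Newick)
#' in a declared output directory. Subcommands:
#' `simulate` (write a synthetic clade), `cluster` (ortholog families +
#' single-copy core), `pangenome` (accumulation curves and fits), `ani`
#' (ANI matrix and species clusters), `phylo` (core-SNP NJ tree with
#' bootstrap), `screen` (BSR cluster screening + GC deviation scan), `dnds`
#' (pairwise NG86 table for single-copy core genes), and `all` (everything,
#' in order, on a freshly simulated dataset).
#'
#' @param subcommand one of the stage names above.
#' @param config named list of stage options (see Details).
#' @param outdir output directory, created if needed.
#' @param seed integer seed used by every stochastic stage.
#' @details Config keys (all optional): `clade` (list of [clade_config()]
#'   arguments for `simulate`/`all`), `data_dir` (input directory holding
#'   per-strain `.fna`/`.faa`/`.ffn`/`.gff`; defaults to `<outdir>/data`),
#'   `min_identity`, `n_permutations`, `ani` (list of [ani_params()]
#'   arguments), `ani_cutoff`, `n_bootstrap`, `distance_model`, `reference`
#'   (reference strain for gene order and cluster queries), `bsr_f`
#'   (cluster-presence fraction), `max_dnds_families`.
#' @return Invisibly, a named list of the file paths written.
#' @export
run_pipeline <- function(subcommand, config = list(), outdir = "panclade_out",
                         seed = 1L) {
  stages <- c("simulate", "cluster", "pangenome", "ani", "phylo", "screen",
              "dnds", "all")
  if (length(subcommand) != 1 || !subcommand %in% stages)
    stop("unknown subcommand '", paste(subcommand, collapse = ","),
         "'; expected one of: ", paste(stages, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- config$data_dir %||% file.path(outdir, "data")
  log <- list(subcommand = subcommand, seed = seed,
              package_version = as.character(utils::packageVersion("panclade")),
              config = config, time = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  out <- list()
  if (subcommand %in% c("simulate", "all")) {
    cfg <- do.call(clade_config, c(config$clade %||% list(),
                                   list(seed = as.integer(seed))))
    ds <- simulate_clade(cfg)
    write_dataset(ds, data_dir)
    out$data_dir <- data_dir
  }
  if (subcommand %in% c("cluster", "all"))
    out <- c(out, stage_cluster(data_dir, outdir, config))
  if (subcommand %in% c("pangenome", "all"))
    out <- c(out, stage_pangenome(outdir, config, seed))
  if (subcommand %in% c("ani", "all"))
    out <- c(out, stage_ani(data_dir, outdir, config))
  if (subcommand %in% c("phylo", "all"))
    out <- c(out, stage_phylo(data_dir, outdir, config, seed))
  if (subcommand %in% c("screen", "all"))
    out <- c(out, stage_screen(data_dir, outdir, config))
  if (subcommand %in% c("dnds", "all"))
    out <- c(out, stage_dnds(data_dir, outdir, config))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

require_files <- function(paths, what) {
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("missing ", what, ": ", paste(miss, collapse = ", "),
         " -- run the upstream stage or point data_dir at existing inputs")
}

strain_files <- function(data_dir, ext) {
  fs <- sort(list.files(data_dir, pattern = paste0("\\.", ext, "$"),
                        full.names = TRUE))
  if (length(fs) == 0)
    stop("missing inputs: no .", ext, " files in ", data_dir)
  setNames(fs, sub(paste0("\\.", ext, "$"), "", basename(fs)))
}

# strip "strain|" prefixes that write_dataset adds to CDS/protein ids
read_tagged_fasta <- function(path) {
  x <- read_fasta(path)
  names(x) <- sub("^[^|]*\\|", "", names(x))
  x
}

stage_cluster <- function(data_dir, outdir, config) {
  faa <- strain_files(data_dir, "faa")
  proteomes <- lapply(faa, read_tagged_fasta)
  edges <- build_rbh_graph(proteomes,
                           min_identity = config$min_identity %||% 0.5)
  fams <- cluster_families(edges)
  scc <- single_copy_core(fams, names(proteomes))
  fam_path <- file.path(outdir, "families.tsv")
  scc_path <- file.path(outdir, "single_copy_core.tsv")
  write.table(fams, fam_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(family_id = scc), scc_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(families = fam_path, single_copy_core = scc_path)
}

stage_pangenome <- function(outdir, config, seed) {
  fam_path <- config$families_file %||% file.path(outdir, "families.tsv")
  require_files(fam_path, "families table")
  fams <- read.delim(fam_path, stringsAsFactors = FALSE)
  mat <- presence_absence_matrix(fams)
  curve <- accumulation_curves(mat,
                               n_permutations = config$n_permutations %||% 100,
                               seed = seed)
  heaps <- fit_heaps(curve)
  decay <- fit_core_decay(curve)
  sing <- singleton_stats(mat)
  curve_path <- file.path(outdir, "accumulation_curve.tsv")
  fits_path <- file.path(outdir, "pangenome_fits.json")
  write.table(curve, curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(heaps = heaps, core_decay = decay,
         pan_size = nrow(mat),
         core_size = sum(rowSums(mat > 0) == ncol(mat)),
         n_singleton = sing$n_singleton,
         singleton_fraction = sing$fraction),
    fits_path, auto_unbox = TRUE, digits = NA)
  list(accumulation_curve = curve_path, pangenome_fits = fits_path)
}

stage_ani <- function(data_dir, outdir, config) {
  fna <- strain_files(data_dir, "fna")
  genomes <- lapply(fna, read_fasta)
  params <- do.call(ani_params, config$ani %||% list())
  res <- ani_matrix_and_species(genomes, params,
                                cutoff = config$ani_cutoff %||% 95)
  mat_path <- file.path(outdir, "ani_matrix.tsv")
  sp_path <- file.path(outdir, "ani_species.tsv")
  par_path <- file.path(outdir, "ani_params.json")
  write.table(res$matrix, mat_path, sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(data.frame(genome = names(res$species),
                         species_cluster = res$species),
              sp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(params, list(cutoff = config$ani_cutoff %||% 95)),
                       par_path, auto_unbox = TRUE)
  list(ani_matrix = mat_path, ani_species = sp_path, ani_params = par_path)
}

# single-copy core families as per-family named CDS vectors, in reference
# genome gene order
core_family_cds <- function(data_dir, outdir, config) {
  fam_path <- config$families_file %||% file.path(outdir, "families.tsv")
  scc_path <- config$scc_file %||% file.path(outdir, "single_copy_core.tsv")
  require_files(c(fam_path, scc_path), "orthology outputs")
  fams <- read.delim(fam_path, stringsAsFactors = FALSE)
  scc <- read.delim(scc_path, stringsAsFactors = FALSE)$family_id
  ffn <- strain_files(data_dir, "ffn")
  cds <- lapply(ffn, read_tagged_fasta)
  reference <- config$reference %||% names(cds)[1]
  fams <- fams[fams$family_id %in% scc, , drop = FALSE]
  # reference gene order: genes appear in genome order in the reference GFF
  gff <- file.path(data_dir, paste0(reference, ".gff"))
  require_files(gff, "reference annotation")
  ref_rec <- read_gff(gff, read_fasta(file.path(data_dir,
                                                paste0(reference, ".fna"))),
                      strain_id = reference)
  ref_order <- ref_rec$genes$gene_id[order(ref_rec$genes$start)]
  ref_genes <- fams$gene_id[fams$strain == reference]
  names(ref_genes) <- fams$family_id[fams$strain == reference]
  fam_order <- names(ref_genes)[order(match(ref_genes, ref_order))]
  blocks <- lapply(fam_order, function(f) {
    rows <- fams[fams$family_id == f, , drop = FALSE]
    setNames(vapply(seq_len(nrow(rows)),
                    function(i) cds[[rows$strain[i]]][[rows$gene_id[i]]], ""),
             rows$strain)
  })
  names(blocks) <- fam_order
  blocks
}

stage_phylo <- function(data_dir, outdir, config, seed) {
  blocks <- core_family_cds(data_dir, outdir, config)
  if (length(blocks) == 0) stop("no single-copy core families for phylogeny")
  alns <- lapply(blocks, center_star_msa, band = config$msa_band %||% 64L)
  snps <- concat_and_extract_snps(alns)
  model <- config$distance_model %||% "p"
  tree <- bootstrap_support(snps, n_reps = config$n_bootstrap %||% 100,
                            seed = seed, model = model,
                            outgroup = config$outgroup)
  d <- snp_distance_matrix(snps, model)
  snp_path <- file.path(outdir, "core_snps.fasta")
  dist_path <- file.path(outdir, "snp_distances.tsv")
  tree_path <- file.path(outdir, "nj_tree.nwk")
  write_fasta(apply(snps$snps, 1, paste, collapse = ""), snp_path)
  write.table(d, dist_path, sep = "\t", quote = FALSE, col.names = NA)
  ape::write.tree(tree, tree_path)
  list(core_snps = snp_path, snp_distances = dist_path, nj_tree = tree_path)
}

read_strain_records <- function(data_dir) {
  fna <- strain_files(data_dir, "fna")
  lapply(setNames(names(fna), names(fna)), function(s) {
    gff <- file.path(data_dir, paste0(s, ".gff"))
    require_files(gff, "annotation")
    read_gff(gff, read_fasta(fna[[s]]), strain_id = s)
  })
}

stage_screen <- function(data_dir, outdir, config) {
  panel <- read_strain_records(data_dir)
  # reference = requested, else the first strain carrying cluster annotations
  has_cl <- vapply(panel, function(r)
    !is.null(r$clusters) && nrow(r$clusters) > 0, TRUE)
  reference <- config$reference %||% names(panel)[which(has_cl)[1]]
  if (is.na(reference) || !isTRUE(has_cl[[reference]]))
    stop("missing inputs: no genome with cluster annotations to screen")
  ref <- panel[[reference]]
  clusters <- lapply(seq_len(nrow(ref$clusters)), function(i) {
    cl <- ref$clusters[i, ]
    inside <- ref$genes$contig == cl$contig & ref$genes$start >= cl$start &
      ref$genes$end <= cl$end
    ref$proteins[ref$genes$gene_id[inside]]
  })
  names(clusters) <- ref$clusters$cluster_id
  res <- screen_clusters(clusters, panel, f = config$bsr_f %||% 0.8)
  gc_rep <- do.call(rbind, lapply(names(panel)[has_cl], function(s) {
    rep <- gc_deviation_scan(panel[[s]])
    rep$genome <- s
    rep
  }))
  bsr_path <- file.path(outdir, "bsr_matrix.tsv")
  sum_path <- file.path(outdir, "cluster_presence.tsv")
  gc_path <- file.path(outdir, "gc_deviation.tsv")
  write.table(res$bsr, bsr_path, sep = "\t", quote = FALSE, col.names = NA)
  write.table(res$summary, sum_path, sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(gc_rep, gc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(bsr_matrix = bsr_path, cluster_presence = sum_path,
       gc_deviation = gc_path)
}

stage_dnds <- function(data_dir, outdir, config) {
  blocks <- core_family_cds(data_dir, outdir, config)
  maxfam <- config$max_dnds_families %||% length(blocks)
  blocks <- blocks[seq_len(min(maxfam, length(blocks)))]
  rows <- list()
  for (f in names(blocks)) {
    blk <- blocks[[f]]
    ref <- names(blk)[1]
    for (s in names(blk)[-1]) {
      if (nchar(blk[[ref]]) != nchar(blk[[s]])) next # indel'd pair: skip
      has_stop <- function(x) {
        cod <- split_codons(x)
        any(cod %in% STOP_CODONS)
      }
      if (has_stop(blk[[ref]]) || has_stop(blk[[s]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste(f, ref, s, sep = "|"),
        cds1 = blk[[ref]], cds2 = blk[[s]], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no stop-free equal-length core pairs for dN/dS")
  tab <- ng86_table(do.call(rbind, rows))
  tab$cds1 <- NULL
  path <- file.path(outdir, "dnds.tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(dnds = path)
}
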