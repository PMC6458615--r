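#' Configuration for a synthetic clade
#'
#' Describes a clade of `n_genomes` strains split into lineages, with gene
#' families partitioned into core (present once in every genome), accessory
#' (Bernoulli presence per genome) and singleton (Poisson per genome,
#' private) classes, tree-structured Jukes-Cantor nucleotide substitution,
#' and optional laterally transferred gene clusters with deviant GC.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param lineage_assignment lineage label per genome; genomes sharing a
#'   label descend from a common lineage ancestor. A label used by a single
#'   genome makes that genome an outlier attached at the root.
#' @param n_core number of core gene families.
#' @param n_accessory number of accessory gene families.
#' @param accessory_presence_prob per-genome presence probability of an
#'   accessory family.
#' @param accessory_mode `"iid"` (presence independent across genomes) or
#'   `"lineage"` (each accessory family is confined to one lineage, drawn
#'   with `accessory_presence_prob` within it).
#' @param singleton_rate expected number of strain-private genes per genome
#'   (Poisson mean, >= 0).
#' @param gene_length_range two nucleotide lengths, both multiples of 3.
#' @param tree_branch_lengths list with elements `stem` (root to lineage
#'   ancestor) and `tip` (lineage ancestor to genome), expected
#'   substitutions/site.
#' @param hgt_clusters list of [hgt_cluster_spec()] objects.
#' @param base_gc genomic GC fraction in (0, 1).
#' @param genome_ids optional genome labels (default `G01`, `G02`, ...).
#' @param seed RNG seed; identical seed and config give byte-identical
#'   output.
#' @return A validated `clade_config` list.
#' @export
clade_config <- function(n_genomes = 14,
                         lineage_assignment = rep("P", n_genomes),
                         n_core = 300,
                         n_accessory = 400,
                         accessory_presence_prob = 0.5,
                         accessory_mode = c("iid", "lineage"),
                         singleton_rate = 10,
                         gene_length_range = c(300, 900),
                         tree_branch_lengths = list(stem = 0.03, tip = 0.01),
                         hgt_clusters = list(),
                         base_gc = 0.468,
                         genome_ids = NULL,
                         seed = 1L) {
  accessory_mode <- match.arg(accessory_mode)
  chk <- function(ok, field, why)
    if (!ok) stop("invalid clade_config field '", field, "': ", why,
                  call. = FALSE)
  chk(is.numeric(n_genomes) && n_genomes >= 2, "n_genomes", "must be >= 2")
  chk(length(lineage_assignment) == n_genomes, "lineage_assignment",
      "must have one label per genome")
  chk(is.numeric(n_core) && n_core >= 0, "n_core", "must be >= 0")
  chk(is.numeric(n_accessory) && n_accessory >= 0, "n_accessory",
      "must be >= 0")
  chk(accessory_presence_prob >= 0 && accessory_presence_prob <= 1,
      "accessory_presence_prob", "must be in [0,1]")
  chk(singleton_rate >= 0, "singleton_rate", "must be >= 0")
  chk(length(gene_length_range) == 2 && all(gene_length_range > 0) &&
        all(gene_length_range %% 3 == 0) &&
        gene_length_range[1] <= gene_length_range[2],
      "gene_length_range", "must be two positive multiples of 3")
  chk(is.list(tree_branch_lengths) &&
        all(c("stem", "tip") %in% names(tree_branch_lengths)) &&
        tree_branch_lengths$stem >= 0 && tree_branch_lengths$tip >= 0,
      "tree_branch_lengths", "needs non-negative 'stem' and 'tip'")
  chk(base_gc > 0 && base_gc < 1, "base_gc", "must be in (0,1)")
  for (h in hgt_clusters)
    chk(inherits(h, "hgt_cluster_spec"), "hgt_clusters",
        "entries must be hgt_cluster_spec objects")
  if (is.null(genome_ids)) genome_ids <- sprintf("G%02d", seq_len(n_genomes))
  chk(length(genome_ids) == n_genomes && !anyDuplicated(genome_ids),
      "genome_ids", "must be unique, one per genome")
  structure(list(n_genomes = as.integer(n_genomes),
                 lineage_assignment = as.character(lineage_assignment),
                 n_core = as.integer(n_core),
                 n_accessory = as.integer(n_accessory),
                 accessory_presence_prob = accessory_presence_prob,
                 accessory_mode = accessory_mode,
                 singleton_rate = singleton_rate,
                 gene_length_range = as.integer(gene_length_range),
                 tree_branch_lengths = tree_branch_lengths,
                 hgt_clusters = hgt_clusters,
                 base_gc = base_gc,
                 genome_ids = genome_ids,
                 seed = as.integer(seed)),
            class = "clade_config")
}

#' Specification of a laterally transferred gene cluster
#'
#' @param cluster_name cluster label.
#' @param n_genes number of genes in the cluster (> 0).
#' @param gene_length nucleotide length per gene, multiple of 3.
#' @param target_gc GC fraction of the inserted region, in (0, 1);
#'   typically deviant from the host's base GC.
#' @param recipient_genomes genome labels receiving the cluster (non-empty).
#' @param insertion_locus `"start"`, `"middle"`, `"end"`, or an integer
#'   position (0-based) in the recipient genome; snapped to the nearest
#'   inter-gene boundary during simulation.
#' @param spacer_length bases between consecutive cluster genes.
#' @return An `hgt_cluster_spec` object.
#' @export
hgt_cluster_spec <- function(cluster_name, n_genes, gene_length = 900,
                             target_gc = 0.386, recipient_genomes,
                             insertion_locus = "middle",
                             spacer_length = 100L) {
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("invalid hgt_cluster_spec field 'n_genes': must be >= 1",
         call. = FALSE)
  if (gene_length %% 3 != 0 || gene_length <= 0)
    stop("invalid hgt_cluster_spec field 'gene_length': positive multiple of 3",
         call. = FALSE)
  if (target_gc <= 0 || target_gc >= 1)
    stop("invalid hgt_cluster_spec field 'target_gc': must be in (0,1)",
         call. = FALSE)
  if (length(recipient_genomes) == 0)
    stop("invalid hgt_cluster_spec field 'recipient_genomes': must be non-empty",
         call. = FALSE)
  structure(list(cluster_name = cluster_name,
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 target_gc = target_gc,
                 recipient_genomes = as.character(recipient_genomes),
                 insertion_locus = insertion_locus,
                 spacer_length = as.integer(spacer_length)),
            class = "hgt_cluster_spec")
}

# Random sequence with an exact GC count: round(gc * n) positions are G or C
# (coin flip each), the rest A or T, in a random order.
random_gc_seq <- function(n, gc) {
  n_gc <- round(gc * n)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), n - n_gc, replace = TRUE))
  paste(bases[sample.int(n)], collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random in-frame gene with exact GC; stop codons are removed by swapping
# bases with random other positions (composition-preserving), so realized GC
# stays exact. Falls back to whatever remains after max_iter sweeps.
random_cds <- function(len, gc, max_iter = 100) {
  s <- strsplit(random_gc_seq(len, gc), "")[[1]]
  for (it in seq_len(max_iter)) {
    cod <- paste0(s[seq(1, len, 3)], s[seq(2, len, 3)], s[seq(3, len, 3)])
    stops <- which(cod %in% STOP_CODONS)
    if (length(stops) == 0) break
    for (ci in stops) {
      p <- (ci - 1) * 3 + sample.int(3, 1)
      q <- sample.int(len, 1)
      tmp <- s[p]; s[p] <- s[q]; s[q] <- tmp
    }
  }
  paste(s, collapse = "")
}

#' Evolve a nucleotide sequence under the Jukes-Cantor model
#'
#' Each site is substituted with probability
#' `p = (3/4) * (1 - exp(-4 d / 3))` (the JC transition probability for a
#' branch of `d` expected substitutions/site), drawing uniformly among the
#' three alternative bases. Ambiguous characters are left untouched.
#'
#' @param seq nucleotide sequence (single string).
#' @param branch_length expected substitutions per site (>= 0).
#' @param seed optional RNG seed; when `NULL` the current RNG stream is used.
#' @return The evolved sequence.
#' @export
evolve_sequence <- function(seq, branch_length, seed = NULL) {
  if (!is.numeric(branch_length) || branch_length < 0)
    stop("branch_length must be >= 0")
  with_seed(seed, {
    if (branch_length == 0) return(seq)
    p <- 0.75 * (1 - exp(-4 * branch_length / 3))
    s <- strsplit(seq, "")[[1]]
    eligible <- s %in% c("A", "C", "G", "T")
    hit <- which(eligible & runif(length(s)) < p)
    if (length(hit)) {
      alt <- matrix(c("C", "G", "T",   # A ->
                      "A", "G", "T",   # C ->
                      "A", "C", "T",   # G ->
                      "A", "C", "G"),  # T ->
                    nrow = 4, byrow = TRUE,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pick <- sample.int(3, length(hit), replace = TRUE)
      s[hit] <- alt[cbind(match(s[hit], rownames(alt)), pick)]
    }
    paste(s, collapse = "")
  })
}

#' Insert a horizontally transferred gene cluster into a genome sequence
#'
#' Builds the cluster (genes at the spec's `target_gc`, joined by spacers at
#' the same GC) and splices it into the host sequence at `locus`. The same
#' `seed` yields the same cluster sequence, so one spec can be inserted
#' identically into several recipient genomes.
#'
#' @param genome host nucleotide sequence (single string).
#' @param spec an [hgt_cluster_spec()].
#' @param locus 0-based insertion position in `[0, nchar(genome)]`.
#' @param seed RNG seed for the cluster sequence.
#' @return List with `sequence` (host with insert), `cluster_start`,
#'   `cluster_end` (internal half-open coordinates of the insert),
#'   `genes` (data frame of within-insert gene coordinates, then shifted to
#'   genome coordinates), and `gene_seqs`.
#' @export
insert_hgt_cluster <- function(genome, spec, locus, seed = NULL) {
  stopifnot(inherits(spec, "hgt_cluster_spec"))
  if (spec$n_genes < 1) stop("configuration error: zero-gene cluster spec")
  if (locus < 0 || locus > nchar(genome))
    stop("insertion locus out of genome bounds: ", locus)
  with_seed(seed, {
    genes <- vapply(seq_len(spec$n_genes), function(i)
      random_cds(spec$gene_length, spec$target_gc), "")
    spacers <- vapply(seq_len(spec$n_genes - 1L), function(i)
      random_gc_seq(spec$spacer_length, spec$target_gc), "")
    parts <- character(2 * spec$n_genes - 1)
    parts[seq(1, length(parts), 2)] <- genes
    if (spec$n_genes > 1) parts[seq(2, length(parts), 2)] <- spacers
    insert <- paste(parts, collapse = "")
    starts <- (seq_len(spec$n_genes) - 1L) *
      (spec$gene_length + spec$spacer_length)
    gdf <- data.frame(
      gene_id = sprintf("%s_gene%02d", spec$cluster_name,
                        seq_len(spec$n_genes)),
      start = locus + starts,
      end = locus + starts + spec$gene_length,
      strand = "+", stringsAsFactors = FALSE)
    list(sequence = paste0(substring(genome, 1, locus), insert,
                           substring(genome, locus + 1, nchar(genome))),
         cluster_start = locus,
         cluster_end = locus + nchar(insert),
         genes = gdf,
         gene_seqs = setNames(genes, gdf$gene_id))
  })
}

# Newick for the lineage topology: multi-member lineages become clades on a
# stem branch; single-member lineages attach at the root with stem+tip.
lineage_tree <- function(genome_ids, lineages, stem, tip) {
  groups <- split(genome_ids, factor(lineages, levels = unique(lineages)))
  clauses <- vapply(groups, function(g) {
    if (length(g) >= 2)
      sprintf("(%s):%g", paste0(g, ":", tip, collapse = ","), stem)
    else sprintf("%s:%g", g, stem + tip)
  }, "")
  if (length(clauses) == 1) {
    nwk <- paste0(clauses, ";")
    # single lineage: clauses is already "(...):stem"
    if (!startsWith(clauses, "(")) nwk <- sprintf("(%s);", clauses)
  } else {
    nwk <- sprintf("(%s);", paste(clauses, collapse = ","))
  }
  ape::read.tree(text = nwk)
}

# Evolve one ancestral sequence down an ape tree; returns tip sequences.
evolve_on_tree <- function(tree, root_seq) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_seq
  # edges are in preorder for trees read from Newick; walk them in order
  for (e in seq_len(nrow(tree$edge))) {
    from <- tree$edge[e, 1]; to <- tree$edge[e, 2]
    seqs[[to]] <- evolve_sequence(seqs[[from]], tree$edge.length[e])
  }
  setNames(seqs[seq_len(ntip)], tree$tip.label)
}

#' Simulate a synthetic clade with full ground truth
#'
#' Generates ancestral gene sequences for every core and accessory family,
#' evolves them down the lineage tree under Jukes-Cantor substitution,
#' assembles per-genome sequences (genes on the forward strand, separated by
#' fixed-length spacers), adds strain-private singleton genes, and splices in
#' HGT clusters. The returned truth table records every gene's family, each
#' family's class, the cluster recipients, and the generating tree.
#'
#' @param config a [clade_config()].
#' @return A `synthetic_clade` object: list with `genomes` (named list of
#'   [genome_record()]), `truth` (list with `gene_map`, `family_class`,
#'   `cluster_recipients`, `tree`), and `config`.
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "clade_config"))
  with_seed(config$seed, {
    ids <- config$genome_ids
    tree <- lineage_tree(ids, config$lineage_assignment,
                         config$tree_branch_lengths$stem,
                         config$tree_branch_lengths$tip)
    glr <- config$gene_length_range
    lens_pool <- seq(glr[1], glr[2], by = 3L)

    n_fam <- config$n_core + config$n_accessory
    fam_ids <- c(sprintf("CORE%04d", seq_len(config$n_core)),
                 sprintf("ACC%04d", seq_len(config$n_accessory)))
    fam_class <- c(rep("core", config$n_core),
                   rep("accessory", config$n_accessory))

    # tip sequences per family; each family carries its downstream 100-bp
    # spacer, evolved together with the gene so intergenic DNA is inherited
    # (homologous across strains) like the real thing
    fam_len <- integer(n_fam)
    tip_seqs <- vector("list", n_fam)
    for (f in seq_len(n_fam)) {
      len <- if (length(lens_pool) == 1) lens_pool else sample(lens_pool, 1)
      fam_len[f] <- len
      anc <- paste0(random_cds(len, config$base_gc),
                    random_gc_seq(100L, config$base_gc))
      tip_seqs[[f]] <- evolve_on_tree(tree, anc)
    }
    # inherited leading spacer
    lead_spacer <- evolve_on_tree(tree, random_gc_seq(100L, config$base_gc))

    # presence of accessory families
    pres <- matrix(TRUE, nrow = n_fam, ncol = config$n_genomes,
                   dimnames = list(fam_ids, ids))
    if (config$n_accessory > 0) {
      acc_rows <- config$n_core + seq_len(config$n_accessory)
      if (config$accessory_mode == "iid") {
        pres[acc_rows, ] <- matrix(
          runif(config$n_accessory * config$n_genomes) <
            config$accessory_presence_prob,
          nrow = config$n_accessory)
      } else {
        lin <- unique(config$lineage_assignment)
        fam_lin <- rep(lin, length.out = config$n_accessory)
        for (r in seq_along(acc_rows)) {
          in_lin <- config$lineage_assignment == fam_lin[r]
          pres[acc_rows[r], ] <- in_lin &
            (runif(config$n_genomes) < config$accessory_presence_prob)
        }
      }
    }

    # singleton draws
    n_sing <- rpois(config$n_genomes, config$singleton_rate)

    gene_map <- list()
    genomes <- list()
    sing_counter <- 0L
    for (g in seq_len(config$n_genomes)) {
      gid <- ids[g]
      present <- which(pres[, g])
      fams <- fam_ids[present]
      # gene and its inherited spacer, already evolved for this tip
      seqs <- vapply(present, function(f)
        substring(tip_seqs[[f]][[gid]], 1, fam_len[f]), "")
      spacers <- vapply(present, function(f)
        substring(tip_seqs[[f]][[gid]], fam_len[f] + 1L), "")
      if (n_sing[g] > 0) {
        sfams <- sprintf("SING%04d", sing_counter + seq_len(n_sing[g]))
        sing_counter <- sing_counter + n_sing[g]
        slen <- if (length(lens_pool) == 1) rep(lens_pool, n_sing[g]) else
          sample(lens_pool, n_sing[g], replace = TRUE)
        sseqs <- vapply(slen, function(l) random_cds(l, config$base_gc), "")
        fams <- c(fams, sfams)
        seqs <- c(seqs, sseqs)
        spacers <- c(spacers, vapply(seq_len(n_sing[g]), function(i)
          random_gc_seq(100L, config$base_gc), ""))
      }
      n_genes <- length(fams)
      if (n_genes == 0) {
        gene_map[[gid]] <- data.frame(strain = character(0),
                                      gene_id = character(0),
                                      family_id = character(0),
                                      stringsAsFactors = FALSE)
        genomes[[gid]] <- list(sequence = lead_spacer[[gid]], genes = NULL,
                               clusters = NULL)
        next
      }
      gene_ids <- sprintf("%s_g%04d", gid, seq_len(n_genes))
      parts <- character(2 * n_genes + 1)
      parts[1] <- lead_spacer[[gid]]
      for (i in seq_len(n_genes)) {
        parts[2 * i] <- seqs[i]
        parts[2 * i + 1] <- spacers[i]
      }
      genome_seq <- paste(parts, collapse = "")
      starts <- cumsum(c(100L, head(nchar(seqs), -1) + 100L))
      genes <- data.frame(gene_id = gene_ids, contig = "chr",
                          start = starts, end = starts + nchar(seqs),
                          strand = "+", stringsAsFactors = FALSE)
      gene_map[[gid]] <- data.frame(strain = gid, gene_id = gene_ids,
                                    family_id = fams,
                                    stringsAsFactors = FALSE)
      genomes[[gid]] <- list(sequence = genome_seq, genes = genes,
                             clusters = NULL)
    }

    # HGT clusters: one seed per spec so each recipient gets the identical
    # cluster sequence
    hgt_fams <- list()
    cluster_recipients <- list()
    for (h in config$hgt_clusters) {
      missing <- setdiff(h$recipient_genomes, ids)
      if (length(missing))
        stop("invalid hgt_cluster_spec field 'recipient_genomes': unknown ",
             paste(missing, collapse = ", "))
      h_seed <- sample.int(.Machine$integer.max, 1)
      cluster_recipients[[h$cluster_name]] <- h$recipient_genomes
      for (gid in h$recipient_genomes) {
        gm <- genomes[[gid]]
        len <- nchar(gm$sequence)
        raw_locus <- switch(as.character(h$insertion_locus),
                            start = 0L, middle = len %/% 2L, end = len,
                            as.integer(h$insertion_locus))
        # snap to the nearest inter-gene boundary
        bounds <- sort(unique(c(0L, gm$genes$end + 50L, len)))
        bounds <- bounds[bounds <= len]
        locus <- bounds[which.min(abs(bounds - raw_locus))]
        ins <- insert_hgt_cluster(gm$sequence, h, locus, seed = h_seed)
        shift <- nchar(ins$sequence) - len
        genes <- gm$genes
        move <- genes$start >= locus
        genes$start[move] <- genes$start[move] + shift
        genes$end[move] <- genes$end[move] + shift
        n_old <- nrow(genes)
        new_ids <- sprintf("%s_g%04d", gid, n_old + seq_len(nrow(ins$genes)))
        add <- data.frame(gene_id = new_ids, contig = "chr",
                          start = ins$genes$start, end = ins$genes$end,
                          strand = "+", stringsAsFactors = FALSE)
        genes <- rbind(genes, add)
        clus <- rbind(gm$clusters,
                      data.frame(cluster_id = h$cluster_name, contig = "chr",
                                 start = ins$cluster_start,
                                 end = ins$cluster_end,
                                 stringsAsFactors = FALSE))
        # shift any previously inserted cluster downstream of this locus
        if (!is.null(gm$clusters)) {
          prev <- seq_len(nrow(gm$clusters))
          move_c <- clus$start[prev] >= locus
          clus$start[prev][move_c] <- clus$start[prev][move_c] + shift
          clus$end[prev][move_c] <- clus$end[prev][move_c] + shift
        }
        genomes[[gid]] <- list(sequence = ins$sequence, genes = genes,
                               clusters = clus)
        gene_map[[gid]] <- rbind(
          gene_map[[gid]],
          data.frame(strain = gid, gene_id = new_ids,
                     family_id = sprintf("HGT_%s_%02d", h$cluster_name,
                                         seq_len(nrow(ins$genes))),
                     stringsAsFactors = FALSE))
      }
      hgt_fams[[h$cluster_name]] <- sprintf(
        "HGT_%s_%02d", h$cluster_name, seq_len(h$n_genes))
    }

    records <- lapply(ids, function(gid) {
      gm <- genomes[[gid]]
      genome_record(gid, c(chr = gm$sequence), gm$genes, gm$clusters)
    })
    names(records) <- ids

    gene_map <- do.call(rbind, gene_map)
    rownames(gene_map) <- NULL
    fam_all <- unique(gene_map$family_id)
    cls <- ifelse(startsWith(fam_all, "CORE"), "core",
           ifelse(startsWith(fam_all, "ACC"), "accessory",
           ifelse(startsWith(fam_all, "SING"), "singleton", "hgt")))
    # accessory families that happened to land in every genome are still
    # class "accessory" (the truth records the generative class); but an
    # accessory family absent everywhere simply never appears
    family_class <- data.frame(family_id = fam_all, class = cls,
                               stringsAsFactors = FALSE)
    structure(list(genomes = records,
                   truth = list(gene_map = gene_map,
                                family_class = family_class,
                                cluster_recipients = cluster_recipients,
                                tree = tree),
                   config = config),
              class = "synthetic_clade")
  })
}

#' @export
print.synthetic_clade <- function(x, ...) {
  cat("synthetic_clade:", length(x$genomes), "genomes,",
      length(unique(x$truth$gene_map$family_id)), "gene families,",
      length(x$truth$cluster_recipients), "HGT cluster(s)\n")
  invisible(x)
}

#' Write a synthetic clade to disk
#'
#' Emits, per strain, a genome FASTA, CDS FASTA and protein FASTA (record
#' ids `strain|gene`) and a GFF3 with gene and cluster features; plus the
#' truth table as TSV and the true tree as Newick.
#'
#' @param dataset a [simulate_clade()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_clade"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(dataset$genomes)) {
    rec <- dataset$genomes[[gid]]
    write_fasta(rec$sequences, file.path(outdir, paste0(gid, ".fna")))
    tagged <- function(x) setNames(x, paste0(gid, "|", names(x)))
    write_fasta(tagged(rec$cds), file.path(outdir, paste0(gid, ".ffn")))
    write_fasta(tagged(rec$proteins), file.path(outdir, paste0(gid, ".faa")))
    write_gff(rec, file.path(outdir, paste0(gid, ".gff")))
  }
  write.table(dataset$truth$gene_map,
              file.path(outdir, "truth_gene_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$family_class,
              file.path(outdir, "truth_family_class.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cr <- dataset$truth$cluster_recipients
  if (length(cr)) {
    write.table(data.frame(cluster = rep(names(cr), lengths(cr)),
                           recipient = unlist(cr, use.names = FALSE)),
                file.path(outdir, "truth_cluster_recipients.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ape::write.tree(dataset$truth$tree, file.path(outdir, "true_tree.nwk"))
  invisible(outdir)
}
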