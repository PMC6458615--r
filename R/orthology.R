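#' Globally align two sequences
#'
#' Needleman-Wunsch global alignment with linear gap penalties; the internal
#' replacement for an external all-against-all protein search. Deterministic:
#' ties in the dynamic program are resolved diagonal-first, and the score is
#' symmetric for symmetric scoring.
#'
#' @param a,b non-empty sequences (protein or nucleotide strings).
#' @param scoring a [scoring_params()] list.
#' @return List with `score`, `identity` (matches / alignment columns),
#'   `aligned_length` (columns), and the aligned strings `a_aln`, `b_aln`.
#' @export
align_pair <- function(a, b, scoring = scoring_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("align_pair: empty sequence")
  cpp_align_pair(a, b, scoring$match, scoring$mismatch, scoring$gap)
}

#' Build the reciprocal-best-hit graph over a set of proteomes
#'
#' For every ordered strain pair, each gene's best hit in the other strain is
#' found by global alignment (with a lossless shared-k-mer prefilter; pairs
#' sharing no k-mer cannot reach the identity threshold at these scales). An
#' undirected edge joins two genes iff each is the other's best hit and the
#' alignment passes both thresholds. Score ties are broken by the
#' lexicographically smallest gene id.
#'
#' @param proteomes named list (by strain) of named character vectors of
#'   protein sequences (names are gene ids).
#' @param scoring a [scoring_params()] list.
#' @param min_identity minimum fractional identity for an edge.
#' @param min_score minimum alignment score (exclusive lower bound at 0 by
#'   default: `score > min_score` is required when `min_score = 0`).
#' @param kmer_prefilter k-mer length of the prefilter; `0` disables it.
#' @param min_shared_kmers minimum shared distinct k-mers to align a pair.
#' @return Data frame of edges: `strain1`, `gene1`, `strain2`, `gene2`,
#'   `score`, `identity`, with an attribute `genes` listing every gene as
#'   `strain|gene`.
#' @export
build_rbh_graph <- function(proteomes, scoring = scoring_params(),
                            min_identity = 0.5, min_score = 0,
                            kmer_prefilter = 5L, min_shared_kmers = 3L) {
  stopifnot(is.list(proteomes), length(proteomes) >= 2,
            !is.null(names(proteomes)))
  empty <- vapply(proteomes, length, 0L) == 0
  if (any(empty)) {
    warning("excluding strain(s) with zero proteins: ",
            paste(names(proteomes)[empty], collapse = ", "))
    proteomes <- proteomes[!empty]
  }
  if (length(proteomes) < 2) stop("need at least 2 non-empty strains")
  strains <- names(proteomes)
  # sort genes by id so index ties equal lexicographic ties
  proteomes <- lapply(proteomes, function(p) p[order(names(p))])
  all_genes <- unlist(lapply(strains, function(s)
    paste0(s, "|", names(proteomes[[s]]))), use.names = FALSE)

  edges <- list()
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (j <= i) next
      pa <- proteomes[[i]]; pb <- proteomes[[j]]
      bh <- cpp_best_hits(unname(pa), unname(pb),
                          scoring$match, scoring$mismatch, scoring$gap,
                          as.integer(kmer_prefilter),
                          as.integer(if (kmer_prefilter > 0)
                            min_shared_kmers else 0L))
      ia <- seq_along(pa)
      recip <- bh$best_a > 0 & bh$best_b[pmax(bh$best_a, 1)] == ia
      keep <- recip & bh$identity_a >= min_identity & bh$score_a > min_score
      if (any(keep)) {
        edges[[length(edges) + 1L]] <- data.frame(
          strain1 = strains[i], gene1 = names(pa)[keep],
          strain2 = strains[j], gene2 = names(pb)[bh$best_a[keep]],
          score = bh$score_a[keep], identity = bh$identity_a[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(strain1 = character(0), gene1 = character(0),
               strain2 = character(0), gene2 = character(0),
               score = numeric(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "genes") <- all_genes
  out
}

#' Cluster genes into ortholog families
#'
#' Families are the connected components of the reciprocal-best-hit graph
#' (single linkage); genes with no edge form singleton families. Family ids
#' are assigned deterministically in order of each component's smallest
#' member id.
#'
#' @param edges edge data frame from [build_rbh_graph()].
#' @param all_genes character vector of every gene as `strain|gene`;
#'   defaults to the attribute carried by `edges`.
#' @return Data frame with columns `family_id`, `strain`, `gene_id`.
#' @export
cluster_families <- function(edges, all_genes = attr(edges, "genes")) {
  stopifnot(!is.null(all_genes), !anyDuplicated(all_genes))
  g <- igraph::make_empty_graph(n = length(all_genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_genes)
  if (nrow(edges) > 0) {
    v1 <- paste0(edges$strain1, "|", edges$gene1)
    v2 <- paste0(edges$strain2, "|", edges$gene2)
    if (!all(c(v1, v2) %in% all_genes))
      stop("edges reference genes not in the gene universe")
    g <- igraph::add_edges(g, rbind(match(v1, all_genes),
                                    match(v2, all_genes)))
  }
  comp <- igraph::components(g)$membership
  # deterministic ids: order components by their smallest member id
  first <- tapply(all_genes, comp, min)
  rank <- match(comp, as.integer(names(sort(first))))
  fam <- sprintf("FAM%05d", rank)
  parts <- strsplit(all_genes, "|", fixed = TRUE)
  out <- data.frame(family_id = fam,
                    strain = vapply(parts, `[`, "", 1),
                    gene_id = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out[order(out$family_id, out$strain, out$gene_id), , drop = FALSE]
}

#' Extract the single-copy core families
#'
#' Keeps exactly the families with one member in every listed genome.
#'
#' @param families data frame from [cluster_families()].
#' @param genome_list character vector of genome/strain ids.
#' @return Character vector of single-copy core family ids.
#' @export
single_copy_core <- function(families, genome_list) {
  if (length(genome_list) == 0) stop("empty genome list")
  tab <- table(families$family_id, families$strain)
  tab <- tab[, intersect(genome_list, colnames(tab)), drop = FALSE]
  if (ncol(tab) < length(genome_list)) return(character(0))
  keep <- rowSums(tab == 1) == length(genome_list) &
    rowSums(tab) == length(genome_list)
  sort(rownames(tab)[keep])
}
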