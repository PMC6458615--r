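#' Center-star multiple sequence alignment
#'
#' Picks the center sequence minimizing the sum of pairwise edit distances
#' (ties: first in input order), aligns every other sequence to the center
#' by global dynamic programming, and merges the pairwise alignments with
#' the once-a-gap-always-a-gap rule. Adequate for the low-divergence
#' single-copy core genes this pipeline aligns, and fully deterministic.
#'
#' @param seqs named character vector, one nucleotide sequence per taxon.
#' @param scoring scoring for the center-to-sequence alignments.
#' @param band optional half-width of a banded dynamic program (`-1` = full,
#'   exact DP). A band is exact whenever the optimal alignment needs at most
#'   `band` indel columns, which holds for substitution-dominated homologs.
#' @return Named character vector of aligned sequences (equal lengths), with
#'   attribute `center` naming the center taxon.
#' @export
center_star_msa <- function(seqs,
                            scoring = scoring_params(match = 1,
                                                     mismatch = -1,
                                                     gap = -2),
                            band = -1L) {
  if (length(seqs) == 0) stop("empty input")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (length(seqs) == 1) return(seqs)
  if (length(unique(seqs)) == 1) {
    out <- seqs
    attr(out, "center") <- names(seqs)[1]
    return(out)
  }
  # center = min total edit distance (unit-cost alignment)
  sc <- cpp_score_matrix(unname(seqs), 0, -1, -1, as.integer(band))
  tot <- rowSums(-sc)
  ci <- which.min(tot)
  center <- seqs[[ci]]
  L <- nchar(center)

  others <- setdiff(seq_along(seqs), ci)
  # ins_counts[[s]][k] = gaps in the center immediately before center char k
  # (k in 1..L+1; L+1 = trailing insertions)
  aln <- vector("list", length(seqs))
  ins <- matrix(0L, nrow = length(seqs), ncol = L + 1)
  blocks <- vector("list", length(seqs))
  for (s in others) {
    a <- cpp_align_pair(center, seqs[[s]], scoring$match, scoring$mismatch,
                        scoring$gap, as.integer(band))
    ca <- strsplit(a$a_aln, "")[[1]]
    sa <- strsplit(a$b_aln, "")[[1]]
    segs <- vector("list", L + 1)
    cur <- character(0)
    k <- 1L
    for (t in seq_along(ca)) {
      if (ca[t] == "-") {
        cur <- c(cur, sa[t])
      } else {
        segs[[k]] <- list(insert = cur, char = sa[t])
        cur <- character(0)
        k <- k + 1L
      }
    }
    segs[[L + 1]] <- list(insert = cur, char = NULL)
    blocks[[s]] <- segs
    ins[s, ] <- vapply(segs, function(x) length(x$insert), 0L)
  }
  max_ins <- apply(ins, 2, max)

  rows <- character(length(seqs))
  # center row
  cch <- strsplit(center, "")[[1]]
  parts <- character(0)
  for (k in seq_len(L))
    parts <- c(parts, strrep("-", max_ins[k]), cch[k])
  parts <- c(parts, strrep("-", max_ins[L + 1]))
  rows[ci] <- paste(parts, collapse = "")
  for (s in others) {
    segs <- blocks[[s]]
    parts <- character(0)
    for (k in seq_len(L)) {
      insrt <- segs[[k]]$insert
      parts <- c(parts, paste(insrt, collapse = ""),
                 strrep("-", max_ins[k] - length(insrt)), segs[[k]]$char)
    }
    insrt <- segs[[L + 1]]$insert
    parts <- c(parts, paste(insrt, collapse = ""),
               strrep("-", max_ins[L + 1] - length(insrt)))
    rows[s] <- paste(parts, collapse = "")
  }
  names(rows) <- names(seqs)
  attr(rows, "center") <- names(seqs)[ci]
  rows
}

#' Concatenate gene alignments and extract SNP columns
#'
#' Gene alignments are concatenated in the given reference gene order
#' (mirroring integration along the reference genome's gene arrangement).
#' Columns containing any gap or ambiguous character are dropped
#' (complete deletion); of the rest, only polymorphic columns are kept.
#'
#' @param alignments named list of aligned blocks (named character vectors
#'   with identical taxa).
#' @param gene_order character vector of gene names in reference order;
#'   defaults to `names(alignments)`.
#' @return Object of class `snp_matrix`: list with `snps` (character matrix,
#'   taxa x variable sites), `provenance` (data frame `gene`, `offset`:
#'   column within that gene's alignment), and `n_total_sites` (gap-free
#'   unambiguous columns before the polymorphism filter).
#' @export
concat_and_extract_snps <- function(alignments, gene_order = names(alignments)) {
  stopifnot(length(alignments) >= 1, !is.null(gene_order))
  taxa <- sort(names(alignments[[1]]))
  snp_cols <- list()
  prov <- list()
  n_total <- 0L
  for (gene in gene_order) {
    blk <- alignments[[gene]]
    if (is.null(blk)) stop("gene absent from alignments: ", gene)
    if (!identical(sort(names(blk)), taxa))
      stop("taxa mismatch across genes at gene: ", gene)
    m <- do.call(rbind, strsplit(blk[taxa], ""))
    rownames(m) <- taxa
    ok <- colSums(m == "A" | m == "C" | m == "G" | m == "T") == nrow(m)
    n_total <- n_total + sum(ok)
    if (!any(ok)) next
    keep <- which(ok)[apply(m[, ok, drop = FALSE], 2,
                            function(col) length(unique(col)) > 1)]
    if (length(keep)) {
      snp_cols[[length(snp_cols) + 1L]] <- m[, keep, drop = FALSE]
      prov[[length(prov) + 1L]] <- data.frame(gene = gene, offset = keep,
                                              stringsAsFactors = FALSE)
    }
  }
  snps <- if (length(snp_cols)) do.call(cbind, snp_cols) else
    matrix(character(0), nrow = length(taxa), ncol = 0,
           dimnames = list(taxa, NULL))
  structure(list(snps = snps,
                 provenance = if (length(prov)) do.call(rbind, prov) else
                   data.frame(gene = character(0), offset = integer(0)),
                 n_total_sites = n_total),
            class = "snp_matrix")
}

#' Distance matrix from a SNP matrix
#'
#' Pairwise differences are counted over the SNP columns and divided by the
#' total number of retained (gap-free) columns, giving the p-distance over
#' the concatenated alignment. Corrections: `"jc"` applies
#' `d = -(3/4) ln(1 - 4p/3)` (undefined at `p >= 0.75`, which raises an
#' error), `"poisson"` applies `d = -ln(1 - p)`.
#'
#' @param snp_obj a [concat_and_extract_snps()] result.
#' @param model `"p"`, `"jc"`, or `"poisson"`.
#' @return Symmetric distance matrix with the model recorded in attribute
#'   `model`.
#' @export
snp_distance_matrix <- function(snp_obj, model = c("p", "jc", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(snp_obj, "snp_matrix"))
  m <- snp_obj$snps
  taxa <- rownames(m)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  tot <- snp_obj$n_total_sites
  if (tot == 0) stop("no usable alignment columns")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- sum(m[i, ] != m[j, ]) / tot
      v <- switch(model,
        p = p,
        jc = {
          if (p >= 0.75)
            stop("JC distance undefined at p >= 0.75 (p = ", round(p, 4), ")")
          -0.75 * log(1 - 4 * p / 3)
        },
        poisson = {
          if (p >= 1) stop("Poisson distance undefined at p >= 1")
          -log(1 - p)
        })
      d[i, j] <- d[j, i] <- v
    }
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration on the Q criterion. Ties in Q are
#' broken by the smallest `(i, j)` index pair (input order). Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling edge,
#' preserving the joined pair's path length. The result is unrooted (root
#' trifurcation); an outgroup taxon can be named to root it.
#'
#' @param d symmetric non-negative distance matrix with a zero diagonal and
#'   dimnames.
#' @param outgroup optional taxon label to root on.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (is.null(dim(d)) || nrow(d) != ncol(d) || is.null(rownames(d)))
    stop("d must be a square matrix with dimnames")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(d < 0)) stop("validation error: negative distances")
  if (max(abs(d - t(d))) > 1e-9) stop("validation error: non-symmetric matrix")
  if (any(diag(d) != 0)) stop("validation error: nonzero diagonal")

  labels <- rownames(d)
  nodes <- labels            # newick fragments per active node
  D <- d
  while (length(nodes) > 3) {
    n <- length(nodes)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j) with i < j among Q minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], vi, nodes[j], vj)
    others <- setdiff(seq_len(n), c(i, j))
    dn <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dn),
                c(dn, 0))
    nodes <- c(nodes[others], newnode)
    D <- D2
  }
  # final three-node star: closed-form branch lengths
  v1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], v1, nodes[2], v2, nodes[3], v3)
  phy <- ape::read.tree(text = nwk)
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label) stop("outgroup not in taxa: ", outgroup)
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  phy
}

# tip label sets below every node (index = node number)
node_tipsets <- function(phy) {
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical key for the non-trivial bipartition below a node, or NA
canonical_split <- function(tips, all_taxa) {
  k <- length(tips)
  n <- length(all_taxa)
  if (k < 2 || k > n - 2) return(NA_character_)
  ref <- min(all_taxa)
  if (ref %in% tips) tips <- setdiff(all_taxa, tips)
  paste(sort(tips), collapse = "\r")
}

tree_split_keys <- function(phy) {
  nt <- length(phy$tip.label)
  sets <- node_tipsets(phy)
  keys <- vapply(seq_len(phy$Nnode) + nt, function(v)
    canonical_split(sets[[v]], phy$tip.label), "")
  keys
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full SNP matrix, then resamples SNP columns
#' with replacement `n_reps` times, rebuilds the tree per replicate, and
#' annotates each internal edge of the original tree with the percentage of
#' replicates containing the same bipartition.
#'
#' @param snp_obj a [concat_and_extract_snps()] result with >= 1 column.
#' @param n_reps number of bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @param model distance model, see [snp_distance_matrix()].
#' @param outgroup optional taxon to root the annotated tree on.
#' @return The original NJ tree with `node.label` holding support
#'   percentages (empty for trivial/root splits).
#' @export
bootstrap_support <- function(snp_obj, n_reps = 100, seed = 1,
                              model = "p", outgroup = NULL) {
  stopifnot(inherits(snp_obj, "snp_matrix"), ncol(snp_obj$snps) >= 1)
  d0 <- snp_distance_matrix(snp_obj, model)
  phy <- nj_tree(d0)
  keys <- tree_split_keys(phy)
  counts <- setNames(rep(0L, length(keys)), keys)
  ncols <- ncol(snp_obj$snps)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      idx <- sample.int(ncols, ncols, replace = TRUE)
      rep_obj <- structure(list(snps = snp_obj$snps[, idx, drop = FALSE],
                                provenance = NULL,
                                n_total_sites = snp_obj$n_total_sites),
                           class = "snp_matrix")
      rphy <- nj_tree(snp_distance_matrix(rep_obj, model))
      rkeys <- tree_split_keys(rphy)
      hit <- !is.na(keys) & keys %in% rkeys
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- ifelse(is.na(keys), "", as.character(100 * counts / n_reps))
  phy$node.label <- support
  if (!is.null(outgroup))
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE)
  phy
}
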