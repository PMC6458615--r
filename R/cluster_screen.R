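#' Blast-score-ratio of a query gene against one genome's gene set
#'
#' BSR = best global-alignment score of the query against any gene of the
#' genome, divided by the query's self-alignment score, clamped to `[0, 1]`.
#' A query screened against the genome that carries it verbatim scores 1.
#'
#' @param query protein (or nucleotide) sequence of the query gene.
#' @param genes character vector of the genome's gene sequences (same
#'   alphabet as the query).
#' @param scoring a [scoring_params()] list (positive match score required).
#' @param kmer_prefilter,min_shared_kmers shared-k-mer prefilter; pairs
#'   sharing fewer k-mers score 0.
#' @return BSR value in `[0, 1]`.
#' @export
compute_bsr <- function(query, genes, scoring = scoring_params(),
                        kmer_prefilter = 5L, min_shared_kmers = 1L) {
  if (!nzchar(query)) stop("empty query")
  self_score <- scoring$match * nchar(query)
  stopifnot(self_score > 0)
  if (length(genes) == 0) return(0)
  best <- cpp_best_scores(query, unname(genes),
                          scoring$match, scoring$mismatch, scoring$gap,
                          as.integer(kmer_prefilter),
                          as.integer(min_shared_kmers))
  min(max(best / self_score, 0), 1)
}

#' Screen reference gene clusters across a genome panel
#'
#' Computes the BSR of every cluster gene against each panel genome's gene
#' set and calls each gene `present` (BSR >= `present_min`), `divergent`
#' (>= `divergent_min`), or `absent`. A cluster is called present in a
#' genome when at least a fraction `f` of its genes are present.
#'
#' @param clusters named list; each element is a named character vector of
#'   gene sequences for one cluster (from the reference genome).
#' @param panel named list of [genome_record()]s (their `proteins` or `cds`
#'   are screened, per `seq_type`).
#' @param seq_type `"protein"` or `"cds"`.
#' @param scoring a [scoring_params()] list.
#' @param present_min,divergent_min BSR thresholds for the calls.
#' @param f fraction of present genes required to call a cluster present.
#' @return List with `bsr` (gene x genome matrix), `calls` (same shape,
#'   character), `genes` (data frame `cluster`, `gene`), and `summary`
#'   (cluster x genome logical presence matrix).
#' @export
screen_clusters <- function(clusters, panel, seq_type = c("protein", "cds"),
                            scoring = scoring_params(),
                            present_min = 0.8, divergent_min = 0.4,
                            f = 0.8) {
  seq_type <- match.arg(seq_type)
  stopifnot(length(panel) >= 1, !is.null(names(panel)))
  keep <- vapply(clusters, length, 0L) > 0
  if (!all(keep)) {
    warning("skipping zero-gene cluster(s): ",
            paste(names(clusters)[!keep], collapse = ", "))
    clusters <- clusters[keep]
  }
  if (length(clusters) == 0) stop("no non-empty clusters to screen")
  gene_tab <- data.frame(
    cluster = rep(names(clusters), lengths(clusters)),
    gene = unlist(lapply(clusters, names), use.names = FALSE),
    stringsAsFactors = FALSE)
  queries <- unlist(lapply(clusters, unname), use.names = FALSE)
  genomes <- names(panel)
  bsr <- matrix(0, nrow = length(queries), ncol = length(genomes),
                dimnames = list(paste(gene_tab$cluster, gene_tab$gene,
                                      sep = "|"), genomes))
  for (g in genomes) {
    genes <- if (seq_type == "protein") panel[[g]]$proteins else
      panel[[g]]$cds
    if (is.null(genes) || length(genes) == 0) next
    best <- cpp_best_scores(queries, unname(genes),
                            scoring$match, scoring$mismatch, scoring$gap,
                            5L, 1L)
    bsr[, g] <- pmin(pmax(best / (scoring$match * nchar(queries)), 0), 1)
  }
  calls <- matrix(ifelse(bsr >= present_min, "present",
                  ifelse(bsr >= divergent_min, "divergent", "absent")),
                  nrow = nrow(bsr), dimnames = dimnames(bsr))
  summary <- matrix(FALSE, length(clusters), length(genomes),
                    dimnames = list(names(clusters), genomes))
  for (cl in names(clusters)) {
    rows <- which(gene_tab$cluster == cl)
    summary[cl, ] <- colMeans(calls[rows, , drop = FALSE] == "present") >= f
  }
  list(bsr = bsr, calls = calls, genes = gene_tab, summary = summary)
}

# GC fraction over A/C/G/T only (ambiguous bases excluded from the
# denominator); NA when no unambiguous base is present.
gc_fraction <- function(seq) {
  counts <- gc_counts(seq)
  if (counts[2] == 0) return(NA_real_)
  counts[1] / counts[2]
}

# returns c(gc_bases, acgt_bases)
gc_counts <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  acgt <- s %in% c("A", "C", "G", "T")
  c(sum(s %in% c("G", "C")), sum(acgt))
}

#' Scan annotated regions for deviant GC content
#'
#' Computes each region's GC fraction and compares it against the null
#' distribution of GC over non-overlapping windows tiling the genome: the
#' z-score is `(region GC - window mean) / window sd`, and a region is
#' flagged as a putative horizontal acquisition when `|z| >= z_threshold`.
#' GC denominators exclude ambiguous bases throughout.
#'
#' @param genome a [genome_record()] or named character vector of contigs.
#' @param regions data frame with columns `region_id`, `contig`, `start`,
#'   `end` (internal 0-based half-open); defaults to the record's cluster
#'   annotations.
#' @param window null-model window size in bp (full windows only enter the
#'   null; the trailing partial window is excluded).
#' @param z_threshold flagging threshold on `|z|`.
#' @return Data frame: `region_id`, `region_gc`, `genome_gc`, `delta_gc`
#'   (percentage points), `z`, `flag`, `low_confidence` (regions under
#'   200 bp).
#' @export
gc_deviation_scan <- function(genome, regions = NULL, window = 10000L,
                              z_threshold = 2.0) {
  seqs <- seqs_of(genome)
  if (is.null(regions)) {
    if (!inherits(genome, "genome_record") || is.null(genome$clusters))
      stop("no regions given and no cluster annotations on the record")
    regions <- data.frame(region_id = genome$clusters$cluster_id,
                          contig = genome$clusters$contig,
                          start = genome$clusters$start,
                          end = genome$clusters$end,
                          stringsAsFactors = FALSE)
  }
  lens <- nchar(seqs)[regions$contig]
  if (any(is.na(lens) | regions$start < 0 | regions$end > lens))
    stop("region out of genome bounds")
  tot <- c(0, 0)
  win_gc <- numeric(0)
  for (ct in names(seqs)) {
    s <- seqs[[ct]]
    n <- nchar(s)
    tot <- tot + gc_counts(s)
    if (n >= window) {
      starts <- seq(1, n - window + 1, by = window)
      # windows overlapping a queried region are excluded from the null so
      # the tested insertion does not contaminate its own background
      reg <- regions[regions$contig == ct, , drop = FALSE]
      clean <- vapply(starts, function(st)
        !any(reg$start < st - 1 + window & reg$end > st - 1), TRUE)
      win_gc <- c(win_gc, vapply(starts[clean], function(st)
        gc_fraction(substring(s, st, st + window - 1)), 0))
    }
  }
  genome_gc <- tot[1] / tot[2]
  mu <- mean(win_gc)
  # empirical sd, floored by the binomial sampling sd of a window at the
  # genome's GC so near-uniform backgrounds don't produce unbounded z
  sd_floor <- sqrt(genome_gc * (1 - genome_gc) / window)
  sdv <- max(sd(win_gc), sd_floor)
  if (length(win_gc) < 2) sdv <- NA_real_
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    rs <- substring(seqs[[regions$contig[i]]], regions$start[i] + 1,
                    regions$end[i])
    rgc <- gc_fraction(rs)
    z <- if (length(win_gc) >= 2 && !is.na(rgc) && sdv > 0)
      (rgc - mu) / sdv else NA_real_
    data.frame(region_id = regions$region_id[i],
               region_gc = rgc,
               genome_gc = genome_gc,
               delta_gc = 100 * (rgc - genome_gc),
               z = z,
               flag = !is.na(z) && abs(z) >= z_threshold,
               low_confidence = (regions$end[i] - regions$start[i]) < 200,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# length-weighted tiling window GC (includes the trailing partial window);
# reconstructs the genome GC exactly. Exposed for the conservation check.
gc_tiling <- function(seq, window) {
  n <- nchar(seq)
  starts <- seq(1, n, by = window)
  t(vapply(starts, function(st)
    gc_counts(substring(seq, st, min(st + window - 1, n))), c(0, 0)))
}
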